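species	group	lat_range	n_sequences
Acanthonyx petiverii	crab	10N-23S	41
Aratus pisonii	crab	27N-23S	61
Arenaeus cribrarius	crab	36N-26S	44
Armases angustipes	crab	2S-25S	66
Callinectes danae	crab	9N-32S	54
Callinectes ornatus	crab	4N-32S	44
Eriphia gonagra	crab	10N-23S	40
Goniopsis cruentata	crab	20N-25S	62
Leptuca leptodactyla	crab	19N-23S	86
Leptuca thayeri	crab	27N-27S	61
Minuca mordax	crab	2N-29S	113
Minuca rapax	crab	28N-25S	57
Sesarma rectum	crab	10N-24S	42
Uca maracoani	crab	19N-25S	103
Ucides cordatus	crab	23N-23S	52
Calcinus tibicen (N)	hermit crab	27N-9N	36
Calcinus tibicen (S)	hermit crab	3S-27S	28
Clibanarius antillensis	hermit crab	18N-26S	37
Clibanarius symmetricus	hermit crab	0-27S	22
Clibanarius tricolor	hermit crab	25N-12N	167
Hippolyte obliquimanus	shrimp	10N-27S	39
Thor amboinensis	shrimp	32N-9N	302
Panulirus argus	lobster	26N-17N	326
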