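#' Pairwise per-site distance matrix between haplotypes
#'
#' Raw difference proportions over the retained site set; no model correction
#' is applied, matching the raw-difference definitions the estimators use.
#'
#' @param haplotypes Character vector of equal-length haplotype strings.
#' @return Symmetric matrix of per-site difference proportions.
#' @export
haplotype_distances <- function(haplotypes) {
  k <- length(haplotypes)
  L <- nchar(haplotypes[1])
  d <- matrix(0, k, k)
  if (k > 1) {
    m <- matrix(unlist(strsplit(haplotypes, "", fixed = TRUE),
                       use.names = FALSE), nrow = k, byrow = TRUE)
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ]) / L
      }
    }
  }
  d
}

#' Nucleotide diversity (Nei)
#'
#' Average number of nucleotide differences per site between two randomly
#' drawn sequences: the mean per-site Hamming distance over all C(n,2)
#' unordered sequence pairs, computed in the equivalent frequency-weighted
#' form `(n/(n-1)) * sum_{i != j} x_i x_j d_ij` with `x_i = count_i / n`.
#'
#' @param sample A `haplotype_sample` (see [collapse_haplotypes()]).
#' @param unbiased Apply the `n/(n-1)` sample-size correction (default); the
#'   biased variant divides pairs by `n^2` instead and is kept for
#'   cross-checks.
#' @return Nucleotide diversity per site.
#' @export
nucleotide_diversity <- function(sample, unbiased = TRUE) {
  n <- sample$n
  if (n < 2) stop_("nucleotide diversity undefined for n < 2")
  x <- sample$counts / n
  d <- haplotype_distances(sample$haplotypes)
  pi_hat <- drop(crossprod(x, d %*% x))
  if (unbiased) pi_hat <- pi_hat * n / (n - 1)
  pi_hat
}

#' Haplotype diversity (Nei)
#'
#' Probability that two randomly drawn sequences carry different haplotypes,
#' regardless of how different: `(n/(n-1)) * (1 - sum_i x_i^2)`.
#'
#' @inheritParams nucleotide_diversity
#' @return Haplotype diversity in \[0, 1\].
#' @export
haplotype_diversity <- function(sample, unbiased = TRUE) {
  n <- sample$n
  if (n < 2) stop_("haplotype diversity undefined for n < 2")
  x <- sample$counts / n
  h <- 1 - sum(x^2)
  if (unbiased) h <- h * n / (n - 1)
  h
}

#' Per-cell diversity estimates
#'
#' Computes nucleotide and haplotype diversity for every retained
#' (species, band) cell. Alignment columns are filtered once per species
#' (complete deletion over that species' analysis sequences), so all of a
#' species' band estimates share one site set.
#'
#' @param cells Retained cells from [apply_species_filters()].
#' @param records Record table that the cells reference.
#' @return Data frame with columns `species_id`, `band`, `n`, `L`, `pi`,
#'   `hd`, ordered by species then band.
#' @export
estimate_all <- function(cells, records) {
  if (nrow(cells) == 0) stop_("no cells to estimate")
  out <- vector("list", nrow(cells))
  for (sp in unique(cells$species_id)) {
    sp_rows <- which(cells$species_id == sp)
    accs <- unlist(cells$accessions[sp_rows], use.names = FALSE)
    ridx <- match(accs, records$accession)
    if (anyNA(ridx)) stop_("species ", sp, ": cell references unknown accession")
    fs <- tryCatch(filter_alignment_sites(records$sequence[ridx]),
                   error = function(e) stop_("species ", sp, ": ",
                                             conditionMessage(e)))
    seq_by_acc <- stats::setNames(fs$sequences, accs)
    for (i in sp_rows) {
      cell_accs <- cells$accessions[[i]]
      hs <- collapse_haplotypes(seq_by_acc[cell_accs], sp, cells$band[i])
      res <- tryCatch(
        data.frame(species_id = sp, band = cells$band[i], n = hs$n, L = hs$L,
                   pi = nucleotide_diversity(hs), hd = haplotype_diversity(hs),
                   stringsAsFactors = FALSE),
        error = function(e) stop_("species ", sp, ", band ", cells$band[i],
                                  ": ", conditionMessage(e))
      )
      out[[i]] <- res
    }
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$species_id, tab$band), ]
  rownames(tab) <- NULL
  tab
}
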