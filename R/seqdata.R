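#' Read georeferenced COI sequence records
#'
#' Joins an aligned FASTA file against a per-individual metadata table to give
#' one record per sequence. The join key is the FASTA identifier up to the
#' first whitespace (GenBank-style headers). Within each `species_id` all
#' aligned sequences must have equal length; split lineages should carry
#' distinct `species_id` labels (e.g. `"Calcinus_tibicen_N"` /
#' `"Calcinus_tibicen_S"`).
#'
#' @param fasta Path to a (plain or gzipped) FASTA file.
#' @param metadata Path to a CSV/TSV file, or a data frame, with columns
#'   `accession`, `species_id`, `latitude`, `longitude`.
#' @return A data frame with columns `accession`, `species_id`, `latitude`,
#'   `longitude`, `sequence` (upper-case IUPAC strings).
#' @export
read_records <- function(fasta, metadata) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  meta <- read_metadata(metadata)
  missing <- setdiff(ids, meta$accession)
  if (length(missing) > 0) {
    stop_("FASTA id(s) absent from metadata: ", paste(missing, collapse = ", "))
  }
  m <- meta[match(ids, meta$accession), ]
  rec <- data.frame(
    accession = ids,
    species_id = as.character(m$species_id),
    latitude = m$latitude,
    longitude = m$longitude,
    sequence = toupper(as.character(seqs)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  validate_records(rec)
  rec
}

read_metadata <- function(metadata) {
  if (is.character(metadata)) {
    metadata <- if (grepl("\\.csv(\\.gz)?$", metadata, ignore.case = TRUE)) {
      utils::read.csv(metadata, stringsAsFactors = FALSE)
    } else {
      utils::read.delim(metadata, stringsAsFactors = FALSE)
    }
  }
  need <- c("accession", "species_id", "latitude", "longitude")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0) stop_("metadata lacks column(s): ", paste(miss, collapse = ", "))
  metadata$accession <- as.character(metadata$accession)
  for (col in c("latitude", "longitude")) {
    v <- metadata[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (anyNA(vn) && !all(is.na(v) == is.na(vn))) {
        stop_("non-numeric ", col, " in metadata")
      }
      metadata[[col]] <- vn
    }
  }
  metadata
}

#' Validate a record table
#'
#' Checks the record invariants: unique accessions, finite in-range
#' coordinates, non-empty sequences, and equal aligned length within each
#' `species_id`.
#'
#' @param records Data frame as returned by [read_records()].
#' @return `records`, invisibly, on success; otherwise a hard error.
#' @export
validate_records <- function(records) {
  if (nrow(records) == 0) stop_("empty record table")
  if (anyDuplicated(records$accession)) {
    stop_("duplicated accession(s): ",
          paste(unique(records$accession[duplicated(records$accession)]),
                collapse = ", "))
  }
  lat <- records$latitude
  if (!is.numeric(lat) || anyNA(lat) || any(!is.finite(lat)) ||
      any(lat < -90 | lat > 90)) {
    stop_("latitude must be finite and within [-90, 90]")
  }
  lon <- records$longitude
  if (!is.numeric(lon) || anyNA(lon) || any(!is.finite(lon)) ||
      any(lon < -180 | lon > 180)) {
    stop_("longitude must be finite and within [-180, 180]")
  }
  if (any(!nzchar(records$sequence))) stop_("empty sequence(s) present")
  lens <- split(nchar(records$sequence), records$species_id)
  bad <- names(lens)[vapply(lens, function(x) length(unique(x)) > 1L, logical(1))]
  if (length(bad) > 0) {
    stop_("unequal aligned sequence lengths within species: ",
          paste(bad, collapse = ", "))
  }
  invisible(records)
}

#' Complete-deletion site filtering
#'
#' Removes every alignment column that contains a gap (`-`) or any symbol
#' other than A, C, G, T in any sequence, so all downstream per-site
#' denominators refer to one unambiguous site set. Idempotent.
#'
#' @param sequences Character vector of equal-length nucleotide strings.
#' @return A list with `sequences` (filtered strings), `L` (number of retained
#'   columns) and `kept` (0-based indices of retained columns, for audit).
#' @export
filter_alignment_sites <- function(sequences) {
  if (length(sequences) < 1) stop_("no sequences supplied")
  lens <- unique(nchar(sequences))
  if (length(lens) != 1) stop_("sequences must have equal aligned length")
  mat <- matrix(
    unlist(strsplit(toupper(sequences), "", fixed = TRUE), use.names = FALSE),
    nrow = length(sequences), byrow = TRUE
  )
  good <- matrix(mat %in% c("A", "C", "G", "T"), nrow = nrow(mat))
  keep <- colSums(good) == nrow(mat)
  if (!any(keep)) stop_("no usable sites after complete deletion")
  sub <- mat[, keep, drop = FALSE]
  out <- apply(sub, 1L, paste0, collapse = "")
  list(sequences = as.character(out), L = sum(keep), kept = which(keep) - 1L)
}

#' Collapse sequences to a haplotype sample
#'
#' Groups identical (site-filtered) sequences into distinct haplotypes with
#' multiplicities. Haplotype identity is exact string equality on the retained
#' columns; ordering follows first occurrence in the input.
#'
#' @param sequences Character vector of equal-length, site-filtered strings.
#' @param species_id Species/lineage label for the cell.
#' @param band Signed integer latitudinal band for the cell.
#' @return An object of class `haplotype_sample`: a list with `species_id`,
#'   `band`, `haplotypes`, `counts`, `n` and `L`.
#' @export
collapse_haplotypes <- function(sequences, species_id = NA_character_,
                                band = NA_integer_) {
  if (length(sequences) < 1) stop_("no sequences to collapse")
  lens <- unique(nchar(sequences))
  if (length(lens) != 1) stop_("sequences must have equal length")
  u <- unique(sequences)
  counts <- as.integer(table(factor(sequences, levels = u)))
  structure(
    list(species_id = species_id, band = as.integer(band),
         haplotypes = u, counts = counts,
         n = length(sequences), L = lens),
    class = "haplotype_sample"
  )
}

#' @export
print.haplotype_sample <- function(x, ...) {
  cat(sprintf("haplotype sample: %s, band %s\n", x$species_id, x$band))
  cat(sprintf("  n = %d sequences, %d haplotypes, L = %d usable sites\n",
              x$n, length(x$haplotypes), x$L))
  cat("  counts:", paste(x$counts, collapse = " "), "\n")
  invisible(x)
}

#' Expand a haplotype sample back to sequences
#'
#' Inverse of [collapse_haplotypes()] up to sequence order: each haplotype is
#' repeated according to its count.
#'
#' @param sample A `haplotype_sample`.
#' @return Character vector of `sample$n` sequences.
#' @export
expand_haplotypes <- function(sample) {
  rep(sample$haplotypes, sample$counts)
}

#' Write haplotype tables to TSV
#'
#' @param samples A list of `haplotype_sample` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(samples, path) {
  rows <- do.call(rbind, lapply(samples, function(s) {
    data.frame(species_id = s$species_id, band = s$band,
               haplotype_index = seq_along(s$haplotypes) - 1L,
               count = s$counts, sequence = s$haplotypes,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
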