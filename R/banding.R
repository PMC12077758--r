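#' Assign one-degree latitudinal bands
#'
#' Truncates latitude toward the equator, keeping the hemisphere in the sign:
#' band = sign(latitude) * floor(|latitude|). Locations at 23°34'S and
#' 23°12'S both fall in band -23; sub-degree latitudes of either hemisphere
#' share band 0.
#'
#' @param latitude Numeric vector of signed decimal degrees in \[-90, 90\].
#' @param absolute If `TRUE`, bands are unsigned (`floor(|latitude|)`),
#'   collapsing the two hemispheres; the default keeps them distinct.
#' @return Integer vector of bands.
#' @export
assign_band <- function(latitude, absolute = FALSE) {
  if (!is.numeric(latitude) || anyNA(latitude) || any(!is.finite(latitude))) {
    stop_("latitude must be finite numeric")
  }
  if (any(latitude < -90 | latitude > 90)) stop_("latitude outside [-90, 90]")
  b <- trunc(latitude)
  if (absolute) b <- abs(b)
  as.integer(b)
}

#' Build per-(species, band) cells from records
#'
#' @param records Record table from [read_records()].
#' @param absolute Passed to [assign_band()].
#' @return Data frame with columns `species_id`, `band`, `n` and a list-column
#'   `accessions` holding the member record ids; one row per occupied cell,
#'   ordered by species then band.
#' @export
band_cells <- function(records, absolute = FALSE) {
  if (nrow(records) == 0) stop_("empty record table")
  band <- assign_band(records$latitude, absolute = absolute)
  key <- paste(records$species_id, band, sep = "\r")
  idx <- split(seq_len(nrow(records)), key)
  cells <- data.frame(
    species_id = vapply(idx, function(i) records$species_id[i[1]], character(1)),
    band = vapply(idx, function(i) band[i[1]], integer(1)),
    n = lengths(idx),
    stringsAsFactors = FALSE, row.names = NULL
  )
  cells$accessions <- I(lapply(idx, function(i) records$accession[i]))
  cells <- cells[order(cells$species_id, cells$band), ]
  rownames(cells) <- NULL
  cells
}

#' Apply the study inclusion filters
#'
#' Drops cells with fewer than `min_n` sequences, then drops whole species
#' whose surviving number of distinct bands falls below `min_bands`. Every
#' drop is recorded with its reason.
#'
#' @param cells Cell table from [band_cells()].
#' @param min_n Minimum sequences per band cell (default 3).
#' @param min_bands Minimum distinct bands per species after the cell filter
#'   (default 4).
#' @return A list with `cells` (retained rows) and `report`, a
#'   `filter_report` holding `dropped_cells`, `dropped_species`,
#'   `retained_cells` and `unique_bands`.
#' @export
apply_species_filters <- function(cells, min_n = 3, min_bands = 4) {
  if (is.null(cells) || nrow(cells) == 0) stop_("empty cell table")
  small <- cells$n < min_n
  dropped_cells <- data.frame(
    species_id = cells$species_id[small], band = cells$band[small],
    n = cells$n[small],
    reason = rep(sprintf("n < %d", min_n), sum(small)),
    stringsAsFactors = FALSE
  )
  kept <- cells[!small, , drop = FALSE]
  nb <- tapply(kept$band, kept$species_id, function(b) length(unique(b)))
  bad_sp <- names(nb)[nb < min_bands]
  dropped_species <- data.frame(
    species_id = bad_sp,
    n_bands = as.integer(nb[bad_sp]),
    reason = rep("insufficient bands", length(bad_sp)),
    stringsAsFactors = FALSE
  )
  sp_cells <- kept$species_id %in% bad_sp
  dropped_cells <- rbind(dropped_cells, data.frame(
    species_id = kept$species_id[sp_cells], band = kept$band[sp_cells],
    n = kept$n[sp_cells],
    reason = rep("species dropped: insufficient bands", sum(sp_cells)),
    stringsAsFactors = FALSE
  ))
  retained <- kept[!sp_cells, , drop = FALSE]
  rownames(retained) <- NULL
  report <- structure(
    list(dropped_cells = dropped_cells[order(dropped_cells$species_id,
                                             dropped_cells$band), ],
         dropped_species = dropped_species,
         retained_cells = nrow(retained),
         unique_bands = length(unique(retained$band))),
    class = "filter_report"
  )
  list(cells = retained, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter report: %d cells retained across %d unique bands\n",
              x$retained_cells, x$unique_bands))
  cat(sprintf("  dropped cells: %d; dropped species: %d\n",
              nrow(x$dropped_cells), nrow(x$dropped_species)))
  invisible(x)
}

#' Restrict pooled analyses to multispecies bands
#'
#' For the total (pooled, all-species) analyses, only bands represented by
#' more than one species are kept. Intraspecific analyses never use this
#' filter.
#'
#' @param estimates Data frame carrying `species_id` and `band` columns.
#' @return The rows of `estimates` whose band hosts at least two species.
#' @export
multispecies_band_filter <- function(estimates) {
  nsp <- tapply(estimates$species_id, estimates$band,
                function(s) length(unique(s)))
  keep_bands <- as.integer(names(nsp)[nsp >= 2])
  out <- estimates[estimates$band %in% keep_bands, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample-size quality-control regression
#'
#' Regresses a diversity metric on the number of sequences behind each
#' estimate, iteratively excluding rows with externally studentized residuals
#' beyond `threshold` (a reproducible stand-in for visual outlier removal),
#' and reports whether sample size interferes with the estimates.
#'
#' @param estimates Diversity table with columns `n` and the chosen metric.
#' @param metric `"pi"` or `"hd"`.
#' @param threshold Absolute externally studentized residual above which a row
#'   is excluded (default 3).
#' @param max_iter Maximum exclusion sweeps (default 20).
#' @return A `qc_report`: slope, two-sided p-value, excluded rows, iteration
#'   count and rows used.
#' @export
sample_size_qc <- function(estimates, metric = c("pi", "hd"), threshold = 3,
                           max_iter = 20) {
  metric <- match.arg(metric)
  if (nrow(estimates) < 10) stop_("need at least 10 rows for the QC regression")
  d <- data.frame(y = estimates[[metric]], n = estimates$n)
  id <- if (all(c("species_id", "band") %in% names(estimates))) {
    paste(estimates$species_id, estimates$band, sep = ":")
  } else {
    as.character(seq_len(nrow(estimates)))
  }
  excluded <- character(0)
  iter <- 0L
  repeat {
    if (nrow(d) < 3) stop_("all rows excluded by the QC outlier rule")
    fit <- stats::lm(y ~ n, data = d)
    if (iter >= max_iter) break
    rs <- stats::rstudent(fit)
    rs[!is.finite(rs)] <- 0
    bad <- which(abs(rs) > threshold)
    if (length(bad) == 0) break
    excluded <- c(excluded, id[bad])
    d <- d[-bad, , drop = FALSE]
    id <- id[-bad]
    iter <- iter + 1L
  }
  # degenerate (perfect-fit) regressions are legitimate here, e.g. a
  # constant metric; lm's perfect-fit warning is not informative
  co <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(co["n", "Estimate"])
  p <- if (nrow(co) > 1) unname(co["n", "Pr(>|t|)"]) else NA_real_
  structure(
    list(metric = metric, slope = slope, p_value = p,
         excluded_rows = excluded, n_excluded = length(excluded),
         iterations = iter, n_used = nrow(d), threshold = threshold),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("sample-size QC (%s ~ n): slope %.4g, p = %.4g\n",
              x$metric, x$slope, x$p_value))
  cat(sprintf("  %d row(s) excluded (|studentized residual| > %g), %d used\n",
              x$n_excluded, x$threshold, x$n_used))
  invisible(x)
}
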