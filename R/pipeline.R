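#' Analysis run configuration
#'
#' Flat key-value configuration for [run_pipeline()]. Every default equals
#' the analysis protocol's stated value, so a bare run applies the full
#' published procedure to the supplied data.
#'
#' @param min_n Minimum sequences per band cell (default 3).
#' @param min_bands Minimum distinct bands per species (default 4).
#' @param r_max Pairwise correlation threshold for collinearity (default 0.7).
#' @param vif_max VIF threshold (default 5).
#' @param delta_aic AIC equivalence gap (default 2).
#' @param delta_aicc AICc top-set gap (default 2).
#' @param ci_level Confidence level for averaged coefficients (default 0.95).
#' @param bootstrap_B Parametric bootstrap replicates (default 1000).
#' @param band_mode `"signed"` (default; hemisphere kept in the band sign) or
#'   `"absolute"`.
#' @param qc_threshold Studentized-residual cutoff for the sample-size QC
#'   (default 3).
#' @param max_order Highest polynomial order in the ladders (default 4).
#' @param seed Integer seed governing every stochastic stage.
#' @return A validated `run_config` list.
#' @export
run_config <- function(min_n = 3, min_bands = 4, r_max = 0.7, vif_max = 5,
                       delta_aic = 2, delta_aicc = 2, ci_level = 0.95,
                       bootstrap_B = 1000, band_mode = c("signed", "absolute"),
                       qc_threshold = 3, max_order = 4, seed = 1) {
  band_mode <- match.arg(band_mode)
  cfg <- list(min_n = min_n, min_bands = min_bands, r_max = r_max,
              vif_max = vif_max, delta_aic = delta_aic,
              delta_aicc = delta_aicc, ci_level = ci_level,
              bootstrap_B = bootstrap_B, band_mode = band_mode,
              qc_threshold = qc_threshold, max_order = max_order, seed = seed)
  num <- setdiff(names(cfg), c("band_mode", "seed"))
  for (v in num) {
    if (!is.numeric(cfg[[v]]) || length(cfg[[v]]) != 1 || cfg[[v]] <= 0) {
      stop_("config value ", v, " must be a positive scalar")
    }
  }
  if (!is_count(abs(seed))) stop_("seed must be an integer")
  structure(cfg, class = "run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_("stage ", stage, ": ", conditionMessage(e))
  })
}

#' Run the full macrogenetics analysis
#'
#' Chains the pipeline stages — simulate (when no records are supplied),
#' diversity estimation with inclusion filters and sample-size QC, the
#' pooled latitude trend (mixed polynomial ladder, R2, parametric
#' bootstrap), the environmental driver analysis, and the within-species
#' trends — and assembles a manifest recording the configuration, seeds and
#' the row counts after every filter. Hard errors name the failing stage.
#'
#' @param records Record table ([read_records()]-style), or `NULL` to
#'   simulate one from `sim`.
#' @param env Environmental table (band- or site-keyed), or `NULL` to
#'   simulate fields for the occupied bands.
#' @param config A [run_config()].
#' @param stages Character vector of stages to run, or `"all"`. Stages:
#'   `"diversity"`, `"total-trend"`, `"drivers"`, `"intraspecific"`.
#' @param sim A [sim_config()] used when `records` is `NULL`.
#' @param out_dir Optional directory for TSV/JSON artifacts.
#' @return A list with `diversity`, `qc`, `total_trend`, `drivers`,
#'   `intraspecific` and `manifest` components (stages not requested are
#'   `NULL`).
#' @export
run_pipeline <- function(records = NULL, env = NULL, config = run_config(),
                         stages = "all", sim = sim_config(), out_dir = NULL) {
  all_stages <- c("diversity", "total-trend", "drivers", "intraspecific")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) stop_("unknown stage(s): ", paste(bad, collapse = ", "))
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))

  simulated <- FALSE
  if (is.null(records)) {
    simulated <- TRUE
    sim_out <- run_stage("simulate", simulate_sequences(sim, seed = config$seed))
    records <- sim_out$records
  }
  run_stage("validate", validate_records(records))
  if (is.null(env) && "drivers" %in% stages) {
    bands <- sort(unique(assign_band(records$latitude,
                                     absolute = config$band_mode == "absolute")))
    env <- run_stage("simulate-env",
                     simulate_env_fields(sim, seed = config$seed + 1,
                                         bands = bands))
    env$band <- env$band_key
  }

  # diversity stage (always needed downstream)
  cells <- run_stage("banding",
                     band_cells(records,
                                absolute = config$band_mode == "absolute"))
  filt <- run_stage("banding",
                    apply_species_filters(cells, min_n = config$min_n,
                                          min_bands = config$min_bands))
  diversity <- run_stage("diversity", estimate_all(filt$cells, records))
  qc <- list()
  for (metric in c("pi", "hd")) {
    qc[[metric]] <- tryCatch(
      sample_size_qc(diversity, metric, threshold = config$qc_threshold),
      error = function(e) {
        note("sample-size QC (%s) skipped: %s", metric, conditionMessage(e))
        NULL
      })
  }

  pooled <- multispecies_band_filter(diversity)

  total_trend <- NULL
  if ("total-trend" %in% stages) {
    total_trend <- run_stage("total-trend", {
      if (nrow(pooled) == 0) stop_("multispecies filter left no data")
      out <- list()
      for (metric in c("pi", "hd")) {
        lad <- polynomial_ladder(pooled[[metric]], pooled$band,
                                 groups = pooled$species_id,
                                 max_order = config$max_order,
                                 delta = config$delta_aic)
        fit <- lad$selected_fit
        boot <- parametric_bootstrap(fit, B = config$bootstrap_B,
                                     seed = config$seed + 2)
        out[[metric]] <- list(ladder = lad, r2 = r2_nakagawa(fit),
                              bootstrap = boot)
      }
      out
    })
  }

  drivers <- NULL
  if ("drivers" %in% stages) {
    drivers <- run_stage("drivers", {
      if (nrow(pooled) == 0) stop_("multispecies filter left no data")
      lapply(stats::setNames(c("pi", "hd"), c("pi", "hd")), function(metric) {
        driver_analysis(pooled, env, metric, r_max = config$r_max,
                        vif_max = config$vif_max,
                        delta_aic = config$delta_aic,
                        delta_aicc = config$delta_aicc,
                        level = config$ci_level)
      })
    })
  }

  intraspecific <- NULL
  if ("intraspecific" %in% stages) {
    intraspecific <- run_stage(
      "intraspecific",
      intraspecific_trends(diversity, max_order = config$max_order,
                           delta = config$delta_aic))
  }

  manifest <- list(
    package = "latdiv",
    version = as.character(utils::packageVersion("latdiv")),
    config = unclass(config),
    seed = config$seed,
    simulated_input = simulated,
    counts = list(
      n_records = nrow(records),
      n_species_input = length(unique(records$species_id)),
      n_cells = nrow(cells),
      retained_cells = filt$report$retained_cells,
      dropped_cells = nrow(filt$report$dropped_cells),
      dropped_species = nrow(filt$report$dropped_species),
      unique_bands = filt$report$unique_bands,
      n_species_retained = length(unique(diversity$species_id)),
      bands_per_species = as.list(
        tapply(diversity$band, diversity$species_id,
               function(b) length(unique(b)))),
      diversity_rows = nrow(diversity),
      diversity_estimates_total = 2L * nrow(diversity),
      pooled_rows = nrow(pooled)
    ),
    warnings = warnings_log,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  result <- list(diversity = diversity, qc = qc, filter_report = filt$report,
                 pooled = pooled, total_trend = total_trend,
                 drivers = drivers, intraspecific = intraspecific,
                 manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$diversity, file.path(out_dir, "diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  for (metric in names(result$qc)) {
    q <- result$qc[[metric]]
    if (!is.null(q)) {
      jsonlite::write_json(unclass(q),
                           file.path(out_dir, sprintf("qc_%s.json", metric)),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  if (!is.null(result$total_trend)) {
    tt <- lapply(result$total_trend, function(x) {
      fit <- x$ladder$selected_fit
      list(selected_order = x$ladder$selected_order,
           selection_reason = x$ladder$selection_reason,
           ladder = x$ladder$table,
           coefficients = as.list(fit$coefficients),
           se = as.list(fit$se),
           sigma2_alpha = fit$sigma2_alpha, sigma2_eps = fit$sigma2_eps,
           r2 = as.list(x$r2),
           bootstrap = list(B = x$bootstrap$B, bias = as.list(x$bootstrap$bias),
                            se = as.list(x$bootstrap$se),
                            n_failed = x$bootstrap$n_failed))
    })
    jsonlite::write_json(tt, file.path(out_dir, "total_trend.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(result$drivers)) {
    dr <- lapply(result$drivers, function(x) {
      list(metric = x$metric, thresholds = x$thresholds,
           global_aic = as.list(x$global_aic),
           retained_sets = x$retained_sets,
           sets = x$sets,
           averaged = lapply(x$averaged, function(a) a$terms))
    })
    jsonlite::write_json(dr, file.path(out_dir, "drivers.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(result$intraspecific)) {
    utils::write.table(result$intraspecific$results,
                       file.path(out_dir, "intraspecific.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
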