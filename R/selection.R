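#' Akaike weights
#'
#' `w_m = exp(-delta_m/2) / sum(exp(-delta/2))` with `delta_m` the difference
#' from the minimum criterion value. Invariant to adding a constant to every
#' value; weights sum to 1 over the supplied set.
#'
#' @param ic Vector of AIC or AICc values.
#' @return Vector of weights summing to 1.
#' @export
akaike_weights <- function(ic) {
  d <- ic - min(ic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' AIC selection with the parsimony rule
#'
#' Takes the minimum-criterion model; if other models fall within `delta`
#' of it, the least complex model in that set is chosen instead.
#'
#' @param aic Criterion values (one per model).
#' @param complexity Complexity ranking (e.g. polynomial order or parameter
#'   count), same length as `aic`.
#' @param delta Criterion gap below which models are considered equivalent
#'   (default 2).
#' @return List with `index` (position of the selected model in `aic`),
#'   `complexity` (its complexity value) and `reason` (either
#'   `"unique best by dAIC>2"` or `"parsimony among dAIC<2 set"`).
#' @export
select_by_aic <- function(aic, complexity = seq_along(aic), delta = 2) {
  if (length(aic) == 0 || anyNA(aic)) stop_("AIC values must be non-missing")
  if (length(complexity) != length(aic)) stop_("complexity length mismatch")
  d <- aic - min(aic)
  set <- which(d < delta)
  if (length(set) == 1) {
    list(index = set, complexity = complexity[set],
         reason = "unique best by dAIC>2")
  } else {
    idx <- set[order(complexity[set], aic[set])][1]
    list(index = idx, complexity = complexity[idx],
         reason = "parsimony among dAIC<2 set")
  }
}

#' Polynomial ladder with AIC selection
#'
#' Fits polynomial models of order 0 (null) through `max_order` in the
#' z-scored predictor — mixed models with a random group intercept for the
#' pooled analysis, OLS for within-species trends — and applies the
#' AIC-parsimony selection rule. Orders whose design would be rank deficient
#' (or, for OLS, leave no residual degrees of freedom) are skipped and
#' logged.
#'
#' @param y Response vector (diversity estimates).
#' @param latitude Predictor (band latitudes); z-scored internally.
#' @param groups Group labels for the mixed ladder, or `NULL` for OLS.
#' @param max_order Highest polynomial order to try (default 4).
#' @param delta AIC equivalence gap (default 2).
#' @param mixed Fit random-intercept models (default: whenever `groups` is
#'   supplied).
#' @return An `aic_ladder`: per-order table (order, k, logLik, AIC,
#'   converged), `selected_order`, `selection_reason`, the fitted objects,
#'   and any `skipped` orders.
#' @export
polynomial_ladder <- function(y, latitude, groups = NULL, max_order = 4,
                              delta = 2, mixed = !is.null(groups)) {
  z <- zscore(latitude)
  if (mixed && is.null(groups)) stop_("mixed ladder needs groups")
  fits <- list()
  rows <- list()
  skipped <- character(0)
  for (ord in 0:max_order) {
    tag <- as.character(ord)
    X <- tryCatch(polynomial_design(z, ord), error = function(e) NULL)
    if (is.null(X) || (!mixed && length(y) - ncol(X) < 1)) {
      skipped <- c(skipped, sprintf("order %d: %s", ord,
                                    if (is.null(X)) "rank deficient"
                                    else "no residual df"))
      next
    }
    fit <- tryCatch(
      if (mixed) lmm_fit(y, X, groups) else ols_ml(y, X),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      skipped <- c(skipped, sprintf("order %d: fit failed", ord))
      next
    }
    conv <- isTRUE(fit$converged)
    fits[[tag]] <- fit
    rows[[tag]] <- data.frame(
      order = ord, k = fit$k, loglik = fit$loglik,
      AIC = -2 * fit$loglik + 2 * fit$k, converged = conv
    )
    if (!conv) {
      warning("order ", ord, " did not converge; excluded from comparison",
              call. = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !any(tab$converged)) stop_("no polynomial order converged")
  rownames(tab) <- NULL
  cand <- tab[tab$converged, , drop = FALSE]
  sel <- select_by_aic(cand$AIC, cand$order, delta = delta)
  selected_order <- cand$order[sel$index]
  structure(
    list(table = tab, selected_order = selected_order,
         selection_reason = sel$reason, fits = fits,
         selected_fit = fits[[as.character(selected_order)]],
         mixed = mixed, delta = delta, skipped = skipped,
         z_center = attr(z, "center"), z_scale = attr(z, "scale")),
    class = "aic_ladder"
  )
}

#' @export
print.aic_ladder <- function(x, ...) {
  cat(sprintf("%s polynomial ladder (AIC, delta = %g)\n",
              if (x$mixed) "mixed-model" else "OLS", x$delta))
  tab <- x$table
  tab$dAIC <- tab$AIC - min(tab$AIC[tab$converged])
  tab$selected <- ifelse(tab$order == x$selected_order, "*", "")
  print(tab, row.names = FALSE, digits = 6)
  cat(sprintf("selected order: %d (%s)\n", x$selected_order,
              x$selection_reason))
  if (length(x$skipped) > 0) cat("skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}

#' Collinearity screen (Pearson r and VIF)
#'
#' Flags predictor pairs with |r| above `r_max` and predictors whose variance
#' inflation factor (1/(1 - R2) from regressing each variable on all others)
#' exceeds `vif_max`, then builds candidate predictor sets by excluding one
#' member of each flagged pair in every combination. With one flagged pair
#' this reproduces the two-set construction (e.g. an oxygen set and a
#' temperature set when SST and dissolved oxygen are inversely collinear).
#'
#' @param env Numeric matrix or data frame of predictors (>= 2 columns,
#'   >= 3 rows).
#' @param r_max Pairwise correlation threshold (default 0.7).
#' @param vif_max VIF threshold (default 5).
#' @return A `collinearity_screen`: correlation matrix, VIF vector,
#'   `flagged_pairs` data frame, `flagged_vars`, and `candidate_sets` (list
#'   of character vectors of retained variable names).
#' @export
collinearity_screen <- function(env, r_max = 0.7, vif_max = 5) {
  env <- as.data.frame(env)
  vars <- names(env)
  if (length(vars) < 2) stop_("need at least 2 predictors")
  if (nrow(env) < 3) stop_("need at least 3 rows")
  M <- as.matrix(env)
  r <- stats::cor(M)
  vif <- vapply(vars, function(v) {
    # perfectly collinear variables give a perfect fit: VIF = Inf below
    r2 <- suppressWarnings(
      summary(stats::lm(stats::reformulate(setdiff(vars, v), v),
                        data = env)))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  pr <- which(upper.tri(r) & abs(r) > r_max, arr.ind = TRUE)
  flagged_pairs <- data.frame(
    var1 = vars[pr[, 1]], var2 = vars[pr[, 2]],
    r = r[pr], stringsAsFactors = FALSE
  )
  flagged_vars <- vars[vif > vif_max]
  candidate_sets <- list(vars)
  if (nrow(flagged_pairs) > 0) {
    # Cartesian choice of which member of each flagged pair to drop
    choices <- expand.grid(lapply(seq_len(nrow(flagged_pairs)), function(i) {
      c(flagged_pairs$var1[i], flagged_pairs$var2[i])
    }), stringsAsFactors = FALSE)
    sets <- lapply(seq_len(nrow(choices)), function(i) {
      setdiff(vars, unlist(choices[i, ], use.names = FALSE))
    })
    candidate_sets <- unique(sets)
  }
  structure(
    list(pearson = r, vif = vif, flagged_pairs = flagged_pairs,
         flagged_vars = flagged_vars, candidate_sets = candidate_sets,
         r_max = r_max, vif_max = vif_max),
    class = "collinearity_screen"
  )
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat(sprintf("collinearity screen (|r| > %g, VIF > %g)\n", x$r_max, x$vif_max))
  cat("  VIF:\n")
  print(round(x$vif, 3))
  if (nrow(x$flagged_pairs) > 0) {
    cat("  flagged pairs:\n")
    print(x$flagged_pairs, row.names = FALSE)
  } else {
    cat("  no flagged pairs\n")
  }
  cat(sprintf("  %d candidate set(s):\n", length(x$candidate_sets)))
  for (s in x$candidate_sets) cat("   -", paste(s, collapse = " + "), "\n")
  invisible(x)
}

#' Compare candidate global models by AIC
#'
#' If the best set leads every other by more than `delta` AIC units it is
#' retained alone; otherwise all sets within `delta` of the best are carried
#' forward (the situation where two sets both "show good fit").
#'
#' @param aic Named vector of global-model AIC values, one per candidate set.
#' @param delta AIC gap (default 2).
#' @return Character vector of retained set names.
#' @export
compare_global_sets <- function(aic, delta = 2) {
  if (is.null(names(aic))) names(aic) <- paste0("set", seq_along(aic))
  names(aic)[aic - min(aic) < delta]
}

#' All-subsets mixed-model ranking by AICc
#'
#' Fits a random-intercept mixed model for every subset of the supplied
#' (pre-standardized) predictors, including the intercept-only null model,
#' and ranks the models by AICc with delta values and Akaike weights over
#' every converged model. Non-convergent subsets are excluded with a warning.
#'
#' @param y Response vector.
#' @param env Matrix/data frame of standardized predictors (p <= 12).
#' @param groups Random-intercept group labels.
#' @return A `subset_ranking`: `table` (terms, k, logLik, AICc, delta_AICc,
#'   weight; sorted ascending by AICc), plus per-model coefficient and
#'   standard-error lists, the term membership matrix and `N`.
#' @export
all_subsets <- function(y, env, groups) {
  env <- as.data.frame(env)
  vars <- names(env)
  p <- length(vars)
  if (p < 1 || p > 12) stop_("need between 1 and 12 predictors")
  M <- as.matrix(env)
  n_models <- 2^p
  keep <- logical(n_models)
  rows <- vector("list", n_models)
  coefs <- vector("list", n_models)
  ses <- vector("list", n_models)
  membership <- matrix(FALSE, n_models, p, dimnames = list(NULL, vars))
  excluded <- character(0)
  for (m in seq_len(n_models) - 1L) {
    sel <- bitwAnd(m, 2^(seq_len(p) - 1L)) > 0
    X <- cbind(`(Intercept)` = 1, M[, sel, drop = FALSE])
    fit <- tryCatch(lmm_fit(y, X, groups), error = function(e) NULL)
    label <- if (any(sel)) paste(vars[sel], collapse = "+") else "(null)"
    if (is.null(fit) || !fit$converged) {
      excluded <- c(excluded, label)
      next
    }
    ic <- information_criteria(fit)
    i <- m + 1L
    keep[i] <- TRUE
    membership[i, ] <- sel
    rows[[i]] <- data.frame(terms = label, k = fit$k, loglik = fit$loglik,
                            AICc = ic[["AICc"]], stringsAsFactors = FALSE)
    coefs[[i]] <- fit$coefficients
    ses[[i]] <- fit$se
  }
  if (!any(keep)) stop_("no subset model converged")
  if (length(excluded) > 0) {
    warning("non-convergent subset(s) excluded: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  tab <- do.call(rbind, rows[keep])
  ord <- order(tab$AICc)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_AICc <- tab$AICc - min(tab$AICc)
  tab$weight <- akaike_weights(tab$AICc)
  rownames(tab) <- NULL
  new_subset_ranking(tab, membership[keep, , drop = FALSE][ord, , drop = FALSE],
                     coefs[keep][ord], ses[keep][ord], length(y),
                     excluded = excluded)
}

#' Construct a subset ranking
#'
#' Low-level constructor used by [all_subsets()] and available for building
#' rankings from externally fitted models (e.g. worked examples).
#'
#' @param table Data frame with columns `terms`, `k`, `loglik`, `AICc` (rows
#'   sorted ascending by AICc); `delta_AICc` and `weight` are added if
#'   absent.
#' @param membership Logical model-by-term matrix with term names as columns.
#' @param coefs,ses Lists of named coefficient / standard-error vectors, one
#'   per model row.
#' @param N Number of observations behind every model.
#' @param excluded Labels of models dropped before ranking.
#' @return A `subset_ranking`.
#' @export
new_subset_ranking <- function(table, membership, coefs, ses, N,
                               excluded = character(0)) {
  if (is.null(table$delta_AICc)) table$delta_AICc <- table$AICc - min(table$AICc)
  if (is.null(table$weight)) table$weight <- akaike_weights(table$AICc)
  structure(
    list(table = table, membership = membership, coefs = coefs, ses = ses,
         N = N, excluded = excluded),
    class = "subset_ranking"
  )
}

#' @export
print.subset_ranking <- function(x, n = 10, ...) {
  cat(sprintf("all-subsets AICc ranking: %d models, N = %d\n",
              nrow(x$table), x$N))
  print(utils::head(x$table, n), row.names = FALSE, digits = 6)
  if (nrow(x$table) > n) cat("  ...\n")
  cat(sprintf("top set (dAICc < 2): %d model(s)\n",
              sum(x$table$delta_AICc < 2)))
  invisible(x)
}

#' Model averaging over the AICc top set
#'
#' Full (zero-substitution) averaging over the models with `delta_AICc <
#' delta`, with weights renormalized over that top set: a term absent from a
#' model contributes estimate 0 and SE 0 there. Unconditional standard errors
#' follow the Burnham-Anderson formula `sum w_m (se_m^2 + (b_m - bbar)^2)`.
#' Term importance is the summed weight of top-set models containing the
#' term (1 exactly when the term appears in every top-set model); the
#' importance over the full ranking (raw weights) is reported alongside.
#'
#' @param ranking A `subset_ranking`.
#' @param delta Top-set AICc gap (default 2).
#' @param level Confidence level (default 0.95, normal approximation).
#' @param mode `"full"` (default) or `"conditional"` (average only over
#'   models containing the term).
#' @return An `averaged_model`: data frame with per-term `estimate`, `se`,
#'   `ci_lo`, `ci_hi`, `importance`, `full_importance` and
#'   `ci_excludes_zero`.
#' @export
model_average <- function(ranking, delta = 2, level = 0.95,
                          mode = c("full", "conditional")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ranking, "subset_ranking"))
  top <- which(ranking$table$delta_AICc < delta)
  if (length(top) == 0) stop_("empty top set")
  w <- ranking$table$weight[top]
  w <- w / sum(w)
  terms <- c("(Intercept)", colnames(ranking$membership))
  zq <- stats::qnorm((1 + level) / 2)
  out <- lapply(terms, function(tm) {
    present <- if (tm == "(Intercept)") rep(TRUE, length(top)) else
      ranking$membership[top, tm]
    est <- vapply(seq_along(top), function(i) {
      b <- ranking$coefs[[top[i]]]
      if (tm %in% names(b)) unname(b[tm]) else 0
    }, numeric(1))
    sem <- vapply(seq_along(top), function(i) {
      s <- ranking$ses[[top[i]]]
      if (tm %in% names(s)) unname(s[tm]) else 0
    }, numeric(1))
    if (mode == "conditional") {
      if (!any(present)) {
        return(data.frame(term = tm, estimate = NA_real_, se = NA_real_,
                          ci_lo = NA_real_, ci_hi = NA_real_,
                          importance = 0, stringsAsFactors = FALSE))
      }
      wc <- w[present] / sum(w[present])
      bbar <- sum(wc * est[present])
      v <- sum(wc * (sem[present]^2 + (est[present] - bbar)^2))
    } else {
      bbar <- sum(w * est)
      v <- sum(w * (sem^2 + (est - bbar)^2))
    }
    se <- sqrt(v)
    data.frame(term = tm, estimate = bbar, se = se,
               ci_lo = bbar - zq * se, ci_hi = bbar + zq * se,
               importance = sum(w[present]), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  full_w <- ranking$table$weight
  tab$full_importance <- vapply(terms, function(tm) {
    if (tm == "(Intercept)") return(1)
    sum(full_w[ranking$membership[, tm]])
  }, numeric(1))
  tab$ci_excludes_zero <- !is.na(tab$ci_lo) & (tab$ci_lo > 0 | tab$ci_hi < 0)
  structure(
    list(terms = tab, n_top = length(top), weights = w, delta = delta,
         level = level, mode = mode),
    class = "averaged_model"
  )
}

#' @export
print.averaged_model <- function(x, ...) {
  cat(sprintf("model averaging (%s) over %d top model(s), dAICc < %g\n",
              x$mode, x$n_top, x$delta))
  print(x$terms, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Environmental-driver analysis
#'
#' Orchestrates the pooled driver inference for one diversity metric:
#' averages the environmental table per band, joins it to the (multispecies
#' filtered) diversity estimates, z-scores the predictors, screens for
#' collinearity, fits one global mixed model per candidate predictor set,
#' retains sets by the AIC rule, and runs the all-subsets AICc ranking and
#' model averaging within every retained set.
#'
#' @param diversity Pooled diversity table (after
#'   [multispecies_band_filter()]), with `species_id`, `band` and the metric
#'   column.
#' @param env Environmental table: either band-keyed (a `band` column) or
#'   site-keyed (a `lat` column, banded and averaged internally).
#' @param metric `"pi"` or `"hd"`.
#' @param r_max,vif_max Collinearity thresholds (defaults 0.7 and 5).
#' @param delta_aic Gap for the global set comparison (default 2).
#' @param delta_aicc Gap for the top model set (default 2).
#' @param level Confidence level for averaged coefficients (default 0.95).
#' @return A `driver_report`: the screen, per-set global AICs, retained set
#'   names, and per-retained-set rankings and averaged models.
#' @export
driver_analysis <- function(diversity, env, metric = c("pi", "hd"),
                            r_max = 0.7, vif_max = 5, delta_aic = 2,
                            delta_aicc = 2, level = 0.95) {
  metric <- match.arg(metric)
  env_band <- aggregate_env_by_band(env)
  d <- merge(diversity, env_band, by = "band")
  if (nrow(d) == 0) stop_("no overlap between diversity bands and env bands")
  evars <- setdiff(names(env_band), "band")
  Z <- as.data.frame(lapply(d[evars], function(v) as.numeric(zscore(v))))
  screen <- collinearity_screen(Z, r_max = r_max, vif_max = vif_max)
  y <- d[[metric]]
  sets <- screen$candidate_sets
  names(sets) <- paste0("set", seq_along(sets))
  global_aic <- vapply(sets, function(vs) {
    fit <- lmm_fit(y, cbind(`(Intercept)` = 1, as.matrix(Z[vs])), d$species_id)
    information_criteria(fit)[["AIC"]]
  }, numeric(1))
  retained <- compare_global_sets(global_aic, delta = delta_aic)
  rankings <- list()
  averaged <- list()
  for (nm in retained) {
    rk <- all_subsets(y, Z[sets[[nm]]], d$species_id)
    rankings[[nm]] <- rk
    averaged[[nm]] <- model_average(rk, delta = delta_aicc, level = level)
  }
  structure(
    list(metric = metric, screen = screen, global_aic = global_aic,
         retained_sets = retained, sets = sets, rankings = rankings,
         averaged = averaged, n_rows = nrow(d),
         thresholds = list(r_max = r_max, vif_max = vif_max,
                           delta_aic = delta_aic, delta_aicc = delta_aicc,
                           ci_level = level)),
    class = "driver_report"
  )
}

#' @export
print.driver_report <- function(x, ...) {
  cat(sprintf("environmental driver analysis (%s), %d band-level rows\n",
              x$metric, x$n_rows))
  cat("global set AICs:\n")
  print(round(x$global_aic, 4))
  cat("retained:", paste(x$retained_sets, collapse = ", "), "\n")
  for (nm in x$retained_sets) {
    cat(sprintf("-- %s: %s\n", nm, paste(x$sets[[nm]], collapse = " + ")))
    print(x$averaged[[nm]])
  }
  invisible(x)
}

# Average site-keyed environmental values within each one-degree band.
aggregate_env_by_band <- function(env) {
  env <- as.data.frame(env)
  if (!"band" %in% names(env)) {
    latcol <- intersect(c("lat", "latitude"), names(env))[1]
    if (is.na(latcol)) stop_("env table needs a 'band' or 'lat' column")
    env$band <- assign_band(env[[latcol]])
  }
  keep <- setdiff(names(env), c("band", "lat", "latitude", "lon", "longitude"))
  agg <- stats::aggregate(env[keep], by = list(band = env$band), FUN = mean)
  agg[order(agg$band), , drop = FALSE]
}

#' Within-species latitude trends
#'
#' OLS polynomial ladder per species and metric, with the same AIC-parsimony
#' selection rule as the pooled analysis. No band filters are applied beyond
#' the inclusion criteria. Orders are capped so at least one residual degree
#' of freedom remains; species where nothing beyond the null model is
#' estimable are skipped with a log entry. Adjusted R-squared is reported
#' only when the selected model is not the null.
#'
#' @param diversity Diversity table (`species_id`, `band`, `pi`, `hd`).
#' @param metrics Metrics to analyze (default both).
#' @param max_order Highest polynomial order to attempt (default 4).
#' @param delta AIC equivalence gap (default 2).
#' @return An `intraspecific_trends` object: `results` data frame
#'   (species_id, metric, selected_order, adj_r_squared, n_bands), the
#'   per-fit ladders, and `skipped` log entries.
#' @export
intraspecific_trends <- function(diversity, metrics = c("pi", "hd"),
                                 max_order = 4, delta = 2) {
  rows <- list()
  ladders <- list()
  skipped <- character(0)
  for (sp in unique(diversity$species_id)) {
    d <- diversity[diversity$species_id == sp, , drop = FALSE]
    n_distinct <- length(unique(d$band))
    cap <- min(max_order, nrow(d) - 2L, n_distinct - 1L)
    if (cap < 1) {
      skipped <- c(skipped, sprintf("%s: only the null model is estimable", sp))
      next
    }
    for (metric in metrics) {
      lad <- tryCatch(
        polynomial_ladder(d[[metric]], d$band, groups = NULL,
                          max_order = cap, delta = delta, mixed = FALSE),
        error = function(e) NULL
      )
      if (is.null(lad)) {
        skipped <- c(skipped, sprintf("%s/%s: ladder failed", sp, metric))
        next
      }
      adj <- if (lad$selected_order > 0) lad$selected_fit$adj_r_squared else NA_real_
      ladders[[paste(sp, metric, sep = ":")]] <- lad
      rows[[paste(sp, metric, sep = ":")]] <- data.frame(
        species_id = sp, metric = metric,
        selected_order = lad$selected_order, adj_r_squared = adj,
        n_bands = n_distinct, stringsAsFactors = FALSE
      )
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results, ladders = ladders, skipped = skipped),
            class = "intraspecific_trends")
}

#' @export
print.intraspecific_trends <- function(x, ...) {
  cat("intraspecific polynomial trends (OLS ladder)\n")
  print(x$results, row.names = FALSE, digits = 4)
  if (length(x$skipped) > 0) cat("skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}
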