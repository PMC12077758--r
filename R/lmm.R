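#' z-score a numeric vector
#'
#' Centers to mean 0 and scales to sample standard deviation 1 (n - 1
#' denominator), keeping the transform parameters as attributes so fitted
#' curves can be mapped back to the original scale.
#'
#' @param v Numeric vector with at least two distinct values.
#' @return Scaled vector with attributes `center` and `scale`.
#' @export
zscore <- function(v) {
  if (!is.numeric(v) || length(v) < 2) stop_("need a numeric vector of length >= 2")
  if (anyNA(v) || any(!is.finite(v))) stop_("non-finite values in input")
  s <- stats::sd(v)
  if (s == 0) stop_("cannot z-score a constant vector")
  structure((v - mean(v)) / s, center = mean(v), scale = s)
}

#' Polynomial design matrix on a scaled predictor
#'
#' Raw powers `1, z, z^2, ..., z^order` of the z-scored predictor. Order 0 is
#' the intercept-only design. Scaling/centering the predictor (not
#' orthogonalizing) is the device used to keep the polynomial terms usable
#' together; an orthogonal basis is available via `orthogonal = TRUE`.
#'
#' @param z Scaled predictor vector (see [zscore()]).
#' @param order Polynomial order, 0 to 4.
#' @param orthogonal Use `stats::poly` orthogonal columns instead of raw
#'   powers.
#' @return Design matrix with an intercept column.
#' @export
polynomial_design <- function(z, order, orthogonal = FALSE) {
  if (!is_count(order) || order > 4) stop_("order must be an integer in 0..4")
  z <- as.numeric(z)
  if (order == 0) {
    X <- matrix(1, length(z), 1, dimnames = list(NULL, "(Intercept)"))
    return(X)
  }
  P <- if (orthogonal) {
    unclass(stats::poly(z, degree = order))
  } else {
    outer(z, seq_len(order), `^`)
  }
  X <- cbind(1, P)
  colnames(X) <- c("(Intercept)", paste0("z^", seq_len(order)))
  if (qr(X)$rank < ncol(X)) {
    stop_("rank-deficient polynomial design (too few distinct predictor values)")
  }
  X
}

# Profiled -2 log-likelihood machinery -----------------------------------
#
# Model: y = X beta + a_g + eps, a_g ~ N(0, s2a) per group, eps ~ N(0, s2e).
# For lambda = s2a/s2e, V_g = s2e (I + lambda J). beta and s2e have closed
# forms given lambda (GLS / ML variance), so optimization is over the single
# parameter t = log(lambda), clamped below at -30 (mapped to s2a = 0).

lmm_profile_env <- function(y, X, groups) {
  groups <- factor(groups)
  N <- length(y)
  ng <- as.integer(table(groups))
  Sx <- rowsum(X, groups, reorder = TRUE)
  Sy <- rowsum(y, groups, reorder = TRUE)[, 1]
  list(N = N, p = ncol(X), ng = ng, groups = groups,
       XtX = crossprod(X), Xty = crossprod(X, y)[, 1], yty = sum(y * y),
       Sx = Sx, Sy = Sy)
}

lmm_profile_eval <- function(t, env) {
  lam <- if (t <= -30) 0 else exp(t)
  w <- lam / (1 + lam * env$ng)
  A <- env$XtX - crossprod(env$Sx * w, env$Sx)
  b <- env$Xty - crossprod(env$Sx, w * env$Sy)[, 1]
  yVy <- env$yty - sum(w * env$Sy^2)
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(list(dev = Inf))
  rss <- max(yVy - sum(beta * b), 1e-300)
  s2e <- rss / env$N
  dev <- env$N * log(2 * pi * s2e) + sum(log1p(lam * env$ng)) + env$N
  list(dev = dev, lambda = lam, beta = drop(beta), s2e = s2e, A = A)
}

#' Low-level ML random-intercept fit
#'
#' Maximizes the Gaussian maximum-likelihood of a random-intercept linear
#' mixed model. The fixed effects and the residual variance are profiled out
#' analytically (generalized least squares given the variance ratio), and
#' Nelder-Mead runs on the one-parameter profiled deviance in
#' log-variance-ratio space from three starts (ratio 0.01, 1, 100). The
#' boundary `sigma2_alpha = 0` is permitted (log-ratio clamped at -30).
#'
#' @param y Response vector.
#' @param X Fixed-effects design matrix (full column rank, with intercept).
#' @param groups Grouping labels (species), one per row.
#' @param starts Variance-ratio starting values for Nelder-Mead.
#' @param reltol Relative convergence tolerance on the deviance.
#' @return An object of class `lmm_ml`.
#' @export
lmm_fit <- function(y, X, groups, starts = c(0.01, 1, 100), reltol = 1e-10) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)) - 1L)
  if (length(y) != nrow(X) || length(groups) != nrow(X)) {
    stop_("y, X and groups must have matching rows")
  }
  if (anyNA(y) || anyNA(X)) stop_("missing values are not supported")
  if (qr(X)$rank < ncol(X)) stop_("rank-deficient fixed-effects design")
  env <- lmm_profile_env(y, X, groups)
  obj <- function(t) lmm_profile_eval(t, env)$dev

  best <- NULL
  converged <- FALSE
  for (s in starts) {
    op <- suppressWarnings(
      stats::optim(log(s), obj, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = 500))
    )
    if (is.null(best) || op$value < best$value) best <- op
    if (op$convergence == 0) converged <- TRUE
  }
  # explicit boundary probe: sigma2_alpha = 0
  if (obj(-30) <= best$value) {
    best <- list(par = -30, value = obj(-30))
  }
  at <- lmm_profile_eval(best$par, env)
  beta <- at$beta
  names(beta) <- colnames(X)
  vc <- at$s2e * solve(at$A)
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vc))
  s2a <- at$lambda * at$s2e
  k <- ncol(X) + 2L
  fit <- structure(
    list(coefficients = beta, se = se, t_values = beta / se,
         sigma2_alpha = s2a, sigma2_eps = at$s2e, lambda = at$lambda,
         loglik = -at$dev / 2, deviance = at$dev, k = k,
         N = env$N, G = nlevels(env$groups),
         converged = converged, singular = at$lambda == 0,
         vcov = vc, X = X, y = y, groups = env$groups,
         fitted_fixed = drop(X %*% beta)),
    class = "lmm_ml"
  )
  fit$residuals <- y - fit$fitted_fixed
  fit
}

#' Fit a random-intercept mixed model by maximum likelihood
#'
#' Formula interface over [lmm_fit()]: `diversity ~ z + I(z^2)` style fixed
#' effects plus a random intercept per group (species). Estimation is full
#' maximum likelihood (not REML) so that models with different fixed effects
#' are comparable by AIC.
#'
#' @param formula Fixed-effects formula.
#' @param data Data frame holding the formula variables.
#' @param group Grouping variable: a column name in `data` or a vector.
#' @param ... Passed to [lmm_fit()].
#' @return An object of class `lmm_ml` with `print`, `summary`, `coef`,
#'   `vcov`, `logLik`, `predict`, `simulate`, `fitted` and `residuals`
#'   methods. `k` counts fixed effects plus the two variance parameters.
#' @examples
#' d <- simulate_response_table(sim_config(S = 8), seed = 1)$table
#' fit <- lmm_ml(pi ~ lat_z + I(lat_z^2), d, group = "species_id")
#' summary(fit)
#' @export
lmm_ml <- function(formula, data, group, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  g <- if (is.character(group) && length(group) == 1) data[[group]] else group
  if (is.null(g)) stop_("group not found")
  fit <- lmm_fit(y, X, g, ...)
  fit$call <- match.call()
  fit$terms <- attr(mf, "terms")
  fit
}

#' @export
print.lmm_ml <- function(x, ...) {
  cat("ML random-intercept linear mixed model\n")
  cat(sprintf("  N = %d rows, %d groups; logLik = %.4f; k = %d%s\n",
              x$N, x$G, x$loglik, x$k,
              if (x$singular) " (singular: sigma2_alpha = 0)" else ""))
  cat("  fixed effects:\n")
  print(round(x$coefficients, 6))
  cat(sprintf("  variances: between-group %.6g, residual %.6g\n",
              x$sigma2_alpha, x$sigma2_eps))
  invisible(x)
}

#' @export
summary.lmm_ml <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$t_values)
  out <- list(coefficients = tab, sigma2_alpha = object$sigma2_alpha,
              sigma2_eps = object$sigma2_eps, loglik = object$loglik,
              k = object$k, N = object$N, G = object$G,
              AIC = -2 * object$loglik + 2 * object$k,
              r2 = tryCatch(r2_nakagawa(object), error = function(e) NULL),
              converged = object$converged, singular = object$singular)
  class(out) <- "summary.lmm_ml"
  out
}

#' @export
print.summary.lmm_ml <- function(x, ...) {
  cat(sprintf("ML mixed model: N = %d, groups = %d, logLik = %.4f, AIC = %.4f\n",
              x$N, x$G, x$loglik, x$AIC))
  print(round(x$coefficients, 6))
  cat(sprintf("variances: between-group %.6g, residual %.6g\n",
              x$sigma2_alpha, x$sigma2_eps))
  if (!is.null(x$r2)) {
    cat(sprintf("R2 (marginal, conditional): %.4f, %.4f\n",
                x$r2[["R2m"]], x$r2[["R2c"]]))
  }
  invisible(x)
}

#' @export
coef.lmm_ml <- function(object, ...) object$coefficients

#' @export
vcov.lmm_ml <- function(object, ...) object$vcov

#' @export
logLik.lmm_ml <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$N, class = "logLik")
}

#' @export
fitted.lmm_ml <- function(object, ...) object$fitted_fixed

#' @export
residuals.lmm_ml <- function(object, level = c("marginal", "conditional"), ...) {
  level <- match.arg(level)
  r <- object$y - object$fitted_fixed
  if (level == "conditional") r <- r - random_intercepts(object)[object$groups]
  r
}

#' Best linear unbiased predictors of the group intercepts
#'
#' @param object An `lmm_ml` fit.
#' @return Named vector of group-level intercept predictions.
#' @export
random_intercepts <- function(object) {
  lam <- object$lambda
  r <- object$y - object$fitted_fixed
  sg <- rowsum(r, object$groups)[, 1]
  ng <- as.integer(table(object$groups))
  stats::setNames(lam / (1 + lam * ng) * sg, levels(object$groups))
}

#' @export
predict.lmm_ml <- function(object, newX = NULL, newgroups = NULL,
                           re = FALSE, ...) {
  X <- if (is.null(newX)) object$X else as.matrix(newX)
  out <- drop(X %*% object$coefficients)
  if (re) {
    g <- if (is.null(newgroups)) object$groups else newgroups
    a <- random_intercepts(object)
    add <- a[as.character(g)]
    add[is.na(add)] <- 0
    out <- out + unname(add)
  }
  out
}

#' @export
simulate.lmm_ml <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    G <- object$G
    N <- object$N
    gidx <- as.integer(object$groups)
    ys <- matrix(NA_real_, N, nsim)
    for (b in seq_len(nsim)) {
      a <- stats::rnorm(G, 0, sqrt(object$sigma2_alpha))
      ys[, b] <- object$fitted_fixed + a[gidx] +
        stats::rnorm(N, 0, sqrt(object$sigma2_eps))
    }
    ys
  })
}

#' Ordinary least squares with Gaussian ML log-likelihood
#'
#' OLS fit reporting the maximum-likelihood Gaussian log-likelihood (variance
#' MLE, RSS/N), so AIC comparisons against mixed fits use one likelihood
#' convention. `k` counts the fixed effects plus one variance parameter.
#'
#' @param y Response vector.
#' @param X Design matrix including an intercept column.
#' @return An object of class `ols_ml` with `coefficients`, `se`, `loglik`,
#'   `k`, `N`, `r_squared`, `adj_r_squared`.
#' @export
ols_ml <- function(y, X) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  N <- length(y)
  p <- ncol(X)
  if (N <= p) stop_("need N > number of coefficients")
  if (qr(X)$rank < p) stop_("rank-deficient design")
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  s2 <- rss / N
  loglik <- -N / 2 * (log(2 * pi * max(s2, 1e-300)) + 1)
  has_int <- any(apply(X, 2, function(c) all(c == c[1]) && c[1] != 0))
  tss <- if (has_int) sum((y - mean(y))^2) else sum(y^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  p_noint <- p - as.integer(has_int)
  adj <- if (N - p_noint - 1 > 0) 1 - (1 - r2) * (N - 1) / (N - p_noint - 1) else NA_real_
  xtxi <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(xtxi) * rss / max(N - p, 1))
  beta <- stats::setNames(fit$coefficients, colnames(X))
  structure(
    list(coefficients = beta, se = stats::setNames(se, colnames(X)),
         loglik = loglik, k = p + 1L, N = N, sigma2 = s2,
         r_squared = r2, adj_r_squared = adj,
         fitted = drop(X %*% fit$coefficients),
         residuals = drop(fit$residuals), X = X, y = y, converged = TRUE),
    class = "ols_ml"
  )
}

#' @export
print.ols_ml <- function(x, ...) {
  cat(sprintf("OLS (ML likelihood): N = %d, logLik = %.4f, R2 = %.4f, adj R2 = %.4f\n",
              x$N, x$loglik, x$r_squared, x$adj_r_squared))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
coef.ols_ml <- function(object, ...) object$coefficients

#' @export
logLik.ols_ml <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$N, class = "logLik")
}

#' AIC and small-sample AICc
#'
#' `AIC = -2 logLik + 2k`; `AICc = AIC + 2k(k+1)/(N-k-1)`. `k` counts fixed
#' effects plus two variance parameters for mixed fits (so the
#' intercept-only mixed model has k = 3) or plus one for OLS fits.
#'
#' @param object An `lmm_ml` or `ols_ml` fit (anything with `loglik`, `k`,
#'   `N` fields).
#' @param N Sample size override.
#' @return Named vector `c(AIC, AICc)`.
#' @export
information_criteria <- function(object, N = object$N) {
  ll <- object$loglik
  k <- object$k
  if (!isTRUE(object$converged %||% TRUE)) stop_("fit did not converge")
  aic <- -2 * ll + 2 * k
  if (N <= k + 1) stop_("AICc undefined: N <= k + 1")
  c(AIC = aic, AICc = aic + 2 * k * (k + 1) / (N - k - 1))
}

#' Marginal and conditional R-squared for mixed models
#'
#' Variance-partition R2: the fixed-effect variance is the population
#' variance (N denominator) of the fitted fixed-effect predictions. Marginal
#' R2 is the fixed-effect share of the total; conditional R2 adds the
#' between-group variance.
#'
#' @param fit An `lmm_ml` fit.
#' @return Named vector `c(R2m, R2c)`.
#' @export
r2_nakagawa <- function(fit) {
  f <- fit$fitted_fixed
  s2f <- mean((f - mean(f))^2)
  tot <- s2f + fit$sigma2_alpha + fit$sigma2_eps
  if (tot <= 0) stop_("zero total variance")
  c(R2m = s2f / tot, R2c = (s2f + fit$sigma2_alpha) / tot)
}

#' Parametric bootstrap of the fixed effects
#'
#' Resimulates the response from the fitted model (drawing both group
#' intercepts and residuals), refits, and summarizes the stability of each
#' fixed-effect estimate as bias (mean of replicate estimates minus the point
#' estimate) and standard error (standard deviation of replicate estimates).
#'
#' @param fit An `lmm_ml` fit.
#' @param B Number of replicates (default 1000).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return An object of class `lmm_boot` with per-coefficient `bias` and
#'   `se`, the replicate estimates, and the number of failed refits.
#'   Summaries with more than 20% failed replicates are flagged unreliable.
#' @export
parametric_bootstrap <- function(fit, B = 1000, seed = NULL) {
  stopifnot(inherits(fit, "lmm_ml"))
  if (!is_count(B) || B < 1) stop_("B must be a positive integer")
  ys <- simulate(fit, nsim = B, seed = seed)
  p <- length(fit$coefficients)
  est <- matrix(NA_real_, B, p, dimnames = list(NULL, names(fit$coefficients)))
  n_failed <- 0L
  for (b in seq_len(B)) {
    rb <- tryCatch(lmm_fit(ys[, b], fit$X, fit$groups),
                   error = function(e) NULL)
    if (is.null(rb) || !rb$converged) {
      n_failed <- n_failed + 1L
    } else {
      est[b, ] <- rb$coefficients
    }
  }
  ok <- stats::complete.cases(est)
  bias <- colMeans(est[ok, , drop = FALSE]) - fit$coefficients
  se <- if (sum(ok) >= 2) apply(est[ok, , drop = FALSE], 2, stats::sd) else
    stats::setNames(rep(NA_real_, p), names(fit$coefficients))
  structure(
    list(B = B, seed = seed, bias = bias, se = se, estimates = est,
         point = fit$coefficients, n_failed = n_failed,
         unreliable = n_failed > 0.2 * B),
    class = "lmm_boot"
  )
}

#' @export
print.lmm_boot <- function(x, ...) {
  cat(sprintf("parametric bootstrap: B = %d (%d failed)%s\n", x$B, x$n_failed,
              if (x$unreliable) " [UNRELIABLE: >20% failures]" else ""))
  print(round(cbind(estimate = x$point, bias = x$bias, se = x$se), 6))
  invisible(x)
}
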