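test_that("zscore centers and scales with the sample SD", {
  expect_equal(as.numeric(zscore(c(1, 2, 3))), c(-1, 0, 1))
  z <- zscore(rnorm(50, 5, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(as.numeric(zscore(as.numeric(z))), as.numeric(z),
               tolerance = 1e-12)
  expect_error(zscore(c(5, 5, 5)), "constant")
})

test_that("polynomial designs are raw powers of the scaled predictor", {
  z <- c(-1, 0, 1)
  X0 <- polynomial_design(z, 0)
  expect_equal(unname(X0), matrix(1, 3, 1))
  X2 <- polynomial_design(z, 2)
  expect_equal(unname(X2),
               rbind(c(1, -1, 1), c(1, 0, 0), c(1, 1, 1)))
  expect_error(polynomial_design(z, 4), "rank")
  expect_error(polynomial_design(z, 5), "0..4")
})

test_that("profiled GLS reproduces the closed form at the fitted ratio", {
  d <- sim_balanced(31)
  fit <- lmm_fit(d$y, d$X, d$g)
  # closed-form GLS at the fitted variances, via dense matrices
  Z <- model.matrix(~ 0 + factor(d$g))
  V <- fit$sigma2_eps * diag(length(d$y)) + fit$sigma2_alpha * tcrossprod(Z)
  Vi <- solve(V)
  beta_gls <- solve(t(d$X) %*% Vi %*% d$X, t(d$X) %*% Vi %*% d$y)
  expect_equal(unname(coef(fit)), unname(drop(beta_gls)), tolerance = 1e-10)
})

test_that("the ML optimum dominates random variance probes", {
  d <- sim_balanced(32)
  fit <- lmm_fit(d$y, d$X, d$g)
  set.seed(1)
  probes <- matrix(exp(runif(100, -3, 3)), ncol = 2)
  for (i in seq_len(nrow(probes))) {
    expect_gte(fit$loglik + 1e-8,
               dense_lmm_loglik(d$y, d$X, d$g, probes[i, 1], probes[i, 2]))
  }
})

test_that("single-group and zero-variance fits collapse to OLS", {
  set.seed(33)
  y <- rnorm(60)
  X <- cbind(1, x = rnorm(60))
  f <- lmm_fit(y, X, rep("only", 60))
  o <- ols_ml(y, X)
  expect_equal(f$loglik, o$loglik, tolerance = 1e-8)
  expect_equal(unname(coef(f)), unname(coef(o)), tolerance = 1e-8)
  expect_true(f$singular)
})

test_that("noiseless data recovers coefficients at the numerical floor", {
  set.seed(34)
  x <- rnorm(80)
  X <- cbind(1, x = x)
  y <- drop(X %*% c(2, -1.5))
  fit <- lmm_fit(y, X, rep(1:8, each = 10))
  expect_equal(unname(coef(fit)), c(2, -1.5), tolerance = 1e-6)
  expect_lt(fit$sigma2_eps, 1e-12)
})

test_that("estimates agree with an independent ML mixed-model implementation", {
  d <- sim_balanced(35)
  fit <- lmm_fit(d$y, d$X, d$g)
  ref <- lme4::lmer(y ~ x + (1 | g), data = data.frame(y = d$y, x = d$X[, 2],
                                                       g = d$g),
                    REML = FALSE,
                    control = lme4::lmerControl(optimizer = "Nelder_Mead"))
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(ref)), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$sigma2_alpha, vc$vcov[1], tolerance = 1e-3)
  expect_equal(fit$sigma2_eps, vc$vcov[2], tolerance = 1e-3)
  expect_equal(unname(fit$se), unname(sqrt(diag(as.matrix(vcov(ref))))),
               tolerance = 1e-3)
})

test_that("information criteria follow the AIC/AICc arithmetic", {
  fake <- list(loglik = -10, k = 3, N = 50, converged = TRUE)
  expect_equal(information_criteria(fake)[["AIC"]], 26)
  fake2 <- list(loglik = -8, k = 5, N = 20, converged = TRUE)
  expect_equal(information_criteria(fake2)[["AICc"]],
               (16 + 10) + 60 / 14, tolerance = 1e-10)
  expect_equal(information_criteria(fake2)[["AICc"]] -
                 information_criteria(fake2)[["AIC"]], 60 / 14,
               tolerance = 1e-10)
  big <- list(loglik = -8, k = 5, N = 1e6, converged = TRUE)
  ic <- information_criteria(big)
  expect_lt(ic[["AICc"]] - ic[["AIC"]], 1e-4)
  expect_error(information_criteria(list(loglik = -8, k = 5, N = 6,
                                         converged = TRUE)), "AICc undefined")
})

test_that("variance-partition R2 follows its defining ratios", {
  f <- list(fitted_fixed = c(-sqrt(2), 0, sqrt(2)),  # population var 4/3
            sigma2_alpha = 4 / 3, sigma2_eps = 8 / 3)
  r2 <- r2_nakagawa(f)
  expect_equal(r2[["R2m"]], 0.25)
  expect_equal(r2[["R2c"]], 0.5)
  f0 <- list(fitted_fixed = rep(2, 10), sigma2_alpha = 0, sigma2_eps = 1)
  expect_equal(r2_nakagawa(f0)[["R2m"]], 0)
  expect_equal(r2_nakagawa(f0)[["R2m"]], r2_nakagawa(f0)[["R2c"]])
})

test_that("the parametric bootstrap is seed-deterministic and sane", {
  d <- sim_balanced(36)
  fit <- lmm_fit(d$y, d$X, d$g)
  b1 <- parametric_bootstrap(fit, B = 60, seed = 9)
  b2 <- parametric_bootstrap(fit, B = 60, seed = 9)
  expect_identical(b1$estimates, b2$estimates)
  expect_equal(b1$bias, b2$bias)
  expect_equal(b1$n_failed, 0L)
  expect_true(all(is.finite(b1$se)))
  # slope bias should be small relative to its bootstrap SE
  expect_lt(abs(b1$bias[["x"]]), 3 * b1$se[["x"]] / sqrt(60) * 5)

  single <- parametric_bootstrap(fit, B = 1, seed = 2)
  expect_true(all(is.na(single$se)))
  expect_true(all(is.finite(single$bias)))
})

test_that("OLS fits report ML likelihood and the adjusted R2 convention", {
  set.seed(40)
  x <- rnorm(30)
  y <- 2 + 3 * x
  X <- cbind(1, x = x)
  f <- ols_ml(y, X)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  yn <- rnorm(30)
  fn <- ols_ml(yn, X)
  expect_lte(fn$adj_r_squared, fn$r_squared)
  expect_lt(abs(fn$adj_r_squared), 0.25)
  # ML loglik convention matches stats::logLik on lm
  lmfit <- lm(yn ~ x)
  expect_equal(fn$loglik, as.numeric(logLik(lmfit)), tolerance = 1e-8)

  f0 <- ols_ml(yn, X[, 1, drop = FALSE])
  expect_equal(f0$r_squared, 0)
  expect_error(ols_ml(yn, cbind(X, x2 = x)), "rank")
})

test_that("simulate() reproduces the fitted generative model", {
  d <- sim_balanced(41, s2a = 4, s2e = 0.25)
  fit <- lmm_fit(d$y, d$X, d$g)
  ys <- simulate(fit, nsim = 200, seed = 5)
  expect_equal(dim(ys), c(200, 200))
  # total variance of centered draws approximates s2a + s2e
  v <- mean(apply(ys - fit$fitted_fixed, 2, var))
  expect_equal(v, fit$sigma2_alpha + fit$sigma2_eps, tolerance = 0.3)
})
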