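test_that("Akaike weights normalize, shift-invariantly", {
  w <- akaike_weights(c(0, 2))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(w, c(0.7311, 0.2689), tolerance = 1e-4)
  set.seed(2)
  ic <- rnorm(7, 100, 5)
  expect_equal(sum(akaike_weights(ic)), 1, tolerance = 1e-12)
  expect_equal(akaike_weights(ic), akaike_weights(ic + 123.4),
               tolerance = 1e-12)
  expect_equal(akaike_weights(c(5, 5)), c(0.5, 0.5))
})

test_that("the AIC parsimony rule picks the simplest near-best model", {
  # clear winner
  s1 <- select_by_aic(c(10, 20, 30), complexity = 0:2)
  expect_equal(s1$complexity, 0)
  expect_match(s1$reason, "unique best")
  # full tie -> least complex
  s2 <- select_by_aic(rep(100, 5), complexity = 0:4)
  expect_equal(s2$complexity, 0)
  expect_match(s2$reason, "parsimony")
  # min at order 3 but orders 2..4 within 2 units -> order 2
  s3 <- select_by_aic(c(0, -1, -4.2, -5, -4), complexity = 0:4)
  expect_equal(s3$complexity, 2)
  expect_error(select_by_aic(numeric(0)), "non-missing")
})

test_that("the mixed polynomial ladder recovers a quadratic trend", {
  set.seed(52)
  g <- rep(sprintf("sp%02d", 1:15), each = 8)
  lat <- as.numeric(replicate(15, sort(sample(-30:30, 8))))
  z <- as.numeric(zscore(lat))
  y <- 0.6 - 0.25 * z^2 + rnorm(15, 0, 0.08)[as.integer(factor(g))] +
    rnorm(120, 0, 0.08)
  lad <- polynomial_ladder(y, lat, groups = g)
  expect_equal(lad$selected_order, 2)
  expect_lt(coef(lad$selected_fit)[["z^2"]], 0)
  expect_equal(lad$table$k, 3:7)  # orders 0..4
  expect_true(all(diff(lad$table$order) == 1))
})

test_that("VIF and correlation flags follow their closed forms", {
  set.seed(53)
  n <- 200
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + sqrt(1 - 0.64) * rnorm(n)
  # force exact empirical correlation 0.8 via residual orthogonalization
  e <- residuals(lm(x2 ~ x1))
  x2 <- 0.8 * scale(x1)[, 1] + sqrt(1 - 0.64) * scale(e)[, 1] /
    sd(scale(e)[, 1])
  x2 <- as.numeric(x2)
  r <- cor(x1, x2)
  sc <- collinearity_screen(data.frame(a = x1, b = x2), r_max = 0.7)
  expect_equal(unname(sc$vif), rep(1 / (1 - r^2), 2), tolerance = 1e-8)
  expect_equal(sc$vif[["a"]], 1 / (1 - 0.64), tolerance = 0.05)
  expect_equal(nrow(sc$flagged_pairs), 1)
  expect_length(sc$flagged_vars, 0)  # VIF 2.78 < 5: flagged by r only
  expect_length(sc$candidate_sets, 2)

  orth <- data.frame(u = rnorm(n), v = rnorm(n), w = rnorm(n))
  sc2 <- collinearity_screen(orth)
  expect_true(all(sc2$vif < 1.2))
  expect_equal(nrow(sc2$flagged_pairs), 0)
  expect_equal(sc2$candidate_sets, list(c("u", "v", "w")))
})

test_that("one strong inverse pair yields exactly two five-variable sets", {
  set.seed(54)
  n <- 60
  sst <- rnorm(n)
  env <- data.frame(
    sst = sst, dox = -0.9 * sst + sqrt(1 - 0.81) * rnorm(n),
    sal = rnorm(n), cur = rnorm(n), chl = rnorm(n), ph = rnorm(n)
  )
  sc <- collinearity_screen(env)
  expect_equal(nrow(sc$flagged_pairs), 1)
  expect_lt(sc$flagged_pairs$r, -0.7)
  expect_length(sc$candidate_sets, 2)
  expect_true(all(lengths(sc$candidate_sets) == 5))
  has_sst <- vapply(sc$candidate_sets, function(s) "sst" %in% s, logical(1))
  has_dox <- vapply(sc$candidate_sets, function(s) "dox" %in% s, logical(1))
  expect_equal(sort(has_sst), c(FALSE, TRUE))
  expect_equal(has_sst, !has_dox)
})

test_that("global candidate sets are retained by the AIC gap rule", {
  expect_equal(compare_global_sets(c(setA = 100, setB = 110)), "setA")
  expect_equal(compare_global_sets(c(setA = 100, setB = 101.5)),
               c("setA", "setB"))
  expect_equal(compare_global_sets(c(only = 50)), "only")
})

test_that("all-subsets ranking enumerates every model and agrees with refits", {
  set.seed(55)
  n <- 90
  g <- rep(1:10, each = 9)
  env <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  names(env) <- paste0("v", 1:5)
  y <- 0.5 * env$v2 + rnorm(10, 0, 0.5)[g] + rnorm(n)
  rk <- all_subsets(y, env, g)
  expect_equal(nrow(rk$table), 32)
  expect_true("(null)" %in% rk$table$terms)
  expect_equal(sum(rk$table$weight), 1, tolerance = 1e-12)
  expect_true(!is.unsorted(rk$table$AICc))
  # independent refit of each ranked row reproduces its AICc
  for (i in sample(nrow(rk$table), 8)) {
    sel <- rk$membership[i, ]
    X <- cbind(`(Intercept)` = 1, as.matrix(env[, sel, drop = FALSE]))
    refit <- lmm_fit(y, X, g)
    expect_equal(information_criteria(refit)[["AICc"]], rk$table$AICc[i],
                 tolerance = 1e-8)
  }
})

test_that("model averaging reduces to the identity for a single top model", {
  set.seed(56)
  n <- 80
  g <- rep(1:8, each = 10)
  env <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- 2 * env$a + rnorm(8, 0, 0.3)[g] + rnorm(n, 0, 0.4)
  rk <- all_subsets(y, env, g)
  if (sum(rk$table$delta_AICc < 2) == 1) {
    avg <- model_average(rk)
    top_terms <- rk$coefs[[1]]
    for (tm in names(top_terms)) {
      row <- avg$terms[avg$terms$term == tm, ]
      expect_equal(row$estimate, unname(top_terms[tm]), tolerance = 1e-12)
      expect_equal(row$se, unname(rk$ses[[1]][tm]), tolerance = 1e-12)
      expect_equal(row$importance, 1)
    }
  }
  # strong predictor: importance 1 and CI excluding zero
  avg <- model_average(rk)
  arow <- avg$terms[avg$terms$term == "a", ]
  expect_equal(arow$importance, 1)
  expect_true(arow$ci_excludes_zero)
})

test_that("full averaging substitutes zero for absent terms (hand example)", {
  # two models with weights 0.6 / 0.4; term x present only in the first
  # (estimate 1.0, se 0.1): averaged estimate 0.6,
  # variance 0.6(0.01 + 0.16) + 0.4(0 + 0.36) = 0.246, SE 0.49598
  tab <- data.frame(terms = c("x", "(null)"), k = c(4, 3),
                    loglik = c(0, 0),
                    AICc = c(0, 2 * log(0.6 / 0.4)),
                    stringsAsFactors = FALSE)
  memb <- matrix(c(TRUE, FALSE), 2, 1, dimnames = list(NULL, "x"))
  rk <- new_subset_ranking(
    tab, memb,
    coefs = list(c(`(Intercept)` = 0.2, x = 1.0), c(`(Intercept)` = 0.1)),
    ses = list(c(`(Intercept)` = 0.05, x = 0.1), c(`(Intercept)` = 0.05)),
    N = 100
  )
  expect_equal(rk$table$weight, c(0.6, 0.4), tolerance = 1e-12)
  avg <- model_average(rk)
  xrow <- avg$terms[avg$terms$term == "x", ]
  expect_equal(xrow$estimate, 0.6, tolerance = 1e-12)
  expect_equal(xrow$se, sqrt(0.246), tolerance = 1e-12)
  expect_equal(xrow$se, 0.4960, tolerance = 1e-4)
  expect_equal(xrow$importance, 0.6, tolerance = 1e-12)
  expect_equal(xrow$ci_lo, 0.6 - qnorm(0.975) * sqrt(0.246), tolerance = 1e-9)
})

test_that("driver analysis recovers a single true environmental driver", {
  hits <- 0L
  runs <- 25L
  for (seed in seq_len(runs)) {
    cfg <- sim_config(env_beta = c(BO_chlomean = 0.05))
    sim <- simulate_response_table(cfg, seed = 300 + seed)
    rep_ <- driver_analysis(
      sim$table[c("species_id", "band", "pi", "hd")],
      sim$table[c("band", "BO_sstmean", "BO_dissox", "BO_salinity",
                  "BO2_curvelmean_bdmean", "BO_chlomean", "BO22_ph")], "pi")
    ok <- TRUE
    for (nm in rep_$retained_sets) {
      tt <- rep_$averaged[[nm]]$terms
      crow <- tt[tt$term == "BO_chlomean", ]
      if (nrow(crow) == 0 || !crow$ci_excludes_zero || crow$importance <= 0.8) {
        ok <- FALSE
      }
    }
    if (ok) hits <- hits + 1L
  }
  expect_gte(hits, 20L)
})

test_that("pure-noise environments mostly yield CIs that cross zero", {
  cross <- 0L
  total <- 0L
  for (seed in seq_len(15)) {
    cfg <- sim_config(beta = c(0.66, 0, 0))  # no latitude trend either
    sim <- simulate_response_table(cfg, seed = 500 + seed)
    rep_ <- driver_analysis(
      sim$table[c("species_id", "band", "pi", "hd")],
      sim$table[c("band", "BO_sstmean", "BO_dissox", "BO_salinity",
                  "BO2_curvelmean_bdmean", "BO_chlomean", "BO22_ph")], "pi")
    for (nm in rep_$retained_sets) {
      tt <- rep_$averaged[[nm]]$terms
      tt <- tt[tt$term != "(Intercept)", ]
      cross <- cross + sum(!tt$ci_excludes_zero)
      total <- total + nrow(tt)
    }
  }
  expect_gte(cross / total, 0.8)
})

test_that("intraspecific ladders detect humps, accept flats, respect df caps", {
  # hump-shaped species: 12 bands, low noise
  hits <- 0L
  for (seed in 1:25) {
    d <- with_seed(700 + seed, {
      bands <- sort(sample(-20:20, 12))
      z <- as.numeric(zscore(bands))
      data.frame(species_id = "spH", band = bands,
                 pi = 0.6 - 0.3 * z^2 + rnorm(12, 0, 0.05),
                 hd = 0.6 - 0.3 * z^2 + rnorm(12, 0, 0.05))
    })
    tr <- intraspecific_trends(d, metrics = "pi")
    if (tr$results$selected_order[1] >= 2) hits <- hits + 1L
  }
  expect_gte(hits, 20L)

  # flat species -> null model in the clear majority of draws, and the
  # null selection never carries an adjusted R2
  nulls <- 0L
  for (seed in 1:20) {
    flat <- with_seed(800 + seed, data.frame(
      species_id = "spF", band = sort(sample(-20:20, 12)),
      pi = rnorm(12, 0.3, 0.02), hd = rnorm(12, 0.3, 0.02)))
    trf <- intraspecific_trends(flat, metrics = "pi")
    if (trf$results$selected_order[1] == 0) {
      nulls <- nulls + 1L
      expect_true(is.na(trf$results$adj_r_squared[1]))
    }
  }
  expect_gte(nulls, 12L)

  # exactly 4 bands: orders above 2 are never attempted
  four <- data.frame(species_id = "sp4", band = c(1, 3, 5, 9),
                     pi = c(0.1, 0.3, 0.25, 0.12),
                     hd = c(0.4, 0.8, 0.7, 0.5))
  tr4 <- intraspecific_trends(four)
  expect_true(all(tr4$results$selected_order <= 2))
  lad <- tr4$ladders[["sp4:pi"]]
  expect_lte(max(lad$table$order), 2)
})
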