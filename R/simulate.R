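#' Simulation configuration
#'
#' Builds and validates the configuration shared by the synthetic-data
#' generators. Defaults mirror the structure of the study system: 23
#' co-distributed species with one-degree band ranges inside 36N-32S, 5-12
#' sampled bands per species, 3-15 sequences per band, a quadratic
#' diversity-latitude trend with species random intercepts, 600-bp
#' alignments, and an environmental field set containing exactly one strongly
#' collinear pair (sea surface temperature vs dissolved oxygen, inverse).
#'
#' @param S Number of species/lineages (default 23).
#' @param lat_range Study latitude bounds (default `c(-32, 36)`).
#' @param bands_range Range of sampled bands per species (default `c(5, 12)`).
#' @param n_range Range of sequences per band cell (default `c(3, 15)`).
#' @param beta Identity-scale trend coefficients (intercept, linear,
#'   quadratic on the z-scored band latitude) for the response-level
#'   generator.
#' @param sigma2_alpha,sigma2_eps Species-intercept and residual variances
#'   for the response-level generator.
#' @param log_beta Log-scale trend coefficients for the sequence-level
#'   generator: per-cell target diversity is
#'   `mu = exp(b0 + b1 z + b2 z^2 + a_s)`.
#' @param log_sigma2_alpha Species-intercept variance on the log scale.
#' @param L Alignment length (default 600).
#' @param theta_scale,lambda_scale Map target diversity to the
#'   Chinese-restaurant concentration (`theta = theta_scale * mu * L`) and to
#'   the per-haplotype private-mutation mean (`lambda = lambda_scale * mu *
#'   L`).
#' @param env_beta Optional named vector of effects of (z-scored)
#'   environmental columns on the response-level diversity; when given, the
#'   linear predictor is environmental instead of latitudinal.
#' @param chl_mu_coef Injected association between chlorophyll-a and the
#'   per-band mean target diversity (default 0 = none).
#' @param env Environmental field parameters (see defaults in the source).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(S = 23,
                       lat_range = c(-32, 36),
                       bands_range = c(5, 12),
                       n_range = c(3, 15),
                       beta = c(0.66, 0, -0.05),
                       sigma2_alpha = 0.015,
                       sigma2_eps = 0.02,
                       log_beta = c(log(0.006), 0, -0.5),
                       log_sigma2_alpha = 0.09,
                       L = 600,
                       theta_scale = 1,
                       lambda_scale = 0.5,
                       env_beta = NULL,
                       chl_mu_coef = 0,
                       env = list()) {
  env_defaults <- list(
    sst_base = 28, sst_lat = 0.25, sst_sd = 1,
    do_base = 350, do_slope = 4, do_sd = 6,
    sal_mean = 35, sal_sd = 1,
    cur_mean = 0.1, cur_sd = 0.05,
    chl_base = 0.3, chl_sd = 0.1,
    ph_mean = 8.05, ph_sd = 0.05,
    r_target = -0.7, max_redraws = 100
  )
  env <- utils::modifyList(env_defaults, env)
  cfg <- list(S = S, lat_range = lat_range, bands_range = bands_range,
              n_range = n_range, beta = beta, sigma2_alpha = sigma2_alpha,
              sigma2_eps = sigma2_eps, log_beta = log_beta,
              log_sigma2_alpha = log_sigma2_alpha, L = L,
              theta_scale = theta_scale, lambda_scale = lambda_scale,
              env_beta = env_beta, chl_mu_coef = chl_mu_coef, env = env)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$S) || cfg$S < 2) stop_("S must be an integer >= 2")
  if (length(cfg$lat_range) != 2 || diff(cfg$lat_range) <= 0 ||
      any(abs(cfg$lat_range) > 90)) {
    stop_("lat_range must be an increasing pair within [-90, 90]")
  }
  if (length(cfg$bands_range) != 2 || cfg$bands_range[1] < 4 ||
      diff(cfg$bands_range) < 0) {
    stop_("bands_range must be a non-decreasing pair with minimum >= 4")
  }
  if (length(cfg$n_range) != 2 || cfg$n_range[1] < 3 || diff(cfg$n_range) < 0) {
    stop_("n_range must be a non-decreasing pair with minimum >= 3")
  }
  if (length(cfg$beta) != 3 || length(cfg$log_beta) != 3) {
    stop_("beta and log_beta must have 3 coefficients (intercept, z, z^2)")
  }
  for (v in c("sigma2_alpha", "sigma2_eps", "log_sigma2_alpha",
              "theta_scale", "lambda_scale")) {
    if (!is.numeric(cfg[[v]]) || length(cfg[[v]]) != 1 || cfg[[v]] < 0) {
      stop_(v, " must be a non-negative scalar")
    }
  }
  if (!is_count(cfg$L) || cfg$L < 1) stop_("L must be a positive integer")
  invisible(cfg)
}

# Draw the per-species sampling layout: which one-degree bands each species
# occupies (contiguous ranges inside the study bounds, bands scattered within)
# and how many sequences per cell.
simulate_species_layout <- function(cfg) {
  lo_all <- ceiling(cfg$lat_range[1])
  hi_all <- floor(cfg$lat_range[2])
  rows <- lapply(seq_len(cfg$S), function(s) {
    nb <- sample(seq(cfg$bands_range[1], cfg$bands_range[2]), 1)
    span <- min(nb - 1L + sample(0:14, 1), hi_all - lo_all)
    lo <- sample(seq(lo_all, hi_all - span), 1)
    bands <- sort(sample(seq(lo, lo + span), nb))
    data.frame(species_id = sprintf("sp%02d", s), band = bands,
               n = sample(seq(cfg$n_range[1], cfg$n_range[2]), nb,
                          replace = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a band-level diversity response table
#'
#' Generates per-(species, band) responses under the model the pooled
#' analysis assumes: `y = b0 + b1 z + b2 z^2 + a_s + eps` with species
#' intercepts `a_s ~ N(0, sigma2_alpha)` and residuals
#' `eps ~ N(0, sigma2_eps)`, on the z-scored band latitude. `pi` and `hd`
#' columns are drawn independently from the same structure. Environmental
#' fields for the occupied bands are attached; when `cfg$env_beta` is set the
#' linear predictor is built from the z-scored environmental columns instead
#' of latitude (for driver-recovery experiments).
#'
#' @param cfg A [sim_config()].
#' @param seed RNG seed; the output is deterministic given the seed.
#' @return List with `table` (species_id, band, lat_z, pi, hd + environmental
#'   columns), `truth` (coefficients, species intercepts, per-row expected
#'   values, seed, config) and `config`.
#' @export
simulate_response_table <- function(cfg = sim_config(), seed = NULL) {
  validate_sim_config(cfg)
  with_seed(seed, {
    layout <- simulate_species_layout(cfg)
    env <- simulate_env_fields(cfg, bands = sort(unique(layout$band)))
    tab <- merge(layout, env, by.x = "band", by.y = "band_key")
    tab <- tab[order(tab$species_id, tab$band), ]
    rownames(tab) <- NULL
    z <- as.numeric(zscore(tab$band))
    sp <- factor(tab$species_id)
    a_pi <- stats::rnorm(nlevels(sp), 0, sqrt(cfg$sigma2_alpha))
    a_hd <- stats::rnorm(nlevels(sp), 0, sqrt(cfg$sigma2_alpha))
    if (is.null(cfg$env_beta)) {
      lp <- cfg$beta[1] + cfg$beta[2] * z + cfg$beta[3] * z^2
      env_coef <- NULL
    } else {
      miss <- setdiff(names(cfg$env_beta), names(tab))
      if (length(miss) > 0) stop_("env_beta names not in env table: ",
                                  paste(miss, collapse = ", "))
      Zenv <- vapply(names(cfg$env_beta),
                     function(v) as.numeric(zscore(tab[[v]])),
                     numeric(nrow(tab)))
      lp <- cfg$beta[1] + drop(Zenv %*% cfg$env_beta)
      env_coef <- cfg$env_beta
    }
    N <- nrow(tab)
    tab$lat_z <- as.numeric(z)
    tab$pi <- lp + a_pi[as.integer(sp)] + stats::rnorm(N, 0, sqrt(cfg$sigma2_eps))
    tab$hd <- lp + a_hd[as.integer(sp)] + stats::rnorm(N, 0, sqrt(cfg$sigma2_eps))
    truth <- list(beta = cfg$beta, env_beta = env_coef,
                  a_pi = stats::setNames(a_pi, levels(sp)),
                  a_hd = stats::setNames(a_hd, levels(sp)),
                  mu = lp, seed = seed, config = unclass(cfg))
    list(table = tab, truth = truth, config = cfg)
  })
}

#' Chinese-restaurant haplotype counts
#'
#' Sequentially seats `n` sequences: sequence i joins an existing haplotype
#' class of size `n_k` with probability `n_k / (i - 1 + theta)` and founds a
#' new one with probability `theta / (i - 1 + theta)` (the Ewens sampling
#' scheme). `theta = 0` gives a monomorphic cell; large `theta` gives
#' all-singleton cells.
#'
#' @param n Number of sequences (>= 1).
#' @param theta Non-negative concentration parameter.
#' @return Integer vector of class sizes summing to `n`.
#' @export
crp_counts <- function(n, theta) {
  if (!is_count(n) || n < 1) stop_("n must be a positive integer")
  if (theta < 0) stop_("theta must be non-negative")
  counts <- c(1L)
  for (i in seq_len(n - 1L) + 1L) {
    p_new <- theta / (i - 1 + theta)
    if (stats::runif(1) < p_new) {
      counts <- c(counts, 1L)
    } else {
      k <- sample.int(length(counts), 1, prob = counts)
      counts[k] <- counts[k] + 1L
    }
  }
  counts
}

# Mutate a reference (character vector) at m random positions, avoiding the
# original base at each mutated site.
mutate_reference <- function(ref, m) {
  bases <- c("A", "C", "G", "T")
  L <- length(ref)
  m <- min(m, L)
  if (m == 0) return(ref)
  pos <- sample.int(L, m)
  for (p in pos) {
    ref[p] <- sample(setdiff(bases, ref[p]), 1)
  }
  ref
}

#' Simulate georeferenced sequence data with a latitudinal diversity trend
#'
#' Star-genealogy generator: per (species, band) cell, haplotype classes are
#' drawn by a Chinese-restaurant scheme with concentration
#' `theta = theta_scale * mu * L`, and each haplotype carries
#' `Poisson(lambda_scale * mu * L)` private substitutions away from a
#' species-level reference sequence (collisions redrawn, so distinct classes
#' stay distinct whenever possible). The per-cell target diversity is
#' `mu = exp(b0 + b1 z + b2 z^2 + a_s)` on the z-scored band latitude, so
#' both the haplotype richness and the mutation load rise monotonically with
#' `mu`. Each individual receives a latitude uniform within its band
#' (hemisphere preserved) and a longitude in the western Atlantic range.
#'
#' @param cfg A [sim_config()].
#' @param seed RNG seed.
#' @param dir Optional output directory: writes `sequences.fasta`,
#'   `metadata.tsv` and `truth.json` (seed and full config embedded).
#' @return List with `records` (accession, species_id, latitude, longitude,
#'   sequence), `truth` (log-scale coefficients, species intercepts, per-cell
#'   `mu`, seed, config) and `config`.
#' @export
simulate_sequences <- function(cfg = sim_config(), seed = NULL, dir = NULL) {
  validate_sim_config(cfg)
  out <- with_seed(seed, {
    layout <- simulate_species_layout(cfg)
    z <- as.numeric(zscore(layout$band))
    sp <- factor(layout$species_id)
    a_s <- stats::rnorm(nlevels(sp), 0, sqrt(cfg$log_sigma2_alpha))
    mu <- exp(cfg$log_beta[1] + cfg$log_beta[2] * z + cfg$log_beta[3] * z^2 +
                a_s[as.integer(sp)])
    refs <- lapply(levels(sp), function(s) {
      sample(c("A", "C", "G", "T"), cfg$L, replace = TRUE)
    })
    names(refs) <- levels(sp)
    recs <- vector("list", nrow(layout))
    counter <- 0L
    for (i in seq_len(nrow(layout))) {
      n <- layout$n[i]
      theta <- cfg$theta_scale * mu[i] * cfg$L
      lam <- cfg$lambda_scale * mu[i] * cfg$L
      counts <- crp_counts(n, theta)
      ref <- refs[[layout$species_id[i]]]
      haps <- character(0)
      for (k in seq_along(counts)) {
        for (try in 1:50) {
          h <- paste0(mutate_reference(ref, stats::rpois(1, lam)),
                      collapse = "")
          if (!h %in% haps) break
        }
        haps <- c(haps, h)
      }
      seqs <- rep(haps, counts)
      b <- layout$band[i]
      lat <- if (b > 0) b + stats::runif(n, 0, 0.999) else
        if (b < 0) b - stats::runif(n, 0, 0.999) else
          stats::runif(n, -0.999, 0.999)
      recs[[i]] <- data.frame(
        accession = sprintf("SIM%06d", counter + seq_len(n)),
        species_id = layout$species_id[i],
        latitude = lat,
        longitude = stats::runif(n, -60, -30),
        sequence = seqs, stringsAsFactors = FALSE
      )
      counter <- counter + n
    }
    records <- do.call(rbind, recs)
    truth <- list(log_beta = cfg$log_beta,
                  a_s = stats::setNames(a_s, levels(sp)),
                  cells = data.frame(species_id = layout$species_id,
                                     band = layout$band, n = layout$n,
                                     mu = mu, stringsAsFactors = FALSE),
                  seed = seed, config = unclass(cfg))
    list(records = records, truth = truth, config = cfg)
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dna <- Biostrings::DNAStringSet(
      stats::setNames(out$records$sequence, out$records$accession))
    Biostrings::writeXStringSet(dna, file.path(dir, "sequences.fasta"))
    utils::write.table(
      out$records[c("accession", "species_id", "latitude", "longitude")],
      file.path(dir, "metadata.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(out$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

#' Simulate band-level environmental fields
#'
#' One row per occupied band. Sea surface temperature decreases with
#' absolute latitude (plus noise); dissolved oxygen is an inverse-linear
#' function of SST with small noise, giving one strongly collinear pair
#' (target realized r at or below `env$r_target`); salinity, current
#' velocity and pH are weakly structured noise; chlorophyll-a optionally
#' carries an injected association with a supplied per-band diversity target
#' (`chl_mu_coef`). Fields failing the correlation constraints are redrawn
#' up to `env$max_redraws` times, then a hard error suggests changing the
#' parameters.
#'
#' @param cfg A [sim_config()].
#' @param seed RNG seed (or `NULL` to draw from the current stream).
#' @param bands Integer vector of occupied bands.
#' @param mu_band Optional per-band diversity target for the chlorophyll
#'   injection (same length as `bands`).
#' @return Data frame with `band_key`, `lat`, `lon` and the six layer columns
#'   `BO_sstmean`, `BO_dissox`, `BO_salinity`, `BO2_curvelmean_bdmean`,
#'   `BO_chlomean`, `BO22_ph`.
#' @export
simulate_env_fields <- function(cfg = sim_config(), seed = NULL,
                                bands = seq(-32, 36), mu_band = NULL) {
  validate_sim_config(cfg)
  if (!is.null(mu_band) && length(mu_band) != length(bands)) {
    stop_("mu_band must match bands")
  }
  e <- cfg$env
  with_seed(seed, {
    lat <- ifelse(bands >= 0, bands + 0.5, bands - 0.5)
    nb <- length(bands)
    for (draw in seq_len(e$max_redraws)) {
      sst <- e$sst_base - e$sst_lat * abs(lat) + stats::rnorm(nb, 0, e$sst_sd)
      dox <- e$do_base - e$do_slope * sst + stats::rnorm(nb, 0, e$do_sd)
      chl <- e$chl_base + stats::rnorm(nb, 0, e$chl_sd)
      if (cfg$chl_mu_coef != 0 && !is.null(mu_band)) {
        chl <- chl + cfg$chl_mu_coef * as.numeric(zscore(mu_band))
      }
      sal <- stats::rnorm(nb, e$sal_mean, e$sal_sd)
      cur <- abs(stats::rnorm(nb, e$cur_mean, e$cur_sd))
      ph <- stats::rnorm(nb, e$ph_mean, e$ph_sd)
      tab <- data.frame(band_key = bands, lat = lat,
                        lon = stats::runif(nb, -60, -30),
                        BO_sstmean = sst, BO_dissox = dox, BO_salinity = sal,
                        BO2_curvelmean_bdmean = cur, BO_chlomean = chl,
                        BO22_ph = ph, stringsAsFactors = FALSE)
      r <- suppressWarnings(stats::cor(tab[, 4:9]))
      r[!is.finite(r)] <- 0
      r_sd <- r["BO_sstmean", "BO_dissox"]
      others <- r
      others["BO_sstmean", "BO_dissox"] <- others["BO_dissox", "BO_sstmean"] <- 0
      diag(others) <- 0
      weak <- c("BO_salinity", "BO2_curvelmean_bdmean", "BO_chlomean", "BO22_ph")
      if (r_sd <= e$r_target && max(abs(others)) < 0.7 &&
          max(abs(r[weak, weak] - diag(length(weak)))) < 0.5) {
        return(tab)
      }
    }
    stop_("environmental fields failed the correlation constraints after ",
          e$max_redraws, " redraws; adjust the env parameters")
  })
}
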