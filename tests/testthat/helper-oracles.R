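# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: brute-force pair enumeration for
# diversity, dense-matrix Gaussian likelihood for the mixed model.

# Nucleotide diversity by explicit enumeration of all C(n,2) sequence pairs.
brute_force_pi <- function(sample) {
  seqs <- expand_haplotypes(sample)
  n <- length(seqs)
  L <- nchar(seqs[1])
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      tot <- tot + sum(m[i, ] != m[j, ]) / L
    }
  }
  tot / choose(n, 2)
}

# Random haplotype sample with n <= n_max sequences over k distinct haplotypes.
random_hap_sample <- function(n_max = 12, L = 25) {
  n <- sample(2:n_max, 1)
  k <- sample(seq_len(min(n, 5)), 1)
  haps <- character(0)
  while (length(haps) < k) {
    h <- paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    if (!h %in% haps) haps <- c(haps, h)
  }
  counts <- tabulate(c(seq_len(k), sample.int(k, n - k, replace = TRUE)), k)
  collapse_haplotypes(rep(haps, counts), "spX", 0L)
}

# Gaussian log-likelihood of the random-intercept model at fixed variances,
# with the fixed effects profiled by dense GLS. No Woodbury shortcuts.
dense_lmm_loglik <- function(y, X, groups, s2a, s2e) {
  g <- factor(groups)
  Z <- stats::model.matrix(~ 0 + g)
  N <- length(y)
  V <- s2e * diag(N) + s2a * tcrossprod(Z)
  cf <- chol(V)
  Vi <- chol2inv(cf)
  A <- t(X) %*% Vi %*% X
  b <- t(X) %*% Vi %*% y
  beta <- solve(A, b)
  r <- y - X %*% beta
  -0.5 * (N * log(2 * pi) + 2 * sum(log(diag(cf))) +
            drop(t(r) %*% Vi %*% r))
}

# Grid-search likelihood maximum for balanced group designs: one dense
# Cholesky of the (identical) per-group covariance block per grid point.
grid_loglik_max <- function(y, X, groups, ngrid = 200,
                            log_range = c(-4, 4)) {
  g <- factor(groups)
  G <- nlevels(g)
  ns <- as.integer(table(g))
  stopifnot(length(unique(ns)) == 1)
  m <- ns[1]
  N <- length(y)
  p <- ncol(X)
  ord <- order(as.integer(g))
  Ym <- matrix(y[ord], nrow = m)
  Xs <- lapply(seq_len(p), function(j) matrix(X[ord, j], nrow = m))
  J <- matrix(1, m, m)
  gridv <- exp(seq(log_range[1], log_range[2], length.out = ngrid))
  best <- -Inf
  for (s2a in gridv) {
    for (s2e in gridv) {
      V <- s2e * diag(m) + s2a * J
      cf <- chol(V)
      Vi <- chol2inv(cf)
      W <- lapply(Xs, function(Xj) Vi %*% Xj)
      A <- matrix(0, p, p)
      b <- numeric(p)
      ViY <- Vi %*% Ym
      for (j in seq_len(p)) {
        b[j] <- sum(Xs[[j]] * ViY)
        for (k in seq_len(p)) A[j, k] <- sum(Xs[[j]] * W[[k]])
      }
      beta <- solve(A, b)
      quad <- sum(Ym * ViY) - 2 * sum(b * beta) + drop(t(beta) %*% A %*% beta)
      ll <- -0.5 * (N * log(2 * pi) + G * 2 * sum(log(diag(cf))) + quad)
      if (ll > best) best <- ll
    }
  }
  best
}

# Sequence-level end-to-end run: simulate, band, filter, estimate, fit the
# pooled mixed ladder for nucleotide diversity.
e2e_pi_ladder <- function(seed, cfg) {
  sim <- simulate_sequences(cfg, seed = seed)
  cells <- band_cells(sim$records)
  filt <- apply_species_filters(cells)
  div <- estimate_all(filt$cells, sim$records)
  pooled <- multispecies_band_filter(div)
  polynomial_ladder(pooled$pi, pooled$band, groups = pooled$species_id)
}

# Small balanced mixed-model dataset with known parameters.
sim_balanced <- function(seed, G = 20, m = 10, beta = c(1, 0.5),
                         s2a = 1, s2e = 1) {
  with_seed(seed, {
    g <- rep(seq_len(G), each = m)
    x <- stats::rnorm(G * m)
    X <- cbind(`(Intercept)` = 1, x = x)
    y <- drop(X %*% beta) + stats::rnorm(G, 0, sqrt(s2a))[g] +
      stats::rnorm(G * m, 0, sqrt(s2e))
    list(y = y, X = X, g = g)
  })
}

# Write a record set as FASTA + metadata CSV in a temp dir.
write_fixture_files <- function(records, dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "seqs.fasta")
  writeLines(paste0(">", records$accession, "\n", records$sequence), fasta)
  meta <- file.path(dir, "meta.csv")
  utils::write.csv(records[c("accession", "species_id", "latitude",
                             "longitude")], meta, row.names = FALSE)
  list(fasta = fasta, metadata = meta)
}
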