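# shared fixtures and independent oracles for the test suite

withr_local_tempfile <- function(ext = "") tempfile(fileext = ext)

# hard (MAP) ancestry calls from nested posteriors
hard_call <- function(X) {
  lapply(X, function(ind) lapply(ind, function(hp) lapply(hp, function(M) {
    Z <- matrix(0, nrow(M), ncol(M))
    Z[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))] <- 1
    Z
  })))
}

# nested truth-track structure matching the pipeline's posterior shape
truth_tracks <- function(truth, hs, grid) {
  smp <- unique(hs$samples$sample[hs$samples$panel == "target"])
  lapply(stats::setNames(smp, smp), function(s)
    lapply(1:2, function(h)
      stats::setNames(lapply(names(grid$chroms), function(ch)
        truth_matrix(truth, grid, paste0(s, "_", h), ch)),
        names(grid$chroms))))
}

# small random-but-valid model parameters for fuzzing
random_params <- function(A = 2, P = 2, targets = "t") {
  mu <- matrix(runif(P * A), P, A)
  mu <- sweep(mu, 2, colSums(mu), "/")
  Pi <- matrix(runif(A * A, 0, 0.9 / A), A, A)
  model_params(A, paste0("p", seq_len(P)),
               stats::setNames(rep(2L, P), paste0("p", seq_len(P))),
               mu, rho = runif(1), theta = runif(1, 0.01, 0.49),
               Pi = Pi, targets = targets)
}

# random tiny match-count instance (K donors, G gridpoints)
random_instance <- function(G = 4, K = 3, n_obs = 2, max_sites = 3) {
  gp <- sort(sample.int(G, n_obs))
  list(gp = gp,
       match = matrix(sample(0:max_sites, K * n_obs, TRUE), K),
       mismatch = matrix(sample(0:max_sites, K * n_obs, TRUE), K),
       n_grid = G)
}

# exhaustive path-enumeration oracle for the two-layer HMM: returns loglik,
# per-gridpoint ancestry posteriors and per-gridpoint donor posteriors
enumerate_oracle <- function(counts, donor_panel, params, target = 1) {
  A <- params$A; K <- length(donor_panel); S <- A * K; G <- counts$n_grid
  Tm <- admixpaint:::transition_matrix(params, donor_panel, target)
  init <- suppressWarnings(initial_distribution(params, donor_panel, target))
  em <- matrix(0, S, G)
  for (i in seq_along(counts$gp))
    for (a in seq_len(A)) for (j in seq_len(K))
      em[(a - 1) * K + j, counts$gp[i]] <-
        emission_logprob(counts$match[j, i], counts$mismatch[j, i],
                         params$theta)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), G)))
  lp <- apply(paths, 1, function(pp) {
    v <- log(init[pp[1]]) + em[pp[1], 1]
    for (g in seq_len(G - 1))
      v <- v + log(Tm[pp[g], pp[g + 1]]) + em[pp[g + 1], g + 1]
    v
  })
  mx <- max(lp)
  ll <- mx + log(sum(exp(lp - mx)))
  w <- exp(lp - mx); w <- w / sum(w)
  X <- matrix(0, G, A)
  gd <- matrix(0, G, K)
  for (g in seq_len(G)) {
    for (a in seq_len(A))
      X[g, a] <- sum(w[paths[, g] %in% ((a - 1) * K + seq_len(K))])
    for (j in seq_len(K))
      gd[g, j] <- sum(w[(paths[, g] - 1) %% K + 1 == j])
  }
  list(loglik = ll, X = X, gamma_donor = gd)
}

# independent log-space forward pass in R (no scaling tricks)
logspace_forward <- function(counts, donor_panel, params, target = 1) {
  Tm <- admixpaint:::transition_matrix(params, donor_panel, target)
  init <- suppressWarnings(initial_distribution(params, donor_panel, target))
  A <- params$A; K <- length(donor_panel); S <- A * K; G <- counts$n_grid
  em <- matrix(0, S, G)
  for (i in seq_along(counts$gp))
    for (a in seq_len(A)) for (j in seq_len(K))
      em[(a - 1) * K + j, counts$gp[i]] <-
        emission_logprob(counts$match[j, i], counts$mismatch[j, i],
                         params$theta)
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  la <- log(init) + em[, 1]
  if (G > 1) for (g in 2:G)
    la <- vapply(seq_len(S), function(s)
      lse(la + log(Tm[, s])) + em[s, g], numeric(1))
  lse(la)
}

# small two-population admixture study for fast end-to-end tests
small_study <- function(seed = 1, lambda_gen = 30, n_targets = 3,
                        n_sites = 600, chr_lengths = c(chr1 = 40, chr2 = 40),
                        n_per_pop = 24, A = 2, n_pops = 2, ...) {
  simulate_admixture_study(n_pops = n_pops, A = A, n_sites = n_sites,
                           chr_lengths_cM = chr_lengths,
                           n_per_pop = n_per_pop, lambda_gen = lambda_gen,
                           n_targets = n_targets, seed = seed, ...)
}
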