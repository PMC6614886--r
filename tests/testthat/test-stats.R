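test_that("expected r-squared matches hand arithmetic and hard limits", {
  # hard assignment: exactly 1
  X <- cbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(expected_r2_haploid(X), 1)
  # worked example: Xa = (1, 0, .5, .5) -> 0.5 per ancestry
  X2 <- cbind(c(1, 0, 0.5, 0.5), c(0, 1, 0.5, 0.5))
  expect_equal(expected_r2_haploid(X2), 0.5)
  # constant ancestry excluded with a warning
  expect_warning(expected_r2_haploid(cbind(rep(1, 4), rep(0, 4))),
                 "constant")
})

test_that("diploid expected r-squared handles the uninformative corner", {
  # X1 = X2 = 0.5 everywhere: numerator 0, denominator G/2, value 0
  X1 <- cbind(rep(0.5, 10), rep(0.5, 10))
  expect_equal(expected_r2_diploid(X1, X1), 0)
  H1 <- cbind(c(1, 0, 1), c(0, 1, 0)); H2 <- cbind(c(1, 1, 0), c(0, 0, 1))
  expect_equal(expected_r2_diploid(H1, H2), 1)
})

test_that("expected r-squared formulas agree with Monte-Carlo sampling", {
  set.seed(81)
  G <- 400
  x <- runif(G, 0.05, 0.95)
  X <- cbind(x, 1 - x)
  # haploid: sample Z ~ Bernoulli(X), average the realised r2
  r2s <- replicate(4000, {
    z <- rbinom(G, 1, x)
    if (sd(z) == 0) return(NA_real_)
    mean(c(stats::cor(x, z)^2, stats::cor(1 - x, 1 - z)^2))
  })
  expect_equal(expected_r2_haploid(X), mean(r2s, na.rm = TRUE),
               tolerance = 0.01)
  # diploid: Z is the sum of two independent Bernoullis
  x2 <- runif(G, 0.05, 0.95)
  X1 <- cbind(x, 1 - x); X2 <- cbind(x2, 1 - x2)
  d <- x + x2
  r2d <- replicate(4000, {
    z <- rbinom(G, 1, x) + rbinom(G, 1, x2)
    mean(c(stats::cor(d, z)^2, stats::cor(2 - d, 2 - z)^2))
  })
  expect_equal(expected_r2_diploid(X1, X2), mean(r2d), tolerance = 0.01)
})

test_that("r2 against truth is permutation-aware and null-calibrated", {
  set.seed(82)
  G <- 10000
  z <- rbinom(G, 1, 0.5)
  Z <- cbind(z, 1 - z)
  expect_equal(r2_vs_truth(Z, Z)$r2, 1)
  # label-swapped truth still scores 1 via the permutation, and the
  # signed-correlation tie-break identifies the swap
  expect_equal(r2_vs_truth(Z[, 2:1], Z)$r2, 1)
  expect_equal(r2_vs_truth(Z[, 2:1], Z)$perm, c(2L, 1L))
  # independent noise: near zero
  x <- runif(G)
  expect_lt(r2_vs_truth(cbind(x, 1 - x), Z)$r2, 0.02)
})

test_that("posterior-based confidence overestimates realised accuracy", {
  # with estimated parameters the model is mildly misspecified, so E[r2]
  # should sit at or above the realised r2 on average
  diffs <- vapply(1:3, function(s) {
    st <- small_study(seed = 90 + s, n_targets = 3)
    fit <- suppressWarnings(
      run_pipeline(st$haps, run_config(A = 2, n_boot = 0, seed = s,
                                       rounds = 2, shared_Pi = TRUE)))
    fit$expected_r2 - score_vs_truth(fit, st$truth)$r2
  }, numeric(1))
  expect_gt(mean(diffs), -0.02)
})

test_that("maximal-posterior assignment builds consistent partial genomes", {
  st <- small_study(seed = 83, n_targets = 2)
  grid <- build_grid(st$haps$sites, 60)
  X <- truth_tracks(st$truth, st$haps, grid)
  tg <- which(st$haps$samples$panel == "target")
  hs_t <- haplotype_set(st$haps$haps[tg, ], st$haps$sites,
                        st$haps$samples[tg, ])
  anc <- reconstruct_ancestral_genomes(hs_t, X, grid)
  # per-site sample sizes count argmax assignments exactly
  expect_equal(colSums(anc$n), rep(4L, ncol(hs_t$haps)))  # 4 haplotypes
  expect_true(all(anc$count <= anc$n))
  # hard truth: every assigned allele comes from the true source population
  # so ancestry-1 genome should be closer to pop1 than to pop2
  pop1 <- st$haps$haps[st$haps$samples$panel == "pop1", ]
  pop2 <- st$haps$haps[st$haps$samples$panel == "pop2", ]
  p_a1 <- anc$count[1, ] / pmax(anc$n[1, ], 1)
  f11 <- fst_weir_cockerham(p_a1, anc$n[1, ], colMeans(pop1),
                            rep(nrow(pop1), ncol(pop1)))
  f12 <- fst_weir_cockerham(p_a1, anc$n[1, ], colMeans(pop2),
                            rep(nrow(pop2), ncol(pop2)))
  expect_lt(f11, f12)
  # uniform posteriors: ties break to the lowest ancestry index
  Xu <- lapply(X, function(ind) lapply(ind, function(h)
    lapply(h, function(M) matrix(0.5, nrow(M), ncol(M)))))
  ancu <- reconstruct_ancestral_genomes(hs_t, Xu, grid)
  expect_true(all(ancu$n[2, ] == 0L))
})

test_that("Weir-Cockerham Fst matches hand-evaluated sites", {
  # one site, n1 = n2 = 4, p1 = 1, p2 = 0: full differentiation
  expect_equal(fst_weir_cockerham(1, 4, 0, 4), 1)
  # one site, equal frequencies 0.5: small-sample negative expectation
  expect_equal(fst_weir_cockerham(0.5, 4, 0.5, 4), -1 / 3)
  # symmetry and allele-label invariance
  set.seed(84)
  p1 <- runif(300); p2 <- runif(300)
  n1 <- sample(4:10, 300, TRUE); n2 <- sample(4:10, 300, TRUE)
  expect_equal(fst_weir_cockerham(p1, n1, p2, n2),
               fst_weir_cockerham(p2, n2, p1, n1))
  flip <- rbinom(300, 1, 0.5) == 1
  q1 <- ifelse(flip, 1 - p1, p1); q2 <- ifelse(flip, 1 - p2, p2)
  expect_equal(fst_weir_cockerham(p1, n1, p2, n2),
               fst_weir_cockerham(q1, n1, q2, n2))
  # a random split of one large panel shows no differentiation
  set.seed(85)
  freq <- runif(2000, 0.05, 0.95)
  pool <- matrix(rbinom(100 * 2000, 1, rep(freq, each = 100)), nrow = 100)
  expect_lt(abs(admixpaint:::fst_from_haps(pool[1:50, ], pool[51:100, ])),
            0.01)
  # undefined cases flagged
  expect_warning(out <- fst_weir_cockerham(numeric(0), integer(0),
                                           numeric(0), integer(0)),
                 "no usable sites")
  expect_true(is.na(out))
})

test_that("Rst matches hand cases and stays within [0, 2]", {
  # identical divergences: zero
  ft <- matrix(c(0.2, 0.2, 0.05, 0.05), 2, 2, byrow = TRUE)
  expect_equal(rst(t(ft))$pairwise$Rst, 0)
  # single panel, Fst(a) = 0, Fst(b) = F: Rst = 2F
  for (F in c(0.1, 0.5, 1))
    expect_equal(rst(matrix(c(0, F), 2, 1))$pairwise$Rst, 2 * F)
  # fuzz: always in [0, 2]
  set.seed(86)
  for (i in 1:2000) {
    P <- sample(1:6, 1)
    tab <- matrix(runif(2 * P), 2, P)
    r <- rst(tab)$pairwise$Rst
    expect_true(r >= 0 && r <= 2)
  }
  # degenerate panel contributes zero with a warning
  expect_warning(r0 <- rst(matrix(c(0, 0), 2, 1)), "zero Fst")
  expect_equal(r0$pairwise$Rst, 0)
  # negative estimates floored
  expect_warning(rst(matrix(c(-0.01, 0.1), 2, 1)), "floored")
})

test_that("the mean-ancestry scan finds a planted peak and masks deserts", {
  set.seed(87)
  st <- small_study(seed = 87, n_targets = 6, n_sites = 1200,
                    chr_lengths = c(chr1 = 60))
  grid <- build_grid(st$haps$sites, 60)
  Z <- truth_tracks(st$truth, st$haps, grid)
  hits <- 0L
  for (s in 1:6) {
    set.seed(100 + s)
    # force ancestry 1 in a 2 cM window around 30 cM in every individual,
    # then add observation noise so the per-gridpoint SE stays positive
    win <- which(grid$chroms$chr1$gridpoint_cM >= 29 &
                   grid$chroms$chr1$gridpoint_cM <= 31)
    dosage <- lapply(Z, function(ind) {
      d <- ind[[1]]$chr1 + ind[[2]]$chr1
      d[win, 1] <- 2; d[win, 2] <- 0
      d <- d + matrix(rnorm(2 * nrow(d), 0, 0.2), ncol = 2)
      list(chr1 = pmin(pmax(d, 0), 2))
    })
    scan <- mean_ancestry_scan(dosage, grid, st$haps$sites, ancestry = 1)
    peak <- scan$gridpoint[which.max(abs(scan$z))]
    if (peak %in% win) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
  # identical constant dosages: z = 0 off-mask
  flat <- lapply(1:4, function(i)
    list(chr1 = matrix(1, grid$chroms$chr1$n_grid, 2)))
  s2 <- mean_ancestry_scan(flat, grid, st$haps$sites)
  expect_true(all(s2$z[!s2$masked] == 0))
  # a 1 Mb window with < 10 markers is masked
  sparse_sites <- st$haps$sites
  drop <- sparse_sites$chrom == "chr1" & sparse_sites$bp >= 10e6 &
    sparse_sites$bp < 11e6
  keep9 <- which(drop)[seq_len(min(9, sum(drop)))]
  sp <- sparse_sites[c(which(!drop), keep9[0]), ]
  sp <- sp[order(sp$bp), ]
  grid_sp <- build_grid(sp, 60)
  flat_sp <- lapply(1:4, function(i)
    list(chr1 = matrix(1, grid_sp$chroms$chr1$n_grid, 2)))
  s3 <- mean_ancestry_scan(flat_sp, grid_sp, sp)
  masked_win <- s3$masked[s3$bp >= 10e6 & s3$bp < 11e6]
  expect_true(all(masked_win))
})
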