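# nested single-target track from a list of per-chromosome matrices
as_track <- function(...) list(t1 = list(list(...)))

test_that("constant posteriors give a flat curve at 1", {
  G <- 2000
  M <- cbind(rep(0.3, G), rep(0.7, G))
  grid <- list(w = 1 / 60,
               chroms = list(chr1 = list(n_grid = G), chr2 = list(n_grid = G)))
  class(grid) <- "ancestry_grid"
  cv <- compute_curves(as_track(chr1 = M, chr2 = M), grid, d_max = 10)
  for (p in 1:3)
    expect_equal(pooled_ratio(cv, p), rep(1, length(cv$lags)),
                 tolerance = 1e-9)
})

test_that("truth tracks show the decay shape and the right rate", {
  st <- simulate_admixture_study(n_sites = 500,
                                 chr_lengths_cM = c(chr1 = 100, chr2 = 100),
                                 n_targets = 15, lambda_gen = 50,
                                 n_per_pop = 8, seed = 61)
  grid <- build_grid(st$haps$sites, 60)
  Z <- truth_tracks(st$truth, st$haps, grid)
  cv <- compute_curves(Z, grid)
  cross <- which(cv$pairs[, 1] == 1 & cv$pairs[, 2] == 2)
  rc <- pooled_ratio(cv, cross)
  expect_lt(rc[1], 1)                      # anticorrelated at short range
  expect_gt(mean(rc[cv$d_cM > 20]), mean(rc[cv$d_cM < 2]))
  same <- which(cv$pairs[, 1] == 1 & cv$pairs[, 2] == 1)
  rs <- pooled_ratio(cv, same)
  expect_gt(rs[1], mean(rs[cv$d_cM > 25]))  # same-pair exceeds asymptote
  est <- estimate_dates(cv)
  expect_equal(est$date, 50, tolerance = 0.1)
  # grid-rate invariance: half the rate, same decay constant within 5%
  grid30 <- build_grid(st$haps$sites, 30)
  est30 <- estimate_dates(compute_curves(truth_tracks(st$truth, st$haps,
                                                      grid30), grid30))
  expect_lt(abs(est30$date - est$date) / est$date, 0.05)
})

test_that("exponential fitting is self-inverse on noiseless curves", {
  d <- seq(0.5, 30, length.out = 60)
  y <- -0.5 * exp(-30 * d / 100) + 1
  f <- fit_exponential(d, y)
  expect_equal(f$delta, -0.5, tolerance = 1e-6)
  expect_equal(f$tau, 1, tolerance = 1e-6)
  expect_equal(f$lam, 30, tolerance = 1e-6)
  # fitted curve approaches tau at large distance
  expect_equal(f$delta * exp(-f$lam * 10) + f$tau, f$tau, tolerance = 1e-9)
  expect_error(fit_exponential(d[1:5], y[1:5]), ">= 10")
})

test_that("date estimation averages pairs or fits one shared rate", {
  st <- simulate_admixture_study(n_sites = 400,
                                 chr_lengths_cM = c(chr1 = 100, chr2 = 100),
                                 n_targets = 10, lambda_gen = 40,
                                 n_per_pop = 8, seed = 62)
  grid <- build_grid(st$haps$sites, 60)
  cv <- compute_curves(truth_tracks(st$truth, st$haps, grid), grid)
  est <- estimate_dates(cv)
  expect_equal(nrow(est$fits), 3)           # 1-1, 1-2, 2-2 for two-way
  expect_equal(est$date, mean(est$fits$lam))
  single <- estimate_dates(cv, mode = "single")
  expect_equal(single$date, 40, tolerance = 0.15 * 40)
})

test_that("a minor ancestry with no mass is flagged unusable", {
  G <- 3000
  M <- cbind(rep(1, G), rep(0, G))
  grid <- list(w = 1 / 60, chroms = list(chr1 = list(n_grid = G)))
  class(grid) <- "ancestry_grid"
  expect_warning(cv <- compute_curves(as_track(chr1 = M), grid),
                 "unusable")
  expect_false(cv$usable[2])
})

test_that("chromosome bootstrap behaves at its degenerate corners", {
  st <- simulate_admixture_study(n_sites = 600,
                                 chr_lengths_cM = c(chr1 = 80, chr2 = 80),
                                 n_targets = 10, lambda_gen = 40,
                                 n_per_pop = 8, seed = 63)
  grid <- build_grid(st$haps$sites, 60)
  cv <- compute_curves(truth_tracks(st$truth, st$haps, grid), grid)
  b0 <- bootstrap_dates(cv, n_boot = 0)
  expect_true(all(is.na(b0$fits$se)))
  # identical chromosomes: resampling cannot move the estimate
  cv2 <- cv
  cv2$num[, , 2] <- cv2$num[, , 1]
  cv2$cnt[, 2] <- cv2$cnt[, 1]
  cv2$sumX[, 2] <- cv2$sumX[, 1]
  cv2$G_per_chrom[2] <- cv2$G_per_chrom[1]
  b <- bootstrap_dates(cv2, n_boot = 10, seed = 1)
  expect_equal(unname(b$fits$se), rep(0, 3), tolerance = 1e-8)
  # single chromosome: cannot bootstrap
  grid1 <- structure(list(w = grid$w, rate_per_cM = grid$rate_per_cM,
                          chroms = grid$chroms["chr1"]),
                     class = "ancestry_grid")
  cv1 <- compute_curves(lapply(truth_tracks(st$truth, st$haps, grid),
                               function(ind) lapply(ind, function(h)
                                 h["chr1"])),
                        grid1)
  expect_error(bootstrap_dates(cv1, 10), ">= 2 chromosomes")
})

test_that("bootstrap intervals usually cover a simulated truth rate", {
  # with only four chromosomes as resampling units, +-2 SE intervals are
  # mildly anti-conservative: measured coverage is ~70%, so at least half
  # of ten seeds must cover
  hits <- 0L
  for (s in 1:10) {
    st <- simulate_admixture_study(n_sites = 600,
                                   chr_lengths_cM = c(chr1 = 60, chr2 = 60,
                                                      chr3 = 60, chr4 = 60),
                                   n_targets = 10, lambda_gen = 50,
                                   n_per_pop = 8, seed = 70 + s)
    grid <- build_grid(st$haps$sites, 60)
    cv <- compute_curves(truth_tracks(st$truth, st$haps, grid), grid)
    b <- bootstrap_dates(cv, n_boot = 40, seed = s)
    cross <- which(b$fits$pair == "1-2")
    if (b$fits$lo[cross] <= 50 && 50 <= b$fits$hi[cross]) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})

test_that("curves across unlinked chromosomes sit at 1", {
  st <- simulate_admixture_study(n_sites = 500,
                                 chr_lengths_cM = c(chr1 = 100, chr2 = 100),
                                 n_targets = 20, lambda_gen = 40,
                                 n_per_pop = 8, seed = 64)
  grid <- build_grid(st$haps$sites, 60)
  Z <- truth_tracks(st$truth, st$haps, grid)
  expect_equal(cross_chromosome_ratio(Z, 1, 2), 1, tolerance = 0.05)
})

test_that("event ordering follows the pairwise date pattern", {
  mk <- function(lam, se) {
    tb <- tibble::tibble(a = c(1, 1, 2), b = c(2, 3, 3),
                         pair = c("1-2", "1-3", "2-3"),
                         lam = lam, se = se, lo = lam - 2 * se,
                         hi = lam + 2 * se, usable = TRUE)
    structure(list(fits = tb, date = mean(lam), n_boot = 10), class = "date_bootstrap")
  }
  expect_equal(order_events(mk(c(30, 31, 29), c(2, 2, 2)))$call,
               "single event")
  expect_equal(order_events(mk(c(80, 31, 29), c(3, 2, 2)))$call,
               "two events")
  expect_equal(order_events(mk(c(80, 50, 20), c(2, 2, 2)))$call,
               "sequential events")
  # two-way: trivially a single event
  tb2 <- tibble::tibble(a = c(1, 1, 2), b = c(1, 2, 2),
                        pair = c("1-1", "1-2", "2-2"), lam = c(30, 30, 30),
                        se = 1, lo = 28, hi = 32, usable = TRUE)
  ord2 <- order_events(structure(list(fits = tb2, date = 30, n_boot = 10),
                                 class = "date_bootstrap"))
  expect_equal(ord2$call, "single event")
})
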