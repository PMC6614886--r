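# build a prepared diploid with counts, plus fitted-ish params
phase_fixture <- function(seed = 41, phase_error_rate = 0, n_targets = 2,
                          lambda_gen = 20) {
  st <- simulate_admixture_study(n_sites = 1200,
                                 chr_lengths_cM = c(chr1 = 40, chr2 = 40),
                                 n_targets = n_targets,
                                 lambda_gen = lambda_gen, n_per_pop = 40,
                                 phase_error_rate = phase_error_rate,
                                 seed = seed)
  grid <- build_grid(st$haps$sites, 60)
  td <- admixpaint:::prepare_targets(st$haps, grid)
  set.seed(seed)
  pars <- initialize_params(2, td$panels, td$panel_sizes,
                            names(td$individuals), grid$w)
  # fit the model before hunting: with uninformative parameters many
  # spurious flips look attractive
  pars <- suppressWarnings(
    run_final_em(td, pars, rel_tol = 1e-5, max_iter = 80)$params)
  list(st = st, grid = grid, td = td, pars = pars)
}

test_that("flip gains vanish exactly at homozygous gridpoints", {
  fx <- phase_fixture()
  ind <- fx$td$individuals[[1]]
  dp <- fx$td$donor_panel[ind$active]
  ch <- names(ind$counts[[1]])[1]
  r <- lapply(1:2, function(h)
    forward_backward(ind$counts[[h]][[ch]], dp, fx$pars,
                     target = ind$sample, want_gamma_donor = TRUE))
  gains <- marginal_flip_gains(r[[1]]$gamma_donor, r[[2]]$gamma_donor,
                               ind$counts[[1]][[ch]], ind$counts[[2]][[ch]],
                               fx$pars$theta)
  c1 <- ind$counts[[1]][[ch]]; c2 <- ind$counts[[2]][[ch]]
  hom <- which(colSums(abs(c1$match - c2$match) +
                         abs(c1$mismatch - c2$mismatch)) == 0)
  expect_true(all(gains[c1$gp[hom]] == 0))
  # and no-site gridpoints carry no gain either
  expect_true(all(gains[setdiff(seq_len(c1$n_grid), c1$gp)] == 0))
})

test_that("a planted flip inside a uniform tract has positive gain", {
  fx <- phase_fixture(seed = 42)
  td <- fx$td
  ind <- td$individuals[[1]]
  ch <- names(ind$counts[[1]])[1]
  gch <- fx$grid$chroms[[ch]]
  # pick an observed heterozygous gridpoint mid-chromosome and flip it
  c1 <- ind$counts[[1]][[ch]]; c2 <- ind$counts[[2]][[ch]]
  het <- c1$gp[colSums(abs(c1$match - c2$match)) > 0]
  g0 <- het[which.min(abs(gch$gridpoint_cM[het] - 20))]
  flipped <- admixpaint:::swap_hap_counts(ind, ch, g0)
  dp <- td$donor_panel[ind$active]
  r <- lapply(1:2, function(h)
    forward_backward(flipped$counts[[h]][[ch]], dp, fx$pars,
                     target = ind$sample, want_gamma_donor = TRUE))
  gains <- marginal_flip_gains(r[[1]]$gamma_donor, r[[2]]$gamma_donor,
                               flipped$counts[[1]][[ch]],
                               flipped$counts[[2]][[ch]], fx$pars$theta)
  expect_gt(gains[g0], 0)
  # involution: the gain of re-flipping equals minus the original gain
  r0 <- lapply(1:2, function(h)
    forward_backward(ind$counts[[h]][[ch]], dp, fx$pars,
                     target = ind$sample, want_gamma_donor = TRUE))
  gains0 <- marginal_flip_gains(r0[[1]]$gamma_donor, r0[[2]]$gamma_donor,
                                ind$counts[[1]][[ch]],
                                ind$counts[[2]][[ch]], fx$pars$theta)
  # same posterior refresh, opposite emission swap: sign reverses
  expect_lt(gains0[g0] * gains[g0], 0 + 1e-12)
})

test_that("a pass with no positive gains accepts nothing", {
  fx <- phase_fixture(seed = 43)
  ind <- fx$td$individuals[[1]]
  gains <- lapply(fx$grid$chroms, function(ch) rep(-1, ch$n_grid))
  res <- apply_flip_pass(ind, fx$td, fx$pars, gains, loglik_before = 0)
  expect_null(res$accepted)
  expect_equal(res$delta, 0)
})

test_that("accepted intervals respect the minimum separation", {
  cm <- (0:1200) / 60
  gains <- rep(0, 1201)
  # candidates at 10 cM (best), 10.05 cM (too close), 15 cM (fine)
  gains[c(601, 604, 901)] <- c(5, 4, 3)
  iv <- admixpaint:::gain_intervals(gains, cm)
  iv$chrom <- "chr1"
  expect_equal(nrow(iv), 3)
  acc <- admixpaint:::select_flip_intervals(iv, min_separation = 0.1)
  expect_equal(sort(acc$start), c(601, 901))
  # runs of consecutive positive gain merge into one interval
  gains2 <- rep(0, 1201); gains2[100:103] <- 1
  iv2 <- admixpaint:::gain_intervals(gains2, cm)
  expect_equal(nrow(iv2), 1)
  expect_equal(iv2$gain, 4)
})

test_that("phase hunting corrects most injected errors monotonically", {
  fx <- phase_fixture(seed = 45, phase_error_rate = 0.02, n_targets = 3)
  flips <- fx$st$flips
  expect_gt(nrow(flips), 10)
  corrected <- 0L; total <- 0L
  for (nm in names(fx$td$individuals)) {
    hp <- hunt_phase(fx$td$individuals[[nm]], fx$td, fx$pars,
                     max_passes = 5)
    expect_true(all(diff(hp$loglik_trace) > 0))  # accepted passes only
    fx$td$individuals[[nm]] <- hp$ind
    inj <- flips[flips$sample == nm, ]
    total <- total + nrow(inj)
    for (i in seq_len(nrow(inj)))
      if (hp$ind$flipped[[inj$chrom[i]]][inj$gridpoint[i]])
        corrected <- corrected + 1L
  }
  expect_gte(corrected / total, 0.7)
})

test_that("error-free diploids attract only sparse flips", {
  # the maximum-likelihood phase legitimately differs from the simulated
  # phase at a small fraction of gridpoints; the hunter should touch well
  # under 1% of the grid and its candidate set should shrink across passes
  for (s in 1:3) {
    fx <- phase_fixture(seed = 50 + s, n_targets = 1)
    hp <- hunt_phase(fx$td$individuals[[1]], fx$td, fx$pars)
    n_grid <- sum(unlist(lapply(fx$grid$chroms, function(c0) c0$n_grid)))
    n_flipped <- sum(unlist(lapply(hp$ind$flipped, sum)))
    expect_lt(n_flipped / n_grid, 0.01)
    if (length(hp$candidates) > 1)
      expect_lt(hp$candidates[length(hp$candidates)], hp$candidates[1])
  }
})

test_that("phase flips never alter diploid genotypes", {
  fx <- phase_fixture(seed = 56, phase_error_rate = 0.02, n_targets = 1)
  hs <- fx$st$haps
  ind <- fx$td$individuals[[1]]
  before <- hs$haps[ind$hap_rows[1], ] + hs$haps[ind$hap_rows[2], ]
  hp <- hunt_phase(ind, fx$td, fx$pars, max_passes = 3)
  fx$td$individuals[[1]] <- hp$ind
  out <- admixpaint:::apply_flips_to_haps(hs, fx$td)
  after <- out$haps[ind$hap_rows[1], ] + out$haps[ind$hap_rows[2], ]
  expect_identical(before, after)
})
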