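# aggregated-count structure for a fully observed (complete-data) path
complete_counts <- function(switch_ba, hapswitch, stay, arrivals,
                            emit_match, emit_mismatch, target = "t") {
  list(per_target = stats::setNames(
    list(list(switch_ba = switch_ba, hapswitch = hapswitch, stay = stay)),
    target),
    pooled = list(arrivals = arrivals, hapswitch = sum(hapswitch),
                  stay = sum(stay), emit_match = emit_match,
                  emit_mismatch = emit_mismatch))
}

test_that("the M-step reproduces complete-data empirical frequencies", {
  prev <- model_params(2, c("p1", "p2"), c(p1 = 2L, p2 = 2L),
                       matrix(0.5, 2, 2), 0.5, 0.01,
                       Pi = matrix(0.1, 2, 2), targets = "t")
  # a hand-built fully observed path over 100 intervals:
  # from ancestry 1: 5 switches to 2, 3 explicit 1->1 switches,
  #                  2 hap switches, 50 stays  (60 source-1 intervals)
  # from ancestry 2: 4 switches to 1, 6 explicit 2->2, 10 hap switch, 20 stay
  sw <- matrix(c(3, 5, 4, 6), 2, 2, byrow = TRUE)
  hsw <- c(2, 10); sty <- c(50, 20)
  arr <- matrix(c(6, 4, 12, 8), 2, 2)  # donor choices per panel | ancestry
  counts <- complete_counts(sw, hsw, sty, arr,
                            emit_match = 980, emit_mismatch = 20)
  up <- m_step(counts, prev)
  expect_equal(up$theta, 20 / 1000)
  expect_equal(up$rho, 12 / (12 + 70))
  expect_equal(up$mu, matrix(c(0.6, 0.4, 0.6, 0.4), 2, 2))
  expect_equal(up$Pi$t[1, ], c(3, 5) / 60)
  expect_equal(up$Pi$t[2, ], c(4, 6) / 40)
})

test_that("symmetric counts give a symmetric switch matrix", {
  prev <- model_params(2, "p", c(p = 4L), matrix(1, 1, 2), 0.5, 0.01,
                       Pi = matrix(0.1, 2, 2), targets = "t")
  sw <- matrix(c(2, 7, 7, 2), 2, 2)
  counts <- complete_counts(sw, c(1, 1), c(40, 40), matrix(c(9, 9), 1, 2),
                            100, 10)
  up <- m_step(counts, prev)
  expect_equal(up$Pi$t, t(up$Pi$t))
})

test_that("all-matching emissions hit the theta floor", {
  prev <- random_params()
  counts <- complete_counts(matrix(1, 2, 2), c(1, 1), c(10, 10),
                            matrix(1, 2, 2), emit_match = 500,
                            emit_mismatch = 0)
  up <- m_step(counts, prev)
  expect_equal(up$theta, 1e-6)
})

test_that("an ancestry never entered keeps its previous copying column", {
  prev <- model_params(2, c("p1", "p2"), c(p1 = 2L, p2 = 2L),
                       matrix(c(0.7, 0.3, 0.2, 0.8), 2, 2), 0.5, 0.01,
                       Pi = matrix(0.1, 2, 2), targets = "t")
  arr <- matrix(c(5, 5, 0, 0), 2, 2)
  counts <- complete_counts(matrix(c(1, 0, 1, 0), 2, 2), c(1, 0), c(10, 0),
                            arr, 100, 10)
  expect_warning(up <- m_step(counts, prev), "never entered")
  expect_equal(up$mu[, 2], prev$mu[, 2])
})

test_that("m_step output is a fixed point of counts drawn from itself", {
  prev <- model_params(2, c("p1", "p2"), c(p1 = 3L, p2 = 3L),
                       matrix(c(0.7, 0.3, 0.2, 0.8), 2, 2),
                       rho = 0.2, theta = 0.05,
                       Pi = matrix(c(0.02, 0.03, 0.04, 0.05), 2, 2,
                                   byrow = TRUE), targets = "t")
  C <- c(600, 400)  # intervals with source ancestry 1 / 2
  sw <- prev$Pi$t * C
  hsw <- (1 - rowSums(prev$Pi$t)) * prev$rho * C
  sty <- (1 - rowSums(prev$Pi$t)) * (1 - prev$rho) * C
  arriv <- sweep(prev$mu, 2, colSums(sw) + hsw, "*")
  counts <- complete_counts(sw, hsw, sty, arriv,
                            emit_match = (1 - prev$theta) * 1e4,
                            emit_mismatch = prev$theta * 1e4)
  up <- m_step(counts, prev)
  expect_equal(up$theta, prev$theta, tolerance = 1e-10)
  expect_equal(up$rho, prev$rho, tolerance = 1e-10)
  expect_equal(up$mu, prev$mu, tolerance = 1e-10)
  expect_equal(up$Pi$t, prev$Pi$t, tolerance = 1e-10)
})

test_that("initialisation satisfies every parameter invariant", {
  set.seed(31)
  p <- initialize_params(2, c("a", "b", "c", "d"),
                         c(a = 5L, b = 5L, c = 5L, d = 5L),
                         targets = c("t1", "t2"), grid_w_cM = 1 / 60)
  expect_equal(colSums(p$mu), c(1, 1))
  expect_false(isTRUE(all.equal(p$mu[, 1], p$mu[, 2])))  # jitter broke ties
  # Pi entries: alpha0 * lambda0 * w = 0.5 * 30 / 6000
  expect_equal(p$Pi$t1, matrix(0.0025, 2, 2))
  set.seed(31)
  p2 <- initialize_params(2, c("a", "b", "c", "d"),
                          c(a = 5L, b = 5L, c = 5L, d = 5L),
                          targets = c("t1", "t2"), grid_w_cM = 1 / 60)
  expect_identical(p$mu, p2$mu)
})

test_that("EM log-likelihood is non-decreasing across seeded simulations", {
  for (s in 1:20) {
    st <- simulate_admixture_study(n_sites = 200,
                                   chr_lengths_cM = c(chr1 = 10),
                                   n_targets = 2, lambda_gen = 30,
                                   n_per_pop = 8, seed = 200 + s)
    grid <- build_grid(st$haps$sites, 60)
    td <- admixpaint:::prepare_targets(st$haps, grid)
    set.seed(s)
    pars <- initialize_params(2, td$panels, td$panel_sizes,
                              names(td$individuals), grid$w)
    stt <- run_round(td, pars, n_iter = 10)   # errors on any real decrease
    expect_true(all(diff(stt$loglik_trace) >
                      -1e-6 * abs(stt$loglik_trace[-10])))
  }
})

test_that("final EM stops on convergence and flags it", {
  st <- small_study(seed = 32, n_sites = 200, n_targets = 2,
                    chr_lengths = c(chr1 = 15), n_per_pop = 10)
  grid <- build_grid(st$haps$sites, 60)
  td <- admixpaint:::prepare_targets(st$haps, grid)
  set.seed(32)
  pars <- initialize_params(2, td$panels, td$panel_sizes,
                            names(td$individuals), grid$w)
  fin <- run_final_em(td, pars, rel_tol = 1e-4, max_iter = 100)
  expect_true(fin$converged)
  # converged params barely move under one more EM cycle
  again <- run_round(td, fin$params, n_iter = 1)
  expect_equal(again$params$theta, fin$params$theta, tolerance = 1e-3)
  # rel_tol = 0 runs to the cap (by request, so without complaint)
  fin0 <- run_final_em(td, pars, rel_tol = 0, max_iter = 3)
  expect_length(fin0$loglik_trace, 3)
  expect_false(fin0$converged)
})

test_that("EM recovers theta and concentrates mu on the true sources", {
  st <- simulate_admixture_study(n_sites = 1200,
                                 chr_lengths_cM = c(chr1 = 50, chr2 = 50),
                                 n_targets = 8, lambda_gen = 30,
                                 n_per_pop = 40, seed = 33)
  fit <- run_pipeline(st$haps, run_config(A = 2, n_boot = 0, seed = 33,
                                          shared_Pi = TRUE,
                                          final_rel_tol = 1e-6))
  sc <- score_vs_truth(fit, st$truth)
  mu_aligned <- fit$params$mu[, sc$perm]
  expect_gt(mu_aligned[1, 1], 0.8)
  expect_gt(mu_aligned[2, 2], 0.8)
  # targets copy held-out relatives of their sources: theta small
  expect_lt(fit$params$theta, 0.02)
})
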