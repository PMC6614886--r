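#' Initialise all model parameters
#'
#' The copying matrix starts at `1/P` per entry with seeded multiplicative
#' jitter (+-`jitter`, columns renormalised). The jitter is mandatory: with
#' exactly symmetric columns the ancestries are exchangeable and EM cannot
#' separate them. Ancestry-switch probabilities start at
#' `alpha0_a * lambda0 * w` with uniform `alpha0` and `lambda0` switches per
#' Morgan over a grid interval of `w` Morgans.
#'
#' @param A number of ancestries
#' @param panels character vector of panel names
#' @param panel_sizes named integer vector of panel haplotype counts
#' @param targets character vector of target individual names
#' @param grid_w_cM grid spacing in cM
#' @param lambda0 initial overall ancestry-switch rate per Morgan
#' @param rho0,theta0 initial haplotype-switch and miscopy rates
#' @param jitter relative amplitude of the symmetry-breaking jitter
#' @return a [model_params()]
#' @export
initialize_params <- function(A, panels, panel_sizes, targets, grid_w_cM,
                              lambda0 = 30, rho0 = 0.05, theta0 = 0.01,
                              jitter = 0.1) {
  P <- length(panels)
  mu <- matrix(1 / P, P, A) *
    matrix(runif(P * A, 1 - jitter, 1 + jitter), P, A)
  mu <- sweep(mu, 2, colSums(mu), "/")
  w_M <- grid_w_cM / 100
  Pi0 <- matrix((1 / A) * lambda0 * w_M, A, A)
  model_params(A, panels, panel_sizes, mu, rho0, theta0,
               Pi = Pi0, targets = targets)
}

# ---- internal target-data container -----------------------------------------

# Bundle per-individual match counts (vs the full donor pool) plus the active
# donor subset; everything the E-step, the thinner and the phase hunter need.
prepare_targets <- function(hs, grid) {
  panels <- panel_names(hs)
  donors <- donor_hap_rows(hs)
  donor_panel <- match(hs$samples$panel[donors], panels)
  smp <- target_samples(hs)
  individuals <- lapply(smp, function(s) {
    r1 <- which(hs$samples$sample == s & hs$samples$hap == 1L)
    r2 <- which(hs$samples$sample == s & hs$samples$hap == 2L)
    list(sample = s, hap_rows = c(r1, r2),
         counts = list(compute_match_counts(hs, r1, donors, grid),
                       compute_match_counts(hs, r2, donors, grid)),
         active = seq_along(donors),
         flipped = lapply(grid$chroms,
                          function(ch) logical(ch$n_grid)))
  })
  names(individuals) <- smp
  list(panels = panels, donors = donors, donor_panel = donor_panel,
       panel_sizes = setNames(tabulate(donor_panel, length(panels)), panels),
       grid = grid, individuals = individuals)
}

subset_counts <- function(counts_chrom, active) {
  if (length(active) == nrow(counts_chrom$match))
    return(counts_chrom)        # full pool: no copy needed
  list(gp = counts_chrom$gp,
       match = counts_chrom$match[active, , drop = FALSE],
       mismatch = counts_chrom$mismatch[active, , drop = FALSE],
       n_grid = counts_chrom$n_grid)
}

# One E-step over all targets: per-individual and pooled expected event
# counts, total log-likelihood, and optionally posteriors.
e_step <- function(td, params, want_X = FALSE, want_gamma = FALSE) {
  A <- params$A; P <- length(params$panels)
  pooled <- list(arrivals = matrix(0, P, A), hapswitch = 0, stay = 0,
                 emit_match = 0, emit_mismatch = 0)
  per_target <- list()
  X <- if (want_X) list() else NULL
  gam <- if (want_gamma) list() else NULL
  loglik <- 0
  for (nm in names(td$individuals)) {
    ind <- td$individuals[[nm]]
    dp <- td$donor_panel[ind$active]
    acc <- list(switch_ba = matrix(0, A, A), hapswitch = numeric(A),
                stay = numeric(A))
    if (want_X) X[[nm]] <- list()
    if (want_gamma) gam[[nm]] <- list()
    for (h in 1:2) {
      if (want_X) X[[nm]][[h]] <- list()
      if (want_gamma) gam[[nm]][[h]] <- list()
      for (ch in names(ind$counts[[h]])) {
        cc <- subset_counts(ind$counts[[h]][[ch]], ind$active)
        r <- forward_backward(cc, dp, params, target = nm,
                              want_gamma_donor = want_gamma,
                              want_X = want_X)
        loglik <- loglik + r$loglik
        acc$switch_ba <- acc$switch_ba + r$switch_ba
        acc$hapswitch <- acc$hapswitch + r$hapswitch_within
        acc$stay <- acc$stay + r$stay
        pooled$arrivals <- pooled$arrivals + r$arrivals_pa
        pooled$hapswitch <- pooled$hapswitch + sum(r$hapswitch_within)
        pooled$stay <- pooled$stay + sum(r$stay)
        pooled$emit_match <- pooled$emit_match + r$emit_match
        pooled$emit_mismatch <- pooled$emit_mismatch + r$emit_mismatch
        if (want_X) X[[nm]][[h]][[ch]] <- r$X
        if (want_gamma) gam[[nm]][[h]][[ch]] <- r$gamma_donor
      }
    }
    per_target[[nm]] <- acc
  }
  list(loglik = loglik, per_target = per_target, pooled = pooled,
       X = X, gamma = gam)
}

#' M-step: closed-form tied-parameter Baum-Welch updates
#'
#' Given aggregated expected event counts from the E-step:
#' `theta` is the pooled expected mismatch fraction of emissions (floored at
#' 1e-6); `mu` columns are the normalised expected donor-choice arrivals into
#' each panel; `rho` is the pooled expected fraction of within-ancestry
#' haplotype switches among non-ancestry-switch events;
#' `Pi[b, a]` per target is the expected number of b->a ancestry arrivals
#' over the expected number of grid intervals spent with source ancestry b.
#' Row sums of `Pi` never exceed 1 by construction (stay and haplotype-switch
#' mass is part of the denominator); a proportional rescale guards numerical
#' violations.
#'
#' @param counts E-step output (`per_target` and `pooled` event counts)
#' @param prev previous [model_params()] (fallback for empty ancestries)
#' @param shared_Pi fit a single joint `Pi` across targets
#' @return updated [model_params()]
#' @export
m_step <- function(counts, prev, shared_Pi = FALSE) {
  A <- prev$A
  pl <- counts$pooled
  em_tot <- pl$emit_match + pl$emit_mismatch
  theta <- if (em_tot > 0) pl$emit_mismatch / em_tot else prev$theta
  theta <- min(max(theta, 1e-6), 0.5 - 1e-6)
  rho_tot <- pl$hapswitch + pl$stay
  rho <- if (rho_tot > 0) pl$hapswitch / rho_tot else prev$rho
  rho <- min(max(rho, 1e-6), 1 - 1e-6)
  arr <- pl$arrivals
  mu <- prev$mu
  for (a in seq_len(A)) {
    tot <- sum(arr[, a])
    if (tot > 0) mu[, a] <- arr[, a] / tot
    else warning("ancestry ", a, " never entered; keeping previous mu column")
  }
  upd_Pi <- function(acc, Pi_prev) {
    Pi <- Pi_prev
    denom <- rowSums(acc$switch_ba) + acc$hapswitch + acc$stay
    for (b in seq_len(A)) {
      if (denom[b] > 0) Pi[b, ] <- acc$switch_ba[b, ] / denom[b]
    }
    rs <- rowSums(Pi)
    bad <- rs > 1
    if (any(bad)) {
      message("Pi row sum(s) > 1 rescaled")
      Pi[bad, ] <- Pi[bad, , drop = FALSE] / rs[bad]
    }
    Pi
  }
  Pi <- prev$Pi
  if (shared_Pi) {
    tot <- Reduce(function(x, y) Map(`+`, x, y), counts$per_target)
    Pi_new <- upd_Pi(tot, prev$Pi[[1]])
    Pi <- setNames(rep(list(Pi_new), length(Pi)), names(Pi))
  } else {
    for (nm in names(counts$per_target))
      Pi[[nm]] <- upd_Pi(counts$per_target[[nm]], prev$Pi[[nm]])
  }
  model_params(A, prev$panels, prev$panel_sizes, mu, rho, theta, Pi = Pi,
               targets = names(Pi))
}

em_iterate <- function(td, params, n_iter, rel_tol_monotone = 1e-6,
                       stop_rel_tol = NULL, want_final_X = FALSE) {
  trace <- numeric(0)
  converged <- FALSE
  agg <- NULL
  for (it in seq_len(n_iter)) {
    agg <- e_step(td, params)
    ll <- agg$loglik
    if (length(trace)) {
      prev_ll <- trace[length(trace)]
      if (ll < prev_ll - rel_tol_monotone * abs(prev_ll))
        stop("log-likelihood decreased beyond tolerance in EM (",
             prev_ll, " -> ", ll, "); implementation bug")
      if (!is.null(stop_rel_tol) &&
          abs(ll - prev_ll) < stop_rel_tol * abs(prev_ll)) {
        trace <- c(trace, ll)
        converged <- TRUE
        break
      }
    }
    trace <- c(trace, ll)
    params <- m_step(agg, params, shared_Pi = attr(td, "shared_Pi") %||% FALSE)
  }
  structure(list(params = params, loglik_trace = trace,
                 converged = converged),
            class = "em_state")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run one round of EM iterations
#'
#' @param td target data from the pipeline's internal preparation
#' @param params current [model_params()]
#' @param n_iter E/M cycles (default 10)
#' @return class `em_state`: updated params, log-likelihood trace (evaluated
#'   at the pre-update parameters of each iteration, hence non-decreasing),
#'   convergence flag
#' @export
run_round <- function(td, params, n_iter = 10) {
  em_iterate(td, params, n_iter)
}

#' Run EM to convergence
#'
#' Iterates until the relative log-likelihood change drops below `rel_tol`
#' or `max_iter` is reached (with a warning).
#'
#' @inheritParams run_round
#' @param rel_tol relative log-likelihood convergence tolerance
#' @param max_iter iteration cap
#' @export
run_final_em <- function(td, params, rel_tol = 1e-5, max_iter = 200) {
  st <- em_iterate(td, params, max_iter, stop_rel_tol = rel_tol)
  if (!st$converged && rel_tol > 0)
    warning("final EM hit max_iter = ", max_iter, " before convergence")
  if (rel_tol == 0) st$converged <- FALSE
  st
}

#' @export
print.em_state <- function(x, ...) {
  n <- length(x$loglik_trace)
  cat("<em_state> ", n, " iteration(s), loglik ",
      if (n) signif(x$loglik_trace[n], 8) else NA,
      if (x$converged) " (converged)" else "", "\n", sep = "")
  invisible(x)
}
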