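#' Model parameters of the two-layer copying HMM
#'
#' Bundles the per-target ancestry-switch matrices `Pi` (A x A, entry
#' `Pi[b, a]` is the unconditional probability of an ancestry switch b -> a
#' between successive gridpoints; row sums must not exceed 1), the copying
#' matrix `mu` (P x A, columns sum to 1: the probability of selecting a donor
#' from panel p given local ancestry a), the within-ancestry haplotype-switch
#' probability `rho` and the miscopying rate `theta`. `Pi` is a list with one
#' matrix per target individual (targets may have experienced the event at
#' different times and in different ratios); `mu`, `rho` and `theta` are
#' shared by the whole admixed sample.
#'
#' @param A number of latent ancestries
#' @param panels character vector of panel names (length P)
#' @param panel_sizes named integer vector, donor haplotypes per panel
#' @param mu P x A copying matrix
#' @param rho within-ancestry haplotype-switch probability
#' @param theta miscopying rate, in (0, 0.5)
#' @param Pi list of A x A matrices, one per target individual (or a single
#'   matrix, recycled, for the shared-Pi variant)
#' @param targets character vector of target individual names (names `Pi`)
#' @export
model_params <- function(A, panels, panel_sizes, mu, rho, theta, Pi,
                         targets = NULL) {
  if (is.matrix(Pi)) Pi <- stats::setNames(rep(list(Pi), length(targets)),
                                           targets)
  stopifnot(is.list(Pi), nrow(mu) == length(panels), ncol(mu) == A)
  obj <- structure(list(A = A, panels = panels,
                        panel_sizes = panel_sizes, mu = mu, rho = rho,
                        theta = theta, Pi = Pi),
                   class = "model_params")
  validate_model_params(obj)
  obj
}

validate_model_params <- function(p, tol = 1e-8) {
  if (any(abs(colSums(p$mu) - 1) > tol))
    stop("columns of mu must sum to 1")
  if (any(p$mu < -tol)) stop("mu must be non-negative")
  if (p$rho < 0 || p$rho > 1) stop("rho must lie in [0, 1]")
  if (p$theta <= 0 || p$theta >= 0.5) stop("theta must lie in (0, 0.5)")
  for (Pi in p$Pi) {
    if (any(Pi < -tol)) stop("Pi entries must be non-negative")
    if (any(rowSums(Pi) > 1 + tol))
      stop("Pi row sums must not exceed 1 (invalid kernel)")
  }
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> A =", x$A, " P =", length(x$panels),
      " rho =", signif(x$rho, 4), " theta =", signif(x$theta, 4), "\n")
  cat("mu (panels x ancestries):\n")
  print(round(x$mu, 4))
  invisible(x)
}

#' Transition probability of the two-layer kernel
#'
#' Reference (scalar) implementation of the piecewise kernel; the C++ engine
#' uses the same algebra in factorised form. States are (ancestry, donor
#' haplotype) pairs.
#'
#' @param from,to integer pairs `c(ancestry, donor_index)`
#' @param params a [model_params()]
#' @param donor_panel integer vector mapping donor index to panel index
#' @param target name/index of the target individual (selects `Pi`)
#' @return transition probability
#' @export
transition_probability <- function(from, to, params, donor_panel,
                                   target = 1) {
  Pi <- params$Pi[[target]]
  if (any(rowSums(Pi) > 1 + 1e-12))
    stop("Pi row sums must not exceed 1 (invalid kernel)")
  b <- from[1]; hq <- from[2]; a <- to[1]; hp <- to[2]
  p <- donor_panel[hp]
  Np <- sum(donor_panel == p)
  muN <- params$mu[p, a] / Np
  PiRow_a <- sum(Pi[a, ])
  if (a != b) return(Pi[b, a] * muN)
  v <- ((1 - PiRow_a) * params$rho + Pi[a, a]) * muN
  if (hp == hq) v <- v + (1 - PiRow_a) * (1 - params$rho)
  v
}

# full dense S x S kernel (oracle-scale only)
transition_matrix <- function(params, donor_panel, target = 1) {
  A <- params$A; K <- length(donor_panel); S <- A * K
  Tm <- matrix(0, S, S)
  for (b in 1:A) for (hq in 1:K) for (a in 1:A) for (hp in 1:K)
    Tm[(b - 1) * K + hq, (a - 1) * K + hp] <-
      transition_probability(c(b, hq), c(a, hp), params, donor_panel, target)
  Tm
}

#' Emission log-probability at a gridpoint
#'
#' A gridpoint carrying `n_match` agreeing and `n_mismatch` disagreeing sites
#' between target and donor emits the product of per-site terms
#' `theta^(mismatch) * (1-theta)^(match)`; an empty gridpoint emits 1.
#'
#' @param n_match,n_mismatch site counts (vectorised)
#' @param theta miscopying rate in (0, 1)
#' @export
emission_logprob <- function(n_match, n_mismatch, theta) {
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)")
  n_match * log1p(-theta) + n_mismatch * log(theta)
}

#' Initial state distribution of the chain
#'
#' Each chromosome starts afresh: ancestry `a` receives weight proportional to
#' the total switch mass into it, `sum_b Pi[b, a]`, normalised across
#' ancestries (a stationary-flavoured proxy for the mixing proportions), and
#' donor weight `mu[p, a] / N_p` within the ancestry. If `Pi` is all zero the
#' ancestry weights fall back to uniform with a warning.
#'
#' @inheritParams transition_probability
#' @return numeric vector of length `A * K`, state `s = (a-1)*K + j`
#' @export
initial_distribution <- function(params, donor_panel, target = 1) {
  Pi <- params$Pi[[target]]
  A <- params$A; K <- length(donor_panel)
  w <- colSums(Pi)
  if (sum(w) == 0) {
    warning("all-zero Pi; uniform initial ancestry weights")
    w <- rep(1, A)
  }
  w <- w / sum(w)
  Np <- tabulate(donor_panel, nbins = length(params$panels))
  init <- numeric(A * K)
  for (a in 1:A)
    init[(a - 1) * K + seq_len(K)] <-
      w[a] * params$mu[donor_panel, a] / Np[donor_panel]
  init
}

#' Scaled forward-backward pass for one target haplotype and chromosome
#'
#' Runs the two-layer HMM over the grid with per-gridpoint rescaling, and
#' returns the local-ancestry posterior `X` (G x A, rows sum to 1), the
#' total log-likelihood, optionally the donor-marginal posteriors, and the
#' expected event counts that the M-step consumes. Counts are obtained by
#' decomposing each pairwise transition posterior into its generative
#' mechanisms (ancestry arrival incl. explicit same-ancestry switches,
#' within-ancestry haplotype switch, stay), which is necessary because the
#' same-ancestry kernel entries are mixtures of two mechanisms.
#'
#' @param counts one chromosome element of [compute_match_counts()]
#' @param donor_panel integer vector, panel index per donor row of `counts`
#' @param params a [model_params()]
#' @param target target individual (selects `Pi`)
#' @param want_gamma_donor also return the G x K donor-marginal posterior
#'   (needed by the phase hunter and by thinning)
#' @param gamma_obs_only return donor posteriors only at observed gridpoints
#'   (rows follow `counts$gp`)
#' @param want_X compute the ancestry posterior matrix (skipped during plain
#'   EM iterations, where only event counts are needed)
#' @return list: `loglik`, `loglik_backward`, `X`, `gamma_donor`,
#'   `switch_ba`, `hapswitch_within`, `stay`, `arrivals_pa`, `emit_match`,
#'   `emit_mismatch`
#' @export
forward_backward <- function(counts, donor_panel, params, target = 1,
                             want_gamma_donor = FALSE,
                             gamma_obs_only = FALSE, want_X = TRUE) {
  init <- initial_distribution(params, donor_panel, target)
  fb_engine_cpp(counts$n_grid, counts$gp - 1L, counts$match, counts$mismatch,
                donor_panel - 1L, length(params$panels),
                params$Pi[[target]], params$mu, params$rho, params$theta,
                init, want_gamma_donor, gamma_obs_only, want_X)
}
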