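#' Ancestry-unaware single-layer painting
#'
#' Fits a Li-and-Stephens copying model with no ancestry layer: between
#' successive gridpoints the chain switches to a uniformly chosen donor with
#' probability `rho_thin` (i.e. `rho_thin / N` per donor, including back to
#' itself) and stays put otherwise; emissions are the usual miscopying model.
#' Used to rank donors before the expensive two-layer pass.
#'
#' @param counts one chromosome element of [compute_match_counts()] over the
#'   full donor pool
#' @param rho_thin per-interval total switch probability
#' @param theta miscopying rate
#' @return list: `gamma` (G x N posterior copying mass per donor), `loglik`
#' @export
paint_single_layer <- function(counts, rho_thin = 0.05, theta = 0.01) {
  K <- nrow(counts$match)
  res <- fb_engine_cpp(counts$n_grid, counts$gp - 1L, counts$match,
                       counts$mismatch, rep(0L, K), 1L,
                       matrix(0, 1, 1), matrix(1, 1, 1),
                       rho_thin, theta, rep(1 / K, K), TRUE, FALSE, FALSE)
  list(gamma = res$gamma_donor, loglik = res$loglik)
}

#' Rank donors per gridpoint and keep the top K per individual
#'
#' Scores each donor at each gridpoint by the sum of the posterior copying
#' masses of the individual's two haplotypes from [paint_single_layer()], so
#' the retained set is shared by both haplotypes (the phase hunter needs
#' donors relevant to either). Ties break toward the lower donor index.
#'
#' @param gamma1,gamma2 G x N donor posteriors of the two haplotypes
#' @param K donors to retain per gridpoint (default 100)
#' @return class `thinned_donors`: `retained` is a G x min(K, N) integer
#'   matrix of donor indices (or `NULL` when all N <= K donors are kept
#'   everywhere), plus the sorted `union` across gridpoints.
#' @export
rank_and_thin <- function(gamma1, gamma2, K = 100) {
  N <- ncol(gamma1)
  G <- nrow(gamma1)
  if (N <= K) {
    return(structure(list(K = K, retained = NULL, n_donors = N,
                          union = seq_len(N)),
                     class = "thinned_donors"))
  }
  score <- gamma1 + gamma2
  retained <- matrix(0L, G, K)
  for (g in seq_len(G)) {
    o <- order(-score[g, ], seq_len(N))  # ties -> lower donor index
    retained[g, ] <- sort(o[seq_len(K)])
  }
  structure(list(K = K, retained = retained, n_donors = N,
                 union = sort(unique(as.integer(retained)))),
            class = "thinned_donors")
}

#' @export
print.thinned_donors <- function(x, ...) {
  cat("<thinned_donors> K =", x$K, "of", x$n_donors, "donors; union size",
      length(x$union), "\n")
  invisible(x)
}

retained_at <- function(thinned, g) {
  if (is.null(thinned$retained)) seq_len(thinned$n_donors)
  else thinned$retained[g, ]
}
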