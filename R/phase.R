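#' Change in log-likelihood from flipping phase at each gridpoint
#'
#' For one chromosome of a diploid target, computes the marginal change in
#' total log-likelihood if the two haplotypes' alleles at a single gridpoint
#' were swapped, from one forward-backward pass per haplotype. The state
#' posterior at the gridpoint is first stripped of that gridpoint's own
#' emission (`u(g,s) = gamma(g,s) / P(y|s)`, renormalised), because the
#' posterior is otherwise dominated by the very observation being
#' questioned; the gain is then
#' `gain(g) = log sum_s u1(g,s) P(y2|s) - log sum_s u1(g,s) P(y1|s)`
#' plus the mirrored term for the second haplotype. For a single-gridpoint
#' swap this is the exact log-likelihood change, since all other emissions
#' and the chain are untouched. Gains are exactly zero where the haplotypes
#' carry identical alleles or no sites.
#'
#' @param gamma1,gamma2 donor-marginal posteriors of the two haplotypes (from
#'   [forward_backward()] with `want_gamma_donor = TRUE`): either G x K, or
#'   length(gp) x K when computed at observed gridpoints only
#' @param counts1,counts2 the matching chromosome elements of
#'   [compute_match_counts()] for the two haplotypes (same donor subset,
#'   same `gp`)
#' @param theta miscopying rate
#' @return numeric vector of length G
#' @export
marginal_flip_gains <- function(gamma1, gamma2, counts1, counts2, theta) {
  stopifnot(identical(counts1$gp, counts2$gp))
  lm <- log1p(-theta); lk <- log(theta)
  l1 <- counts1$match * lm + counts1$mismatch * lk  # K x nne: log P(y1|j)
  l2 <- counts2$match * lm + counts2$mismatch * lk
  if (nrow(gamma1) == counts1$n_grid) {
    gamma1 <- gamma1[counts1$gp, , drop = FALSE]
    gamma2 <- gamma2[counts1$gp, , drop = FALSE]
  }
  lse_rows <- function(M) {           # row-wise log-sum-exp, nne x K input
    mx <- apply(M, 1, max)
    mx + log(rowSums(exp(M - mx)))
  }
  lg1 <- log(t(gamma1))               # K x nne
  lg2 <- log(t(gamma2))
  d1 <- lse_rows(t(lg1 - l1 + l2)) - lse_rows(t(lg1))
  d2 <- lse_rows(t(lg2 - l2 + l1)) - lse_rows(t(lg2))
  g <- d1 + d2
  g[colSums(abs(l1 - l2)) == 0] <- 0   # identical alleles: exact zero
  gains <- numeric(counts1$n_grid)
  gains[counts1$gp] <- g
  gains
}

# positive-gain runs as candidate flip intervals
gain_intervals <- function(gains, gridpoint_cM) {
  pos <- gains > 0
  if (!any(pos)) return(NULL)
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep],
             start_cM = gridpoint_cM[starts[keep]],
             end_cM = gridpoint_cM[ends[keep]],
             gain = vapply(keep, function(i)
               sum(gains[starts[i]:ends[i]]), numeric(1)))
}

swap_hap_counts <- function(ind, chrom, gridpoints) {
  c1 <- ind$counts[[1]][[chrom]]; c2 <- ind$counts[[2]][[chrom]]
  cols <- which(c1$gp %in% gridpoints)
  if (length(cols)) {
    tmpm <- c1$match[, cols, drop = FALSE]
    tmpk <- c1$mismatch[, cols, drop = FALSE]
    c1$match[, cols] <- c2$match[, cols, drop = FALSE]
    c1$mismatch[, cols] <- c2$mismatch[, cols, drop = FALSE]
    c2$match[, cols] <- tmpm
    c2$mismatch[, cols] <- tmpk
    ind$counts[[1]][[chrom]] <- c1
    ind$counts[[2]][[chrom]] <- c2
  }
  ind$flipped[[chrom]][gridpoints] <- !ind$flipped[[chrom]][gridpoints]
  ind
}

# greedy ranked selection: best summed gain first, later intervals accepted
# only if their cM span is >= min_separation from every accepted interval on
# the same chromosome
select_flip_intervals <- function(iv, min_separation = 0.1) {
  iv <- iv[order(-iv$gain), , drop = FALSE]
  acc <- iv[0, ]
  for (i in seq_len(nrow(iv))) {
    same <- acc[acc$chrom == iv$chrom[i], , drop = FALSE]
    ok <- TRUE
    if (nrow(same)) {
      gap <- pmax(same$start_cM - iv$end_cM[i], iv$start_cM[i] - same$end_cM)
      ok <- all(gap >= min_separation)
    }
    if (ok) acc <- rbind(acc, iv[i, ])
  }
  acc
}

ind_loglik <- function(ind, td, params) {
  dp <- td$donor_panel[ind$active]
  ll <- 0
  for (h in 1:2)
    for (ch in names(ind$counts[[h]]))
      ll <- ll + forward_backward(subset_counts(ind$counts[[h]][[ch]],
                                                ind$active),
                                  dp, params, target = ind$sample,
                                  want_X = FALSE)$loglik
  ll
}

#' Apply one pass of the phase hunter
#'
#' Ranks positive-gain runs by summed gain, greedily accepts intervals whose
#' cM span lies at least `min_separation` from every previously accepted
#' interval on the same chromosome, swaps the two haplotypes' alleles at all
#' accepted gridpoints, and refits the HMM. If the total log-likelihood did
#' not increase the pass is reverted.
#'
#' @param ind internal per-individual data (counts for both haplotypes)
#' @param td internal target data (donor pool, grid)
#' @param params current [model_params()]
#' @param gains list of per-chromosome gain vectors from
#'   [marginal_flip_gains()]
#' @param loglik_before current total log-likelihood of the individual
#' @param min_separation minimum cM gap between accepted intervals
#' @return list: updated `ind`, `accepted` interval table, `delta` loglik
#'   change, `reverted` flag
#' @export
apply_flip_pass <- function(ind, td, params, gains, loglik_before,
                            min_separation = 0.1) {
  iv <- list()
  for (ch in names(gains)) {
    d <- gain_intervals(gains[[ch]], td$grid$chroms[[ch]]$gridpoint_cM)
    if (!is.null(d)) { d$chrom <- ch; iv[[ch]] <- d }
  }
  if (!length(iv))
    return(list(ind = ind, accepted = NULL, delta = 0, reverted = FALSE))
  iv <- do.call(rbind, iv)
  acc <- select_flip_intervals(iv, min_separation)
  for (ch in unique(acc$chrom)) {
    gps <- unlist(lapply(which(acc$chrom == ch),
                         function(i) acc$start[i]:acc$end[i]))
    ind <- swap_hap_counts(ind, ch, gps)
  }
  ll_after <- ind_loglik(ind, td, params)
  if (ll_after <= loglik_before) {
    for (ch in unique(acc$chrom)) {   # revert
      gps <- unlist(lapply(which(acc$chrom == ch),
                           function(i) acc$start[i]:acc$end[i]))
      ind <- swap_hap_counts(ind, ch, gps)
    }
    return(list(ind = ind, accepted = NULL, delta = 0, reverted = TRUE))
  }
  list(ind = ind, accepted = acc, delta = ll_after - loglik_before,
       reverted = FALSE)
}

#' Hill-climb the phase of one diploid target
#'
#' Repeats gain computation and flip passes as long as the log-likelihood
#' increases; phase flips only ever swap alleles between the two haplotypes,
#' so the diploid genotypes are untouched. Typically few passes suffice and
#' the number of candidate gridpoints shrinks each pass.
#'
#' @inheritParams apply_flip_pass
#' @param max_passes oscillation guard (warns if reached)
#' @return list: updated `ind`, `n_passes`, `accepted` interval log,
#'   `loglik_trace` (monotone over accepted passes), `candidates` per pass
#' @export
hunt_phase <- function(ind, td, params, min_separation = 0.1,
                       max_passes = 25) {
  dp <- td$donor_panel[ind$active]
  accepted <- NULL
  trace <- numeric(0)
  cand <- integer(0)
  for (pass in seq_len(max_passes)) {
    gains <- list()
    ll <- 0
    for (ch in names(ind$counts[[1]])) {
      r <- lapply(1:2, function(h)
        forward_backward(subset_counts(ind$counts[[h]][[ch]], ind$active),
                         dp, params, target = ind$sample,
                         want_gamma_donor = TRUE, gamma_obs_only = TRUE,
                         want_X = FALSE))
      ll <- ll + r[[1]]$loglik + r[[2]]$loglik
      gains[[ch]] <- marginal_flip_gains(
        r[[1]]$gamma_donor, r[[2]]$gamma_donor,
        subset_counts(ind$counts[[1]][[ch]], ind$active),
        subset_counts(ind$counts[[2]][[ch]], ind$active), params$theta)
    }
    if (!length(trace)) trace <- ll
    cand <- c(cand, sum(unlist(lapply(gains, function(g) sum(g > 0)))))
    res <- apply_flip_pass(ind, td, params, gains, ll, min_separation)
    ind <- res$ind
    if (is.null(res$accepted)) break
    accepted <- rbind(accepted, res$accepted)
    trace <- c(trace, ll + res$delta)
    if (pass == max_passes)
      warning("phase hunter reached max_passes = ", max_passes)
  }
  list(ind = ind, n_passes = pass, accepted = accepted,
       loglik_trace = trace, candidates = cand)
}

# apply accumulated flips back to the haplotype matrix (for VCF export)
apply_flips_to_haps <- function(hs, td) {
  for (ind in td$individuals) {
    for (ch in names(ind$flipped)) {
      gps <- which(ind$flipped[[ch]])
      if (!length(gps)) next
      gch <- td$grid$chroms[[ch]]
      sel <- gch$site_idx[gch$site_to_grid %in% gps]
      r1 <- ind$hap_rows[1]; r2 <- ind$hap_rows[2]
      tmp <- hs$haps[r1, sel]
      hs$haps[r1, sel] <- hs$haps[r2, sel]
      hs$haps[r2, sel] <- tmp
    }
  }
  hs
}
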