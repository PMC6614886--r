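#' Build coancestry curves from local-ancestry posteriors
#'
#' For each unordered ancestry pair (a, b), estimates the probability of
#' being in ancestry a at one gridpoint and ancestry b at a gridpoint a
#' genetic distance d away, relative to the genome-wide average
#' (`P(a,b,d) = E[X_a(g) X_b(g+d)] / (mean X_a * mean X_b)`). Pairs are taken
#' within chromosomes only. The pooled (black) curve is the ratio of pooled
#' numerator and denominator across targets and chromosomes — not the mean of
#' per-target ratios, which is unstable for rare ancestries — and per-target
#' (gray) curves are also returned. Distances are scaled by the grid width so
#' that the fitted decay constant is in generations. Numerators are computed
#' by FFT cross-correlation; per-chromosome sufficient statistics are kept so
#' that chromosome bootstrap replicates are cheap.
#'
#' An ancestry whose genome-wide mean mass falls below `min_mass` yields
#' curves flagged unusable (minor-ancestry curves are dominated by noise).
#'
#' @param X nested list of posteriors, `X[[individual]][[haplotype]][[chrom]]`
#'   each a G x A matrix (the pipeline's shape; a truth track in indicator
#'   form works too)
#' @param grid an [build_grid()] result
#' @param d_max,d_min curve range in cM. Lags shorter than `d_min` are
#'   excluded: HMM posterior smoothing inflates tiny-lag ratios and biases
#'   the decay constant.
#' @param min_mass usability threshold on genome-wide ancestry mass
#' @return class `coancestry_curves`
#' @export
compute_curves <- function(X, grid, d_max = 30, d_min = 0.5,
                           min_mass = 1e-4) {
  w <- grid$w
  lmin <- max(1L, as.integer(ceiling(d_min / w - 1e-9)))
  first <- X[[1]][[1]][[1]]
  A <- ncol(first)
  chroms <- names(grid$chroms)
  Gs <- vapply(grid$chroms, function(ch) as.numeric(ch$n_grid),
               numeric(1))
  lmax <- min(as.integer(floor(d_max / w + 1e-9)), min(Gs) - 1L)
  lags <- lmin:lmax
  nl <- length(lags)
  prs <- which(upper.tri(diag(A), diag = TRUE), arr.ind = TRUE)
  prs <- prs[order(prs[, 1], prs[, 2]), , drop = FALSE]
  pairs <- cbind(a = prs[, 1], b = prs[, 2])
  np <- nrow(pairs)
  targets <- names(X)
  nt <- length(targets)

  num <- array(0, c(np, nl, length(chroms)),
               dimnames = list(NULL, NULL, chroms))
  num_t <- array(0, c(np, nl, nt), dimnames = list(NULL, NULL, targets))
  cnt <- matrix(0, nl, length(chroms), dimnames = list(NULL, chroms))
  cnt_t <- matrix(0, nl, nt, dimnames = list(NULL, targets))
  sumX <- matrix(0, A, length(chroms), dimnames = list(NULL, chroms))
  sumX_t <- matrix(0, A, nt, dimnames = list(NULL, targets))
  G_t <- numeric(nt)

  for (ti in seq_len(nt)) {
    for (h in seq_along(X[[ti]])) {
      for (ci in seq_along(chroms)) {
        M <- X[[ti]][[h]][[chroms[ci]]]
        G <- nrow(M)
        N <- stats::nextn(G + lmax, 2)
        Fc <- apply(rbind(M, matrix(0, N - G, A)), 2, fft)
        for (p in seq_len(np)) {
          a <- pairs[p, 1]; b <- pairs[p, 2]
          cc <- Re(fft(Conj(Fc[, a]) * Fc[, b] +
                         Conj(Fc[, b]) * Fc[, a], inverse = TRUE)) / (2 * N)
          v <- cc[lags + 1L]
          num[p, , ci] <- num[p, , ci] + v
          num_t[p, , ti] <- num_t[p, , ti] + v
        }
        cnt[, ci] <- cnt[, ci] + (G - lags)
        cnt_t[, ti] <- cnt_t[, ti] + (G - lags)
        sumX[, ci] <- sumX[, ci] + colSums(M)
        sumX_t[, ti] <- sumX_t[, ti] + colSums(M)
      }
    }
    G_t[ti] <- sum(Gs) * length(X[[ti]])
  }
  n_haps <- sum(vapply(X, length, integer(1)))
  mean_X <- rowSums(sumX) / (sum(Gs) * n_haps)
  usable <- mean_X >= min_mass
  if (any(!usable))
    warning("ancestry(ies) ", paste(which(!usable), collapse = ", "),
            " have genome-wide mass < ", min_mass,
            "; their curves are flagged unusable")
  structure(list(A = A, w_cM = w, lags = lags, d_cM = lags * w,
                 pairs = pairs, chroms = chroms, n_haps = n_haps,
                 G_per_chrom = Gs, num = num, cnt = cnt, sumX = sumX,
                 num_t = num_t, cnt_t = cnt_t, sumX_t = sumX_t, G_t = G_t,
                 mean_X = mean_X, usable = usable),
            class = "coancestry_curves")
}

#' Pooled coancestry ratio for one ancestry pair
#'
#' @param cv a [compute_curves()] result
#' @param pair row index into `cv$pairs`
#' @param chrom_idx chromosome indices to pool (bootstrap resampling hook)
#' @return numeric vector over `cv$d_cM`
#' @export
pooled_ratio <- function(cv, pair, chrom_idx = seq_along(cv$chroms)) {
  nume <- apply(cv$num[pair, , chrom_idx, drop = FALSE], 2, sum)
  cntp <- rowSums(cv$cnt[, chrom_idx, drop = FALSE])
  Gp <- sum(cv$G_per_chrom[chrom_idx]) * cv$n_haps
  ma <- sum(cv$sumX[cv$pairs[pair, 1], chrom_idx]) / Gp
  mb <- sum(cv$sumX[cv$pairs[pair, 2], chrom_idx]) / Gp
  (nume / cntp) / (ma * mb)
}

per_target_ratio <- function(cv, pair, target) {
  ma <- cv$sumX_t[cv$pairs[pair, 1], target] / cv$G_t[target]
  mb <- cv$sumX_t[cv$pairs[pair, 2], target] / cv$G_t[target]
  (cv$num_t[pair, , target] / cv$cnt_t[, target]) / (ma * mb)
}

#' @export
print.coancestry_curves <- function(x, ...) {
  cat("<coancestry_curves> A =", x$A, ",", nrow(x$pairs), "pairs,",
      length(x$lags), "lags in [", round(min(x$d_cM), 3), ",",
      round(max(x$d_cM), 3), "] cM\n")
  invisible(x)
}

#' Diagnostic: coancestry ratio across unlinked chromosomes
#'
#' Pairs of positions on different chromosomes are unlinked, so their
#' relative pairwise-ancestry probability should sit at ~1 at every lag; a
#' systematic departure indicates confounding (e.g. strong inter-individual
#' proportion differences). Returns the ratio for one ancestry pair computed
#' over all between-chromosome position pairs.
#'
#' @param X nested posteriors as in [compute_curves()]
#' @param a,b ancestry pair
#' @return scalar ratio
#' @export
cross_chromosome_ratio <- function(X, a = 1, b = 2) {
  num <- 0; npairs <- 0
  sa <- 0; sb <- 0; n <- 0
  for (ti in seq_along(X)) for (h in seq_along(X[[ti]])) {
    chs <- X[[ti]][[h]]
    if (length(chs) < 2) stop("need >= 2 chromosomes")
    for (c1 in seq_along(chs)) {
      sa <- sa + sum(chs[[c1]][, a]); sb <- sb + sum(chs[[c1]][, b])
      n <- n + nrow(chs[[c1]])
      for (c2 in seq_along(chs)) {
        if (c1 == c2) next
        num <- num + sum(chs[[c1]][, a]) * sum(chs[[c2]][, b])
        npairs <- npairs + nrow(chs[[c1]]) * nrow(chs[[c2]])
      }
    }
  }
  (num / npairs) / ((sa / n) * (sb / n))
}

#' Fit a single-pulse exponential decay to a coancestry curve
#'
#' Fits `P(d) = delta * exp(-lambda * d) + tau` by nonlinear least squares,
#' with distance in Morgans so that `lambda` reads as generations since
#' admixture. The optimisation is initialised with the crude closed-form
#' estimates (`tau = 1`, `delta = P(d_min) - tau`, and `lambda` from the
#' mid-curve point halfway between `P(d_min)` and the asymptote); if those
#' are non-finite, or the optimiser fails, a coarse grid search over
#' `lambda = 1..500` with a linear solve for `(delta, tau)` takes over with a
#' warning.
#'
#' @param d_cM distances in cM
#' @param y curve values
#' @return class `coancestry_fit`: `delta`, `tau`, `lam` (generations),
#'   `sse`, `method`
#' @export
fit_exponential <- function(d_cM, y) {
  stopifnot(length(d_cM) == length(y))
  if (length(y) < 10) stop("need >= 10 distance points to fit a decay")
  dM <- d_cM / 100
  tau0 <- 1
  delta0 <- y[1] - tau0
  half <- (y[1] + tau0) / 2
  ih <- if (delta0 < 0) which(y >= half) else which(y <= half)
  ih <- ih[ih > 1]
  i_half <- if (length(ih)) ih[1] else ceiling(length(y) / 2)
  lam0 <- -log((y[i_half] - tau0) / delta0) / dM[i_half]
  fit <- NULL
  if (is.finite(lam0) && lam0 > 0) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ delta * exp(-lam * dM) + tau,
                        data = data.frame(y = y, dM = dM),
                        start = list(delta = delta0, tau = tau0, lam = lam0),
                        lower = c(-Inf, -Inf, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    return(structure(list(delta = unname(cf["delta"]), tau = unname(cf["tau"]),
                          lam = unname(cf["lam"]),
                          sse = sum(stats::resid(fit)^2), method = "nls"),
                     class = "coancestry_fit"))
  }
  warning("nonlinear fit failed or crude initialisation non-finite; ",
          "falling back to coarse lambda grid search")
  best <- NULL
  for (lam in 1:500) {
    Xd <- cbind(exp(-lam * dM), 1)
    co <- stats::lm.fit(Xd, y)$coefficients
    sse <- sum((y - Xd %*% co)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(delta = unname(co[1]), tau = unname(co[2]), lam = lam,
                   sse = sse, method = "grid")
  }
  structure(best, class = "coancestry_fit")
}

#' @export
print.coancestry_fit <- function(x, ...) {
  cat("<coancestry_fit> delta =", signif(x$delta, 4),
      "tau =", signif(x$tau, 4), "lambda =", signif(x$lam, 4),
      "generations (sse ", signif(x$sse, 3), ", ", x$method, ")\n")
  invisible(x)
}

# shared-lambda joint fit: solve (delta, tau) linearly per pair, optimise
# the common lambda on a log scale
fit_shared_lambda <- function(curves_list, dM) {
  sse_at <- function(loglam) {
    lam <- exp(loglam)
    Xd <- cbind(exp(-lam * dM), 1)
    sum(vapply(curves_list, function(y)
      sum(stats::lm.fit(Xd, y)$residuals^2), numeric(1)))
  }
  op <- optimize(sse_at, c(log(0.5), log(500)))
  exp(op$minimum)
}

#' Estimate admixture dates from fitted coancestry curves
#'
#' Fits every usable ancestry-pair curve and reports per-pair decay
#' constants; the event date is the average across pairs (`mode =
#' "flexible"`), or a single decay constant fitted jointly to all pair
#' curves (`mode = "single"`).
#'
#' @param cv a [compute_curves()] result
#' @param mode `"flexible"` (per-pair rates, averaged) or `"single"` (one
#'   shared rate)
#' @return class `date_estimates`: tibble of per-pair fits plus the event
#'   `date` in generations
#' @export
estimate_dates <- function(cv, mode = c("flexible", "single")) {
  mode <- match.arg(mode)
  ok <- cv$usable[cv$pairs[, 1]] & cv$usable[cv$pairs[, 2]]
  na_fit <- list(delta = NA_real_, tau = NA_real_, lam = NA_real_,
                 sse = NA_real_, method = "unusable")
  fits <- lapply(seq_len(nrow(cv$pairs)), function(p)
    if (ok[p]) fit_exponential(cv$d_cM, pooled_ratio(cv, p)) else na_fit)
  tb <- tibble::tibble(
    a = cv$pairs[, 1], b = cv$pairs[, 2],
    pair = paste0(cv$pairs[, 1], "-", cv$pairs[, 2]),
    delta = vapply(fits, `[[`, numeric(1), "delta"),
    tau = vapply(fits, `[[`, numeric(1), "tau"),
    lam = vapply(fits, `[[`, numeric(1), "lam"),
    sse = vapply(fits, `[[`, numeric(1), "sse"),
    usable = ok)
  if (!any(ok)) warning("no usable ancestry pair: date undefined")
  date <- if (mode == "flexible") mean(tb$lam[tb$usable])
  else fit_shared_lambda(lapply(which(ok), function(p) pooled_ratio(cv, p)),
                         cv$d_cM / 100)
  structure(list(fits = tb, date = date, mode = mode),
            class = "date_estimates")
}

#' @export
print.date_estimates <- function(x, ...) {
  cat("<date_estimates> mode =", x$mode, " date =",
      signif(x$date, 4), "generations\n")
  print(as.data.frame(x$fits))
  invisible(x)
}

#' Chromosome bootstrap of admixture dates
#'
#' Resamples chromosomes with replacement, recomputes the pooled curves from
#' the cached per-chromosome sufficient statistics, refits every pair, and
#' reports the bootstrap SD and a +-2 SE interval per pair (and for the
#' averaged event date).
#'
#' @param cv a [compute_curves()] result built on >= 2 chromosomes
#' @param n_boot bootstrap replicates (0 = point estimates only)
#' @param seed optional RNG seed
#' @param mode passed to the per-replicate date summary
#' @return class `date_bootstrap`: per-pair tibble with `lam`, `se`, `lo`,
#'   `hi`, plus `date`, `date_se` and the replicate matrix
#' @export
bootstrap_dates <- function(cv, n_boot = 100, seed = NULL,
                            mode = "flexible") {
  nc <- length(cv$chroms)
  if (nc < 2) stop("chromosome bootstrap requires >= 2 chromosomes")
  if (!is.null(seed)) set.seed(seed)
  est <- estimate_dates(cv, mode = mode)
  np <- nrow(cv$pairs)
  boot <- matrix(NA_real_, n_boot, np)
  dates <- numeric(n_boot)
  ok <- est$fits$usable
  for (r in seq_len(n_boot)) {
    idx <- sample.int(nc, nc, replace = TRUE)
    lam <- vapply(seq_len(np), function(p)
      if (ok[p]) fit_exponential(cv$d_cM, pooled_ratio(cv, p, idx))$lam
      else NA_real_, numeric(1))
    boot[r, ] <- lam
    dates[r] <- mean(lam[ok])
  }
  se <- if (n_boot > 0) apply(boot, 2, sd) else rep(NA_real_, np)
  tb <- est$fits
  tb$se <- se
  tb$lo <- tb$lam - 2 * se
  tb$hi <- tb$lam + 2 * se
  structure(list(fits = tb, date = est$date,
                 date_se = if (n_boot > 0) sd(dates) else NA_real_,
                 boot = boot, n_boot = n_boot, mode = mode),
            class = "date_bootstrap")
}

#' Classify the ordering of admixture events from pairwise dates
#'
#' Compares the cross-ancestry decay constants using bootstrap +-2 SE
#' intervals: mutually overlapping intervals suggest a single event;
#' one pair strictly older than two overlapping others suggests that pair
#' mixed first and the compound then mixed with the third group; fully
#' distinct monotone dates suggest sequential events. The report is
#' deliberately narrative — pairwise decays cannot always identify the
#' history uniquely.
#'
#' @param bt a [bootstrap_dates()] result
#' @return class `event_order`: `call` (classification string) and `detail`
#' @export
order_events <- function(bt) {
  tb <- bt$fits[bt$fits$a != bt$fits$b & bt$fits$usable, , drop = FALSE]
  if (nrow(tb) <= 1) {
    call <- "single event"
    detail <- sprintf("one ancestry pair: single admixture event ~%.1f generations ago",
                      if (nrow(tb)) tb$lam else bt$date)
    return(structure(list(call = call, detail = detail, pairs = tb),
                     class = "event_order"))
  }
  overlap <- function(i, j)
    tb$lo[i] <= tb$hi[j] && tb$lo[j] <= tb$hi[i]
  n <- nrow(tb)
  ov <- outer(seq_len(n), seq_len(n), Vectorize(overlap))
  if (all(ov)) {
    call <- "single event"
    detail <- sprintf("all pairwise intervals overlap: a single event ~%.1f generations ago involving all ancestries",
                      mean(tb$lam))
  } else {
    o <- order(-tb$lam)
    top <- o[1]; rest <- o[-1]
    rest_overlap <- all(ov[rest, rest])
    top_above <- all(tb$lo[top] > tb$hi[rest])
    if (top_above && rest_overlap) {
      call <- "two events"
      detail <- sprintf("ancestries %d and %d mixed first (~%.1f gen); the admixed group then mixed with the remaining ancestry(ies) (~%.1f gen)",
                        tb$a[top], tb$b[top], tb$lam[top],
                        mean(tb$lam[rest]))
    } else if (!any(ov[upper.tri(ov)])) {
      call <- "sequential events"
      detail <- paste("pairwise dates are mutually distinct:",
                      "sequential non-overlapping admixture events, oldest first:",
                      paste(sprintf("%d-%d (~%.1f)", tb$a[o], tb$b[o],
                                    tb$lam[o]), collapse = ", "))
    } else {
      call <- "ambiguous"
      detail <- "pairwise dates partially overlap; history not uniquely identified"
    }
  }
  structure(list(call = call, detail = detail, pairs = tb),
            class = "event_order")
}

#' @export
print.event_order <- function(x, ...) {
  cat("<event_order>", x$call, "\n ", x$detail, "\n")
  invisible(x)
}
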