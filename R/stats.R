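#' Expected coefficient of determination, haploid
#'
#' Expected squared correlation between the inferred local ancestry X and the
#' unobserved truth Z, computed from the posterior alone by treating each
#' Z_ag as Bernoulli(X_ag):
#' `E[r2] = (sum X^2 - (sum X)^2/G) / (sum X - (sum X)^2/G)` per ancestry,
#' averaged over ancestries. Hard 0/1 posteriors give exactly 1. An ancestry
#' with constant posterior (zero denominator) is excluded with a warning.
#'
#' @param X G x A posterior matrix (rows sum to 1), or a list of such
#'   matrices (gridpoints concatenated, e.g. across chromosomes)
#' @return scalar in \[0, 1\]
#' @export
expected_r2_haploid <- function(X) {
  if (is.list(X)) X <- do.call(rbind, X)
  G <- nrow(X)
  per <- vapply(seq_len(ncol(X)), function(a) {
    x <- X[, a]
    sx <- sum(x)
    num <- sum(x^2) - sx^2 / G
    den <- sx - sx^2 / G
    if (den <= 0) return(NA_real_)
    num / den
  }, numeric(1))
  if (anyNA(per))
    warning("ancestry(ies) with constant posterior excluded from E[r2]")
  mean(per, na.rm = TRUE)
}

#' Expected coefficient of determination, diploid
#'
#' Diploid dosage version: X = X1 + X2 in \[0, 2\], with Z the sum of two
#' independent Bernoullis. The denominator becomes
#' `sum(X + 2*X1*X2) - (sum X)^2/G`. Individuals are pooled by concatenating
#' gridpoints.
#'
#' @param X1,X2 G x A posteriors of the two haplotypes, or lists of such
#'   matrices (one element per individual/chromosome, pooled)
#' @return scalar in \[0, 1\]
#' @export
expected_r2_diploid <- function(X1, X2) {
  if (is.list(X1)) { X1 <- do.call(rbind, X1); X2 <- do.call(rbind, X2) }
  stopifnot(identical(dim(X1), dim(X2)))
  X <- X1 + X2
  G <- nrow(X)
  per <- vapply(seq_len(ncol(X)), function(a) {
    x <- X[, a]
    sx <- sum(x)
    num <- sum(x^2) - sx^2 / G
    den <- sum(x + 2 * X1[, a] * X2[, a]) - sx^2 / G
    if (den <= 0) return(NA_real_)
    num / den
  }, numeric(1))
  if (anyNA(per))
    warning("ancestry(ies) with constant posterior excluded from E[r2]")
  mean(per, na.rm = TRUE)
}

#' Squared correlation between inferred and true local ancestry
#'
#' Scored over the best permutation of ancestry labels (the model's ancestry
#' labels are arbitrary). Ancestries with constant truth are excluded.
#'
#' @param X inferred G x A matrix (haploid posterior or diploid dosage), or
#'   list of such (concatenated)
#' @param Z truth in the same shape (indicators or diploid 0/1/2 dosage)
#' @return list: `r2` (mean over ancestries at the best permutation),
#'   `perm` (the label permutation applied to columns of X)
#' @export
r2_vs_truth <- function(X, Z) {
  if (is.list(X)) X <- do.call(rbind, X)
  if (is.list(Z)) Z <- do.call(rbind, Z)
  stopifnot(identical(dim(X), dim(Z)))
  A <- ncol(X)
  perms <- all_permutations(A)
  score <- function(pm, squared = TRUE) {
    r2s <- vapply(seq_len(A), function(a) {
      z <- Z[, a]; x <- X[, pm[a]]
      if (sd(z) == 0 || sd(x) == 0) return(NA_real_)
      if (squared) stats::cor(x, z)^2 else stats::cor(x, z)
    }, numeric(1))
    mean(r2s, na.rm = TRUE)
  }
  sc <- vapply(perms, score, numeric(1))
  best <- which(sc > max(sc) - 1e-12)
  if (length(best) > 1) {
    # complementary columns tie on r^2; break by signed correlation
    signed <- vapply(perms[best], score, numeric(1), squared = FALSE)
    best <- best[which.max(signed)]
  } else best <- best[1]
  list(r2 = sc[best], perm = perms[[best]])
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    sub <- all_permutations(n - 1L)
    for (s in sub) out[[length(out) + 1L]] <-
        c(i, setdiff(seq_len(n), i)[s])
  }
  out
}

#' Reconstruct partial ancestral genomes by maximal posterior assignment
#'
#' Each gridpoint of each target haplotype contributes its alleles to the
#' ancestry with the largest posterior there (ties to the lowest index), so
#' each (haplotype, site) is assigned to exactly one ancestry. The per-site
#' haploid sample size of each reconstructed genome varies along the genome.
#'
#' @param hs the [haplotype_set()] holding the targets
#' @param X nested posteriors `X[[individual]][[hap]][[chrom]]` (G x A)
#' @param grid an [build_grid()] result
#' @return class `ancestral_genomes`: per ancestry, `n` (haploid sample size
#'   per site) and `count` (derived allele count per site); plus the argmax
#'   assignment used
#' @export
reconstruct_ancestral_genomes <- function(hs, X, grid) {
  A <- ncol(X[[1]][[1]][[1]])
  S <- nrow(hs$sites)
  n <- matrix(0L, A, S)
  count <- matrix(0L, A, S)
  for (nm in names(X)) {
    for (h in seq_along(X[[nm]])) {
      row <- which(hs$samples$sample == nm & hs$samples$hap == h)
      for (ch in names(grid$chroms)) {
        gch <- grid$chroms[[ch]]
        am <- max.col(X[[nm]][[h]][[ch]], ties.method = "first")
        a_site <- am[gch$site_to_grid]
        al <- hs$haps[row, gch$site_idx]
        keep <- !is.na(al)
        idx <- cbind(a_site[keep], gch$site_idx[keep])
        n[idx] <- n[idx] + 1L
        count[idx] <- count[idx] + al[keep]
      }
    }
  }
  structure(list(A = A, n = n, count = count), class = "ancestral_genomes")
}

#' Weir-Cockerham-style Fst from per-site frequencies and sample sizes
#'
#' Ratio-of-averages estimator: per site s with haploid sample sizes n1, n2
#' and frequencies p1, p2,
#' `a = n1*n2/(n1+n2)`, `b = 1/(n1+n2-2)`,
#' `c = n1*p1*(1-p1) + n2*p2*(1-p2)`, `d = a*(p1-p2)^2`, and
#' `Fst = 1 - sum(2*a*b*c) / sum(d + (2*a-1)*b*c)`
#' with numerator and denominator summed across sites before the ratio is
#' taken (numerically stable, and robust to sample sizes that vary along the
#' genome, as they do for reconstructed ancestral genomes). Sites with
#' `n1 + n2 < 3`, or missing from either group, are skipped.
#'
#' @param p1,n1 per-site frequency and haploid sample size of group 1
#' @param p2,n2 the same for group 2
#' @return scalar estimate; `NA` with a warning if no site is usable
#' @export
fst_weir_cockerham <- function(p1, n1, p2, n2) {
  ok <- n1 >= 1 & n2 >= 1 & (n1 + n2) >= 3 & !is.na(p1) & !is.na(p2)
  if (!any(ok)) {
    warning("no usable sites: Fst undefined (one group may be empty)")
    return(NA_real_)
  }
  p1 <- p1[ok]; p2 <- p2[ok]; n1 <- n1[ok]; n2 <- n2[ok]
  a <- n1 * n2 / (n1 + n2)
  b <- 1 / (n1 + n2 - 2)
  cc <- n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)
  d <- a * (p1 - p2)^2
  den <- sum(d + (2 * a - 1) * b * cc)
  if (den == 0) {
    warning("zero denominator: Fst undefined")
    return(NA_real_)
  }
  1 - sum(2 * a * b * cc) / den
}

# convenience: Fst from two allele matrices (haplotypes x sites)
fst_from_haps <- function(h1, h2) {
  n1 <- colSums(!is.na(h1)); n2 <- colSums(!is.na(h2))
  p1 <- colMeans(h1, na.rm = TRUE); p2 <- colMeans(h2, na.rm = TRUE)
  fst_weir_cockerham(p1, n1, p2, n2)
}

#' Rst: panel-averaged relative squared Fst difference between ancestries
#'
#' `Rst(a,b) = (1/P) * sum_p (Fst(a,p) - Fst(b,p))^2 / (0.5*(Fst(a,p) +
#' Fst(b,p)))`, a measure of whether the panels differentiate the two latent
#' ancestries; it lies in \[0, 2\]. Negative Fst estimates are floored at 0
#' (the denominator must stay non-negative); a panel with both Fst equal to 0
#' contributes 0 with a warning.
#'
#' @param fst_table A x P matrix of Fst between each ancestry (row) and panel
#'   (column)
#' @return list: `pairwise` tibble of Rst per ancestry pair, `mean` over
#'   pairs
#' @export
rst <- function(fst_table) {
  A <- nrow(fst_table); P <- ncol(fst_table)
  ft <- fst_table
  if (any(ft < 0, na.rm = TRUE)) {
    warning("negative Fst estimate(s) floored at 0 for Rst")
    ft[ft < 0] <- 0
  }
  prs <- utils::combn(A, 2)
  out <- apply(prs, 2, function(pr) {
    a <- pr[1]; b <- pr[2]
    terms <- vapply(seq_len(P), function(p) {
      s <- 0.5 * (ft[a, p] + ft[b, p])
      if (is.na(s)) return(NA_real_)
      if (s == 0) {
        warning("panel ", p, " has zero Fst to both ancestries; term set to 0")
        return(0)
      }
      (ft[a, p] - ft[b, p])^2 / s
    }, numeric(1))
    mean(terms, na.rm = TRUE)
  })
  tb <- tibble::tibble(a = prs[1, ], b = prs[2, ], Rst = out)
  list(pairwise = tb, mean = mean(out, na.rm = TRUE))
}

#' Mean-ancestry selection scan
#'
#' Average diploid ancestry dosage per gridpoint across individuals, with a
#' z-track against the genome-wide mean using the across-individual SE at
#' each gridpoint, reported with a two-sided normal -log10 p. The track is
#' exploratory: no formal genome-wide significance theory is attached. Any
#' 1 Mb physical window containing fewer than `min_markers` markers is
#' masked (centromere-like regions carry no information).
#'
#' @param dosage list per individual of per-chromosome G x A dosage matrices
#'   (X1 + X2)
#' @param grid an [build_grid()] result
#' @param sites site table (for physical marker positions)
#' @param ancestry which ancestry to scan
#' @param min_markers mask threshold per 1 Mb window
#' @return tibble: chrom, gridpoint, cM, bp, mean, z, neglog10p, masked
#' @export
mean_ancestry_scan <- function(dosage, grid, sites, ancestry = 1,
                               min_markers = 10) {
  n_ind <- length(dosage)
  if (n_ind < 2) stop("scan requires >= 2 individuals")
  out <- list()
  allmeans <- unlist(lapply(names(grid$chroms), function(ch)
    rowMeans(vapply(dosage, function(d) d[[ch]][, ancestry],
                    numeric(grid$chroms[[ch]]$n_grid)))))
  gw_mean <- mean(allmeans)
  for (ch in names(grid$chroms)) {
    gch <- grid$chroms[[ch]]
    M <- vapply(dosage, function(d) d[[ch]][, ancestry],
                numeric(gch$n_grid))            # G x n_ind
    mu <- rowMeans(M)
    se <- apply(M, 1, sd) / sqrt(n_ind)
    z <- ifelse(se > 0, (mu - gw_mean) / se, 0)
    # physical mask: 1 Mb windows with < min_markers markers
    bp_site <- sites$bp[gch$site_idx]
    # gridpoint bp by interpolation between flanking sites
    gp_bp <- approx(sites$cM[gch$site_idx], bp_site, xout = gch$gridpoint_cM,
                    rule = 2, ties = "ordered")$y
    win <- floor(gp_bp / 1e6)
    site_win <- floor(bp_site / 1e6)
    counts <- table(site_win)
    masked <- !(as.character(win) %in%
                  names(counts)[counts >= min_markers])
    z[masked] <- NA_real_
    out[[ch]] <- tibble::tibble(
      chrom = ch, gridpoint = seq_len(gch$n_grid),
      cM = gch$gridpoint_cM, bp = gp_bp, mean = mu, z = z,
      neglog10p = -pnorm(-abs(z), log.p = TRUE) / log(10) - log10(2),
      masked = masked)
  }
  dplyr::bind_rows(out)
}
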