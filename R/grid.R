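#' Build an even genetic-distance grid
#'
#' Imposes an even grid on recombination distance along each chromosome. With
#' `rate_per_cM` gridpoints per centimorgan the grid has
#' `G = ceil(span_cM * rate_per_cM) + 1` points; every site is assigned to its
#' nearest gridpoint by genetic distance, with exact midpoints broken toward
#' the lower-index gridpoint so the mapping is platform-deterministic. A
#' gridpoint may carry 0, 1 or many sites, so grid size depends on genetic
#' span only, not on marker density.
#'
#' @param sites site table (`chrom`, `cM`, ...) as in [haplotype_set()]
#' @param rate_per_cM gridpoints per centimorgan (default 60)
#' @return An object of class `ancestry_grid`: per-chromosome gridpoint
#'   positions, the site-to-gridpoint map (indices into the full site table)
#'   and the common spacing `w = 1/rate_per_cM`.
#' @export
build_grid <- function(sites, rate_per_cM = 60) {
  stopifnot(rate_per_cM > 0)
  w <- 1 / rate_per_cM
  chroms <- unique(sites$chrom)
  out <- lapply(chroms, function(ch) {
    idx <- which(sites$chrom == ch)
    cm <- sites$cM[idx]
    origin <- min(cm)
    span <- max(cm) - origin
    if (span == 0) {
      warning("zero genetic span on chromosome ", ch, "; single gridpoint")
      n_grid <- 1L
    } else {
      n_grid <- as.integer(ceiling(span * rate_per_cM)) + 1L
    }
    # nearest gridpoint, midpoint ties to the lower index
    g0 <- ceiling((cm - origin) / w - 0.5)
    g0 <- pmin(pmax(g0, 0), n_grid - 1L)
    list(chrom = ch, origin_cM = origin, n_grid = n_grid,
         gridpoint_cM = origin + w * (seq_len(n_grid) - 1L),
         site_idx = idx, site_to_grid = as.integer(g0) + 1L)
  })
  names(out) <- chroms
  structure(list(rate_per_cM = rate_per_cM, w = w, chroms = out),
            class = "ancestry_grid")
}

#' @export
print.ancestry_grid <- function(x, ...) {
  cat("<ancestry_grid> ", length(x$chroms), " chromosome(s), ",
      x$rate_per_cM, " gridpoints/cM (w = ", signif(x$w, 4), " cM)\n",
      sep = "")
  for (ch in x$chroms)
    cat("  ", ch$chrom, ": G = ", ch$n_grid, ", ",
        length(ch$site_idx), " sites\n", sep = "")
  invisible(x)
}

#' Per-gridpoint match/mismatch counts against a donor pool
#'
#' For one target haplotype, counts at every gridpoint and donor how many of
#' the sites mapped there agree and disagree. Missing alleles (on either side)
#' contribute to neither count, which is how missing data enters the model:
#' a gridpoint with fewer observations simply carries less evidence. Counts
#' are computed once and reused by every forward-backward sweep.
#'
#' @param hs a [haplotype_set()]
#' @param target_row row index of the target haplotype in `hs$haps`
#' @param donor_rows row indices of the donor haplotypes
#' @param grid an [build_grid()] result
#' @return class `match_counts`: per chromosome a list with `gp` (sorted
#'   1-based indices of gridpoints carrying sites), `match` and `mismatch`
#'   (donors x length(gp) integer matrices) and `n_grid`.
#' @export
compute_match_counts <- function(hs, target_row, donor_rows, grid) {
  out <- lapply(grid$chroms, function(ch) {
    sidx <- ch$site_idx
    tg <- hs$haps[target_row, sidx]
    D <- hs$haps[donor_rows, sidx, drop = FALSE]
    gp <- sort(unique(ch$site_to_grid))
    gfac <- factor(ch$site_to_grid, levels = gp)
    eq <- D == matrix(tg, nrow = nrow(D), ncol = length(sidx), byrow = TRUE)
    mm <- (!is.na(eq)) & eq
    kk <- (!is.na(eq)) & !eq
    match <- t(rowsum(t(mm + 0L), gfac))
    mismatch <- t(rowsum(t(kk + 0L), gfac))
    storage.mode(match) <- "integer"
    storage.mode(mismatch) <- "integer"
    list(gp = gp, match = match, mismatch = mismatch, n_grid = ch$n_grid)
  })
  structure(out, class = "match_counts", donors = donor_rows)
}
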