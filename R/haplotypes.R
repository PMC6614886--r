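#' Assemble a set of phased haplotypes with panel labels
#'
#' The central data container: a matrix of phased biallelic alleles (one row
#' per haplotype, one column per site), a site table with physical and genetic
#' positions, and a sample table assigning every haplotype to a labeled
#' reference panel or to the admixed `"target"` group.
#'
#' @param haps integer matrix of 0/1 alleles (`NA` = missing), one row per
#'   haplotype. Row names are haplotype ids (`<sample>_1`, `<sample>_2`).
#' @param sites data frame with columns `chrom`, `id`, `bp`, `cM` (and
#'   optionally `ref`, `alt`); `bp` strictly increasing and `cM` non-decreasing
#'   within each chromosome.
#' @param samples data frame with columns `hap_id`, `sample`, `hap` (1 or 2)
#'   and `panel` (a panel label or `"target"`), one row per haplotype row.
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(haps, sites, samples) {
  stopifnot(is.matrix(haps), nrow(haps) == nrow(samples),
            ncol(haps) == nrow(sites))
  storage.mode(haps) <- "integer"
  bad <- !(haps %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("haplotype alleles must be 0, 1 or NA")
  sites$chrom <- as.character(sites$chrom)
  for (ch in unique(sites$chrom)) {
    i <- sites$chrom == ch
    if (is.unsorted(sites$bp[i], strictly = TRUE))
      stop("bp positions must be strictly increasing within chromosome ", ch)
    if (!anyNA(sites$cM[i]) && is.unsorted(sites$cM[i]))
      stop("cM positions must be non-decreasing within chromosome ", ch)
  }
  rownames(haps) <- samples$hap_id
  structure(list(haps = haps, sites = sites, samples = samples),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  tab <- table(x$samples$panel)
  cat("<haplotype_set> ", nrow(x$haps), " haplotypes x ", ncol(x$haps),
      " sites on ", length(unique(x$sites$chrom)), " chromosome(s)\n", sep = "")
  cat("  panels:", paste0(names(tab), " (", tab, ")", collapse = ", "), "\n")
  invisible(x)
}

panel_names <- function(hs) {
  setdiff(unique(hs$samples$panel), "target")
}

target_samples <- function(hs) {
  unique(hs$samples$sample[hs$samples$panel == "target"])
}

donor_hap_rows <- function(hs) {
  which(hs$samples$panel != "target")
}

#' Write a plain 0/1 haplotype matrix to a text file
#'
#' One row per haplotype, whitespace delimited, with a header line of site
#' ids; missing alleles written as `NA`.
#'
#' @param hs a [haplotype_set()]
#' @param path output file
#' @export
write_haplotype_matrix <- function(hs, path) {
  m <- hs$haps
  df <- as.data.frame(m)
  names(df) <- hs$sites$id
  write.table(df, path, quote = FALSE, row.names = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read haplotypes from a plain matrix or a phased VCF
#'
#' Accepts either a whitespace-delimited 0/1 matrix written by
#' [write_haplotype_matrix()] plus an explicit site table, or a phased VCF
#' (`|`-separated GT). Multiallelic records are skipped with a message;
#' unphased genotypes in any sample are a hard error naming the record, as
#' phase is meaningful to every downstream step.
#'
#' @param path path to the haplotype file
#' @param panel_labels named character vector mapping sample name to panel
#'   label (use `"target"` for admixed samples); every sample must be covered.
#' @param sites site table (required for the plain-matrix format; ignored for
#'   VCF, where positions come from the records). `cM` may be added later via
#'   [interpolate_cM()].
#' @param format `"auto"`, `"matrix"` or `"vcf"`.
#' @return A [haplotype_set()].
#' @export
read_haplotypes <- function(path, panel_labels, sites = NULL,
                            format = c("auto", "matrix", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "matrix"
  if (format == "vcf") {
    return(read_phased_vcf(path, panel_labels))
  }
  df <- read.table(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(df)
  if (is.null(sites)) stop("a site table is required for the matrix format")
  hap_ids <- rownames(m)
  sample <- sub("_[12]$", "", hap_ids)
  hap <- as.integer(sub("^.*_", "", hap_ids))
  miss <- setdiff(unique(sample), names(panel_labels))
  if (length(miss))
    stop("no panel label for sample(s): ", paste(miss, collapse = ", "))
  samples <- data.frame(hap_id = hap_ids, sample = sample, hap = hap,
                        panel = unname(panel_labels[sample]))
  haplotype_set(m, sites, samples)
}

read_phased_vcf <- function(path, panel_labels) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) != 1L |
    nchar(fix[, "ALT"]) != 1L
  if (any(multi))
    message(sum(multi), " multiallelic/non-SNP record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  smp <- colnames(gt)
  miss <- setdiff(smp, names(panel_labels))
  if (length(miss))
    stop("no panel label for sample(s): ", paste(miss, collapse = ", "))
  unph <- which(grepl("/", gt) & !is.na(gt))
  if (length(unph)) {
    i <- arrayInd(unph[1], dim(gt))
    stop("unphased genotype at record ", fix[i[1], "ID"], " (",
         fix[i[1], "CHROM"], ":", fix[i[1], "POS"], ") in sample ",
         smp[i[2]])
  }
  a1 <- suppressWarnings(matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt)))
  a2 <- suppressWarnings(matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt)))
  # a column of single-character GTs is a haploid sample (e.g. a stored
  # reference haplotype): it contributes one haplotype row
  haploid <- apply(gt, 2, function(x) all(nchar(x) == 1L | is.na(x)))
  haps <- NULL; hap_ids <- character(0); hap_no <- integer(0)
  sample_of <- character(0)
  for (s in seq_along(smp)) {
    if (haploid[s]) {
      haps <- rbind(haps, a1[, s])
      hap_ids <- c(hap_ids, paste0(smp[s], "_1"))
      hap_no <- c(hap_no, 1L); sample_of <- c(sample_of, smp[s])
    } else {
      haps <- rbind(haps, a1[, s], a2[, s])
      hap_ids <- c(hap_ids, paste0(smp[s], "_1"), paste0(smp[s], "_2"))
      hap_no <- c(hap_no, 1L, 2L); sample_of <- c(sample_of, smp[s], smp[s])
    }
  }
  sites <- data.frame(chrom = fix[, "CHROM"],
                      id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                  paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                                  fix[, "ID"]),
                      bp = as.integer(fix[, "POS"]),
                      cM = NA_real_,
                      ref = fix[, "REF"], alt = fix[, "ALT"])
  samples <- data.frame(hap_id = hap_ids,
                        sample = sample_of,
                        hap = hap_no,
                        panel = unname(panel_labels[sample_of]))
  haplotype_set(haps, sites, samples)
}

#' Write a phased VCF (GT with "|" separator)
#'
#' Emits an uncompressed minimal VCFv4.2 with one GT field per sample; missing
#' alleles become `.`.
#'
#' @param hs a [haplotype_set()]
#' @param path output file
#' @export
write_phased_vcf <- function(hs, path) {
  smp <- unique(hs$samples$sample)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=admixpaint",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", smp), collapse = "\t")), con)
  al <- function(x) ifelse(is.na(x), ".", as.character(x))
  row_of <- function(s, h) {
    r <- which(hs$samples$sample == s & hs$samples$hap == h)
    if (length(r)) r else NA_integer_
  }
  r1 <- vapply(smp, row_of, integer(1), h = 1L)
  r2 <- vapply(smp, row_of, integer(1), h = 2L)
  ref <- if (!is.null(hs$sites$ref)) hs$sites$ref else rep("A", nrow(hs$sites))
  alt <- if (!is.null(hs$sites$alt)) hs$sites$alt else rep("G", nrow(hs$sites))
  gts <- matrix("", length(smp), ncol(hs$haps))
  for (s in seq_along(smp)) {
    gts[s, ] <- if (is.na(r2[s])) al(hs$haps[r1[s], ])  # haploid sample
    else paste0(al(hs$haps[r1[s], ]), "|", al(hs$haps[r2[s], ]))
  }
  lines <- paste(hs$sites$chrom, hs$sites$bp, hs$sites$id, ref, alt,
                 ".", "PASS", ".", "GT",
                 apply(gts, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a HapMap-style recombination map
#'
#' Three or more whitespace-delimited columns: chromosome, bp position and
#' cumulative genetic position in cM (a header line is tolerated).
#'
#' @param path map file
#' @return data frame with columns `chrom`, `bp`, `cM`
#' @export
read_recomb_map <- function(path) {
  raw <- read.table(path, header = FALSE, colClasses = "character")
  if (suppressWarnings(is.na(as.numeric(raw[1, 2]))))
    raw <- raw[-1, , drop = FALSE]  # header line
  m <- data.frame(chrom = raw[, 1],
                  bp = as.numeric(raw[, 2]),
                  cM = as.numeric(raw[, 3]))
  for (ch in unique(m$chrom)) {
    i <- m$chrom == ch
    if (is.unsorted(m$cM[i]))
      stop("decreasing cM in recombination map on chromosome ", ch)
  }
  m
}

#' Interpolate genetic positions from a recombination map
#'
#' Linear interpolation of cM at arbitrary bp positions; positions outside the
#' map are extrapolated with the terminal segment's recombination rate and a
#' warning is emitted.
#'
#' @param bp physical positions (single chromosome)
#' @param recomb_map data frame `chrom`/`bp`/`cM` as from [read_recomb_map()],
#'   or just `bp`/`cM` for a single chromosome
#' @param chrom chromosome to use when the map covers several
#' @return numeric vector of cM positions
#' @export
interpolate_cM <- function(bp, recomb_map, chrom = NULL) {
  m <- recomb_map
  if (!is.null(chrom) && "chrom" %in% names(m)) m <- m[m$chrom == chrom, ]
  if (is.unsorted(m$cM)) stop("decreasing cM in recombination map")
  out <- approx(m$bp, m$cM, xout = bp, ties = "ordered")$y
  lo <- bp < m$bp[1]; hi <- bp > m$bp[nrow(m)]
  if (any(lo) || any(hi)) {
    warning("positions outside the recombination map extrapolated at the ",
            "terminal rate")
    n <- nrow(m)
    rate_lo <- (m$cM[2] - m$cM[1]) / (m$bp[2] - m$bp[1])
    rate_hi <- (m$cM[n] - m$cM[n - 1]) / (m$bp[n] - m$bp[n - 1])
    out[lo] <- m$cM[1] + (bp[lo] - m$bp[1]) * rate_lo
    out[hi] <- m$cM[n] + (bp[hi] - m$bp[n]) * rate_hi
  }
  out
}
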