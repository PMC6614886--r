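#' Describe a set of populations diverged by drift
#'
#' Populations diverge from a common ancestor by pure drift: per-site allele
#' frequencies are drawn around the ancestral frequency from the
#' Balding-Nichols Beta distribution with drift coefficient `drift_F`, founder
#' haplotypes are drawn site-wise from those frequencies, and the haplotypes
#' actually emitted are Li-and-Stephens-style mosaics of the founders so that
#' realistic within-population LD exists.
#'
#' @param n_pops number of populations
#' @param drift_F per-population drift coefficient, in (0, 1); a single value
#'   is recycled
#' @param founder_pool founder haplotypes per population (>= 2)
#' @param ancestral_freq_range range for the per-site ancestral allele
#'   frequency; the default avoids monomorphic sites
#' @param mosaic_switch_rate founder-switch rate per Morgan when building
#'   mosaic haplotypes
#' @param mutation_rate per-site copy-error probability, in \[0, 0.5)
#' @return class `population_model`
#' @export
population_model <- function(n_pops = 2, drift_F = 0.1, founder_pool = 10,
                             ancestral_freq_range = c(0.05, 0.95),
                             mosaic_switch_rate = 30, mutation_rate = 0.002) {
  drift_F <- rep_len(drift_F, n_pops)
  stopifnot(n_pops >= 1, all(drift_F > 0), all(drift_F < 1),
            founder_pool >= 2, mutation_rate >= 0, mutation_rate < 0.5,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            mosaic_switch_rate >= 0)
  structure(list(n_pops = n_pops, drift_F = drift_F,
                 founder_pool = founder_pool,
                 ancestral_freq_range = ancestral_freq_range,
                 mosaic_switch_rate = mosaic_switch_rate,
                 mutation_rate = mutation_rate),
            class = "population_model")
}

#' Describe an admixture scenario
#'
#' Ancestry-tract breakpoints fall as a Poisson process at `lambda_gen` per
#' Morgan and the ancestry after each breakpoint is redrawn i.i.d. from
#' `alpha` (possibly unchanged), so the pairwise-ancestry autocorrelation
#' decays as `exp(-lambda_gen * d)` exactly. Under the classical tract-length
#' model the rate is one less than the number of generations since admixture;
#' [generations_to_rate()] converts.
#'
#' @param A number of ancestries (>= 2)
#' @param source_pop_of_ancestry integer/character vector mapping each
#'   ancestry to a source population of the [population_model()]
#' @param alpha mixing proportions (sum to 1)
#' @param lambda_gen breakpoint rate per Morgan (> 0)
#' @param n_targets number of admixed diploids
#' @param hap_switch_rate additional within-tract donor-haplotype switch rate
#'   per Morgan (background LD scale of the copying process)
#' @return class `admixture_scenario`
#' @export
admixture_scenario <- function(A = 2, source_pop_of_ancestry = seq_len(A),
                               alpha = rep(1 / A, A), lambda_gen = 50,
                               n_targets = 10, hap_switch_rate = 30) {
  stopifnot(A >= 2, length(alpha) == A, abs(sum(alpha) - 1) < 1e-8,
            all(alpha >= 0), lambda_gen > 0, n_targets >= 1,
            length(source_pop_of_ancestry) == A)
  structure(list(A = A, source_pop_of_ancestry = source_pop_of_ancestry,
                 alpha = alpha, lambda_gen = lambda_gen,
                 n_targets = n_targets, hap_switch_rate = hap_switch_rate),
            class = "admixture_scenario")
}

#' Convert generations since admixture to a tract breakpoint rate
#'
#' The expected ancestry-chunk length in Morgans is `1/(g - 1)` for an event
#' `g` generations ago, i.e. the exponential tract-length rate is `g - 1`.
#'
#' @param generations generations since admixture (>= 2)
#' @export
generations_to_rate <- function(generations) {
  stopifnot(all(generations >= 2))
  generations - 1
}

#' Evenly spaced synthetic site table
#'
#' Sites uniformly spaced in genetic distance across one or more chromosomes,
#' with physical positions implied by a uniform 1 cM/Mb map.
#'
#' @param n_sites total number of sites (split proportionally to length)
#' @param chr_lengths_cM chromosome lengths in cM (named or not)
#' @export
make_sites <- function(n_sites, chr_lengths_cM = c(chr1 = 100, chr2 = 100)) {
  if (is.null(names(chr_lengths_cM)))
    names(chr_lengths_cM) <- paste0("chr", seq_along(chr_lengths_cM))
  per <- round(n_sites * chr_lengths_cM / sum(chr_lengths_cM))
  do.call(rbind, lapply(names(chr_lengths_cM), function(ch) {
    n <- per[[ch]]
    cm <- seq(0, chr_lengths_cM[[ch]], length.out = n)
    data.frame(chrom = ch, id = paste0(ch, "_s", seq_len(n)),
               bp = as.integer(round(cm * 1e6)) + 1L, cM = cm,
               ref = "A", alt = "G")
  }))
}

# mosaic copy of one haplotype from a pool, switching founders at a Poisson
# rate per Morgan; returns integer vector of pool row indices per site
mosaic_path <- function(site_cM, span_cM, origin_cM, rate_per_M, n_pool) {
  span_M <- span_cM / 100
  n_bk <- if (rate_per_M > 0) rpois(1, rate_per_M * span_M) else 0L
  bk <- sort(runif(n_bk, origin_cM, origin_cM + span_cM))
  seg <- findInterval(site_cM, bk) + 1L
  picks <- sample.int(n_pool, n_bk + 1L, replace = TRUE)
  picks[seg]
}

#' Simulate diverged reference panels
#'
#' Implements the generative model described in [population_model()]. Sites
#' monomorphic across all output haplotypes are dropped with a message.
#'
#' @param model a [population_model()]
#' @param sites site table with strictly increasing `cM` per chromosome (see
#'   [make_sites()])
#' @param n_per_pop haplotypes to emit per population
#' @param seed optional RNG seed
#' @return A [haplotype_set()] with panels `pop1`, `pop2`, ...
#' @export
simulate_panels <- function(model, sites, n_per_pop = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_sites <- nrow(sites)
  if (n_sites < 2) stop("need at least 2 sites")
  for (ch in unique(sites$chrom))
    if (is.unsorted(sites$cM[sites$chrom == ch], strictly = TRUE))
      stop("site cM positions must be strictly increasing")
  p_anc <- runif(n_sites, model$ancestral_freq_range[1],
                 model$ancestral_freq_range[2])
  chroms <- unique(sites$chrom)
  haps <- matrix(NA_integer_, 0L, n_sites)
  samples <- NULL
  for (pop in seq_len(model$n_pops)) {
    F <- model$drift_F[pop]
    freq <- rbeta(n_sites, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    founders <- matrix(rbinom(model$founder_pool * n_sites, 1L,
                              rep(freq, each = model$founder_pool)),
                       nrow = model$founder_pool)
    hp <- matrix(0L, n_per_pop, n_sites)
    for (h in seq_len(n_per_pop)) {
      for (ch in chroms) {
        idx <- which(sites$chrom == ch)
        cm <- sites$cM[idx]
        path <- mosaic_path(cm, max(cm) - min(cm), min(cm),
                            model$mosaic_switch_rate, model$founder_pool)
        hp[h, idx] <- founders[cbind(path, idx)]
      }
      if (model$mutation_rate > 0) {
        flip <- runif(n_sites) < model$mutation_rate
        hp[h, flip] <- 1L - hp[h, flip]
      }
    }
    haps <- rbind(haps, hp)
    nm <- paste0("pop", pop, "_", seq_len(n_per_pop))
    samples <- rbind(samples,
                     data.frame(hap_id = nm, sample = nm,
                                hap = 1L, panel = paste0("pop", pop)))
  }
  mono <- colSums(haps, na.rm = TRUE) %in% c(0L, nrow(haps))
  if (any(mono)) {
    message(sum(mono), " monomorphic site(s) dropped")
    haps <- haps[, !mono, drop = FALSE]
    sites <- sites[!mono, , drop = FALSE]
  }
  haplotype_set(haps, sites, samples)
}

#' Simulate admixed diploid targets with a known ancestry truth track
#'
#' Per target haplotype and chromosome, ancestry-tract breakpoints fall at
#' Poisson rate `lambda_gen` per Morgan; at each breakpoint the ancestry is
#' redrawn i.i.d. from `alpha`. Within a tract, alleles are copied verbatim
#' from a randomly chosen haplotype of the tract's source population,
#' re-chosen at every breakpoint and additionally at `hap_switch_rate` per
#' Morgan.
#'
#' @param sources a [haplotype_set()] whose panels are the source populations
#'   (typically the held-out half from [split_panels()])
#' @param scenario an [admixture_scenario()]
#' @param seed optional RNG seed
#' @return list with `targets` (a [haplotype_set()] of the admixed diploids)
#'   and `truth` (class `truth_set`: tract table plus flip bookkeeping slot)
#' @export
simulate_admixed <- function(sources, scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- scenario$A
  pools <- lapply(seq_len(A), function(a) {
    pop <- scenario$source_pop_of_ancestry[a]
    pop <- if (is.numeric(pop)) paste0("pop", pop) else pop
    rows <- which(sources$samples$panel == pop)
    if (!length(rows)) stop("empty source pool for ancestry ", a)
    rows
  })
  sites <- sources$sites
  chroms <- unique(sites$chrom)
  n_hap <- 2L * scenario$n_targets
  haps <- matrix(NA_integer_, n_hap, nrow(sites))
  tracts <- vector("list", n_hap * length(chroms))
  ti <- 0L
  hap_ids <- paste0("adm", rep(seq_len(scenario$n_targets), each = 2L),
                    "_", rep(1:2, scenario$n_targets))
  for (h in seq_len(n_hap)) {
    for (ch in chroms) {
      idx <- which(sites$chrom == ch)
      cm <- sites$cM[idx]
      lo <- min(cm); hi <- max(cm)
      span_M <- (hi - lo) / 100
      n_bk <- rpois(1, scenario$lambda_gen * span_M)
      bk <- sort(runif(n_bk, lo, hi))
      anc <- sample.int(A, n_bk + 1L, replace = TRUE, prob = scenario$alpha)
      seg_start <- c(lo, bk)
      seg_end <- c(bk, hi)
      seg_of_site <- findInterval(cm, bk) + 1L
      for (s in seq_along(anc)) {
        in_seg <- which(seg_of_site == s)
        if (length(in_seg)) {
          pool <- pools[[anc[s]]]
          sub <- mosaic_path(cm[in_seg], seg_end[s] - seg_start[s],
                             seg_start[s], scenario$hap_switch_rate,
                             length(pool))
          haps[h, idx[in_seg]] <- sources$haps[cbind(pool[sub], idx[in_seg])]
        }
      }
      ti <- ti + 1L
      tracts[[ti]] <- data.frame(hap_id = hap_ids[h], chrom = ch,
                                 start_cM = seg_start, end_cM = seg_end,
                                 ancestry = anc)
    }
  }
  tracts <- do.call(rbind, tracts[seq_len(ti)])
  samples <- data.frame(hap_id = hap_ids,
                        sample = paste0("adm",
                                        rep(seq_len(scenario$n_targets),
                                            each = 2L)),
                        hap = rep(1:2, scenario$n_targets),
                        panel = "target")
  targets <- haplotype_set(haps, sites, samples)
  truth <- structure(list(tracts = tracts, flip_positions = NULL,
                          A = A, alpha = scenario$alpha,
                          lambda_gen = scenario$lambda_gen),
                     class = "truth_set")
  list(targets = targets, truth = truth)
}

#' True local-ancestry indicator matrix on a grid
#'
#' @param truth a `truth_set` from [simulate_admixed()]
#' @param grid an [build_grid()] result
#' @param hap_id target haplotype id
#' @param chrom chromosome
#' @return G x A matrix of 0/1 indicators (one ancestry per gridpoint)
#' @export
truth_matrix <- function(truth, grid, hap_id, chrom) {
  ch <- grid$chroms[[chrom]]
  tr <- truth$tracts[truth$tracts$hap_id == hap_id &
                       truth$tracts$chrom == chrom, ]
  anc_at <- tr$ancestry[findInterval(ch$gridpoint_cM, tr$start_cM,
                                     rightmost.closed = TRUE)]
  Z <- matrix(0L, ch$n_grid, truth$A)
  Z[cbind(seq_len(ch$n_grid), anc_at)] <- 1L
  Z
}

#' Split simulated panels into admixture sources and held-out donors
#'
#' The haplotypes used to build the admixed targets are by default withheld
#' from inference, mimicking the realistic situation where the true mixing
#' haplotypes are not among the reference panels.
#'
#' @param hs panels from [simulate_panels()]
#' @param frac_source fraction of each panel used as admixture source
#' @return list with `sources` and `panels`, both [haplotype_set()]s
#' @export
split_panels <- function(hs, frac_source = 0.5) {
  src <- unlist(lapply(split(seq_len(nrow(hs$haps)), hs$samples$panel),
                       function(i) i[seq_len(floor(length(i) * frac_source))]))
  keep <- setdiff(seq_len(nrow(hs$haps)), src)
  sub <- function(rows)
    haplotype_set(hs$haps[rows, , drop = FALSE], hs$sites,
                  hs$samples[rows, , drop = FALSE])
  list(sources = sub(sort(src)), panels = sub(sort(keep)))
}

#' Inject phase errors into target diploids
#'
#' At each gridpoint independently, with probability `error_rate`, swap the
#' two haplotypes' alleles at all sites mapped to that gridpoint. Gridpoints
#' where the haplotypes carry identical alleles are unaffected by the swap and
#' are excluded from the recorded flip positions.
#'
#' @param targets a [haplotype_set()] of diploid targets
#' @param grid an [build_grid()] result
#' @param error_rate per-gridpoint flip probability, in \[0, 0.5\]
#' @param seed optional RNG seed
#' @return list: `targets` (scrambled copy) and `flips` (data frame of
#'   sample/chrom/gridpoint/cM actually changed)
#' @export
inject_phase_errors <- function(targets, grid, error_rate, seed = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 0.5)
  if (!is.null(seed)) set.seed(seed)
  haps <- targets$haps
  smp <- unique(targets$samples$sample)
  flips <- list()
  for (s in smp) {
    r1 <- which(targets$samples$sample == s & targets$samples$hap == 1L)
    r2 <- which(targets$samples$sample == s & targets$samples$hap == 2L)
    for (ch in grid$chroms) {
      sel <- which(runif(ch$n_grid) < error_rate)
      if (!length(sel)) next
      site_sel <- ch$site_idx[ch$site_to_grid %in% sel]
      if (length(site_sel)) {
        tmp <- haps[r1, site_sel]
        haps[r1, site_sel] <- haps[r2, site_sel]
        haps[r2, site_sel] <- tmp
      }
      # record only gridpoints where the swap changed anything
      diff_site <- which(haps[r1, ch$site_idx] != haps[r2, ch$site_idx])
      het_gp <- unique(ch$site_to_grid[diff_site])
      eff <- intersect(sel, het_gp)
      if (length(eff))
        flips[[length(flips) + 1L]] <-
          data.frame(sample = s, chrom = ch$chrom, gridpoint = eff,
                     cM = ch$gridpoint_cM[eff])
    }
  }
  flips <- if (length(flips)) do.call(rbind, flips) else
    data.frame(sample = character(), chrom = character(),
               gridpoint = integer(), cM = numeric())
  out <- haplotype_set(haps, targets$sites, targets$samples)
  list(targets = out, flips = flips)
}

#' One-stop synthetic admixture study
#'
#' Generates diverged populations, splits each into admixture sources and
#' held-out reference panels, simulates admixed diploids with a truth track,
#' optionally scrambles phase, and assembles the combined haplotype set that
#' [run_pipeline()] consumes.
#'
#' @param n_pops,drift_F,founder_pool,mosaic_switch_rate,mutation_rate see
#'   [population_model()]
#' @param n_sites,chr_lengths_cM see [make_sites()]
#' @param A,alpha,lambda_gen,n_targets,hap_switch_rate see
#'   [admixture_scenario()]; ancestry `a` sources from population `a`
#' @param n_per_pop haplotypes per population before the source/panel split
#' @param phase_error_rate per-gridpoint phase-scramble probability (0 = off)
#' @param grid_rate_per_cM grid used for phase-error injection bookkeeping
#' @param seed RNG seed for the whole study
#' @return list: `haps` (panels + targets), `truth`, `flips`, `scenario`,
#'   `model`, `sources`
#' @export
simulate_admixture_study <- function(n_pops = 2, drift_F = 0.1,
                                     n_sites = 2000,
                                     chr_lengths_cM = c(chr1 = 100,
                                                        chr2 = 100),
                                     founder_pool = 10, n_per_pop = 60,
                                     mosaic_switch_rate = 30,
                                     mutation_rate = 0.002,
                                     A = n_pops, alpha = rep(1 / A, A),
                                     lambda_gen = 50, n_targets = 10,
                                     hap_switch_rate = 30,
                                     phase_error_rate = 0,
                                     grid_rate_per_cM = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- population_model(n_pops, drift_F, founder_pool,
                            mosaic_switch_rate = mosaic_switch_rate,
                            mutation_rate = mutation_rate)
  sites <- make_sites(n_sites, chr_lengths_cM)
  panels_all <- simulate_panels(model, sites, n_per_pop = n_per_pop)
  sp <- split_panels(panels_all)
  scen <- admixture_scenario(A = A, alpha = alpha, lambda_gen = lambda_gen,
                             n_targets = n_targets,
                             hap_switch_rate = hap_switch_rate)
  sim <- simulate_admixed(sp$sources, scen)
  flips <- NULL
  if (phase_error_rate > 0) {
    grid <- build_grid(sim$targets$sites, grid_rate_per_cM)
    pe <- inject_phase_errors(sim$targets, grid, phase_error_rate)
    sim$targets <- pe$targets
    flips <- pe$flips
    sim$truth$flip_positions <- flips
  }
  combined <- haplotype_set(rbind(sp$panels$haps, sim$targets$haps),
                            sp$panels$sites,
                            rbind(sp$panels$samples, sim$targets$samples))
  list(haps = combined, truth = sim$truth, flips = flips, scenario = scen,
       model = model, sources = sp$sources)
}
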