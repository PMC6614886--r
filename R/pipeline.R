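#' Configuration for a full inference run
#'
#' @param A number of latent ancestries (>= 2)
#' @param grid_rate gridpoints per cM (default 60)
#' @param rounds outer thin/rephase/EM rounds (default 5; a round with zero
#'   accepted phase flips also ends the loop, which is the phase-convergence
#'   criterion)
#' @param em_iters_per_round EM iterations within each round (default 10)
#' @param K_thin donors retained per gridpoint by thinning (default 100)
#' @param rho_thin single-layer switch probability used for thinning
#' @param shared_Pi fit one joint ancestry-switch matrix for all targets
#' @param rephase run the phase hunter (disable for perfectly phased input)
#' @param lambda0,rho0,theta0 parameter initialisation, see
#'   [initialize_params()]
#' @param n_init jittered initialisations screened by log-likelihood after
#'   `init_screen_iters` EM iterations before the main loop commits to one
#'   (EM on a symmetric-but-jittered start is multi-modal, especially for
#'   three or more ancestries)
#' @param init_screen_iters burn-in EM iterations per screened start
#' @param date_mode `"flexible"` or `"single"`, see [estimate_dates()]
#' @param curve_source `"map"` (default) builds the coancestry curves from
#'   maximal-a-posteriori ancestry calls, matching the hard assignment used
#'   for the drift summaries; `"posterior"` uses the probabilistic track.
#'   At sparse marker densities the posterior track is smoothed by the HMM,
#'   which attenuates the fitted decay rate; hard calls largely remove that
#'   attenuation
#' @param n_boot bootstrap replicates for dating (0 disables)
#' @param d_min,d_max coancestry curve range in cM
#' @param final_rel_tol,final_max_iter final-EM convergence control
#' @param seed RNG seed for the run
#' @export
run_config <- function(A = 2, grid_rate = 60, rounds = 5,
                       em_iters_per_round = 10, K_thin = 100,
                       rho_thin = 0.05, shared_Pi = FALSE, rephase = TRUE,
                       lambda0 = 30, rho0 = 0.05, theta0 = 0.01,
                       n_init = 5, init_screen_iters = 2,
                       date_mode = "flexible", curve_source = "map",
                       n_boot = 100,
                       d_min = 0.5, d_max = 30,
                       final_rel_tol = 1e-5, final_max_iter = 200,
                       seed = 1) {
  stopifnot(A >= 2, grid_rate > 0, rounds >= 1, em_iters_per_round >= 1,
            K_thin >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full local-ancestry inference pipeline
#'
#' Executes: parameter initialisation; repeated rounds of donor thinning,
#' phase hunting and EM updates until phase convergence (a round with no
#' accepted flips) or the round cap; a final EM to convergence; a last E-step
#' for posteriors; coancestry-curve dating with chromosome bootstrap; and
#' drift/accuracy summaries (Fst between ancestries and to every panel, Rst,
#' expected r-squared). A warning is raised when an inferred ancestry's
#' genome-wide mass is below 0.5% — with effectively no minor ancestry the
#' between-ancestry Fst is meaningless and there may be no admixture signal.
#'
#' @param hs a [haplotype_set()] containing labeled panels and `"target"`
#'   samples
#' @param config a [run_config()]
#' @return class `ancestry_fit`: posteriors, parameters, EM trace, flip log,
#'   curves and dates, summary statistics, and a provenance record
#' @export
run_pipeline <- function(hs, config = run_config()) {
  set.seed(config$seed)
  t0 <- Sys.time()
  grid <- build_grid(hs$sites, config$grid_rate)
  td <- prepare_targets(hs, grid)
  attr(td, "shared_Pi") <- config$shared_Pi
  targets <- names(td$individuals)
  # screen several jittered starts by log-likelihood after a short burn-in
  best <- NULL
  for (i in seq_len(max(1L, config$n_init))) {
    cand <- initialize_params(config$A, td$panels, td$panel_sizes, targets,
                              grid_w_cM = grid$w, lambda0 = config$lambda0,
                              rho0 = config$rho0, theta0 = config$theta0)
    if (config$n_init > 1L) {
      stt <- em_iterate(td, cand, config$init_screen_iters)
      ll <- stt$loglik_trace[length(stt$loglik_trace)]
      if (is.null(best) || ll > best$ll)
        best <- list(params = stt$params, ll = ll)
    } else best <- list(params = cand, ll = NA_real_)
  }
  params <- best$params
  loglik_rounds <- numeric(0)
  flip_log <- list()
  rounds_run <- 0L
  for (round in seq_len(config$rounds)) {
    rounds_run <- round
    # --- thin ---
    for (nm in targets) {
      ind <- td$individuals[[nm]]
      g12 <- lapply(1:2, function(h) {
        gam <- lapply(names(ind$counts[[h]]), function(ch)
          paint_single_layer(ind$counts[[h]][[ch]],
                             rho_thin = config$rho_thin,
                             theta = params$theta)$gamma)
        do.call(rbind, gam)
      })
      th <- rank_and_thin(g12[[1]], g12[[2]], K = config$K_thin)
      td$individuals[[nm]]$active <- th$union
    }
    # --- rephase ---
    n_flips <- 0L
    if (config$rephase) {
      for (nm in targets) {
        hp <- hunt_phase(td$individuals[[nm]], td, params)
        td$individuals[[nm]] <- hp$ind
        if (!is.null(hp$accepted)) {
          n_flips <- n_flips + nrow(hp$accepted)
          hp$accepted$sample <- nm
          hp$accepted$round <- round
          flip_log[[length(flip_log) + 1L]] <- hp$accepted
        }
      }
    }
    # --- EM ---
    st <- run_round(td, params, n_iter = config$em_iters_per_round)
    params <- st$params
    loglik_rounds <- c(loglik_rounds, st$loglik_trace)
    if (n_flips == 0L) break  # phase converged
  }
  st <- run_final_em(td, params, rel_tol = config$final_rel_tol,
                     max_iter = config$final_max_iter)
  params <- st$params
  loglik_rounds <- c(loglik_rounds, st$loglik_trace)
  # --- posteriors ---
  final <- e_step(td, params, want_X = TRUE)
  X <- final$X
  props <- ancestry_proportions(X)
  check_admixture_signal(props)
  # --- dating ---
  Xcurve <- if (identical(config$curve_source, "map")) map_track(X) else X
  curves <- compute_curves(Xcurve, grid, d_max = config$d_max,
                           d_min = config$d_min)
  dates <- estimate_dates(curves, mode = config$date_mode)
  boot <- NULL
  if (config$n_boot > 0 && length(grid$chroms) >= 2)
    boot <- bootstrap_dates(curves, n_boot = config$n_boot,
                            mode = config$date_mode)
  # --- drift summaries ---
  hs_re <- apply_flips_to_haps(hs, td)
  anc <- reconstruct_ancestral_genomes(hs_re, X, grid)
  fst <- fst_summary(hs_re, anc, td)
  er2 <- expected_r2_fit(X)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  structure(list(
    X = X, params = params, grid = grid, config = config,
    loglik_trace = loglik_rounds, rounds_run = rounds_run,
    flips = if (length(flip_log)) do.call(rbind, flip_log) else NULL,
    proportions = props, curves = curves, dates = dates, boot = boot,
    ancestral_genomes = anc, fst = fst, expected_r2 = er2,
    rephased = hs_re, td = td,
    provenance = list(config = unclass(config), seed = config$seed,
                      package_version = as.character(
                        utils::packageVersion("admixpaint")),
                      loglik = final$loglik, elapsed_sec = elapsed,
                      timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"))),
    class = "ancestry_fit")
}

# hard maximal-a-posteriori ancestry indicator tracks
map_track <- function(X) {
  lapply(X, function(ind) lapply(ind, function(hp) lapply(hp, function(M) {
    Z <- matrix(0, nrow(M), ncol(M))
    Z[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))] <- 1
    Z
  })))
}

#' Warn when an inferred ancestry has essentially no genome-wide mass
#'
#' With all segments assigned to one ancestry there is effectively no
#' admixture signal and the between-ancestry Fst estimator breaks down
#' (an empty group); the minor-ancestry proportion itself is then
#' meaningless. Called by [run_pipeline()] after the final E-step.
#'
#' @param props genome-wide ancestry proportions (sum to 1)
#' @param threshold mass below which an ancestry is flagged
#' @return `props`, invisibly
#' @export
check_admixture_signal <- function(props, threshold = 0.005) {
  low <- props < threshold
  if (any(low))
    warning("ancestry(ies) ", paste(which(low), collapse = ", "),
            " have genome-wide mass < ", 100 * threshold,
            "%: weak or no admixture signal; between-ancestry Fst will be ",
            "unreliable")
  invisible(props)
}

# genome-wide posterior ancestry proportions, pooled over targets
ancestry_proportions <- function(X) {
  tot <- NULL; n <- 0
  for (nm in names(X)) for (h in seq_along(X[[nm]]))
    for (ch in names(X[[nm]][[h]])) {
      cs <- colSums(X[[nm]][[h]][[ch]])
      tot <- if (is.null(tot)) cs else tot + cs
      n <- n + nrow(X[[nm]][[h]][[ch]])
    }
  tot / n
}

# per-individual diploid dosage lists (X1 + X2 per chromosome)
diploid_dosage <- function(X) {
  lapply(X, function(ind) {
    chs <- names(ind[[1]])
    setNames(lapply(chs, function(ch) ind[[1]][[ch]] + ind[[2]][[ch]]), chs)
  })
}

expected_r2_fit <- function(X) {
  X1 <- list(); X2 <- list()
  for (nm in names(X)) {
    X1[[nm]] <- do.call(rbind, X[[nm]][[1]])
    X2[[nm]] <- do.call(rbind, X[[nm]][[2]])
  }
  expected_r2_diploid(X1, X2)
}

# Fst between reconstructed ancestral genomes and each panel, and between
# the ancestral genomes themselves
fst_summary <- function(hs, anc, td) {
  A <- anc$A
  panels <- td$panels
  p_anc <- anc$count / pmax(anc$n, 1L)
  p_anc[anc$n == 0L] <- NA_real_
  anc_panel <- matrix(NA_real_, A, length(panels),
                      dimnames = list(paste0("ancestry", seq_len(A)),
                                      panels))
  for (p in seq_along(panels)) {
    rows <- td$donors[td$donor_panel == p]
    hp <- hs$haps[rows, , drop = FALSE]
    np <- colSums(!is.na(hp))
    pp <- colMeans(hp, na.rm = TRUE)
    for (a in seq_len(A))
      anc_panel[a, p] <- fst_weir_cockerham(p_anc[a, ], anc$n[a, ], pp, np)
  }
  prs <- utils::combn(A, 2)
  anc_anc <- tibble::tibble(
    a = prs[1, ], b = prs[2, ],
    fst = apply(prs, 2, function(pr)
      fst_weir_cockerham(p_anc[pr[1], ], anc$n[pr[1], ],
                         p_anc[pr[2], ], anc$n[pr[2], ])))
  rst_res <- rst(anc_panel)
  list(ancestry_panel = anc_panel, ancestry_pair = anc_anc, rst = rst_res)
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat("<ancestry_fit> A =", x$config$A, ",",
      length(x$X), "target(s),", length(x$grid$chroms), "chromosome(s)\n")
  cat("  proportions:", paste(sprintf("%.1f%%", 100 * x$proportions),
                              collapse = " / "), "\n")
  cat("  date:", signif(x$dates$date, 4), "generations",
      if (!is.null(x$boot)) paste0("(+-", signif(2 * x$boot$date_se, 3),
                                   " [2 SE])"), "\n")
  cat("  E[r2]:", signif(x$expected_r2, 4),
      " Rst:", signif(x$fst$rst$mean, 4), "\n")
  cat("  loglik:", signif(x$provenance$loglik, 8), "after",
      x$rounds_run, "round(s)\n")
  invisible(x)
}

#' Score an inference run against a simulation truth set
#'
#' @param fit an [run_pipeline()] result
#' @param truth a `truth_set` from [simulate_admixed()]
#' @return list: diploid `r2` (best label permutation), the permutation,
#'   haploid `r2_haploid`, and truth-aligned ancestry proportions
#' @export
score_vs_truth <- function(fit, truth) {
  Xd <- list(); Zd <- list(); Xh <- list(); Zh <- list()
  for (nm in names(fit$X)) {
    for (ch in names(fit$grid$chroms)) {
      h1 <- paste0(nm, "_1"); h2 <- paste0(nm, "_2")
      Z1 <- truth_matrix(truth, fit$grid, h1, ch)
      Z2 <- truth_matrix(truth, fit$grid, h2, ch)
      Xd[[paste(nm, ch)]] <- fit$X[[nm]][[1]][[ch]] + fit$X[[nm]][[2]][[ch]]
      Zd[[paste(nm, ch)]] <- Z1 + Z2
      Xh[[paste(nm, ch, 1)]] <- fit$X[[nm]][[1]][[ch]]
      Xh[[paste(nm, ch, 2)]] <- fit$X[[nm]][[2]][[ch]]
      Zh[[paste(nm, ch, 1)]] <- Z1
      Zh[[paste(nm, ch, 2)]] <- Z2
    }
  }
  dip <- r2_vs_truth(Xd, Zd)
  hap <- r2_vs_truth(Xh, Zh)
  list(r2 = dip$r2, perm = dip$perm, r2_haploid = hap$r2,
       proportions_aligned = fit$proportions[dip$perm])
}

#' Export posterior local ancestry as a tidy table
#'
#' @param fit an [run_pipeline()] result
#' @return tibble: sample, hap, chrom, gridpoint, cM, one column per ancestry
#' @export
posterior_table <- function(fit) {
  out <- list()
  for (nm in names(fit$X)) for (h in 1:2)
    for (ch in names(fit$grid$chroms)) {
      gch <- fit$grid$chroms[[ch]]
      M <- fit$X[[nm]][[h]][[ch]]
      colnames(M) <- paste0("X", seq_len(ncol(M)))
      out[[paste(nm, h, ch)]] <- dplyr::bind_cols(
        tibble::tibble(sample = nm, hap = h, chrom = ch,
                       gridpoint = seq_len(gch$n_grid),
                       cM = gch$gridpoint_cM),
        tibble::as_tibble(M))
    }
  dplyr::bind_rows(out)
}

#' Write the standard results bundle to a directory
#'
#' Posteriors as TSV, parameters and dates as JSON, coancestry curves as TSV,
#' the ancestry-informed rephased targets as a phased VCF, and a provenance
#' record (config, seed, versions, log-likelihood trace) as JSON.
#'
#' @param fit an [run_pipeline()] result
#' @param dir output directory (created if needed)
#' @export
write_results <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(posterior_table(fit), file.path(dir, "posteriors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(mu = fit$params$mu, rho = fit$params$rho, theta = fit$params$theta,
         Pi = fit$params$Pi, proportions = fit$proportions,
         loglik_trace = fit$loglik_trace),
    file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA)
  crv <- do.call(rbind, lapply(seq_len(nrow(fit$curves$pairs)), function(p)
    data.frame(pair = paste0(fit$curves$pairs[p, 1], "-",
                             fit$curves$pairs[p, 2]),
               d_cM = fit$curves$d_cM, ratio = pooled_ratio(fit$curves, p))))
  write.table(crv, file.path(dir, "curves.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(date = fit$dates$date, mode = fit$dates$mode,
         fits = fit$dates$fits,
         boot = if (!is.null(fit$boot))
           list(date_se = fit$boot$date_se, fits = fit$boot$fits)),
    file.path(dir, "dates.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(fst_ancestry_panel = fit$fst$ancestry_panel,
         fst_ancestry_pair = fit$fst$ancestry_pair,
         rst = fit$fst$rst, expected_r2 = fit$expected_r2),
    file.path(dir, "stats.json"), auto_unbox = TRUE, digits = NA)
  tg <- fit$rephased$samples$panel == "target"
  write_phased_vcf(
    haplotype_set(fit$rephased$haps[tg, , drop = FALSE], fit$rephased$sites,
                  fit$rephased$samples[tg, , drop = FALSE]),
    file.path(dir, "rephased_targets.vcf"))
  jsonlite::write_json(fit$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
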