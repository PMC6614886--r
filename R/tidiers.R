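#' Tidy an ancestry fit: per-pair admixture dates
#'
#' @param x an `ancestry_fit`
#' @param ... unused
#' @return tibble with one row per ancestry pair: fitted decay parameters
#'   and, when a bootstrap was run, SE and a +-2 SE interval
#' @method tidy ancestry_fit
#' @export
tidy.ancestry_fit <- function(x, ...) {
  if (!is.null(x$boot)) x$boot$fits else x$dates$fits
}

#' One-row summary of an ancestry fit
#'
#' @param x an `ancestry_fit`
#' @param ... unused
#' @method glance ancestry_fit
#' @export
glance.ancestry_fit <- function(x, ...) {
  tibble::tibble(
    A = x$config$A,
    n_targets = length(x$X),
    loglik = x$provenance$loglik,
    date = x$dates$date,
    date_se = if (!is.null(x$boot)) x$boot$date_se else NA_real_,
    expected_r2 = x$expected_r2,
    rst = x$fst$rst$mean,
    rho = x$params$rho,
    theta = x$params$theta,
    rounds = x$rounds_run,
    n_flips = if (is.null(x$flips)) 0L else nrow(x$flips))
}

#' @method tidy date_estimates
#' @export
tidy.date_estimates <- function(x, ...) x$fits

#' @method tidy date_bootstrap
#' @export
tidy.date_bootstrap <- function(x, ...) x$fits

#' Plot coancestry curves with their fitted exponentials
#'
#' Black: pooled across-targets curve; gray: per-target curves; green: the
#' fitted single-pulse exponential decay (its rate, in generations, labels
#' each panel).
#'
#' @param object an `ancestry_fit` or `coancestry_curves`
#' @param fits optional `date_estimates` (required for a bare curves object)
#' @param ... unused
#' @return a ggplot object, faceted by ancestry pair
#' @method autoplot ancestry_fit
#' @export
autoplot.ancestry_fit <- function(object, ...) {
  plot_coancestry_curves(object$curves, object$dates)
}

#' @rdname autoplot.ancestry_fit
#' @method autoplot coancestry_curves
#' @export
autoplot.coancestry_curves <- function(object, fits = NULL, ...) {
  plot_coancestry_curves(object, fits)
}

#' @rdname autoplot.ancestry_fit
#' @param cv a `coancestry_curves`
#' @export
plot_coancestry_curves <- function(cv, fits = NULL) {
  np <- nrow(cv$pairs)
  lab <- function(p) {
    l <- paste0(cv$pairs[p, 1], "-", cv$pairs[p, 2])
    if (!is.null(fits)) l <- paste0(l, " (", signif(fits$fits$lam[p], 3), ")")
    l
  }
  pooled <- dplyr::bind_rows(lapply(seq_len(np), function(p)
    tibble::tibble(pair = lab(p), d_cM = cv$d_cM,
                   ratio = pooled_ratio(cv, p), what = "pooled")))
  per_t <- dplyr::bind_rows(lapply(seq_len(np), function(p)
    dplyr::bind_rows(lapply(colnames(cv$sumX_t), function(tg)
      tibble::tibble(pair = lab(p), target = tg, d_cM = cv$d_cM,
                     ratio = per_target_ratio(cv, p, tg))))))
  g <- ggplot2::ggplot(pooled, ggplot2::aes(x = .data$d_cM,
                                            y = .data$ratio)) +
    ggplot2::geom_line(data = per_t,
                       ggplot2::aes(group = .data$target),
                       color = "grey70", linewidth = 0.3) +
    ggplot2::geom_line(color = "black") +
    ggplot2::facet_wrap(~pair, scales = "free_y") +
    ggplot2::labs(x = "genetic distance (cM)",
                  y = "relative pairwise ancestry probability")
  if (!is.null(fits)) {
    fitted <- dplyr::bind_rows(lapply(seq_len(np), function(p)
      tibble::tibble(pair = lab(p), d_cM = cv$d_cM,
                     ratio = fits$fits$delta[p] *
                       exp(-fits$fits$lam[p] * cv$d_cM / 100) +
                       fits$fits$tau[p])))
    g <- g + ggplot2::geom_line(data = fitted, color = "forestgreen")
  }
  g
}

#' Plot local-ancestry posteriors along the genome
#'
#' Stacked per-gridpoint ancestry probabilities for chosen targets.
#'
#' @param fit an `ancestry_fit`
#' @param samples targets to show (default: first)
#' @param chrom chromosome (default: first)
#' @export
plot_local_ancestry <- function(fit, samples = names(fit$X)[1],
                                chrom = names(fit$grid$chroms)[1]) {
  tb <- posterior_table(fit)
  tb <- tb[tb$sample %in% samples & tb$chrom == chrom, ]
  long <- tidyr_longer(tb)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cM, y = .data$prob,
                                     fill = .data$ancestry)) +
    ggplot2::geom_area() +
    ggplot2::facet_grid(sample + hap ~ .) +
    ggplot2::labs(x = "position (cM)", y = "ancestry probability")
}

# minimal wide->long for the posterior table (avoids a tidyr dependency)
tidyr_longer <- function(tb) {
  acols <- grep("^X\\d+$", names(tb), value = TRUE)
  dplyr::bind_rows(lapply(acols, function(a) {
    out <- tb[setdiff(names(tb), acols)]
    out$ancestry <- a
    out$prob <- tb[[a]]
    out
  }))
}

#' @importFrom rlang .data
NULL
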