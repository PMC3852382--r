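#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a stepwise selection
#'
#' One row per selected term with its entry P value; `effects = TRUE`
#' returns the per-family, per-environment allele effects instead.
#'
#' @param x A `gate_stepwise` object.
#' @param effects Return effect estimates rather than entry records.
#' @param ... Unused.
#' @export
tidy.gate_stepwise <- function(x, effects = FALSE, ...) {
  if (effects) x$effects else x$terms
}

#' @rdname tidy.gate_stepwise
#' @export
glance.gate_stepwise <- function(x, ...) {
  tibble::tibble(n_terms = nrow(x$terms), sle = x$sle,
                 min_p_entry = suppressWarnings(min(x$terms$p_entry)))
}

#' Tidy a threshold calibration
#'
#' One row per entry threshold with aggregate TP/FP/FN counts, positive
#' predictive value, sensitivity and FDR.
#'
#' @param x A `gate_calibration` object.
#' @param ... Unused.
#' @export
tidy.gate_calibration <- function(x, ...) x$by_sle

#' @rdname tidy.gate_calibration
#' @export
glance.gate_calibration <- function(x, ...) {
  best <- suppressWarnings(best_sle(x))
  row <- x$by_sle[x$by_sle$sle == as.numeric(best), ]
  tibble::tibble(n_sims = x$n_sims, best_sle = as.numeric(best),
                 ppv = row$ppv, sensitivity = row$sensitivity, fdr = row$fdr)
}

#' Tidy a variance-component fit
#' @param x A `gate_varcomp` tibble.
#' @param ... Unused.
#' @export
tidy.gate_varcomp <- function(x, ...) tibble::as_tibble(unclass(x))

#' Genome-scan profile plot
#'
#' Manhattan-style profile of the genotype-by-environment interaction scan:
#' -log10 of the q-value (or smoothed/raw P) along the map, faceted by
#' chromosome, with the FDR threshold drawn.
#'
#' @param object A `gate_scan` tibble carrying `chrom`/`pos_cM` columns.
#' @param y Which column to plot (`"q_value"`, `"smoothed_p"`, `"raw_p"`).
#' @param fdr_alpha Threshold line.
#' @param ... Unused.
#' @export
autoplot.gate_scan <- function(object, y = "q_value", fdr_alpha = 0.05, ...) {
  if (!all(c("chrom", "pos_cM") %in% names(object))) {
    stop("scan needs map columns; pass `map` to scan_interaction()", call. = FALSE)
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$pos_cM, y = -log10(.data[[y]]))) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(fdr_alpha), linetype = "dashed") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = bquote(-log[10] ~ .(y))) +
    ggplot2::theme_bw()
}

#' Calibration operating-characteristic plot
#'
#' Sensitivity, positive predictive value and FDR against the entry
#' threshold (log scale).
#'
#' @param object A `gate_calibration` object.
#' @param ... Unused.
#' @export
autoplot.gate_calibration <- function(object, ...) {
  d <- object$by_sle |>
    tidyr::pivot_longer(c("ppv", "sensitivity", "fdr"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sle, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "entry threshold (SLE)", y = NULL, colour = NULL) +
    ggplot2::theme_bw()
}

#' Per-environment allele-effect plot for one locus
#'
#' Point-and-CI display of both allele classes' deviations from the
#' environment mean across the four environments — the per-locus evidence
#' the gate classifier consumes.
#'
#' @param effects Tibble from [allele_effects()].
#' @param title Optional plot title.
#' @export
plot_allele_effects <- function(effects, title = NULL) {
  effects$environment <- factor(effects$environment, levels = stress_environments())
  ggplot2::ggplot(effects,
                  ggplot2::aes(x = .data$environment, y = .data$effect,
                               colour = .data$allele)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(y = "allele effect (deviation from environment mean)",
                  x = NULL, title = title) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
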