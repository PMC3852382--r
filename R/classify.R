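#' Pattern labels for cross-environment allele-effect architectures
#' @export
pattern_levels <- function() {
  c("uv_effect_lost", "drought_effect_lost", "combined_only_dose_dependent",
    "additive_opposite_xor", "additive_or", "synergistic",
    "independent_consistent", "complex")
}

#' Classify one locus's cross-environment effect pattern
#'
#' Assigns a locus to one architecture category from its per-environment
#' allele effects and significance flags (never from raw magnitudes alone).
#' "Significant" means the 95% CI excludes zero. Decision rules, applied in
#' order:
#' \enumerate{
#'   \item significant in exactly one single stress and not in combined
#'     stress: `uv_effect_lost` / `drought_effect_lost` (the signature of an
#'     attenuating modifier);
#'   \item significant only in combined stress:
#'     `combined_only_dose_dependent` (AND-gate-like novel locus);
#'   \item significant in both single stresses with opposite signs, not in
#'     combined: `additive_opposite_xor` (effects cancel);
#'   \item significant in both single stresses with the same sign, combined
#'     significant and its CI containing the sum of the single-stress
#'     estimates: `additive_or`;
#'   \item significant in at least one single stress and in combined, with
#'     the combined CI excluding the summed single estimates and the
#'     combined magnitude exceeding that sum: `synergistic`;
#'   \item significant in one single stress and in combined with consistent
#'     sign, the combined CI containing that single-stress estimate:
#'     `independent_consistent`;
#'   \item anything else: `complex`.
#' }
#' A significant control-environment effect is an error: control-responsive
#' loci must be excluded upstream, since the gate categories describe
#' stress-specific signaling.
#'
#' @param effects Tibble with one row per environment: `environment`,
#'   `effect`, `ci_lo`, `ci_hi`, `significant`. Must contain `drought`,
#'   `UV` and `combined`; `control`, if present, must be non-significant.
#' @param tol Numeric tolerance for CI containment in degenerate (noiseless)
#'   fits.
#' @return One-row tibble: `observed_label` plus the per-environment
#'   evidence spread wide.
#' @export
classify_locus <- function(effects, tol = 1e-8) {
  need <- c("drought", "UV", "combined")
  if (!all(need %in% effects$environment)) {
    stop("effects must cover environments: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  row_of <- function(ev) effects[effects$environment == ev, ][1, ]
  if ("control" %in% effects$environment && isTRUE(row_of("control")$significant)) {
    stop("control-significant locus: exclude control-responsive loci upstream",
         call. = FALSE)
  }
  u <- row_of("UV"); d <- row_of("drought"); cb <- row_of("combined")
  in_ci <- function(x, row) x >= row$ci_lo - tol & x <= row$ci_hi + tol
  sum_single <- u$effect + d$effect

  label <-
    if (xor(u$significant, d$significant) && !cb$significant) {
      if (u$significant) "uv_effect_lost" else "drought_effect_lost"
    } else if (cb$significant && !u$significant && !d$significant) {
      "combined_only_dose_dependent"
    } else if (u$significant && d$significant && !cb$significant &&
               sign(u$effect) != sign(d$effect)) {
      "additive_opposite_xor"
    } else if (u$significant && d$significant && cb$significant &&
               sign(u$effect) == sign(d$effect) && in_ci(sum_single, cb)) {
      "additive_or"
    } else if ((u$significant || d$significant) && cb$significant &&
               !in_ci(sum_single, cb) && abs(cb$effect) > abs(sum_single) + tol) {
      "synergistic"
    } else if (xor(u$significant, d$significant) && cb$significant &&
               {
                 single <- if (u$significant) u else d
                 sign(cb$effect) == sign(single$effect) && in_ci(single$effect, cb)
               }) {
      "independent_consistent"
    } else {
      "complex"
    }

  evid <- effects |>
    dplyr::select("environment", "effect", "significant") |>
    tidyr::pivot_wider(names_from = "environment",
                       values_from = c("effect", "significant"))
  dplyr::bind_cols(tibble::tibble(observed_label = label), evid)
}

#' Theory-expected detection pattern for each gate
#'
#' The pattern a locus generated by each signal-combination gate should show
#' in a well-powered scan: which environments carry a significant allele
#' effect, and the resulting [classify_locus()] label. The `independent`
#' entry describes the single-input case (an allele acting in one stress
#' pathway); an independent locus with inputs in both stresses is
#' indistinguishable from an OR-gate integrator at the level of detection
#' patterns.
#'
#' @param gate One of [gate_levels()].
#' @return One-row tibble: `gate`, `expected_label`, and logical
#'   `detect_drought`, `detect_UV`, `detect_combined`.
#' @export
expected_pattern <- function(gate) {
  patterns <- tibble::tribble(
    ~gate,                 ~expected_label,                ~detect_drought, ~detect_UV, ~detect_combined,
    "independent",         "independent_consistent",       FALSE,           TRUE,       TRUE,
    "AND_gate",            "combined_only_dose_dependent", FALSE,           FALSE,      TRUE,
    "OR_gate",             "additive_or",                  TRUE,            TRUE,       TRUE,
    "XOR",                 "additive_opposite_xor",        TRUE,            TRUE,       FALSE,
    "attenuator_UV",       "uv_effect_lost",               FALSE,           TRUE,       FALSE,
    "attenuator_drought",  "drought_effect_lost",          TRUE,            FALSE,      FALSE
  )
  out <- patterns[patterns$gate == gate, ]
  if (!nrow(out)) stop("unknown gate label: ", gate, call. = FALSE)
  out
}

#' Classify every locus in a scan result
#'
#' Applies [classify_locus()] to each requested marker of a `gate_scan`
#' produced with `effects = TRUE`. Markers with a significant control
#' effect are dropped with a message (control-responsive loci are outside
#' the stress-gate taxonomy).
#'
#' @param scan A `gate_scan` tibble with wide per-environment effect columns.
#' @param markers Markers to classify (default: all with effects available).
#' @return Tibble with `marker`, `observed_label` and evidence columns.
#' @export
classify_scan <- function(scan, markers = NULL) {
  if (!"effect_UV" %in% names(scan)) {
    stop("scan lacks per-environment effects; rerun scan_interaction(effects = TRUE)",
         call. = FALSE)
  }
  if (is.null(markers)) markers <- scan$marker[!is.na(scan$effect_UV)]
  scan <- scan[match(markers, scan$marker), ]
  if ("significant_control" %in% names(scan)) {
    drop <- !is.na(scan$significant_control) & scan$significant_control
    if (any(drop)) {
      message(sum(drop), " control-significant locus/loci excluded from classification")
      scan <- scan[!drop, ]
    }
  }
  purrr::map_dfr(seq_len(nrow(scan)), function(i) {
    long <- tidyr::pivot_longer(
      scan[i, grep("^(effect|se|ci_lo|ci_hi|significant)_", names(scan))],
      dplyr::everything(),
      names_to = c(".value", "environment"),
      names_pattern = "^(effect|se|ci_lo|ci_hi|significant)_(.*)$"
    )
    dplyr::bind_cols(tibble::tibble(marker = scan$marker[i]),
                     classify_locus(long))
  })
}

#' Summarise observed vs theory-expected architecture patterns
#'
#' Tabulates observed pattern labels and, when the generating truth is
#' known, crosses them with the labels each gate predicts, yielding a
#' confusion matrix and per-gate recovery rates.
#'
#' @param calls Tibble from [classify_scan()] / [classify_locus()] with a
#'   `marker` and `observed_label` column.
#' @param truth Optional [architecture()] object (markers must match calls).
#' @return A list of class `gate_fit_report`: `counts` (label tallies),
#'   and with truth, `confusion` (expected x observed contingency tibble)
#'   and `recovery` (per gate: n, matched, recovery rate).
#' @export
architecture_fit_report <- function(calls, truth = NULL) {
  if (!nrow(calls)) stop("no calls to summarise", call. = FALSE)
  counts <- calls |>
    dplyr::count(.data$observed_label, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  out <- list(counts = counts)
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "gate_architecture"))
    joined <- calls |>
      dplyr::inner_join(truth$qtl[, c("marker", "gate")], by = "marker") |>
      dplyr::mutate(expected_label = purrr::map_chr(.data$gate,
                                                    ~ expected_pattern(.x)$expected_label))
    out$confusion <- joined |>
      dplyr::count(.data$expected_label, .data$observed_label, name = "n")
    out$recovery <- joined |>
      dplyr::group_by(.data$gate) |>
      dplyr::summarise(n = dplyr::n(),
                       matched = sum(.data$observed_label == .data$expected_label),
                       recovery = .data$matched / .data$n, .groups = "drop")
  }
  class(out) <- "gate_fit_report"
  out
}

#' @export
print.gate_fit_report <- function(x, ...) {
  cat("Architecture pattern calls\n")
  print(x$counts)
  if (!is.null(x$confusion)) {
    cat("\nExpected vs observed (truth known):\n")
    print(tidyr::pivot_wider(x$confusion, names_from = "observed_label",
                             values_from = "n", values_fill = 0))
    cat("\nPer-gate recovery:\n")
    print(x$recovery)
  }
  invisible(x)
}
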