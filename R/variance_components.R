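#' Line percentage of phenotypic variance
#'
#' The share of phenotypic variance attributable to line (genotype)
#' differences, `100 * v_line / (v_line + v_error)`. Values of 1 or more are
#' reported to one decimal place; values below 1 to two significant digits
#' (the printing convention of broad-sense heritability tables where small
#' shares would otherwise round to one digit).
#'
#' @param v_line,v_error Nonnegative variance components (not both zero).
#' @param round Round for reporting (default) or return full precision.
#' @return The line percentage, or `NA` when `v_line` is zero (the
#'   conventionally blank table cell).
#' @examples
#' line_pct(0.12094, 0.75083) # 13.9
#' @export
line_pct <- function(v_line, v_error, round = TRUE) {
  if (v_line < 0 || v_error < 0) stop("variance components must be >= 0", call. = FALSE)
  if (v_line == 0 && v_error == 0) {
    stop("line percentage undefined when both components are zero", call. = FALSE)
  }
  if (v_line == 0) return(NA_real_)
  pct <- 100 * v_line / (v_line + v_error)
  if (!round) return(pct)
  if (pct >= 1) round(pct, 1) else signif(pct, 2)
}

#' Estimate line and error variance components
#'
#' One-way random-effects decomposition `value_ij = mu + line_i + e_ij` for a
#' single trait in a single environment, fitted by REML (replicate blocks are
#' folded into the error term). Component estimates are truncated at zero; a
#' method-of-moments (expected mean squares) estimator using the
#' unbalanced-design coefficient for replicates per line is available as
#' `method = "moments"` and as an automatic fallback if the REML fit fails.
#'
#' @param pheno Long phenotype tibble (`line_id`, `environment`, `trait`,
#'   `value`).
#' @param trait Trait to analyse.
#' @param environment One of [stress_environments()].
#' @param method `"reml"` (default) or `"moments"`.
#' @return A one-row tibble of class `gate_varcomp`: `trait`, `environment`,
#'   `v_line`, `v_error`, `line_pct` (`NA` when `v_line` is 0), `n_lines`,
#'   `n_obs`, `method`.
#' @export
estimate_components <- function(pheno, trait, environment, method = c("reml", "moments")) {
  method <- match.arg(method)
  d <- pheno |>
    dplyr::filter(.data$trait == !!trait, .data$environment == !!environment,
                  !is.na(.data$value))
  if (nrow(d) == 0) stop("no data for trait/environment", call. = FALSE)
  reps <- table(d$line_id)
  if (length(reps) < 2 || max(reps) < 2) {
    stop("need >= 2 lines and replication to separate line from error variance",
         call. = FALSE)
  }
  comp <- if (method == "reml") {
    fit <- tryCatch(
      lme4::lmer(value ~ 1 + (1 | line_id), data = d, REML = TRUE),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      .moments_components(d)
    } else {
      vc <- as.data.frame(lme4::VarCorr(fit))
      c(v_line = max(0, vc$vcov[vc$grp == "line_id"]),
        v_error = max(0, vc$vcov[vc$grp == "Residual"]))
    }
  } else {
    .moments_components(d)
  }
  out <- tibble::tibble(
    trait = trait, environment = environment,
    v_line = unname(comp["v_line"]), v_error = unname(comp["v_error"]),
    line_pct = if (comp["v_line"] > 0 || comp["v_error"] > 0) {
      line_pct(comp["v_line"], comp["v_error"])
    } else NA_real_,
    n_lines = length(reps), n_obs = nrow(d), method = method
  )
  class(out) <- c("gate_varcomp", class(out))
  out
}

# expected-mean-squares estimator; n0 is the unbalanced-design coefficient
.moments_components <- function(d) {
  fit <- stats::aov(value ~ line_id, data = d)
  tab <- summary(fit)[[1]]
  ms_line <- tab["line_id", "Mean Sq"]
  ms_err <- tab["Residuals", "Mean Sq"]
  n_i <- as.numeric(table(d$line_id))
  n0 <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (length(n_i) - 1)
  c(v_line = max(0, (ms_line - ms_err) / n0), v_error = max(0, ms_err))
}

#' Variance-component table across environments and traits
#'
#' Convenience wrapper producing the per-environment, per-trait table of
#' line and error components and line percentages.
#'
#' @inheritParams estimate_components
#' @param traits,environments Subsets to tabulate (defaults: all present).
#' @return A tibble with one row per (trait, environment).
#' @export
variance_component_table <- function(pheno, traits = unique(pheno$trait),
                                     environments = intersect(stress_environments(),
                                                              unique(pheno$environment)),
                                     method = "reml") {
  tidyr::expand_grid(trait = traits, environment = environments) |>
    purrr::pmap_dfr(function(trait, environment) {
      estimate_components(pheno, trait, environment, method = method)
    })
}
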