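#' Per-marker genotype-by-environment interaction scan
#'
#' For each marker, fits the fixed-effects model
#' `value ~ block + environment + marker + marker:environment` (allele coded
#' +1/-1, blocks as factors, sum-to-zero environment contrasts) and reports
#' the F-test P value of the marker-by-environment interaction — the
#' stress-specificity signal. Because the interaction is the highest-order
#' term, its marginal (type III) sum of squares equals the model-comparison
#' sum of squares used here. Optionally attaches per-environment allele
#' effects from [allele_effects()]. Markers that are monomorphic or have
#' fewer than 2 lines in either allele class are reported with missing P,
#' not dropped.
#'
#' @param geno Genotype tibble (`line_id`, `family`, marker columns).
#' @param pheno Long phenotype tibble.
#' @param trait Trait to scan.
#' @param map Optional map tibble; adds `chrom`, `pos_cM`, `bin` columns.
#' @param effects Attach per-environment allele-A effect columns (default
#'   TRUE; set FALSE for speed in large null simulations).
#' @param main_effect Also report the marker main-effect P value (marker
#'   term in the no-interaction model), used to distinguish purely additive
#'   loci from stress-specific ones.
#'
#' @return A tibble of class `gate_scan`, one row per marker: `marker`,
#'   `raw_p` (interaction), optionally `main_p`, `smoothed_p` and `q_value`
#'   placeholders filled by [smooth_pvalues()]/[bh_fdr()], and wide
#'   effect/se/CI/significance columns per environment when
#'   `effects = TRUE`.
#' @export
scan_interaction <- function(geno, pheno, trait, map = NULL, effects = TRUE,
                             main_effect = FALSE) {
  if (!trait %in% pheno$trait) stop("trait not present: ", trait, call. = FALSE)
  d0 <- pheno |>
    dplyr::filter(.data$trait == !!trait, !is.na(.data$value))
  if (dplyr::n_distinct(d0$environment) < 2) {
    stop("need >= 2 environments for an interaction scan", call. = FALSE)
  }
  gm <- geno_matrix(geno)
  markers <- colnames(gm)
  row_of <- match(d0$line_id, rownames(gm))
  env_f <- factor(d0$environment, levels = intersect(stress_environments(),
                                                     unique(d0$environment)))
  blk_f <- factor(d0$block)
  y <- d0$value

  res <- purrr::map_dfr(markers, function(mk) {
    g <- gm[row_of, mk]
    ok <- !is.na(g)
    tab <- table(g[ok][!duplicated(d0$line_id[ok])])
    if (length(tab) < 2 || min(tab) < 2) {
      return(tibble::tibble(marker = mk, raw_p = NA_real_, main_p = NA_real_,
                            monomorphic = TRUE))
    }
    dd <- data.frame(y = y[ok], g = g[ok], env = droplevels(env_f[ok]),
                     blk = droplevels(blk_f[ok]))
    old <- options(contrasts = c("contr.sum", "contr.poly")); on.exit(options(old))
    f0 <- stats::lm(y ~ blk + env + g, data = dd)
    f1 <- stats::lm(y ~ blk + env + g + env:g, data = dd)
    a <- stats::anova(f0, f1)
    main_p <- if (main_effect) {
      fb <- stats::lm(y ~ blk + env, data = dd)
      stats::anova(fb, f0)[2, "Pr(>F)"]
    } else NA_real_
    tibble::tibble(marker = mk, raw_p = a[2, "Pr(>F)"], main_p = main_p,
                   monomorphic = FALSE)
  })
  if (!main_effect) res$main_p <- NULL
  res$smoothed_p <- NA_real_
  res$q_value <- NA_real_

  if (!is.null(map)) {
    res <- map |>
      dplyr::select("marker", "chrom", "pos_cM", "bin") |>
      dplyr::inner_join(res, by = "marker")
  }
  if (effects) {
    eff <- purrr::map_dfr(res$marker[!res$monomorphic], function(mk) {
      allele_effects(geno, pheno, trait, mk) |>
        dplyr::filter(.data$allele == "A") |>
        dplyr::mutate(marker = mk)
    })
    if (nrow(eff)) {
      wide <- eff |>
        dplyr::select("marker", "environment", "effect", "se",
                      "ci_lo", "ci_hi", "significant") |>
        tidyr::pivot_wider(names_from = "environment",
                           values_from = c("effect", "se", "ci_lo", "ci_hi",
                                           "significant"))
      res <- dplyr::left_join(res, wide, by = "marker")
    }
  }
  class(res) <- c("gate_scan", class(res))
  res
}

#' Per-environment allele effects at one marker
#'
#' Within each environment, fits `value ~ block + allele` (allele coded +1
#' for A, -1 for B) and reports each allele class's deviation from the
#' environment population mean — the allele effect in the
#' relative-to-population-mean convention, with negative estimates meaning
#' the allele confers less growth than average. SEs and 95% confidence
#' intervals come from standard linear-model theory; `significant` means the
#' CI excludes zero. In a balanced design the two allele effects in an
#' environment sum to zero exactly.
#'
#' @inheritParams scan_interaction
#' @param marker Marker name.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble: `environment`, `allele`, `effect`, `se`, `ci_lo`,
#'   `ci_hi`, `significant`, `n_lines`.
#' @export
allele_effects <- function(geno, pheno, trait, marker, conf_level = 0.95) {
  if (!marker %in% names(geno)) stop("unknown marker: ", marker, call. = FALSE)
  gm <- geno_matrix(geno)
  d <- pheno |>
    dplyr::filter(.data$trait == !!trait, !is.na(.data$value)) |>
    dplyr::mutate(g = gm[match(.data$line_id, rownames(gm)), marker]) |>
    dplyr::filter(!is.na(.data$g))
  if (length(unique(d$g)) < 2) stop("marker is monomorphic: ", marker, call. = FALSE)
  alpha <- 1 - conf_level
  purrr::map_dfr(unique(d$environment), function(ev) {
    de <- d[d$environment == ev, ]
    fit <- if (dplyr::n_distinct(de$block) > 1) {
      stats::lm(value ~ factor(block) + g, data = de)
    } else {
      stats::lm(value ~ g, data = de)
    }
    sm <- summary(fit)$coefficients
    est <- sm["g", "Estimate"]; se <- sm["g", "Std. Error"]
    tcrit <- stats::qt(1 - alpha / 2, df = fit$df.residual)
    purrr::map_dfr(c(A = 1, B = -1), function(sgn) {
      tibble::tibble(effect = sgn * est, se = se,
                     ci_lo = sgn * est - tcrit * se,
                     ci_hi = sgn * est + tcrit * se)
    }, .id = "allele") |>
      dplyr::mutate(environment = ev,
                    significant = .data$ci_lo > 0 | .data$ci_hi < 0,
                    n_lines = dplyr::n_distinct(de$line_id), .before = 1) |>
      dplyr::select("environment", "allele", "effect", "se", "ci_lo", "ci_hi",
                    "significant", "n_lines")
  })
}

#' Flag artificial coinheritance between significant markers
#'
#' Pairs of significant markers on *different* chromosomes whose genotype
#' vectors are strongly correlated are suspicious: a shared low P value can
#' reflect duplicated or misplaced marker data rather than two true loci.
#'
#' @inheritParams scan_interaction
#' @param map Map tibble giving each marker's chromosome.
#' @param significant_markers Character vector of markers to examine.
#' @param threshold Absolute correlation above which a pair is flagged.
#' @return Tibble `marker1`, `marker2`, `r` (possibly empty).
#' @export
coinheritance_check <- function(geno, map, significant_markers, threshold = 0.5) {
  sig <- intersect(significant_markers, names(geno))
  if (length(sig) < 2) {
    return(tibble::tibble(marker1 = character(), marker2 = character(),
                          r = numeric()))
  }
  gm <- geno_matrix(geno)[, sig, drop = FALSE]
  chrom <- map$chrom[match(sig, map$marker)]
  cc <- suppressWarnings(stats::cor(gm, use = "pairwise.complete.obs"))
  pairs <- which(upper.tri(cc), arr.ind = TRUE)
  out <- tibble::tibble(
    marker1 = sig[pairs[, 1]], marker2 = sig[pairs[, 2]],
    chrom1 = chrom[pairs[, 1]], chrom2 = chrom[pairs[, 2]],
    r = cc[pairs]
  )
  out |>
    dplyr::filter(.data$chrom1 != .data$chrom2, !is.na(.data$r),
                  abs(.data$r) > threshold) |>
    dplyr::select("marker1", "marker2", "r")
}
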