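#' Environment levels for the factorial stress design
#'
#' The closed vocabulary of environments: an unstressed control, each single
#' stress, and both stresses applied together.
#' @export
stress_environments <- function() c("control", "drought", "UV", "combined")

#' Gate labels understood by the simulator
#' @export
gate_levels <- function() {
  c("independent", "AND_gate", "OR_gate", "XOR", "attenuator_UV", "attenuator_drought")
}

#' Describe a true genetic architecture
#'
#' Bundles the ground-truth QTL list with the trait mean and noise structure
#' used by [simulate_phenotypes()]. Effects are *half-differences*: the
#' deviation of one allele class (A, the common parent) from the population
#' mean, so the A-vs-B class mean difference is twice the effect. This
#' matches the convention of reporting allele effects relative to the
#' population mean; conventions differ by a factor of 2 across software, so
#' the choice is stated here prominently.
#'
#' @param qtl Tibble/data frame with columns `marker`, `gate` (one of
#'   [gate_levels()]), `effect_uv`, `effect_drought` and optionally
#'   `effect_combined` (trait units; `NA` means derived from the gate rule).
#' @param trait_mean Baseline trait value.
#' @param block_sd SD of the per-(block, environment) random effect.
#' @param residual_sd SD of the residual noise.
#'
#' @return An object of class `gate_architecture`.
#' @examples
#' architecture(data.frame(marker = "m01_001", gate = "attenuator_UV",
#'                         effect_uv = 0.5, effect_drought = 0))
#' @export
architecture <- function(qtl, trait_mean = 0, block_sd = 0, residual_sd = 1) {
  qtl <- tibble::as_tibble(qtl)
  if (!"effect_combined" %in% names(qtl)) qtl$effect_combined <- NA_real_
  bad <- setdiff(qtl$gate, gate_levels())
  if (length(bad)) {
    stop("unknown gate label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (block_sd < 0 || residual_sd < 0) stop("SDs must be >= 0", call. = FALSE)
  structure(
    list(qtl = qtl, trait_mean = trait_mean,
         block_sd = block_sd, residual_sd = residual_sd),
    class = "gate_architecture"
  )
}

#' Per-environment effect implied by each QTL's gate
#'
#' Expands the architecture's QTL list into one row per (marker,
#' environment) holding the effect a carrier of allele A adds in that
#' environment. Gate rules:
#' \describe{
#'   \item{independent}{separate pathways: `effect_uv` under UV,
#'     `effect_drought` under drought, their sum under combined stress.}
#'   \item{AND_gate}{a sensor activated only by both stresses together:
#'     nonzero only under combined stress (`effect_combined`, defaulting to
#'     `effect_uv + effect_drought` when `NA`).}
#'   \item{OR_gate}{a shared integrator: single-stress effects as given,
#'     combined effect their sum.}
#'   \item{XOR}{opposite single-stress effects (`effect_drought` is forced
#'     to `-effect_uv` when `NA`) cancelling under combined stress.}
#'   \item{attenuator_UV}{a modifier activated by drought blocks the UV
#'     pathway: `effect_uv` under UV only, zero under drought and combined.}
#'   \item{attenuator_drought}{the symmetric case.}
#' }
#' All gates give a zero effect in the control environment.
#'
#' @param arch A [architecture()] object.
#' @return Tibble with columns `marker`, `gate`, `environment`, `effect`.
#' @export
gate_effect_table <- function(arch) {
  stopifnot(inherits(arch, "gate_architecture"))
  one <- function(marker, gate, eu, ed, ec) {
    e <- switch(
      gate,
      independent = c(0, ed, eu, eu + ed),
      AND_gate = c(0, 0, 0, if (is.na(ec)) eu + ed else ec),
      OR_gate = c(0, ed, eu, eu + ed),
      XOR = {
        if (is.na(ed)) ed <- -eu
        if (abs(eu + ed) > 1e-12) {
          stop("XOR gate requires effect_drought = -effect_uv", call. = FALSE)
        }
        c(0, ed, eu, 0)
      },
      attenuator_UV = c(0, 0, eu, 0),
      attenuator_drought = c(0, ed, 0, 0),
      stop("unknown gate label: ", gate, call. = FALSE)
    )
    tibble::tibble(marker = marker, gate = gate,
                   environment = stress_environments(), effect = e)
  }
  purrr::pmap_dfr(
    list(arch$qtl$marker, arch$qtl$gate, arch$qtl$effect_uv,
         arch$qtl$effect_drought, arch$qtl$effect_combined),
    function(m, g, eu, ed, ec) one(m, g, eu, ed, ec)
  )
}

#' Simulate phenotypes from genotypes and a gate architecture
#'
#' Generates the long-format phenotype table of the factorial greenhouse
#' design: every line observed in all four environments in `n_blocks`
#' replicate blocks. The generating model is
#' `value = trait_mean + block(block, env) + sum_q s(line, q) * e(q, env) + noise`
#' with `s = +1` for allele A and `-1` for allele B, and `e` from
#' [gate_effect_table()]. Block effects are drawn once per (block,
#' environment), emulating month-replicates crossed with treatments. Lines
#' with a missing genotype at any architecture marker get missing phenotype
#' values (never silently imputed).
#'
#' @param geno Genotype tibble from the simulators or [read_genotypes()].
#' @param arch A [architecture()] object; all its markers must be genotyped.
#' @param n_blocks Replicate blocks per environment (>= 1).
#' @param seed Integer seed; output is bit-identical given the same inputs.
#' @param trait Trait name recorded in the output.
#'
#' @return A tibble with columns `line_id`, `family`, `environment`,
#'   `block`, `trait`, `value`.
#' @examples
#' map <- make_map(1, 3, 100)
#' g <- simulate_ril_genotypes(map, 20, seed = 1)
#' a <- architecture(data.frame(marker = "m01_002", gate = "independent",
#'                              effect_uv = 1, effect_drought = 0.5))
#' simulate_phenotypes(g, a, n_blocks = 2, seed = 1)
#' @export
simulate_phenotypes <- function(geno, arch, n_blocks = 4L, seed = 1L,
                                trait = "trait") {
  stopifnot(inherits(arch, "gate_architecture"))
  if (n_blocks < 1) stop("`n_blocks` must be >= 1", call. = FALSE)
  markers <- arch$qtl$marker
  absent <- setdiff(markers, names(geno))
  if (length(absent)) {
    stop("architecture marker(s) not in genotype table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  envs <- stress_environments()
  if (nrow(arch$qtl)) {
    eff <- gate_effect_table(arch)
    # lines x environments genetic value
    s <- geno_matrix(geno)[, markers, drop = FALSE]
    e_mat <- eff |>
      tidyr::pivot_wider(id_cols = "marker", names_from = "environment",
                         values_from = "effect") |>
      (\(d) as.matrix(d[match(markers, d$marker), envs]))()
    gvalue <- s %*% e_mat  # NA propagates for missing genotype calls
  } else {
    gvalue <- matrix(0, nrow(geno), length(envs))  # pure-noise null
  }

  grid <- tidyr::expand_grid(
    line_id = geno$line_id,
    environment = envs,
    block = seq_len(n_blocks)
  )
  block_eff <- tidyr::expand_grid(environment = envs, block = seq_len(n_blocks))
  block_eff$b <- rnorm(nrow(block_eff), 0, arch$block_sd)

  grid |>
    dplyr::left_join(block_eff, by = c("environment", "block")) |>
    dplyr::mutate(
      family = geno$family[match(.data$line_id, geno$line_id)],
      g = gvalue[cbind(match(.data$line_id, geno$line_id),
                       match(.data$environment, envs))],
      trait = trait,
      value = arch$trait_mean + .data$b + .data$g +
        rnorm(dplyr::n(), 0, arch$residual_sd)
    ) |>
    dplyr::select("line_id", "family", "environment", "block", "trait", "value")
}

#' Effect sizes hitting per-QTL variance targets
#'
#' Converts per-QTL variance-explained targets into half-difference allele
#' effects, for allele frequency 1/2 (so each QTL contributes genetic
#' variance `a^2`). Two conventions are supported:
#' \describe{
#'   \item{`joint = TRUE`}{`a_i^2 / (sum_j a_j^2 + residual_sd^2) =
#'     target_i`; requires `sum(targets) < 1` and has the closed form
#'     `a_i = residual_sd * sqrt(t_i / (1 - sum(t)))`.}
#'   \item{`joint = FALSE`}{each QTL judged against the residual alone,
#'     `a_i^2 / (a_i^2 + residual_sd^2) = target_i`; feasible for any
#'     targets below 1 individually. This is the convention under which
#'     a five-QTL series from 50% down to 8% is well defined, and the one
#'     used by [calibrate_sle()].}
#' }
#'
#' @param target_r2 Vector of per-QTL variance fractions in `[0, 1)`.
#' @param residual_sd Residual SD of the generating model.
#' @param joint Which convention (see above).
#' @return Numeric vector of half-difference effects, same length as
#'   `target_r2`.
#' @examples
#' effects_for_variance_target(0.5, 1) # == 1
#' @export
effects_for_variance_target <- function(target_r2, residual_sd = 1, joint = TRUE) {
  if (any(target_r2 < 0) || any(target_r2 >= 1)) {
    stop("targets must be in [0, 1)", call. = FALSE)
  }
  if (residual_sd <= 0) stop("`residual_sd` must be > 0", call. = FALSE)
  if (joint) {
    if (sum(target_r2) >= 1) {
      stop("infeasible targets: sum(target_r2) must be < 1 when joint = TRUE",
           call. = FALSE)
    }
    residual_sd * sqrt(target_r2 / (1 - sum(target_r2)))
  } else {
    residual_sd * sqrt(target_r2 / (1 - target_r2))
  }
}
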