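#' Run the full simulate-scan-smooth-classify pipeline
#'
#' Chains the pipeline stages with a single root seed: (optionally) simulate
#' a mapping population and gate-structured phenotypes, scan every marker
#' for genotype-by-environment interaction, smooth and FDR-adjust the P
#' values, call QTL intervals, and classify each significant locus's
#' cross-environment pattern. Every stage's randomness derives
#' deterministically from `seed`; the same configuration yields
#' byte-identical results.
#'
#' @param config A named list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{design}{`"ibm"` (biparental, with intermating) or `"nam"`.}
#'     \item{map}{list of `n_chromosomes`, `markers_per_chromosome`,
#'       `chrom_length` (or `map_path` to read one).}
#'     \item{n_lines, n_intermating_generations / n_families,
#'       lines_per_family}{population sizes.}
#'     \item{qtl}{data frame for [architecture()]; plus `trait_mean`,
#'       `block_sd`, `residual_sd`.}
#'     \item{n_blocks}{replicate blocks.}
#'     \item{window, method, fdr_alpha}{smoothing/FDR settings.}
#'     \item{seed}{root seed.}
#'     \item{geno_path, pheno_path}{read instead of simulating.}
#'     \item{out_dir}{if set, stage outputs are written there as TSV.}
#'   }
#' @return A list of class `gate_pipeline`: `map`, `geno`, `pheno`, `truth`,
#'   `scan`, `qtl`, `calls`, `report`, `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  known <- c("design", "map", "map_path", "n_lines", "n_intermating_generations",
             "n_families", "lines_per_family", "qtl", "trait_mean", "block_sd",
             "residual_sd", "n_blocks", "window", "method", "fdr_alpha",
             "seed", "geno_path", "pheno_path", "out_dir", "trait")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(
    list(design = "ibm", n_lines = 92, n_intermating_generations = 4,
         n_families = 5, lines_per_family = 50, n_blocks = 4,
         trait_mean = 10, block_sd = 0.25, residual_sd = 1,
         window = 3, method = "simes", fdr_alpha = 0.05, seed = 1,
         trait = "trait"),
    config
  )
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 4)

  map <- if (!is.null(cfg$map_path)) read_map(cfg$map_path) else {
    do.call(make_map, c(cfg$map, list(seed = seeds[1])))
  }
  truth <- NULL
  if (!is.null(cfg$geno_path)) {
    geno <- read_genotypes(cfg$geno_path)
  } else {
    geno <- if (cfg$design == "nam") {
      simulate_nam_genotypes(map, cfg$n_families, cfg$lines_per_family,
                             seed = seeds[2])
    } else {
      simulate_ril_genotypes(map, cfg$n_lines, cfg$n_intermating_generations,
                             seed = seeds[2])
    }
  }
  if (!is.null(cfg$pheno_path)) {
    pheno <- read_phenotypes(cfg$pheno_path)
  } else {
    if (is.null(cfg$qtl)) stop("config needs `qtl` or `pheno_path`", call. = FALSE)
    truth <- architecture(tibble::as_tibble(cfg$qtl), trait_mean = cfg$trait_mean,
                          block_sd = cfg$block_sd, residual_sd = cfg$residual_sd)
    pheno <- simulate_phenotypes(geno, truth, n_blocks = cfg$n_blocks,
                                 seed = seeds[3], trait = cfg$trait)
  }

  scan <- scan_interaction(geno, pheno, cfg$trait, map = map, effects = TRUE)
  # q-values from window-combined raw P values: the rank-transformed variant
  # localizes peaks but cannot clear a genome-wide FDR threshold (see
  # ?smooth_pvalues), so interval calling uses the raw-P combination
  scan <- smooth_pvalues(scan, map, window = cfg$window, method = cfg$method,
                         rank = FALSE)
  scan$q_value <- bh_fdr(scan$smoothed_p)
  qtl <- call_qtl(scan, map, fdr_alpha = cfg$fdr_alpha)
  sig_markers <- scan$marker[!is.na(scan$q_value) & scan$q_value < cfg$fdr_alpha]
  calls <- if (length(sig_markers)) classify_scan(scan, sig_markers) else
    tibble::tibble(marker = character(), observed_label = character())
  report <- if (nrow(calls)) architecture_fit_report(calls, truth) else NULL

  out <- structure(
    list(map = map, geno = geno, pheno = pheno, truth = truth, scan = scan,
         qtl = qtl, calls = calls, report = report, config = cfg),
    class = "gate_pipeline"
  )
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_map(map, file.path(cfg$out_dir, "map.tsv"))
    write_genotypes(geno, file.path(cfg$out_dir, "genotypes.tsv"))
    write_phenotypes(pheno, file.path(cfg$out_dir, "phenotypes.tsv"))
    readr::write_tsv(scan, file.path(cfg$out_dir, "scan.tsv"))
    readr::write_tsv(qtl, file.path(cfg$out_dir, "qtl.tsv"))
    readr::write_tsv(calls, file.path(cfg$out_dir, "calls.tsv"))
    if (!is.null(truth)) write_architecture(truth, file.path(cfg$out_dir, "truth.json"))
  }
  out
}

#' @export
print.gate_pipeline <- function(x, ...) {
  cat(sprintf("stressgate pipeline: %d lines, %d markers, %d phenotype records\n",
              nrow(x$geno), sum(!names(x$geno) %in% c("line_id", "family")),
              nrow(x$pheno)))
  cat(sprintf("QTL intervals called at FDR %.2g: %d\n",
              x$config$fdr_alpha, nrow(x$qtl)))
  if (nrow(x$calls)) print(x$report)
  invisible(x)
}
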