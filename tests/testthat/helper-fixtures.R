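# Small populations reused across tests; everything is generated in code.

two_marker_map <- function(d_cM, chrom_length = max(100, d_cM)) {
  m <- make_map(1, 2, chrom_length, spacing = "even", seed = 1)
  m$pos_cM <- c(0, d_cM)
  m
}

# a genotype tibble built directly from allele calls (one marker)
geno_from_calls <- function(calls, marker = "mk1", family = "fam1") {
  d <- tibble::tibble(
    line_id = sprintf("L%03d", seq_along(calls)),
    family = family
  )
  d[[marker]] <- calls
  d
}

# noiseless single-QTL dataset for a given gate
noiseless_gate_data <- function(gate, eu, ed, ec = NA, n_lines = 100, seed = 6) {
  map <- make_map(1, 5, 100, seed = 5)
  geno <- simulate_ril_genotypes(map, n_lines, 0, seed = seed)
  arch <- architecture(
    tibble::tibble(marker = "m01_003", gate = gate, effect_uv = eu,
                   effect_drought = ed, effect_combined = ec),
    trait_mean = 10, block_sd = 0, residual_sd = 0
  )
  pheno <- simulate_phenotypes(geno, arch, n_blocks = 2, seed = seed + 1)
  list(map = map, geno = geno, arch = arch, pheno = pheno)
}

# standard small mapping dataset with one attenuator QTL and noise
small_qtl_data <- function(n_lines = 150, effect = 1, residual_sd = 1, seed = 3) {
  map <- make_map(3, 20, 100, seed = 2)
  geno <- simulate_ril_genotypes(map, n_lines, 0, seed = seed)
  arch <- architecture(
    tibble::tibble(marker = "m02_010", gate = "attenuator_UV",
                   effect_uv = effect, effect_drought = 0),
    trait_mean = 10, block_sd = 0.2, residual_sd = residual_sd
  )
  pheno <- simulate_phenotypes(geno, arch, n_blocks = 4, seed = seed + 1)
  list(map = map, geno = geno, arch = arch, pheno = pheno)
}
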