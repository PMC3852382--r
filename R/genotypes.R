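#' @importFrom rlang .data
#' @importFrom stats rbinom runif rnorm setNames
NULL

# One meiosis per individual, vectorised over individuals within a chromosome.
# h1, h2: n x m 0/1 matrices (parental origin); r: recombination fractions
# between adjacent markers (length m-1). Crossover process is Markov along
# the chromosome (Haldane, no interference).
.gamete_chrom <- function(h1, h2, r) {
  n <- nrow(h1); m <- ncol(h1)
  state <- matrix(0L, n, m)
  state[, 1] <- rbinom(n, 1L, 0.5)
  if (m > 1) {
    for (j in 2:m) {
      sw <- rbinom(n, 1L, r[j - 1])
      state[, j] <- bitwXor(state[, j - 1], sw)
    }
  }
  ifelse(state == 0L, h1, h2)
}

.gametes <- function(h1, h2, r_by_chrom, chrom) {
  out <- matrix(0L, nrow(h1), ncol(h1))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    out[, idx] <- .gamete_chrom(h1[, idx, drop = FALSE], h2[, idx, drop = FALSE],
                                r_by_chrom[[as.character(ch)]])
  }
  out
}

# Resolve residual heterozygosity after the final selfing generation: one
# fair coin per contiguous heterozygous run (runs never span chromosomes),
# choosing one of the two haplotypes for the whole run. Keeps co-located
# markers identical and respects linkage within the run.
.fix_het <- function(h1, h2, chrom) {
  n <- nrow(h1)
  chrom_break <- c(TRUE, chrom[-1] != chrom[-length(chrom)])
  for (i in seq_len(n)) {
    het <- h1[i, ] != h2[i, ]
    if (!any(het)) next
    run_start <- het & (c(TRUE, !het[-length(het)]) | chrom_break)
    run_id <- cumsum(run_start) * het
    for (g in unique(run_id[run_id > 0])) {
      if (runif(1) < 0.5) {
        sel <- run_id == g
        h1[i, sel] <- h2[i, sel]
      }
    }
  }
  h1
}

#' Simulate recombinant inbred line genotypes
#'
#' Simulates a biparental RIL population by explicit generations: an F1
#' (fully heterozygous), optional random-intermating generations (as in the
#' intermated B73xMo17 population, which expands the effective map), then
#' single-seed-descent selfing for four generations with residual
#' heterozygosity at F6 resolved by a fair coin per heterozygous run.
#' Recombination follows the Haldane map function (no interference).
#'
#' @param map Genetic map tibble from [make_map()] or [read_map()].
#' @param n_lines Number of inbred lines to derive (>= 1).
#' @param n_intermating_generations Random-mating generations between F2 and
#'   selfing (0 for a conventional selfed RIL).
#' @param seed Integer seed; output is bit-identical given the same inputs.
#' @param missing_rate Fraction of genotype calls masked to `NA` (default 0).
#' @param family Family label recorded for every line.
#' @param line_prefix Prefix for generated line ids.
#'
#' @return A tibble with columns `line_id`, `family`, then one column per
#'   marker holding allele codes `"A"` (common/reference parent) or `"B"`.
#' @examples
#' map <- make_map(1, 5, 100)
#' simulate_ril_genotypes(map, n_lines = 4, seed = 1)
#' @export
simulate_ril_genotypes <- function(map, n_lines, n_intermating_generations = 0L,
                                   seed = 1L, missing_rate = 0,
                                   family = "fam1", line_prefix = "RIL") {
  validate_map(map)
  if (nrow(map) == 0) stop("map has no markers", call. = FALSE)
  if (n_lines < 1) stop("`n_lines` must be >= 1", call. = FALSE)
  if (n_intermating_generations < 0) {
    stop("`n_intermating_generations` must be >= 0", call. = FALSE)
  }
  set.seed(seed)
  m <- nrow(map)
  chrom <- map$chrom
  r_by <- adjacent_r(map)

  g <- n_intermating_generations
  # population that undergoes intermating; each final line descends from one
  # member by single-seed descent
  n_pop <- if (g > 0) max(2L * n_lines, 200L) else n_lines
  f1_h1 <- matrix(0L, n_pop, m)
  f1_h2 <- matrix(1L, n_pop, m)
  # F2: each individual from two independent F1 gametes
  h1 <- .gametes(f1_h1, f1_h2, r_by, chrom)
  h2 <- .gametes(f1_h1, f1_h2, r_by, chrom)
  for (gen in seq_len(g)) {
    p1 <- sample.int(n_pop, n_pop, replace = TRUE)
    p2 <- sample.int(n_pop, n_pop, replace = TRUE)
    new_h1 <- .gametes(h1[p1, , drop = FALSE], h2[p1, , drop = FALSE], r_by, chrom)
    new_h2 <- .gametes(h1[p2, , drop = FALSE], h2[p2, , drop = FALSE], r_by, chrom)
    h1 <- new_h1; h2 <- new_h2
  }
  if (n_pop > n_lines) {
    keep <- sample.int(n_pop, n_lines)
    h1 <- h1[keep, , drop = FALSE]; h2 <- h2[keep, , drop = FALSE]
  }
  # single-seed-descent selfing F2 -> F6
  for (gen in 1:4) {
    new_h1 <- .gametes(h1, h2, r_by, chrom)
    new_h2 <- .gametes(h1, h2, r_by, chrom)
    h1 <- new_h1; h2 <- new_h2
  }
  hap <- .fix_het(h1, h2, chrom)

  calls <- matrix(ifelse(hap == 0L, "A", "B"), nrow(hap), m)
  if (missing_rate > 0) {
    calls[runif(length(calls)) < missing_rate] <- NA_character_
  }
  colnames(calls) <- map$marker
  out <- tibble::tibble(
    line_id = sprintf("%s%04d", line_prefix, seq_len(n_lines)),
    family = family
  )
  dplyr::bind_cols(out, tibble::as_tibble(calls))
}

#' Simulate nested association mapping (NAM) genotypes
#'
#' Families of RILs each derived from a cross between a common parent
#' (allele code `"A"`, as B73 in the maize NAM resource) and a distinct
#' alternate parent (`"B"`). Each family behaves as a conventional selfed
#' RIL population on the shared marker map.
#'
#' @inheritParams simulate_ril_genotypes
#' @param n_families Number of families (>= 1).
#' @param lines_per_family RILs per family (>= 1).
#'
#' @return A tibble as in [simulate_ril_genotypes()], with `family` holding
#'   the family label and `n_families * lines_per_family` rows.
#' @examples
#' map <- make_map(1, 5, 100)
#' simulate_nam_genotypes(map, n_families = 2, lines_per_family = 3, seed = 1)
#' @export
simulate_nam_genotypes <- function(map, n_families = 5L, lines_per_family = 50L,
                                   seed = 1L, missing_rate = 0) {
  if (n_families < 1 || lines_per_family < 1) {
    stop("`n_families` and `lines_per_family` must be >= 1", call. = FALSE)
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_families)
  purrr::map_dfr(seq_len(n_families), function(f) {
    simulate_ril_genotypes(
      map, lines_per_family, n_intermating_generations = 0L,
      seed = seeds[f], missing_rate = missing_rate,
      family = sprintf("fam%d", f), line_prefix = sprintf("Z%03d_", f)
    )
  })
}

# numeric genotype matrix: +1 for A, -1 for B, NA for missing; rows = lines
geno_matrix <- function(geno) {
  markers <- setdiff(names(geno), c("line_id", "family"))
  x <- as.matrix(geno[, markers])
  bad <- !is.na(x) & !(x %in% c("A", "B"))
  if (any(bad)) {
    stop("unknown allele code(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  num <- matrix(NA_real_, nrow(x), ncol(x), dimnames = list(geno$line_id, markers))
  num[x == "A"] <- 1
  num[x == "B"] <- -1
  num
}
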