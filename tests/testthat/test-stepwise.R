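# shared small NAM fixture for the stepwise tests
nam_fixture <- function(n_families = 3, lines_per_family = 40, qtl = NULL,
                        seed = 42, residual_sd = 1) {
  map <- make_map(3, 8, 100, seed = seed)
  geno <- simulate_nam_genotypes(map, n_families, lines_per_family,
                                 seed = seed + 1)
  if (is.null(qtl)) {
    qtl <- tibble::tibble(marker = character(), gate = character(),
                          effect_uv = numeric(), effect_drought = numeric())
  }
  arch <- architecture(qtl, trait_mean = 10, block_sd = 0.25,
                       residual_sd = residual_sd)
  pheno <- simulate_phenotypes(geno, arch, n_blocks = 2, seed = seed + 2)
  list(map = map, geno = geno, pheno = pheno)
}

test_that("entry threshold zero always returns the empty model", {
  a <- effects_for_variance_target(0.4, 1, joint = FALSE)
  d <- nam_fixture(qtl = tibble::tibble(marker = "m02_004",
                                        gate = "independent",
                                        effect_uv = a, effect_drought = a))
  fit <- joint_stepwise(d$geno, d$pheno, "trait", sle = 0)
  expect_s3_class(fit, "gate_stepwise")
  expect_equal(nrow(fit$terms), 0)
  expect_equal(nrow(fit$effects), 0)
  expect_error(joint_stepwise(d$geno, d$pheno, "trait", sle = 1), "\\[0, 1\\)")
})

test_that("a strong QTL is selected first and its effects carry the right sign", {
  a <- effects_for_variance_target(0.5, 1, joint = FALSE)
  d <- nam_fixture(qtl = tibble::tibble(marker = "m02_004",
                                        gate = "independent",
                                        effect_uv = a, effect_drought = a))
  fit <- joint_stepwise(d$geno, d$pheno, "trait", sle = 0.001, max_terms = 6)
  expect_gte(nrow(fit$terms), 1)
  first <- fit$terms$marker[1]
  pos <- d$map[match(c(first, "m02_004"), d$map$marker), ]
  expect_equal(pos$chrom[1], pos$chrom[2])
  expect_lte(abs(diff(pos$pos_cM)), 15)
  # UV-cell effects at the selected marker are positive (allele A carries +a)
  ef <- fit$effects[fit$effects$marker == first & fit$effects$environment == "UV", ]
  expect_true(all(ef$effect > 0))
  expect_true(all(is.finite(ef$se) & ef$se > 0))
  # entry P values are nondecreasing along a forward path in expectation;
  # the first entry must beat the threshold
  expect_lt(fit$terms$p_entry[1], 0.001)
})

test_that("null data enters almost no terms at a strict threshold", {
  entered <- vapply(1:15, function(i) {
    d <- nam_fixture(seed = 100 + i)
    nrow(joint_stepwise(d$geno, d$pheno, "trait", sle = 0.001,
                        max_terms = 5)$terms)
  }, numeric(1))
  # expected false entries per null dataset at SLE 0.001 is far below 1
  expect_lt(mean(entered), 0.5)
})

test_that("the stepwise F-test agrees with lm/anova on the first entry", {
  a <- effects_for_variance_target(0.4, 1, joint = FALSE)
  d <- nam_fixture(n_families = 2, lines_per_family = 25,
                   qtl = tibble::tibble(marker = "m01_004",
                                        gate = "independent",
                                        effect_uv = a, effect_drought = a))
  prep <- stressgate:::.stepwise_data(d$geno, d$pheno, "trait")
  path <- stressgate:::.stepwise_path(prep$X, prep$y, prep$cell, prep$base_mm,
                                      sle_stop = 1, max_terms = 1)$path
  mk <- path$marker[1]
  # independent route: explicit cell columns via lm + anova model comparison
  cellcols <- stats::model.matrix(~ 0 + cell, data = list(cell = prep$cell)) *
    prep$X[, mk]
  cellcols <- cellcols[, colSums(cellcols^2) > 0, drop = FALSE]
  f0 <- stats::lm(prep$y ~ prep$base_mm - 1)
  f1 <- stats::lm(prep$y ~ cbind(prep$base_mm, cellcols) - 1)
  p_ref <- stats::anova(f0, f1)[2, "Pr(>F)"]
  expect_equal(path$p_entry[1], p_ref, tolerance = 1e-8)
  expect_equal(path$df_term[1], stats::anova(f0, f1)[2, "Df"])
})

test_that("calibration bookkeeping is internally consistent", {
  map <- make_map(5, 10, 100, seed = 3)
  cal <- calibrate_sle(map, n_families = 3, lines_per_family = 30,
                       sle_grid = c(1e-3, 1e-2), n_sims = 4, max_terms = 8,
                       seed = 5)
  expect_s3_class(cal, "gate_calibration")
  b <- cal$by_sle
  # per sim: 5 true QTL, so tp + fn = 5 * n_sims at every threshold
  expect_true(all(b$tp + b$fn == 5 * 4))
  expect_true(all(b$ppv + b$fdr == 1, na.rm = TRUE))
  expect_true(all(b$tp <= 5 * 4))
  expect_true(all(b$sensitivity >= 0 & b$sensitivity <= 1, na.rm = TRUE))
  # a looser threshold can only keep or extend the selected prefix
  expect_true(all(diff(b$tp + b$fp) >= 0))
  # per-QTL detections sum to total tp at each threshold
  agg <- tapply(cal$per_qtl$detected, cal$per_qtl$sle, sum)
  expect_equal(as.numeric(agg[as.character(b$sle)]), b$tp)
})

test_that("selection scoring credits each true QTL at most once", {
  map <- make_map(2, 11, 100, seed = 7)  # 10 cM spacing
  truth <- c("m01_003", "m02_006")
  # two selections near the same QTL: one TP, one FP
  sc <- stressgate:::.score_selection(c("m01_003", "m01_004", "m02_006"),
                                      map, truth, tp_window = 10)
  expect_equal(sc$tp, 2L)
  expect_equal(sc$fp, 1L)
  expect_equal(sc$fn, 0L)
  # right position, wrong chromosome: never a TP
  sc2 <- stressgate:::.score_selection("m02_003", map, "m01_003", tp_window = 10)
  expect_equal(sc2$tp, 0L)
  expect_equal(sc2$fp, 1L)
  expect_equal(sc2$fn, 1L)
  # outside the window on the same chromosome: FP
  sc3 <- stressgate:::.score_selection("m01_010", map, "m01_001", tp_window = 10)
  expect_equal(sc3$fp, 1L)
})

test_that("detection rises with the variance target and best_sle honors the constraint", {
  map <- make_map(5, 10, 100, seed = 11)
  cal <- calibrate_sle(map, n_families = 3, lines_per_family = 40,
                       sle_grid = c(1e-3, 1e-2), n_sims = 12, max_terms = 10,
                       seed = 13)
  pq <- cal$per_qtl[cal$per_qtl$sle == 1e-2, ]
  pq <- pq[order(pq$target_r2), ]
  # largest target detected at least as often as the smallest
  expect_gte(pq$detected[nrow(pq)], pq$detected[1])
  expect_gt(pq$detected[nrow(pq)] / cal$n_sims, 0.8)

  s <- best_sle(cal, max_fdr = 0.10)
  expect_true(s %in% cal$by_sle$sle)
  expect_lte(cal$by_sle$fdr[cal$by_sle$sle == s], 0.10)
  # impossible constraint falls back with a warning
  expect_warning(s0 <- best_sle(cal, max_fdr = -1), "constraint")
  expect_false(attr(s0, "constrained"))
})

test_that("stepwise input validation", {
  d <- nam_fixture(n_families = 1)
  expect_error(joint_stepwise(d$geno, d$pheno, "trait"), ">= 2 families")
  d2 <- nam_fixture()
  expect_error(joint_stepwise(d2$geno, d2$pheno, "absent"), "no data for trait")
  mono <- d2$geno
  mono[, -(1:2)] <- "A"
  expect_error(joint_stepwise(mono, d2$pheno, "trait"), "polymorphic")
})
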