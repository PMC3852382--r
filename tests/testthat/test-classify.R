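# build a per-environment evidence tibble for classify_locus
evidence <- function(uv, dr, cb, ctrl = 0, sig_uv = FALSE, sig_dr = FALSE,
                     sig_cb = FALSE, sig_ctrl = FALSE, half = 0.2) {
  tibble::tibble(
    environment = c("control", "drought", "UV", "combined"),
    effect = c(ctrl, dr, uv, cb),
    se = half / 2,
    ci_lo = effect - half, ci_hi = effect + half,
    significant = c(sig_ctrl, sig_dr, sig_uv, sig_cb)
  )
}

test_that("each decision rule fires on its canonical evidence tuple", {
  # rule 1: single-stress only => attenuated in combined stress
  expect_equal(classify_locus(evidence(uv = 1, dr = 0, cb = 0,
                                       sig_uv = TRUE))$observed_label,
               "uv_effect_lost")
  expect_equal(classify_locus(evidence(uv = 0, dr = -0.8, cb = 0,
                                       sig_dr = TRUE))$observed_label,
               "drought_effect_lost")
  # rule 2: combined only
  expect_equal(classify_locus(evidence(uv = 0, dr = 0, cb = 1.2,
                                       sig_cb = TRUE))$observed_label,
               "combined_only_dose_dependent")
  # rule 3: opposite single-stress signs cancelling
  expect_equal(classify_locus(evidence(uv = 0.9, dr = -0.9, cb = 0,
                                       sig_uv = TRUE, sig_dr = TRUE))$observed_label,
               "additive_opposite_xor")
  # rule 4: combined CI contains the sum of the single estimates
  expect_equal(classify_locus(evidence(uv = 0.5, dr = 0.4, cb = 0.95,
                                       sig_uv = TRUE, sig_dr = TRUE,
                                       sig_cb = TRUE))$observed_label,
               "additive_or")
  # rule 5: combined exceeds the sum and its CI excludes it
  expect_equal(classify_locus(evidence(uv = 0.5, dr = 0.4, cb = 2.5,
                                       sig_uv = TRUE, sig_dr = TRUE,
                                       sig_cb = TRUE))$observed_label,
               "synergistic")
  # rule 6: one stress plus combined, consistent magnitude
  expect_equal(classify_locus(evidence(uv = 0.8, dr = 0, cb = 0.85,
                                       sig_uv = TRUE, sig_cb = TRUE))$observed_label,
               "independent_consistent")
  # rule 7: fallback
  expect_equal(classify_locus(evidence(uv = 0, dr = 0, cb = 0))$observed_label,
               "complex")
  # same-sign singles with non-significant combined don't fit rules 1-6
  expect_equal(classify_locus(evidence(uv = 0.5, dr = 0.5, cb = 0,
                                       sig_uv = TRUE, sig_dr = TRUE))$observed_label,
               "complex")
})

test_that("all emitted labels come from the declared vocabulary", {
  set.seed(33)
  for (i in 1:50) {
    ev <- evidence(uv = rnorm(1), dr = rnorm(1), cb = rnorm(1),
                   sig_uv = runif(1) < 0.5, sig_dr = runif(1) < 0.5,
                   sig_cb = runif(1) < 0.5)
    expect_true(classify_locus(ev)$observed_label %in% pattern_levels())
  }
})

test_that("control-significant loci error; incomplete environments error", {
  expect_error(classify_locus(evidence(uv = 1, dr = 0, cb = 0, ctrl = 1,
                                       sig_uv = TRUE, sig_ctrl = TRUE)),
               "control-significant")
  expect_error(classify_locus(evidence(1, 0, 0)[-2, ]), "must cover")
})

test_that("expected_pattern maps every gate and rejects unknown labels", {
  expect_equal(expected_pattern("attenuator_UV")$expected_label, "uv_effect_lost")
  expect_equal(expected_pattern("attenuator_drought")$expected_label,
               "drought_effect_lost")
  expect_equal(expected_pattern("AND_gate")$expected_label,
               "combined_only_dose_dependent")
  expect_equal(expected_pattern("OR_gate")$expected_label, "additive_or")
  expect_equal(expected_pattern("XOR")$expected_label, "additive_opposite_xor")
  expect_equal(expected_pattern("independent")$expected_label,
               "independent_consistent")
  expect_false(expected_pattern("AND_gate")$detect_UV)
  expect_error(expected_pattern("NAND"), "unknown gate")
})

test_that("noiseless simulated data recovers every gate's expected label", {
  gates <- c(independent = NA, AND_gate = NA, OR_gate = NA, XOR = NA,
             attenuator_UV = NA, attenuator_drought = NA)
  for (g in names(gates)) {
    args <- switch(g,
      AND_gate = list(eu = 0, ed = 0, ec = 1),
      XOR = list(eu = 0.8, ed = -0.8),
      list(eu = 0.8, ed = if (g %in% c("attenuator_UV")) 0
                          else if (g == "attenuator_drought") 0.8 else 0.6))
    if (g == "attenuator_drought") args$eu <- 0
    if (g == "independent") args$ed <- 0  # single-input case
    d <- do.call(noiseless_gate_data, c(list(gate = g), args, seed = 6))
    ph <- d$pheno
    set.seed(7); ph$value <- ph$value + rnorm(nrow(ph), 0, 0.02)
    sc <- scan_interaction(d$geno, ph, "trait", effects = TRUE)
    call <- classify_scan(sc, markers = "m01_003")
    gates[g] <- call$observed_label
  }
  expect_equal(unname(gates[c("attenuator_UV", "attenuator_drought",
                              "AND_gate", "XOR", "OR_gate", "independent")]),
               c("uv_effect_lost", "drought_effect_lost",
                 "combined_only_dose_dependent", "additive_opposite_xor",
                 "additive_or", "independent_consistent"))
})

test_that("classify_scan drops control-significant markers with a message", {
  d <- noiseless_gate_data("attenuator_UV", eu = 0.8, ed = 0)
  ph <- d$pheno
  set.seed(9); ph$value <- ph$value + rnorm(nrow(ph), 0, 0.02)
  sc <- scan_interaction(d$geno, ph, "trait", effects = TRUE)
  sc$significant_control[sc$marker == "m01_003"] <- TRUE
  expect_message(out <- classify_scan(sc, markers = c("m01_002", "m01_003")),
                 "control-significant")
  expect_false("m01_003" %in% out$marker)
  expect_error(classify_scan(sc[, c("marker", "raw_p")]), "effects")
})

test_that("fit report counts, confusion and recovery are coherent", {
  calls <- tibble::tibble(
    marker = c("a", "b", "c"),
    observed_label = c("uv_effect_lost", "uv_effect_lost", "additive_or")
  )
  rep0 <- architecture_fit_report(calls)
  expect_s3_class(rep0, "gate_fit_report")
  expect_equal(rep0$counts$n[rep0$counts$observed_label == "uv_effect_lost"], 2L)
  truth <- architecture(tibble::tibble(
    marker = c("a", "b", "c"),
    gate = c("attenuator_UV", "attenuator_UV", "OR_gate"),
    effect_uv = 1, effect_drought = c(0, 0, 1)
  ))
  rep1 <- architecture_fit_report(calls, truth)
  expect_equal(sum(rep1$confusion$n), 3L)
  expect_equal(rep1$recovery$recovery, c(1, 1))
  expect_output(print(rep1), "recovery")
  expect_error(architecture_fit_report(calls[0, ]), "no calls")
})

test_that("classification is reasonably robust under realistic noise", {
  # with residual noise at half the effect scale, most gates still land on
  # their expected label; require at least 4 of 6
  specs <- list(
    list(gate = "attenuator_UV", eu = 1, ed = 0),
    list(gate = "attenuator_drought", eu = 0, ed = 1),
    list(gate = "AND_gate", eu = 0, ed = 0, ec = 1),
    list(gate = "XOR", eu = 1, ed = -1),
    list(gate = "OR_gate", eu = 1, ed = 0.8),
    list(gate = "independent", eu = 1, ed = 0)
  )
  hits <- vapply(specs, function(sp) {
    d <- do.call(noiseless_gate_data, c(sp, list(n_lines = 200, seed = 17)))
    ph <- d$pheno
    set.seed(18); ph$value <- ph$value + rnorm(nrow(ph), 0, 0.5)
    sc <- scan_interaction(d$geno, ph, "trait", effects = TRUE)
    call <- classify_scan(sc, markers = "m01_003")
    call$observed_label == expected_pattern(sp$gate)$expected_label
  }, logical(1))
  expect_gte(sum(hits), 4)
})
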