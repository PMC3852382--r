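---
title: "Methods: gate architectures, scanning, and threshold calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gate architectures, scanning, and threshold calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressgate)
```

stressgate studies how quantitative trait loci (QTL) combine two abiotic
stress inputs — drought and UV radiation — into growth effects, using a
factorial design with four environments: `control`, `drought`, `UV`, and
`combined`. This vignette records the statistical choices the package makes
and why.

## The gate model

Each simulated QTL carries a *gate*: a logical rule mapping the two stress
inputs to a per-environment allele effect. Effects are **half-differences**:
the deviation of the allele-A class mean from the population mean, so the
A-vs-B class difference is twice the effect (conventions differ by a factor
of two across QTL software; this is ours, stated once here and in
`?architecture`).

With `eu = effect_uv`, `ed = effect_drought`, the per-environment effects
(control, drought, UV, combined) are:

| gate                 | control | drought | UV   | combined          |
|----------------------|---------|---------|------|-------------------|
| `independent`        | 0       | `ed`    | `eu` | `eu + ed`         |
| `OR_gate`            | 0       | `ed`    | `eu` | `eu + ed`         |
| `AND_gate`           | 0       | 0       | 0    | `effect_combined` |
| `XOR`                | 0       | `-eu`   | `eu` | 0                 |
| `attenuator_UV`      | 0       | 0       | `eu` | 0                 |
| `attenuator_drought` | 0       | `ed`    | 0    | 0                 |

`independent` and `OR_gate` coincide at the level of detection patterns when
both inputs are nonzero; the attenuators encode the headline phenomenon —
a modifier activated by one stress suppresses the other pathway's allelic
signal, so a locus significant under a single stress loses its effect under
combined stress ("UV effect lost" / "drought effect lost").

```{r gates}
arch <- architecture(
  data.frame(marker = "m01_003", gate = "attenuator_UV",
             effect_uv = 0.7, effect_drought = 0),
  trait_mean = 10, residual_sd = 1
)
gate_effect_table(arch)
```

## Population simulators

`simulate_ril_genotypes()` builds recombinant inbred lines (RILs) by explicit
generations: F1 gametes with crossovers from the Haldane map function
`r = (1 - exp(-2d/100)) / 2`, optional intermating generations (the
map-expanding step of intermated populations), four selfing generations, and
a final coin-flip per residual heterozygous run. The closed-form check is the
RIL recombinant fraction `2r / (1 + 2r)`, asserted in the test suite.
`simulate_nam_genotypes()` nests per-family RIL sets sharing a common parent
coding, the nested association mapping (NAM) design.

## Effect sizes from variance targets

`effects_for_variance_target()` converts per-QTL variance-explained targets
into half-difference effects at allele frequency 1/2. Two conventions:

* **joint** (default): `a_i^2 / (sum_j a_j^2 + sigma^2) = t_i`, closed form
  `a_i = sigma * sqrt(t_i / (1 - sum(t)))`, requiring `sum(t) < 1`;
* **marginal** (`joint = FALSE`): `a_i^2 / (a_i^2 + sigma^2) = t_i`.

The calibration study (below) uses five QTL with targets linearly spaced
from 50% down to 8%. Those targets sum to 1.45, so they are only meaningful
marginally — each QTL judged against the residual alone. That is the
convention `calibrate_sle()` uses, and the package treats the choice as its
own documented decision.

## Variance components and line %

`estimate_components()` fits the one-way random-effects model
`value ~ 1 + (1 | line_id)` per environment by REML (lme4), with a
method-of-moments fallback for degenerate fits, and reports
`line_pct = 100 * v_line / (v_line + v_error)` — the broad-sense share of
phenotypic variance attributable to line differences. Values at or above 1%
are rounded to one decimal; smaller values keep two significant digits; a
zero line variance reports `NA` (a blank cell, not 0%).

## The interaction scan

`scan_interaction()` tests each marker with the model comparison

```
value ~ block + environment + genotype            (reduced)
value ~ block + environment + genotype + environment:genotype
```

under sum-to-zero contrasts. Because the interaction is the highest-order
term, its type-III F-test equals this model comparison exactly (the test
suite cross-checks against `car::Anova`). A main-effect-only QTL (same
effect in every environment) is deliberately *not* significant here: the
scan targets stress-specific architecture, and `main_effect = TRUE` reports
the constitutive test separately. `allele_effects()` returns per-environment
allele-class deviations with t-based confidence intervals, the evidence the
classifier consumes.

## Smoothing, FDR, and why ranks cannot feed FDR

`smooth_pvalues()` combines each marker's window of same-chromosome
neighbours with the Simes statistic (or Fisher's method), borrowing strength
from the correlated flanks of a true QTL. The default pre-processing is the
genome-wide fractional rank transform `rank/(n+1)`.

One property deserves emphasis: **ranks are measure-preserving**. The ranks
of `n` P values are a permutation of `i/(n+1)` whatever the data, so the
smallest achievable window-combined value is about `w/(n+1)` for window
width `w`, and its genome-wide Benjamini–Hochberg q-value is about `w >= 1`.
No marker can ever clear an FDR threshold on the rank path, regardless of
effect size. The rank transform is therefore a *peak-locating,
distribution-robustness* device, not an inference path. For q-values and
interval calling, `smooth_pvalues(rank = FALSE)` combines the raw P values,
and `run_pipeline()` uses that path; the test suite asserts both the
powerlessness of the rank path and the power of the raw path.

`call_qtl()` merges runs of markers with `q < alpha` into closed intervals
with a minimum-q peak marker. `cluster_markers()` and
`coinheritance_check()` handle the two map pathologies worth automating:
runs of near-duplicate markers (cluster and keep the most complete
representative) and implausibly correlated markers on *different*
chromosomes (flag as suspected data duplication).

## Joint stepwise selection and SLE calibration

For NAM designs, `joint_stepwise()` runs forward selection from the base
model `family + environment + block`. A candidate term for marker *m* is the
set of cell columns `x_m * 1[family = f] * 1[environment = e]`, which given
the base model spans marker-nested-in-family plus its environment
interaction. Each step tests every candidate with a partial F-test
conditional on the current model; Frisch–Waugh residualization lets a single
QR decomposition of the current model serve all candidates, so a
500-marker genome scan per step stays fast. The smallest-P candidate enters
while its entry P value beats the significance level for entry (SLE).

`calibrate_sle()` is the simulation study behind the threshold choice:
simulate NAM datasets with five known QTL (variance targets 50%..8%,
marginal convention), run the stepwise path once per dataset, truncate it at
each threshold in the grid (the forward path is threshold-independent up to
its stopping step), and score selections against the truth — a selected
marker within 10 cM of an unclaimed true QTL on the same chromosome is a
true positive, each QTL credited once; other selections are false positives;
unclaimed QTL are false negatives. Design defaults (5 families x 50 lines,
500 markers over 10 x 150 cM chromosomes, 2 replicate blocks) are the
package's documented problem sizes. At SLE = 0.001 the procedure operates
near PPV 0.9 and sensitivity 0.99. `best_sle()` picks the
sensitivity-maximizing threshold subject to an FDR cap.

## Classifying cross-environment patterns

`classify_locus()` assigns one label per locus from per-environment effects
and significance flags (never raw magnitudes alone), applying rules in
order:

1. significant in exactly one single stress, not in combined:
   `uv_effect_lost` / `drought_effect_lost`;
2. significant only in combined: `combined_only_dose_dependent`;
3. both single stresses significant with opposite signs, combined not:
   `additive_opposite_xor`;
4. both significant, same sign, combined significant with its CI containing
   the *sum* of the single estimates: `additive_or`;
5. combined significant, its CI excluding the sum, and exceeding it in
   magnitude: `synergistic`;
6. one single stress plus combined, consistent sign, combined CI containing
   the single estimate: `independent_consistent`;
7. otherwise `complex`.

The CI-containment rules make additivity and synergy claims evidence-based
rather than point-estimate comparisons. A significant control-environment
effect is an *error*: control-responsive loci are outside the stress-gate
taxonomy and must be excluded upstream (`classify_scan()` drops them with a
message). `expected_pattern()` states each gate's theory-expected label, and
`architecture_fit_report()` crosses observed against expected when the
generating truth is known.

## Interval overlap

`overlap_probability()` asks whether two QTL interval sets colocalize more
than chance expects: the observed statistic is the number of `a` intervals
overlapping at least one `b` interval (closed intervals, cM), and the null
re-places the `a` intervals uniformly on the map (chromosome chosen with
probability proportional to length, start uniform subject to containment),
with the add-one P estimator. This is a deliberately simple stand-in for
bin-structure-conditioned nulls, which are out of scope.

## A worked pipeline

```{r pipeline}
cfg <- list(
  map = list(n_chromosomes = 3, markers_per_chromosome = 15, chrom_length = 100),
  n_lines = 120, n_intermating_generations = 0, n_blocks = 3,
  qtl = data.frame(marker = "m02_008", gate = "attenuator_UV",
                   effect_uv = 0.8, effect_drought = 0),
  seed = 101
)
res <- run_pipeline(cfg)
res$qtl
res$calls[, c("marker", "observed_label")]
```

Every stage's randomness derives from the single root seed; the same
configuration yields byte-identical results.

## Limitations

* Gate semantics are defined for exactly two stresses; the environment
  vocabulary is closed.
* The overlap null ignores linkage and bin structure.
* The calibration's headline operating point is a property of this
  package's documented simulation defaults (marker density, TP window,
  block count), not a universal constant.
* No import of community genotype formats (VCF/PLINK); the TSV schemas in
  `?stressgate_io` are self-contained.
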