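#' @keywords internal
# Forward joint stepwise path for a multiparent (NAM) design.
#
# Base model: family + environment + block. A candidate term for marker m is
# the set of columns x_m * 1[family = f] * 1[environment = e] over all
# (f, e) cells; given the base model this spans the same space as
# marker-nested-in-family plus its environment interaction. Candidate P
# values are partial F-tests conditional on the current model, computed by
# Frisch-Waugh residualization so one QR of the current model serves all
# candidates. Returns the entry path: the sequence of best markers with
# their entry P values, extended while the entry P is below `sle_stop`.
.stepwise_path <- function(X, y, cell, base_mm, sle_stop, max_terms,
                           marker_pos = NULL) {
  n <- length(y)
  G <- nlevels(cell)
  cell_i <- as.integer(cell)
  counts <- rowsum(X^2, cell_i)           # G x n_markers; diag of C'C
  markers <- colnames(X)
  X0 <- base_mm
  in_model <- rep(FALSE, ncol(X))
  path <- list()
  rows_by_cell <- split(seq_len(n), cell_i)

  for (step in seq_len(max_terms)) {
    qr0 <- qr(X0)
    p0 <- qr0$rank
    Q <- qr.Q(qr0)[, seq_len(p0), drop = FALSE]
    yt <- y - Q %*% crossprod(Q, y)
    rss0 <- sum(yt^2)
    b_all <- rowsum(X * as.vector(yt), cell_i)   # G x n_markers
    Tg <- lapply(rows_by_cell, function(rows) {
      crossprod(Q[rows, , drop = FALSE], X[rows, , drop = FALSE])
    })
    # K[g,h,] = per-marker inner products of residualized-cell loadings
    K <- array(0, c(G, G, ncol(X)))
    for (g in seq_len(G)) {
      for (h in g:G) {
        v <- colSums(Tg[[g]] * Tg[[h]])
        K[g, h, ] <- v
        K[h, g, ] <- v
      }
    }
    best_p <- Inf; best_m <- NA_integer_; best_q <- NA_integer_
    for (m in seq_len(ncol(X))) {
      if (in_model[m]) next
      M <- -K[, , m]
      diag(M) <- diag(M) + counts[, m]
      b <- b_all[, m]
      eg <- eigen(M, symmetric = TRUE)
      tol <- max(eg$values, 0) * 1e-8
      keep <- eg$values > tol
      qrank <- sum(keep)
      if (qrank == 0) next
      z <- crossprod(eg$vectors[, keep, drop = FALSE], b)
      rss_red <- sum(z^2 / eg$values[keep])
      df2 <- n - p0 - qrank
      if (df2 <= 0) next
      rss1 <- max(rss0 - rss_red, 0)
      fstat <- (rss_red / qrank) / (rss1 / df2)
      pval <- stats::pf(fstat, qrank, df2, lower.tail = FALSE)
      if (is.finite(pval) && pval < best_p) {
        best_p <- pval; best_m <- m; best_q <- qrank
      }
    }
    if (!is.finite(best_p) || best_p >= sle_stop) break
    in_model[best_m] <- TRUE
    newcols <- matrix(0, n, G)
    for (g in seq_len(G)) newcols[rows_by_cell[[g]], g] <- X[rows_by_cell[[g]], best_m]
    keep_cols <- counts[, best_m] > 0
    newcols <- newcols[, keep_cols, drop = FALSE]
    colnames(newcols) <- paste(markers[best_m], levels(cell)[keep_cols], sep = "|")
    X0 <- cbind(X0, newcols)
    path[[step]] <- tibble::tibble(step = step, marker = markers[best_m],
                                   p_entry = best_p, df_term = best_q)
  }
  list(path = if (length(path)) dplyr::bind_rows(path) else
         tibble::tibble(step = integer(), marker = character(),
                        p_entry = numeric(), df_term = integer()),
       X_final = X0)
}

# shared data preparation for the stepwise fitters
.stepwise_data <- function(geno, pheno, trait) {
  d <- pheno |>
    dplyr::filter(.data$trait == !!trait, !is.na(.data$value))
  if (nrow(d) == 0) stop("no data for trait: ", trait, call. = FALSE)
  if (dplyr::n_distinct(d$family) < 2) stop("need >= 2 families", call. = FALSE)
  if (dplyr::n_distinct(d$environment) < 2) stop("need >= 2 environments", call. = FALSE)
  gm <- geno_matrix(geno)
  poly <- apply(gm, 2, function(x) dplyr::n_distinct(x[!is.na(x)]) > 1)
  if (!any(poly)) stop("no polymorphic markers", call. = FALSE)
  gm <- gm[, poly, drop = FALSE]
  if (anyNA(gm)) gm[is.na(gm)] <- 0  # missing calls contribute no signal
  X <- gm[match(d$line_id, rownames(gm)), , drop = FALSE]
  fam <- factor(d$family)
  env <- factor(d$environment, levels = intersect(stress_environments(),
                                                  unique(d$environment)))
  blk <- factor(d$block)
  base_mm <- stats::model.matrix(~ fam + env + blk)
  cell <- interaction(fam, env, sep = ":", drop = FALSE)
  list(y = d$value, X = X, cell = cell, base_mm = base_mm)
}

#' Joint forward stepwise marker selection for NAM designs
#'
#' Forward model selection over markers for a multiparent population,
#' starting from a base model of family, environment and block effects. At
#' each step every candidate marker is tested as a family-nested allele
#' effect together with its environment interaction (an F-test conditional
#' on the current model); the smallest-P candidate enters if its P value
#' beats the entry threshold `sle`, and selection stops when no candidate
#' passes or `max_terms` is reached. Allele effects are family-specific
#' (no allelic-series constraint across families).
#'
#' @inheritParams scan_interaction
#' @param sle Significance level for entry, in `[0, 1)`; `sle = 0` always
#'   returns the empty model.
#' @param max_terms Maximum number of marker terms.
#' @return An object of class `gate_stepwise`: a list with `terms` (tibble
#'   `step`, `marker`, `p_entry`, `df_term`), `effects` (per selected marker,
#'   family and environment: allele-A effect and SE from the final joint
#'   fit) and `sle`.
#' @export
joint_stepwise <- function(geno, pheno, trait, sle = 0.001, max_terms = 25L) {
  if (sle < 0 || sle >= 1) stop("`sle` must be in [0, 1)", call. = FALSE)
  prep <- .stepwise_data(geno, pheno, trait)
  res <- .stepwise_path(prep$X, prep$y, prep$cell, prep$base_mm,
                        sle_stop = sle, max_terms = max_terms)
  effects <- .stepwise_effects(res$X_final, prep$y, ncol(prep$base_mm))
  structure(list(terms = res$path, effects = effects, sle = sle),
            class = "gate_stepwise")
}

# effects/SEs of the selected term columns from the final least-squares fit
.stepwise_effects <- function(X_final, y, n_base) {
  term_cols <- setdiff(seq_len(ncol(X_final)), seq_len(n_base))
  if (!length(term_cols)) {
    return(tibble::tibble(marker = character(), family = character(),
                          environment = character(), effect = numeric(),
                          se = numeric()))
  }
  fit <- stats::lm.fit(X_final, y)
  p <- fit$rank
  sigma2 <- sum(fit$residuals^2) / (length(y) - p)
  R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  xtx_inv <- chol2inv(R)
  piv <- fit$qr$pivot[seq_len(p)]
  se_full <- rep(NA_real_, ncol(X_final))
  se_full[piv] <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  info <- strsplit(colnames(X_final)[term_cols], "|", fixed = TRUE)
  cellinfo <- strsplit(vapply(info, `[`, "", 2), ":", fixed = TRUE)
  tibble::tibble(
    marker = vapply(info, `[`, "", 1),
    family = vapply(cellinfo, `[`, "", 1),
    environment = vapply(cellinfo, `[`, "", 2),
    effect = unname(fit$coefficients[term_cols]),
    se = se_full[term_cols]
  )
}

#' Calibrate the stepwise entry threshold by simulation
#'
#' The simulation study behind the choice of entry threshold: generate
#' NAM-like datasets with five QTL of known positions and per-QTL variance
#' targets linearly spaced from 50% down to 8% (marginal convention, see
#' [effects_for_variance_target()]), run forward joint stepwise selection,
#' and score selected markers against the truth. A selected marker within
#' `tp_window` cM of a true QTL (same chromosome) is a true positive, with
#' each true QTL credited at most once; other selections are false
#' positives; undetected QTL are false negatives. Counts are aggregated over
#' simulations for every threshold in `sle_grid`. Because the forward path
#' is threshold-independent up to the stopping step, one path per simulation
#' serves the whole grid.
#'
#' @param map Marker map for the simulated panel.
#' @param n_families,lines_per_family,n_blocks NAM design.
#' @param r2_targets Per-QTL variance fractions (marginal convention).
#' @param sle_grid Entry thresholds to evaluate.
#' @param n_sims Number of simulated datasets.
#' @param tp_window True-positive crediting distance in cM.
#' @param gate Gate type for the simulated QTL (default `"independent"`,
#'   with equal UV and drought inputs).
#' @param block_sd,residual_sd,trait_mean Generating-model noise structure.
#' @param max_terms Cap on entered terms per path.
#' @param seed Root seed; all per-simulation randomness derives from it.
#' @return An object of class `gate_calibration`: list with `by_sle`
#'   (tibble `sle`, `tp`, `fp`, `fn`, `ppv`, `sensitivity`, `fdr`),
#'   `per_qtl` (detections per variance target per threshold), and the call
#'   parameters.
#' @export
calibrate_sle <- function(map, n_families = 5L, lines_per_family = 50L,
                          n_blocks = 2L,
                          r2_targets = seq(0.50, 0.08, length.out = 5),
                          sle_grid = c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2),
                          n_sims = 200L, tp_window = 10,
                          gate = "independent",
                          block_sd = 0.25, residual_sd = 1, trait_mean = 10,
                          max_terms = 12L, seed = 1L) {
  if (n_sims < 1) stop("`n_sims` must be >= 1", call. = FALSE)
  if (!length(sle_grid)) stop("`sle_grid` must be nonempty", call. = FALSE)
  if (any(r2_targets < 0 | r2_targets >= 1)) {
    stop("infeasible variance targets", call. = FALSE)
  }
  sle_grid <- sort(sle_grid)
  set.seed(seed)
  geno_seed <- sample.int(.Machine$integer.max - 1L, 1)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, n_sims)
  geno <- simulate_nam_genotypes(map, n_families, lines_per_family,
                                 seed = geno_seed)
  a <- effects_for_variance_target(r2_targets, residual_sd, joint = FALSE)
  a_drought <- if (gate == "XOR") -a else a
  n_qtl <- length(r2_targets)

  tallies <- array(0, c(length(sle_grid), 3),
                   dimnames = list(NULL, c("tp", "fp", "fn")))
  qtl_det <- matrix(0, length(sle_grid), n_qtl)
  for (s in seq_len(n_sims)) {
    set.seed(sim_seeds[s])
    qtl_idx <- sample.int(nrow(map), n_qtl)
    arch <- architecture(
      tibble::tibble(marker = map$marker[qtl_idx], gate = gate,
                     effect_uv = a, effect_drought = a_drought),
      trait_mean = trait_mean, block_sd = block_sd, residual_sd = residual_sd
    )
    pheno <- simulate_phenotypes(geno, arch, n_blocks = n_blocks,
                                 seed = sim_seeds[s])
    prep <- .stepwise_data(geno, pheno, "trait")
    path <- .stepwise_path(prep$X, prep$y, prep$cell, prep$base_mm,
                           sle_stop = max(sle_grid), max_terms = max_terms)$path
    for (k in seq_along(sle_grid)) {
      stop_at <- which(path$p_entry >= sle_grid[k])
      sel <- if (length(stop_at)) path$marker[seq_len(min(stop_at) - 1)] else path$marker
      score <- .score_selection(sel, map, map$marker[qtl_idx], tp_window)
      tallies[k, ] <- tallies[k, ] + c(score$tp, score$fp, score$fn)
      qtl_det[k, ] <- qtl_det[k, ] + score$detected
    }
  }
  by_sle <- tibble::tibble(
    sle = sle_grid,
    tp = tallies[, "tp"], fp = tallies[, "fp"], fn = tallies[, "fn"]
  ) |>
    dplyr::mutate(
      ppv = ifelse(.data$tp + .data$fp > 0, .data$tp / (.data$tp + .data$fp), NA_real_),
      sensitivity = ifelse(.data$tp + .data$fn > 0,
                           .data$tp / (.data$tp + .data$fn), NA_real_),
      fdr = 1 - .data$ppv
    )
  per_qtl <- tidyr::expand_grid(sle = sle_grid, qtl = seq_len(n_qtl)) |>
    dplyr::mutate(target_r2 = r2_targets[.data$qtl],
                  detected = as.vector(t(qtl_det)), n_sims = n_sims)
  structure(list(by_sle = by_sle, per_qtl = per_qtl, n_sims = n_sims,
                 tp_window = tp_window, r2_targets = r2_targets),
            class = "gate_calibration")
}

# greedy matching of selected markers (entry order) to true QTL positions
.score_selection <- function(selected, map, true_markers, tp_window) {
  truth <- map[match(true_markers, map$marker), c("chrom", "pos_cM")]
  claimed <- rep(FALSE, nrow(truth))
  tp <- 0L; fp <- 0L
  for (mk in selected) {
    i <- match(mk, map$marker)
    cand <- which(!claimed & truth$chrom == map$chrom[i] &
                    abs(truth$pos_cM - map$pos_cM[i]) <= tp_window)
    if (length(cand)) {
      j <- cand[which.min(abs(truth$pos_cM[cand] - map$pos_cM[i]))]
      claimed[j] <- TRUE
      tp <- tp + 1L
    } else {
      fp <- fp + 1L
    }
  }
  list(tp = tp, fp = fp, fn = sum(!claimed), detected = as.integer(claimed))
}

#' Pick the best entry threshold from a calibration
#'
#' Default criterion: the threshold maximizing sensitivity subject to
#' `fdr <= max_fdr`, with ties broken toward the smaller (stricter)
#' threshold. If no grid point satisfies the constraint, the minimum-FDR
#' point is returned with a warning and attribute `constrained = FALSE`.
#'
#' @param cal A `gate_calibration` object.
#' @param max_fdr FDR constraint (default 0.10).
#' @return The selected threshold (numeric scalar).
#' @export
best_sle <- function(cal, max_fdr = 0.10) {
  stopifnot(inherits(cal, "gate_calibration"))
  d <- cal$by_sle[!is.na(cal$by_sle$fdr), ]
  if (!nrow(d)) stop("empty calibration", call. = FALSE)
  ok <- d[d$fdr <= max_fdr, ]
  if (nrow(ok)) {
    ok <- ok[order(-ok$sensitivity, ok$sle), ]
    out <- ok$sle[1]
    attr(out, "constrained") <- TRUE
  } else {
    warning("no threshold satisfies the FDR constraint; returning minimum-FDR point")
    out <- d$sle[which.min(d$fdr)]
    attr(out, "constrained") <- FALSE
  }
  out
}
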