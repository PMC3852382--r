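#' Fractional ranks of P values
#'
#' Transforms P values to `rank/(n+1)` with average ranks for ties — the
#' rank pre-processing applied before window smoothing, which removes the
#' dependence of combined statistics on the raw P-value distribution.
#'
#' @param pvals Numeric vector of probabilities (no missing values).
#' @return Fractional ranks in (0, 1), order-preserving.
#' @examples
#' fractional_ranks(c(0.2, 0.01, 0.99)) # 0.50 0.25 0.75
#' @export
fractional_ranks <- function(pvals) {
  if (length(pvals) == 0) stop("empty input", call. = FALSE)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("P values must be in [0, 1] with no missing values", call. = FALSE)
  }
  rank(pvals, ties.method = "average") / (length(pvals) + 1)
}

.simes <- function(p) {
  k <- length(p)
  min(1, min(k * sort(p) / seq_len(k)))
}

.fisher <- function(p) {
  stats::pchisq(-2 * sum(log(pmax(p, .Machine$double.xmin))),
                df = 2 * length(p), lower.tail = FALSE)
}

#' Smooth scan P values along the chromosome
#'
#' Rank-transforms the raw interaction P values genome-wide, then combines
#' each marker's window of adjacent values on the same chromosome with the
#' Simes statistic (default) or Fisher's method. Smoothing borrows strength
#' from the correlated flanking markers of a true QTL, increasing detection
#' power at the cost of broadening the called interval. Windows never span
#' chromosome boundaries; near chromosome ends the window shrinks
#' symmetrically so every marker stays at its window's center.
#'
#' @param scan A `gate_scan` tibble with a `raw_p` column, or any tibble with
#'   `marker` and `raw_p`.
#' @param map Map tibble; `scan` markers must appear in map order (sorted by
#'   chromosome then position) — unsorted input is an error, never silently
#'   reordered.
#' @param window Odd window width in markers (1 = no smoothing).
#' @param method `"simes"` or `"fisher"`.
#' @param rank Rank-transform genome-wide before combining (default TRUE).
#'   The rank transform makes the smoothing distribution-free when the raw
#'   model P values are miscalibrated, but ranks are measure-preserving
#'   (a permutation of `i/(n+1)`), so window combinations of ranks have a
#'   hard floor near `window/(n+1)` and their genome-wide BH q-values can
#'   never fall below ~1: rank-smoothed values locate peaks but cannot
#'   clear an FDR threshold. For FDR-based QTL calling combine the raw
#'   P values instead (`rank = FALSE`), as [run_pipeline()] does.
#' @return `scan` with `smoothed_p` filled in.
#' @export
smooth_pvalues <- function(scan, map, window = 3L, method = c("simes", "fisher"),
                           rank = TRUE) {
  method <- match.arg(method)
  if (window < 1 || window %% 2 == 0) stop("`window` must be odd and >= 1", call. = FALSE)
  map_sub <- map[match(scan$marker, map$marker), ]
  if (anyNA(map_sub$marker)) stop("scan contains markers absent from map", call. = FALSE)
  o <- order(map_sub$chrom, map_sub$pos_cM)
  if (!identical(o, seq_len(nrow(scan)))) {
    stop("scan must be sorted by (chromosome, position); sort before smoothing",
         call. = FALSE)
  }
  usable <- !is.na(scan$raw_p)
  r <- rep(NA_real_, nrow(scan))
  r[usable] <- if (rank) fractional_ranks(scan$raw_p[usable]) else scan$raw_p[usable]

  combine <- if (method == "simes") .simes else .fisher
  half <- (window - 1L) / 2L
  smoothed <- rep(NA_real_, nrow(scan))
  for (ch in unique(map_sub$chrom)) {
    idx <- which(map_sub$chrom == ch & usable)
    nc <- length(idx)
    for (k in seq_len(nc)) {
      h <- min(half, k - 1L, nc - k)
      smoothed[idx[k]] <- combine(r[idx[(k - h):(k + h)]])
    }
  }
  scan$smoothed_p <- smoothed
  scan
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment of a P-value vector (via
#' `stats::p.adjust`). Missing values are carried through.
#'
#' @param pvals Probabilities in `[0, 1]`.
#' @return q-values; `q >= p`, monotone in sorted-p order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) stop("empty input", call. = FALSE)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("P values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Cluster correlated adjacent markers
#'
#' Greedy merge along the map: a marker joins the current cluster when its
#' genotype r-squared with the cluster representative reaches `cluster_r2`;
#' otherwise it starts a new cluster. The representative is the most
#' complete (fewest missing calls), then leftmost, member. Dense intermated
#' maps carry runs of near-identical markers; clustering them into one
#' representation raises detection power at the cost of positional
#' resolution.
#'
#' @inheritParams coinheritance_check
#' @param cluster_r2 r-squared threshold in (0, 1].
#' @return Tibble `marker`, `chrom`, `pos_cM`, `cluster`, `representative`.
#' @export
cluster_markers <- function(geno, map, cluster_r2 = 0.99) {
  if (cluster_r2 <= 0 || cluster_r2 > 1) stop("`cluster_r2` must be in (0, 1]", call. = FALSE)
  gm <- geno_matrix(geno)
  map <- map[map$marker %in% colnames(gm), ]
  out <- map |> dplyr::select("marker", "chrom", "pos_cM")
  out$cluster <- NA_integer_
  cl <- 0L
  rep_of <- integer(0)
  for (ch in unique(out$chrom)) {
    idx <- which(out$chrom == ch)
    rep_col <- NA_integer_
    for (i in idx) {
      join <- FALSE
      if (!is.na(rep_col)) {
        r <- suppressWarnings(stats::cor(gm[, out$marker[i]], gm[, out$marker[rep_col]],
                                         use = "pairwise.complete.obs"))
        join <- !is.na(r) && r^2 >= cluster_r2
      }
      if (join) {
        out$cluster[i] <- cl
        # representative: most complete, then leftmost
        if (sum(!is.na(gm[, out$marker[i]])) > sum(!is.na(gm[, out$marker[rep_col]]))) {
          rep_col <- i
          rep_of[cl] <- i
        }
      } else {
        cl <- cl + 1L
        out$cluster[i] <- cl
        rep_col <- i
        rep_of[cl] <- i
      }
    }
  }
  out$representative <- out$marker[rep_of[out$cluster]]
  out
}

#' Call QTL intervals from q-values
#'
#' Merges maximal runs of consecutive markers with `q < fdr_alpha` on the
#' same chromosome into intervals; the peak is the minimum-q marker. A
#' single significant marker yields a zero-width interval at its position.
#'
#' @param scan Tibble with `marker` and `q_value` (e.g. a smoothed
#'   `gate_scan` after [bh_fdr()]).
#' @param map Map tibble.
#' @param fdr_alpha FDR threshold.
#' @return Tibble `chrom`, `start_cM`, `end_cM`, `peak_marker`, `peak_q`,
#'   `n_markers` (possibly empty).
#' @export
call_qtl <- function(scan, map, fdr_alpha = 0.05) {
  d <- map |>
    dplyr::select("marker", "chrom", "pos_cM") |>
    dplyr::inner_join(scan[, c("marker", "q_value")], by = "marker") |>
    dplyr::arrange(.data$chrom, .data$pos_cM)
  d$hit <- !is.na(d$q_value) & d$q_value < fdr_alpha
  if (!any(d$hit)) {
    return(tibble::tibble(chrom = integer(), start_cM = numeric(),
                          end_cM = numeric(), peak_marker = character(),
                          peak_q = numeric(), n_markers = integer()))
  }
  d |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(run = cumsum(.data$hit & !dplyr::lag(.data$hit, default = FALSE))) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$hit) |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(
      start_cM = min(.data$pos_cM), end_cM = max(.data$pos_cM),
      peak_marker = .data$marker[which.min(.data$q_value)],
      peak_q = min(.data$q_value), n_markers = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::select(-"run")
}
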