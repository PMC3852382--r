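#' Permutation probability of QTL interval overlap
#'
#' Tests whether two sets of genomic intervals (e.g. QTL for two traits)
#' colocalize more than chance expects. The observed statistic is the number
#' of `a` intervals overlapping at least one `b` interval (closed intervals,
#' cM coordinates). The null is built by re-placing the `a` intervals,
#' lengths preserved, uniformly at random on the map — chromosome chosen
#' with probability proportional to its length, start uniform on the range
#' that keeps the interval inside the chromosome — and the P value uses the
#' add-one estimator `(1 + #{perms >= observed}) / (n_perm + 1)`.
#'
#' @param a,b Tibbles with columns `chrom`, `start_cM`, `end_cM`.
#' @param map Map tibble; chromosome lengths are the maximum marker
#'   positions.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return A list of class `gate_overlap`: `p_value`, `observed`,
#'   `n_perm`, `null_mean`.
#' @export
overlap_probability <- function(a, b, map, n_perm = 10000L, seed = 1L) {
  if (!nrow(a) || !nrow(b)) stop("both interval sets must be nonempty", call. = FALSE)
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  chr_len <- tapply(map$pos_cM, map$chrom, max)
  chroms <- as.integer(names(chr_len))
  check <- function(iv, nm) {
    if (any(iv$end_cM < iv$start_cM)) stop(nm, ": interval with end < start", call. = FALSE)
    if (any(!iv$chrom %in% chroms)) stop(nm, ": chromosome not on map", call. = FALSE)
  }
  check(a, "a"); check(b, "b")
  len_a <- a$end_cM - a$start_cM
  if (any(len_a > min(chr_len))) {
    stop("an `a` interval exceeds a chromosome length; cannot re-place uniformly",
         call. = FALSE)
  }
  overlaps_b <- function(chrom, s, e) {
    any(b$chrom == chrom & b$start_cM <= e & b$end_cM >= s)
  }
  observed <- sum(purrr::pmap_lgl(
    list(a$chrom, a$start_cM, a$end_cM), overlaps_b
  ))
  set.seed(seed)
  probs <- chr_len / sum(chr_len)
  n_a <- nrow(a)
  stat <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    ch <- chroms[sample.int(length(chroms), n_a, replace = TRUE, prob = probs)]
    start <- runif(n_a, 0, chr_len[as.character(ch)] - len_a)
    stat[i] <- sum(vapply(seq_len(n_a), function(j) {
      overlaps_b(ch[j], start[j], start[j] + len_a[j])
    }, logical(1)))
  }
  structure(
    list(p_value = (1 + sum(stat >= observed)) / (n_perm + 1),
         observed = observed, n_perm = n_perm, null_mean = mean(stat)),
    class = "gate_overlap"
  )
}

#' @export
print.gate_overlap <- function(x, ...) {
  cat(sprintf("Interval overlap permutation test: observed = %d, null mean = %.2f, P = %.4g (%d permutations)\n",
              x$observed, x$null_mean, x$p_value, x$n_perm))
  invisible(x)
}
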