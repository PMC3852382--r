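#' Build a synthetic genetic map
#'
#' Generates an ordered marker map over a given number of chromosomes.
#' Positions are in centimorgans (cM), 0-based at the chromosome start.
#' Bin labels follow the maize community convention `chrom.decile`
#' (e.g. `"3.07"`), here assigned from the position decile within the
#' chromosome.
#'
#' @param n_chromosomes Number of chromosomes (>= 1).
#' @param markers_per_chromosome Markers on each chromosome (>= 1).
#' @param chrom_length Chromosome length in cM (> 0).
#' @param spacing `"even"` places markers at equal intervals from 0 to
#'   `chrom_length`; `"random"` draws positions uniformly and sorts them.
#' @param seed Integer seed; the map is deterministic given the seed.
#'
#' @return A tibble with columns `marker`, `chrom`, `pos_cM`, `bin`,
#'   ordered by chromosome then position.
#' @examples
#' make_map(2, 10, 100)
#' @export
make_map <- function(n_chromosomes, markers_per_chromosome, chrom_length,
                     spacing = c("even", "random"), seed = 1L) {
  spacing <- match.arg(spacing)
  if (n_chromosomes < 1 || markers_per_chromosome < 1 || chrom_length <= 0) {
    stop("`n_chromosomes`, `markers_per_chromosome` must be >= 1 and `chrom_length` > 0",
         call. = FALSE)
  }
  set.seed(seed)
  m <- markers_per_chromosome
  pos_one <- function() {
    if (spacing == "even") {
      if (m == 1) 0 else seq(0, chrom_length, length.out = m)
    } else {
      sort(stats::runif(m, 0, chrom_length))
    }
  }
  purrr::map_dfr(seq_len(n_chromosomes), function(ch) {
    pos <- pos_one()
    tibble::tibble(
      marker = sprintf("m%02d_%03d", ch, seq_len(m)),
      chrom = as.integer(ch),
      pos_cM = pos,
      bin = sprintf("%d.%02d", ch, pmin(9L, as.integer(floor(10 * pos / chrom_length))))
    )
  })
}

validate_map <- function(map) {
  req <- c("marker", "chrom", "pos_cM", "bin")
  missing_cols <- setdiff(req, names(map))
  if (length(missing_cols)) {
    stop("map is missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(map$marker)) stop("marker names must be unique", call. = FALSE)
  ok <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(sorted = !is.unsorted(.data$pos_cM), .groups = "drop")
  if (!all(ok$sorted)) {
    stop("positions must be nondecreasing within each chromosome", call. = FALSE)
  }
  invisible(map)
}

# Haldane map function: recombination fraction between adjacent markers
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

# adjacent recombination fractions per chromosome; list of numeric vectors
adjacent_r <- function(map) {
  split(map$pos_cM, map$chrom) |>
    lapply(function(p) haldane_r(diff(p)))
}
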