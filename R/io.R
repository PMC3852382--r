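#' Read and write the pipeline's tab-separated tables
#'
#' All files are TSV, UTF-8, `.` decimal, `NA` for missing, with a header
#' row. Schema violations are reported with the offending line (header = 1).
#'
#' @param path File path.
#' @name stressgate_io
NULL

.parse_error <- function(path, lines, what) {
  stop(sprintf("%s: %s at line(s) %s", path, what,
               paste(utils::head(lines, 5), collapse = ", ")), call. = FALSE)
}

# verify required header columns before committing to a typed read
.check_header <- function(path, need) {
  hdr <- names(readr::read_tsv(path, n_max = 0,
                               col_types = readr::cols(.default = "c")))
  if (!all(need %in% hdr)) {
    .parse_error(path, 1, paste("missing column(s):",
                                paste(setdiff(need, hdr), collapse = ", ")))
  }
}

#' @rdname stressgate_io
#' @return `read_map()`: a map tibble (`marker`, `chrom`, `pos_cM`, `bin`).
#' @export
read_map <- function(path) {
  .check_header(path, c("marker", "chrom", "pos_cM", "bin"))
  d <- readr::read_tsv(path, col_types = readr::cols(
    marker = readr::col_character(), chrom = readr::col_integer(),
    pos_cM = readr::col_double(), bin = readr::col_character()
  ))
  if (anyNA(d$pos_cM)) .parse_error(path, which(is.na(d$pos_cM)) + 1, "non-numeric position")
  validate_map(d)
  d
}

#' @rdname stressgate_io
#' @return `read_genotypes()`: a genotype tibble (`line_id`, `family`,
#'   marker columns with codes A/B/NA).
#' @export
read_genotypes <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!identical(names(d)[1:2], c("line_id", "family"))) {
    .parse_error(path, 1, "first two columns must be line_id, family")
  }
  calls <- as.matrix(d[, -(1:2)])
  bad <- !is.na(calls) & !(calls %in% c("A", "B"))
  if (any(bad)) {
    rows <- unique(which(bad, arr.ind = TRUE)[, 1]) + 1
    .parse_error(path, rows,
                 paste("unknown allele code(s):",
                       paste(unique(calls[bad]), collapse = ", ")))
  }
  if (anyDuplicated(d$line_id)) {
    .parse_error(path, which(duplicated(d$line_id)) + 1, "duplicate line_id")
  }
  d
}

#' @rdname stressgate_io
#' @return `read_phenotypes()`: a long phenotype tibble (`line_id`,
#'   `family`, `environment`, `block`, `trait`, `value`).
#' @export
read_phenotypes <- function(path) {
  .check_header(path, c("line_id", "family", "environment", "block",
                        "trait", "value"))
  d <- readr::read_tsv(path, col_types = readr::cols(
    line_id = readr::col_character(), family = readr::col_character(),
    environment = readr::col_character(), block = readr::col_integer(),
    trait = readr::col_character(), value = readr::col_double()
  ))
  bad_env <- !d$environment %in% stress_environments()
  if (any(bad_env)) {
    .parse_error(path, which(bad_env) + 1,
                 paste("unknown environment(s):",
                       paste(unique(d$environment[bad_env]), collapse = ", ")))
  }
  key <- paste(d$line_id, d$environment, d$block, d$trait)
  if (anyDuplicated(key)) {
    .parse_error(path, which(duplicated(key)) + 1,
                 "duplicate (line, environment, block, trait) record")
  }
  d
}

#' @rdname stressgate_io
#' @param x Object to write.
#' @export
write_map <- function(x, path) readr::write_tsv(x, path)

#' @rdname stressgate_io
#' @export
write_genotypes <- function(x, path) readr::write_tsv(x, path)

#' @rdname stressgate_io
#' @export
write_phenotypes <- function(x, path) readr::write_tsv(x, path)

#' @rdname stressgate_io
#' @param arch An [architecture()] object.
#' @export
write_architecture <- function(arch, path) {
  stopifnot(inherits(arch, "gate_architecture"))
  jsonlite::write_json(
    list(qtl = arch$qtl, trait_mean = arch$trait_mean,
         block_sd = arch$block_sd, residual_sd = arch$residual_sd),
    path, auto_unbox = TRUE, digits = NA
  )
}

#' @rdname stressgate_io
#' @export
read_architecture <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  architecture(tibble::as_tibble(x$qtl), trait_mean = x$trait_mean,
               block_sd = x$block_sd, residual_sd = x$residual_sd)
}
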