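#' @importFrom stats runif setNames
#' @importFrom utils write.table read.delim packageVersion
NULL

IUPAC_DNA <- c("A", "C", "G", "T", "N", "M", "R", "W", "S", "Y", "K", "V", "H", "D", "B")

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; titer fold ratios are reported with
#' conventional half-up rounding (20.60/1.25 = 16.48 prints as 16.5).
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Run code with a private RNG stream; the global .Random.seed is untouched.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation so one user seed fans out to module
# seeds; double arithmetic keeps the product below 2^53 before the modulus.
derive_seed <- function(seed, salt) {
  as.integer(((as.numeric(seed) %% 2147483629) * 7919 +
                as.numeric(salt) * 104729) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# TSV writers keep a stable, header-first plain-text schema.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_report_json <- function(x, path, header = NULL) {
  if (!is.null(header)) x <- c(list(run = header), x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

report_header <- function(seed = NULL, params = list()) {
  list(
    tool = "strainlift",
    version = as.character(utils::packageVersion("strainlift")),
    seed = seed,
    params = params
  )
}
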