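#' Fragment-based average nucleotide identity
#'
#' Genome `a` is tiled into non-overlapping fragments (default 1020 bp,
#' the conventional fragment length) and each fragment is placed on genome
#' `b` with the seed-and-extend engine. Fragments passing the conventional
#' fragment-ANI acceptance rule (>= 30% identity over aligned columns and
#' >= 70% of the fragment aligned, both configurable) contribute their
#' identity; the ANI is the mean identity of accepted fragments, in
#' percent. The 95% ANI value is applied as the conventional threshold for
#' calling two genomes the same species. This estimator is deliberately
#' simple and is not a MUMmer-based ANIm reimplementation.
#'
#' @param a,b `DNAStringSet` genomes (query and subject).
#' @param fragment_length tile size in bp (default 1020).
#' @param min_identity,min_coverage fragment acceptance rule (defaults
#'   0.3 and 0.7).
#' @param species_threshold same-species ANI threshold in percent
#'   (default 95).
#' @param params an [alignment_params()] object for the placement engine.
#' @return list of class `ani_result`: `genome_a`, `genome_b`,
#'   `ani_percent`, `aligned_fraction`, `fragment_length`, `n_fragments`,
#'   `n_accepted`, `same_species_call`.
#' @export
fragment_ani <- function(a, b, fragment_length = 1020L,
                         min_identity = 0.3, min_coverage = 0.7,
                         species_threshold = 95,
                         params = alignment_params()) {
  if (max(Biostrings::width(a)) < fragment_length)
    stopf("genome 'a' is shorter than one fragment (%d bp)", fragment_length)
  params$length_fraction <- min_coverage
  params$similarity_fraction <- min_identity
  frags <- character(0)
  for (i in seq_along(a)) {
    s <- as.character(a[[i]])
    n_tiles <- nchar(s) %/% fragment_length
    if (n_tiles == 0L) next
    st <- (seq_len(n_tiles) - 1L) * fragment_length + 1L
    frags <- c(frags, substring(s, st, st + fragment_length - 1L))
  }
  pl <- place_queries(frags, b, params)
  acc <- isTRUE_vec(pl$mapped)
  ani <- if (any(acc)) 100 * mean(pl$identity_fraction[acc]) else 0
  structure(list(
    genome_a = paste(names(a), collapse = ","),
    genome_b = paste(names(b), collapse = ","),
    ani_percent = ani,
    aligned_fraction = mean(acc),
    fragment_length = as.integer(fragment_length),
    n_fragments = length(frags),
    n_accepted = sum(acc),
    same_species_call = ani >= species_threshold
  ), class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("ANI %s vs %s: %.2f%% (aligned fraction %.2f, %d/%d fragments of %d bp)\n",
              x$genome_a, x$genome_b, x$ani_percent, x$aligned_fraction,
              x$n_accepted, x$n_fragments, x$fragment_length))
  cat("same-species call (95% threshold):", x$same_species_call, "\n")
  invisible(x)
}

#' Production fold-change arithmetic
#'
#' Ratio of two mean titers, rounded half-up to one decimal (so mean
#' titers of 20.60 and 1.25 mg/L give a 16.5-fold difference). A zero
#' denominator is flagged as a not-detected comparison instead of a
#' numeric ratio.
#'
#' @param mean_a,mean_b non-negative mean titers (same units).
#' @return list of class `production_comparison`: `mean_a`, `mean_b`,
#'   `fold_change` (`NA` when `mean_b` is 0), `direction`,
#'   `not_detected`.
#' @export
fold_change <- function(mean_a, mean_b) {
  if (mean_a < 0 || mean_b < 0) stopf("titers must be non-negative")
  if (mean_b == 0) {
    return(structure(list(mean_a = mean_a, mean_b = mean_b,
                          fold_change = NA_real_, direction = "not_detected",
                          not_detected = TRUE),
                     class = "production_comparison"))
  }
  fc <- round_half_up(mean_a / mean_b, 1)
  structure(list(
    mean_a = mean_a, mean_b = mean_b, fold_change = fc,
    direction = if (fc > 1) "higher" else if (fc < 1) "lower" else "equal",
    not_detected = FALSE
  ), class = "production_comparison")
}

#' @export
print.production_comparison <- function(x, ...) {
  if (x$not_detected) cat("comparison against a non-producing condition\n")
  else cat(sprintf("%.4g / %.4g = %.1f-fold (%s)\n", x$mean_a, x$mean_b,
                   x$fold_change, x$direction))
  invisible(x)
}
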