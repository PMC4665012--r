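#' DUST masking parameters
#'
#' @param score_threshold DUST level; an interval is low-complexity when its
#'   normalized triplet score exceeds `score_threshold / 10` (default 20, the
#'   de facto standard level).
#' @param window Maximum interval length considered, in bp (default 64).
#' @return A list of class `pf_dust_params`.
#' @export
dust_params <- function(score_threshold = 20, window = 64) {
  window <- check_count(window, "window", min = 3)
  if (!is.numeric(score_threshold) || score_threshold < 0) {
    rlang::abort("`score_threshold` must be >= 0")
  }
  structure(list(score_threshold = score_threshold, window = as.integer(window)),
            class = "pf_dust_params")
}

#' Hard-mask low-complexity regions (DUST)
#'
#' Scores every interval of length 4..window by its triplet coincidence
#' statistic S = sum over the 64 ACGT triplet types of c(c-1)/2, normalized
#' by (l - 1) where l is the number of N-free triplets in the interval
#' (intervals with fewer than two scoreable triplets are never flagged).
#' Every base inside an interval whose score exceeds `score_threshold / 10`
#' is converted to N.  Output length always equals input length; only
#' substitutions to N occur, so masked panels stay coordinate-compatible.
#'
#' Low-complexity sequence is masked because it would otherwise seed
#' nonspecific capture probes.
#'
#' @param seqs Sequence or target-entry tibble (any tibble with a `seq`
#'   column), or a character vector.
#' @param params [dust_params()].
#' @return The input with the `seq` column hard-masked (and `length`
#'   refreshed if present).
#' @examples
#' dust_mask(paste0(strrep("ACGTT", 20), strrep("A", 80)))
#' @export
dust_mask <- function(seqs, params = dust_params()) {
  if (is.character(seqs)) {
    return(vapply(seqs, function(s) {
      .pf_dust_mask(normalize_residues(s), params$score_threshold / 10, params$window)
    }, character(1), USE.NAMES = FALSE))
  }
  seqs <- tibble::as_tibble(seqs)
  if (!"seq" %in% names(seqs)) rlang::abort("`seqs` must have a `seq` column")
  seqs$seq <- vapply(seqs$seq, function(s) {
    .pf_dust_mask(s, params$score_threshold / 10, params$window)
  }, character(1), USE.NAMES = FALSE)
  seqs
}
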