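#' Exhaustive fixed-step k-mer decomposition
#'
#' Decomposes each input sequence into k-mers at offsets `0, step, 2*step, ...`
#' — the exhaustive 1-bp sliding window when `step = 1`, producing every
#' possible k-bp subsequence.  Sequences shorter than `k` contribute no k-mers
#' and raise a warning (partial records are common in neighbor sets).  K-mers
#' containing N are emitted; identity scoring treats N as a mismatch.
#'
#' @param seqs Sequence tibble (or character vector) to decompose.
#' @param k K-mer length in bp (default 100, the capture probe length).
#' @param step Offset step in bp (default 1).
#' @return A tibble with columns `source_id`, `offset` (0-based start in the
#'   source), `kmer`.  For a sequence of length L >= k there are exactly
#'   `floor((L - k) / step) + 1` rows.
#' @examples
#' kmerize(tibble::tibble(id = "x", seq = strrep("ACGT", 30)), k = 100)
#' @export
kmerize <- function(seqs, k = 100, step = 1) {
  k <- check_count(k, "k")
  step <- check_count(step, "step")
  seqs <- as_seq_tbl(seqs, "seqs")
  short <- seqs$length < k
  if (any(short)) {
    rlang::warn(paste0(
      "skipping ", sum(short), " sequence(s) shorter than k = ", k, ": ",
      paste(utils::head(seqs$id[short], 5), collapse = ", ")
    ))
  }
  seqs <- seqs[!short, , drop = FALSE]
  if (nrow(seqs) == 0) {
    return(tibble::tibble(source_id = character(), offset = integer(), kmer = character()))
  }
  purrr::pmap_dfr(
    list(seqs$id, seqs$seq, seqs$length),
    function(id, seq, len) {
      offsets <- seq.int(0L, len - k, by = step)
      tibble::tibble(
        source_id = id,
        offset = offsets,
        kmer = substring(seq, offsets + 1L, offsets + k)
      )
    }
  )
}
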