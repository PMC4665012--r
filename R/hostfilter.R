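#' Host-similarity filter parameters
#'
#' @param identity_threshold Glocal identity at or above which a probe-sized
#'   window counts as host-like (default 0.75).
#' @param window Window length in bp, the probe level at which similarity is
#'   assessed (default 100).
#' @param mode `"drop_entry"` removes any entry with at least one host-like
#'   window (conservative against on-panel host sequence, the default);
#'   `"mask_window"` hard-masks only the offending windows to N.
#' @return A list of class `pf_host_params`.
#' @export
host_filter_params <- function(identity_threshold = 0.75, window = 100,
                               mode = c("drop_entry", "mask_window")) {
  structure(
    list(
      identity_threshold = check_fraction(identity_threshold, "identity_threshold",
                                          lo = 0, hi = 1, lo_open = TRUE),
      window = check_count(window, "window"),
      mode = match.arg(mode)
    ),
    class = "pf_host_params"
  )
}

#' Remove panel entries by blocked taxonomic labels
#'
#' An entry is removed when its description contains any blocked term
#' (case-insensitive substring match) — e.g. endogenous retrovirus
#' annotations, which are excluded from viral panels because of their
#' prevalence in the host genome.
#'
#' @param entries Target-entry tibble.
#' @param blocked_terms Character vector of terms.
#' @return A list with tibbles `kept` and `removed` (an exhaustive, disjoint
#'   partition of the input).
#' @export
filter_by_label <- function(entries, blocked_terms) {
  entries <- tibble::as_tibble(entries)
  if (length(blocked_terms) == 0 || nrow(entries) == 0) {
    return(list(kept = entries, removed = entries[0, , drop = FALSE]))
  }
  hit <- Reduce(`|`, lapply(blocked_terms, function(term) {
    stringr::str_detect(entries$description,
                        stringr::fixed(term, ignore_case = TRUE))
  }))
  list(kept = entries[!hit, , drop = FALSE], removed = entries[hit, , drop = FALSE])
}

# Probe-level windows of an entry: starts step window/2, final window
# right-anchored; entries shorter than the window are compared full-length.
host_windows <- function(seq, window) {
  len <- nchar(seq)
  if (len <= window) {
    return(tibble::tibble(start = 0L, end = len))
  }
  step <- max(1L, window %/% 2L)
  starts <- seq.int(0L, len - window, by = step)
  if (utils::tail(starts, 1) + window < len) starts <- c(starts, len - window)
  tibble::tibble(start = starts, end = starts + window)
}

#' Filter panel entries by sequence similarity to a host genome
#'
#' Each entry is scanned in probe-sized sliding windows (step = window/2,
#' final window right-anchored); a window hits when its best glocal identity
#' anywhere in the host genome (either strand) reaches the threshold.
#' Depending on the mode, entries with hit windows are dropped, or the hit
#' windows are hard-masked to N.
#'
#' @param entries Target-entry tibble.
#' @param host Host genome sequence (string or single-row tibble).
#' @param params [host_filter_params()].
#' @param cluster [cluster_params()] supplying the alignment scoring.
#' @return A list: `kept` (surviving entries — in `mask_window` mode all
#'   entries, with hit windows masked), `removed` (dropped entries,
#'   `drop_entry` mode only), and `report` (one row per hit window:
#'   `source_id`, `window_start`, `window_end`, `identity`).
#' @export
filter_by_host_similarity <- function(entries, host,
                                      params = host_filter_params(),
                                      cluster = cluster_params()) {
  entries <- tibble::as_tibble(entries)
  host <- as_seq_string(host, "host")
  if (nchar(host) == 0) rlang::abort("`host` must be non-empty")
  report <- list()
  hit_any <- logical(nrow(entries))
  masked_seq <- entries$seq
  for (i in seq_len(nrow(entries))) {
    wins <- host_windows(entries$seq[i], params$window)
    for (w in seq_len(nrow(wins))) {
      wseq <- substring(entries$seq[i], wins$start[w] + 1L, wins$end[w])
      res <- .pf_best_glocal_hit(
        wseq, unname(host), params$identity_threshold, cluster$rc_aware,
        cluster$match, cluster$mismatch, cluster$gap_open, cluster$gap_extend
      )
      if (isTRUE(res$hit)) {
        hit_any[i] <- TRUE
        report[[length(report) + 1]] <- tibble::tibble(
          source_id = entries$source_id[i],
          window_start = wins$start[w], window_end = wins$end[w],
          identity = res$identity
        )
        if (params$mode == "mask_window") {
          substr(masked_seq[i], wins$start[w] + 1L, wins$end[w]) <-
            strrep("N", wins$end[w] - wins$start[w])
        }
      }
    }
  }
  report <- if (length(report)) dplyr::bind_rows(report) else
    tibble::tibble(source_id = character(), window_start = integer(),
                   window_end = integer(), identity = numeric())
  if (params$mode == "drop_entry") {
    list(kept = entries[!hit_any, , drop = FALSE],
         removed = entries[hit_any, , drop = FALSE],
         report = report)
  } else {
    entries$seq <- masked_seq
    list(kept = entries, removed = entries[0, , drop = FALSE], report = report)
  }
}
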