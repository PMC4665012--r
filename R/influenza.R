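#' Build a segmented parent construct for long-sequence clustering
#'
#' For very large redundant sets the per-k-mer route is replaced by direct
#' clustering of full-length sequences.  To make greedy clustering seed on
#' the canonical references, all parents are concatenated into one linear
#' representation and split into `n_segments` near-equal segments (sizes
#' differing by at most 1 bp) that are always longer than the individual
#' strain sequences, so they are taken first as centroids.
#'
#' @param parents Sequence tibble of parent (reference) sequences.
#' @param n_segments Number of construct segments (default 6).
#' @return An object of class `pf_parent_construct`: `segments` (sequence
#'   tibble, ids `construct_seg1..n`) and `provenance` (tibble mapping each
#'   segment to the parent spans it contains: `segment_id`, `parent_id`,
#'   `parent_start`, `parent_end`, `segment_start`, `segment_end`; 0-based
#'   half-open).
#' @export
build_parent_construct <- function(parents, n_segments = 6) {
  n_segments <- check_count(n_segments, "n_segments")
  parents <- as_seq_tbl(parents, "parents")
  if (nrow(parents) == 0) rlang::abort("`parents` must contain at least one sequence")
  concat <- paste(parents$seq, collapse = "")
  total <- nchar(concat)
  if (total < n_segments) {
    rlang::abort("total parent length must be >= n_segments")
  }
  base <- total %/% n_segments
  rem <- total %% n_segments
  sizes <- rep(base, n_segments) + c(rep(1L, rem), rep(0L, n_segments - rem))
  seg_end <- cumsum(sizes)
  seg_start <- seg_end - sizes
  segments <- tibble::tibble(
    id = paste0("construct_seg", seq_len(n_segments)),
    description = paste0("construct_seg", seq_len(n_segments),
                         " concatenated parent construct"),
    seq = substring(concat, seg_start + 1L, seg_end),
    length = sizes
  )
  # parent spans in construct coordinates
  p_end <- cumsum(parents$length)
  p_start <- p_end - parents$length
  prov <- purrr::map_dfr(seq_len(n_segments), function(s) {
    keep <- which(p_start < seg_end[s] & p_end > seg_start[s])
    purrr::map_dfr(keep, function(p) {
      lo <- max(p_start[p], seg_start[s])
      hi <- min(p_end[p], seg_end[s])
      tibble::tibble(
        segment_id = segments$id[s],
        parent_id = parents$id[p],
        parent_start = lo - p_start[p],
        parent_end = hi - p_start[p],
        segment_start = lo - seg_start[s],
        segment_end = hi - seg_start[s]
      )
    })
  })
  structure(list(segments = segments, provenance = prov),
            class = "pf_parent_construct")
}

#' @export
print.pf_parent_construct <- function(x, ...) {
  cat("<pf_parent_construct>", nrow(x$segments), "segments,",
      sum(x$segments$length), "bp total\n")
  invisible(x)
}

#' Condense a large sequence set by long-sequence clustering
#'
#' Greedy centroid clustering over full-length sequences, seeded with the
#' segmented parent construct: clustering order is construct segments first,
#' then input sequences length-descending.  Sequences that fold into any
#' centroid at or above the identity threshold are redundant; the retained
#' panel additions are exactly the non-construct centroids, kept full-length
#' (no excision in this mode).
#'
#' @param parents Parent sequence tibble (concatenated into the construct).
#' @param sequences Sequence tibble of the redundant strain collection.
#' @param params [cluster_params()].
#' @param n_segments Construct segments (default 6).
#' @return An object of class `pf_condense_long`: `entries` (target entries,
#'   provenance `long_cluster_centroid`), `assignments` (from
#'   [greedy_cluster()]), `construct`, and `stats`.  [glance()] reports
#'   `input_bp`, `retained_bp`, `entries_out`, `reduction_ratio`.
#' @export
condense_long_set <- function(parents, sequences, params = cluster_params(),
                              n_segments = 6) {
  params <- as_cluster_params(params)
  construct <- build_parent_construct(parents, n_segments)
  sequences <- as_seq_tbl(sequences, "sequences")
  ord <- sequences[order(-sequences$length, seq_len(nrow(sequences))), , drop = FALSE]
  stack <- dplyr::bind_rows(
    construct$segments[, c("id", "description", "seq", "length")],
    ord[, c("id", "description", "seq", "length")]
  )
  assignments <- greedy_cluster(stack, params)
  keep_ids <- select_nonparent_centroids(assignments, construct$segments$id)
  kept <- sequences[match(keep_ids, sequences$id), , drop = FALSE]
  entries <- if (nrow(kept) > 0) {
    tibble::tibble(
      source_id = kept$id, description = kept$description,
      start = NA_integer_, end = NA_integer_,
      provenance = "long_cluster_centroid", seq = kept$seq
    )
  } else {
    empty_entries()
  }
  stats <- tibble::tibble(
    sequence_id = sequences$id, length = sequences$length,
    retained = sequences$id %in% keep_ids
  )
  structure(
    list(entries = entries, assignments = assignments,
         construct = construct, stats = stats, params = params),
    class = "pf_condense_long"
  )
}

#' @export
print.pf_condense_long <- function(x, ...) {
  g <- glance(x)
  cat("<pf_condense_long>", nrow(x$stats), "sequences |",
      g$entries_out, "retained centroids |", g$retained_bp, "of",
      g$input_bp, "bp\n")
  invisible(x)
}

#' @rdname condense_long_set
#' @param x A `pf_condense_long` object.
#' @param ... Unused.
#' @export
tidy.pf_condense_long <- function(x, ...) x$entries

#' @rdname condense_long_set
#' @export
glance.pf_condense_long <- function(x, ...) {
  input_bp <- sum(x$stats$length)
  retained_bp <- sum(x$stats$length[x$stats$retained])
  tibble::tibble(
    input_bp = input_bp, retained_bp = retained_bp,
    entries_out = nrow(x$entries),
    reduction_ratio = if (input_bp > 0) retained_bp / input_bp else 0
  )
}
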