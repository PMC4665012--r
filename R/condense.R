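#' Merge genomic intervals into contiguous spans
#'
#' Overlapping and bookended intervals (end of one equals start of the next)
#' merge into single spans; a gap of even one base keeps spans separate.
#' K-mers at consecutive offsets overlap by k-1 bp, so contiguity is the
#' natural unit for excision.
#'
#' @param intervals Tibble with columns `seq_id`, `start`, `end` (0-based
#'   half-open), all on the same `seq_id`.
#' @return A tibble of sorted, pairwise-disjoint intervals covering exactly
#'   the same positions.
#' @examples
#' merge_spans(tibble::tibble(seq_id = "x", start = c(0, 50), end = c(100, 150)))
#' @export
merge_spans <- function(intervals) {
  stopifnot(all(c("seq_id", "start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0) {
    return(tibble::tibble(seq_id = character(), start = integer(), end = integer()))
  }
  if (length(unique(intervals$seq_id)) > 1) {
    rlang::abort("merge_spans() requires all intervals on the same seq_id")
  }
  if (any(intervals$start < 0 | intervals$end <= intervals$start)) {
    rlang::abort("intervals must satisfy 0 <= start < end")
  }
  ir <- IRanges::reduce(IRanges::IRanges(intervals$start + 1L, intervals$end))
  tibble::tibble(
    seq_id = intervals$seq_id[1],
    start = IRanges::start(ir) - 1L,
    end = IRanges::end(ir)
  )
}

#' Condense neighbor genomes against a tiled parent
#'
#' The core redundancy-reduction step of capture panel design.  Each neighbor
#' is decomposed into k-mers by an exhaustive 1-bp sliding window; k-mers with
#' best glocal identity to the parent at or above the threshold are already
#' represented by the fully tiled parent and are discarded; divergent k-mers
#' are merged by their neighbor coordinates into contiguous spans, which are
#' excised as supplementary panel entries carrying the `{SQ start-end}`
#' header dialect.
#'
#' @param parent Parent (reference) sequence; length >= `k`.
#' @param neighbors Sequence tibble of same-species genome neighbors.
#' @param params [cluster_params()]; the identity threshold defaults to 0.90.
#' @param k K-mer / probe length in bp (default 100).
#' @return An object of class `pf_condense`: list with `entries` (target-entry
#'   tibble, provenance `neighbor_subseq`), `stats` (per-neighbor tibble:
#'   `neighbor_id`, `length`, `retained_bp`, `entries`), and the parameters.
#'   [glance()] gives the aggregate: `input_bp`, `retained_bp`, `entries_out`,
#'   `reduction_ratio` (retained/input; 0 for empty input).  [tidy()] returns
#'   the entries.  Neighbors shorter than `k` are skipped with a warning but
#'   still counted in `input_bp`.
#' @export
condense_neighbors <- function(parent, neighbors, params = cluster_params(), k = 100) {
  params <- as_cluster_params(params)
  k <- check_count(k, "k")
  parent_tbl <- as_seq_tbl(parent, "parent")
  if (nrow(parent_tbl) != 1) rlang::abort("`parent` must be a single sequence")
  if (parent_tbl$length < k) rlang::abort("parent must be at least k bp long")
  neighbors <- as_seq_tbl(neighbors, "neighbors")

  entries <- list()
  stats <- vector("list", nrow(neighbors))
  for (i in seq_len(nrow(neighbors))) {
    nb <- neighbors[i, ]
    if (nb$length < k) {
      rlang::warn(paste0("neighbor '", nb$id, "' is shorter than k = ", k, "; skipped"))
      stats[[i]] <- tibble::tibble(
        neighbor_id = nb$id, length = nb$length, retained_bp = 0L, entries = 0L
      )
      next
    }
    cls <- .pf_classify_kmers(
      nb$seq, parent_tbl$seq, k, 1L,
      params$identity_threshold, params$rc_aware,
      params$match, params$mismatch, params$gap_open, params$gap_extend
    )
    div_off <- which(cls == 0L) - 1L
    if (length(div_off) == 0) {
      stats[[i]] <- tibble::tibble(
        neighbor_id = nb$id, length = nb$length, retained_bp = 0L, entries = 0L
      )
      next
    }
    spans <- merge_spans(tibble::tibble(
      seq_id = nb$id, start = div_off, end = div_off + k
    ))
    entries[[length(entries) + 1]] <- tibble::tibble(
      source_id = nb$id,
      description = nb$description,
      start = spans$start,
      end = spans$end,
      provenance = "neighbor_subseq",
      seq = substring(nb$seq, spans$start + 1L, spans$end)
    )
    stats[[i]] <- tibble::tibble(
      neighbor_id = nb$id, length = nb$length,
      retained_bp = sum(spans$end - spans$start), entries = nrow(spans)
    )
  }
  empty_stats <- tibble::tibble(neighbor_id = character(), length = integer(),
                                retained_bp = integer(), entries = integer())
  structure(
    list(
      entries = if (length(entries)) dplyr::bind_rows(entries) else empty_entries(),
      stats = if (length(stats)) dplyr::bind_rows(stats) else empty_stats,
      parent_id = parent_tbl$id,
      params = params,
      k = k
    ),
    class = "pf_condense"
  )
}

#' Condense a full species set with per-neighbor reporting
#'
#' Batch wrapper around [condense_neighbors()] mirroring per-species review
#' of a reference and its genome neighbors; optionally writes the
#' per-neighbor statistics table as TSV.
#'
#' @inheritParams condense_neighbors
#' @param stats_file Optional TSV path for the per-neighbor stats.
#' @return See [condense_neighbors()].
#' @export
condense_species_set <- function(parent, neighbors, params = cluster_params(),
                                 k = 100, stats_file = NULL) {
  res <- condense_neighbors(parent, neighbors, params = params, k = k)
  if (!is.null(stats_file)) {
    utils::write.table(res$stats, stats_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  res
}

#' @export
print.pf_condense <- function(x, ...) {
  g <- glance(x)
  cat("<pf_condense> parent:", x$parent_id,
      "| neighbors:", nrow(x$stats),
      "| input:", g$input_bp, "bp | retained:", g$retained_bp, "bp",
      sprintf("(ratio %.3f)", g$reduction_ratio),
      "| entries:", g$entries_out, "\n")
  invisible(x)
}

#' @rdname condense_neighbors
#' @param x A `pf_condense` object.
#' @param ... Unused.
#' @export
tidy.pf_condense <- function(x, ...) x$entries

#' @rdname condense_neighbors
#' @export
glance.pf_condense <- function(x, ...) {
  input_bp <- sum(x$stats$length)
  retained_bp <- sum(x$stats$retained_bp)
  tibble::tibble(
    input_bp = input_bp,
    retained_bp = retained_bp,
    entries_out = sum(x$stats$entries),
    reduction_ratio = if (input_bp > 0) retained_bp / input_bp else 0
  )
}

#' Retained-span map for a condensation result
#'
#' @param object A `pf_condense` object.
#' @param ... Unused.
#' @return A ggplot showing retained (divergent) spans along each neighbor.
#' @export
autoplot.pf_condense <- function(object, ...) {
  entries <- object$entries
  if (nrow(entries) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no retained spans") +
             ggplot2::theme_void())
  }
  lens <- object$stats[, c("neighbor_id", "length")]
  ggplot2::ggplot(entries) +
    ggplot2::geom_segment(
      data = lens,
      ggplot2::aes(x = 0, xend = .data$length, y = .data$neighbor_id,
                   yend = .data$neighbor_id),
      colour = "grey80", linewidth = 1
    ) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$source_id,
                   yend = .data$source_id),
      colour = "firebrick", linewidth = 3
    ) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = "Divergent spans retained for capture") +
    ggplot2::theme_minimal()
}
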