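#' Clustering and identity-scoring parameters
#'
#' Bundles the identity threshold and alignment scoring used throughout the
#' condensation workflow.  Identity is defined as matching columns divided by
#' total alignment columns of a glocal alignment (the shorter sequence
#' end-to-end against its best placement in the longer; gaps count against
#' identity; N never matches).  Among score-optimal alignments the one with
#' the most matches (then fewest columns) defines the identity, so the value
#' does not depend on traceback tie-breaking.
#'
#' @param identity_threshold Fraction in (0, 1]; members at or above this
#'   identity to a centroid fold into it (default 0.90, the panel-design
#'   clustering threshold).
#' @param rc_aware Consider the reverse complement as well (default TRUE,
#'   the `-rev` behaviour of length-sorted greedy clustering).
#' @param match,mismatch Per-column scores (+1 / -1).
#' @param gap_open,gap_extend Affine gap costs; a gap of length g costs
#'   `gap_open + g * gap_extend` (2 + g by default).
#' @return A list of class `pf_cluster_params`.
#' @export
cluster_params <- function(identity_threshold = 0.90, rc_aware = TRUE,
                           match = 1, mismatch = -1,
                           gap_open = 2, gap_extend = 1) {
  identity_threshold <- check_fraction(identity_threshold, "identity_threshold",
                                       lo = 0, hi = 1, lo_open = TRUE)
  structure(
    list(
      identity_threshold = identity_threshold,
      rc_aware = isTRUE(rc_aware),
      match = as.integer(match), mismatch = as.integer(mismatch),
      gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend)
    ),
    class = "pf_cluster_params"
  )
}

as_cluster_params <- function(params) {
  if (inherits(params, "pf_cluster_params")) return(params)
  do.call(cluster_params, as.list(params))
}

#' Glocal percent identity between two sequences
#'
#' Aligns the shorter sequence end-to-end against its best placement in the
#' longer (free ends on the longer sequence) under affine gap scoring, and
#' reports identity = matching columns / alignment columns.  With
#' `rc_aware`, the better of the forward and reverse-complement orientation
#' is returned (forward on ties).
#'
#' @param a,b Sequences (strings or single-row sequence tibbles); non-empty.
#' @param rc_aware Consider the reverse complement (default TRUE).
#' @param params Scoring parameters from [cluster_params()].
#' @return A one-row tibble: `identity`, `orientation`, `score`, `matches`,
#'   `columns`.
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGT")
#' @export
pairwise_identity <- function(a, b, rc_aware = TRUE, params = cluster_params()) {
  params <- as_cluster_params(params)
  a <- as_seq_string(a, "a")
  b <- as_seq_string(b, "b")
  if (nchar(a) == 0 || nchar(b) == 0) rlang::abort("sequences must be non-empty")
  res <- .pf_glocal_identity(
    unname(a), unname(b), isTRUE(rc_aware),
    params$match, params$mismatch, params$gap_open, params$gap_extend
  )
  tibble::tibble(
    identity = res$identity, orientation = res$orientation,
    score = res$score, matches = res$matches, columns = res$columns
  )
}

#' Classify k-mers as represented in or divergent from a parent sequence
#'
#' A k-mer is `represented` when its best glocal identity anywhere in the
#' parent (either orientation when `rc_aware`) reaches the identity
#' threshold; such k-mers are already captured by the fully tiled parent and
#' are discarded from the panel.  K-mers below the threshold are `divergent`
#' and are retained.
#'
#' @param kmers K-mer tibble from [kmerize()] (columns `source_id`, `offset`,
#'   `kmer`), or a character vector of k-mers.
#' @param parent Parent sequence (string or single-row tibble), at least as
#'   long as the k-mers.
#' @param params [cluster_params()].
#' @return The k-mer tibble with a `status` column
#'   (`"represented"`/`"divergent"`) and `best_identity` (the best identity
#'   found among candidate placements; may be below the true best when no
#'   placement is near the threshold, in which case the classification is
#'   still exact).
#' @export
classify_kmer_vs_parent <- function(kmers, parent, params = cluster_params()) {
  params <- as_cluster_params(params)
  if (is.character(kmers)) {
    kmers <- tibble::tibble(
      source_id = names(kmers) %||% paste0("kmer", seq_along(kmers)),
      offset = NA_integer_, kmer = normalize_residues(kmers)
    )
  }
  parent <- as_seq_string(parent, "parent")
  if (any(nchar(kmers$kmer) > nchar(parent))) {
    rlang::abort("parent must be at least as long as every k-mer")
  }
  hits <- purrr::map(kmers$kmer, function(km) {
    .pf_best_glocal_hit(
      km, unname(parent), params$identity_threshold, params$rc_aware,
      params$match, params$mismatch, params$gap_open, params$gap_extend
    )
  })
  kmers$status <- ifelse(purrr::map_lgl(hits, "hit"), "represented", "divergent")
  kmers$best_identity <- purrr::map_dbl(hits, "identity")
  kmers$best_identity[kmers$best_identity < 0] <- NA_real_
  kmers
}

#' Single-pass greedy centroid clustering
#'
#' Entries are processed in the caller's order (sort length-descending with
#' designated parent constructs first to reproduce length-seeded clustering):
#' each entry folds into the first existing centroid it matches at or above
#' the identity threshold, otherwise it becomes a new centroid.  The result
#' is deterministic given the input order.
#'
#' @param entries Sequence tibble, pre-ordered by the caller.
#' @param params [cluster_params()].
#' @return A tibble with one row per entry: `member_id`, `centroid_id`,
#'   `identity`, `orientation`.  Centroids are assigned to themselves with
#'   identity 1 and forward orientation.
#' @export
greedy_cluster <- function(entries, params = cluster_params()) {
  params <- as_cluster_params(params)
  entries <- as_seq_tbl(entries, "entries")
  if (anyDuplicated(entries$id)) rlang::abort("entry ids must be unique")
  n <- nrow(entries)
  centroid_ids <- character(0)
  centroid_seqs <- character(0)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    assigned <- FALSE
    for (ci in seq_along(centroid_ids)) {
      res <- .pf_glocal_identity(
        entries$seq[i], centroid_seqs[ci], params$rc_aware,
        params$match, params$mismatch, params$gap_open, params$gap_extend
      )
      if (res$identity >= params$identity_threshold - 1e-12) {
        out[[i]] <- tibble::tibble(
          member_id = entries$id[i], centroid_id = centroid_ids[ci],
          identity = res$identity, orientation = res$orientation
        )
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      centroid_ids <- c(centroid_ids, entries$id[i])
      centroid_seqs <- c(centroid_seqs, entries$seq[i])
      out[[i]] <- tibble::tibble(
        member_id = entries$id[i], centroid_id = entries$id[i],
        identity = 1, orientation = "forward"
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Centroids outside a designated parent set
#'
#' After greedy clustering seeded with parent sequences, the centroids that
#' are not parents are the novel representatives chosen for panel inclusion.
#'
#' @param assignments Assignment tibble from [greedy_cluster()].
#' @param parent_ids Character vector of parent/construct ids.
#' @return Character vector of non-parent centroid ids in discovery order.
#' @export
select_nonparent_centroids <- function(assignments, parent_ids) {
  cents <- assignments$centroid_id[assignments$member_id == assignments$centroid_id]
  setdiff(cents, parent_ids)
}

#' Write cluster assignments as TSV
#'
#' @param assignments Tibble from [greedy_cluster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  out <- assignments
  out$identity <- sprintf("%.4f", out$identity)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
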