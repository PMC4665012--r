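#' Read alignment records from SAM or tabular files
#'
#' SAM input keeps mapped, primary, non-supplementary records; each read's
#' reference footprint (sum of reference-consuming CIGAR operations) is
#' collapsed to a single span, the simplified record these evaluation
#' metrics operate on.  The tabular format is a TSV with columns
#' `read_id`, `ref_id`, `start`, `end`, `orientation`, `quality`
#' (0-based half-open coordinates).
#'
#' @param path Input path (`.sam` or `.tsv`).
#' @param format `"auto"` (by extension), `"sam"` or `"tsv"`.
#' @return An alignment tibble: `read_id`, `ref_id`, `start`, `end`,
#'   `orientation` (`"forward"`/`"reverse"`), `quality`.
#' @export
read_alignments <- function(path, format = c("auto", "sam", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  }
  if (format == "sam") {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      rlang::abort("SAM input requires the Rsamtools package")
    }
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
    flt <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
    prm <- Rsamtools::ScanBamParam(
      flag = flt, what = c("qname", "rname", "pos", "cigar", "strand", "mapq")
    )
    rec <- Rsamtools::scanBam(bam, param = prm)[[1]]
    # reference-consuming CIGAR ops: M, D, N, =, X
    ref_width <- vapply(rec$cigar, function(cg) {
      if (is.na(cg)) return(NA_integer_)
      ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
      sum(as.integer(sub("[A-Z=]", "", ops))[grepl("[MDN=X]", ops)])
    }, integer(1), USE.NAMES = FALSE)
    tibble::tibble(
      read_id = rec$qname,
      ref_id = as.character(rec$rname),
      start = rec$pos - 1L,
      end = rec$pos - 1L + ref_width,
      orientation = ifelse(as.character(rec$strand) == "-", "reverse", "forward"),
      quality = as.integer(rec$mapq)
    )
  } else {
    tibble::as_tibble(utils::read.table(
      path, header = TRUE, sep = "\t",
      colClasses = c("character", "character", "integer", "integer",
                     "character", "integer")
    ))
  }
}

#' Choose a single reporting reference per species
#'
#' When many similar genomes are present in the alignment database, coverage
#' is reported against one reference per species: the one with the highest
#' number of reference bases covered (ties broken by lexicographically
#' smallest reference id, deterministically).
#'
#' @param covered Tibble with columns `ref_id`, `species`, `covered_bases`.
#' @return A tibble `species`, `ref_id`.
#' @export
select_species_reference <- function(covered) {
  stopifnot(all(c("ref_id", "species", "covered_bases") %in% names(covered)))
  covered |>
    dplyr::arrange(.data$species, dplyr::desc(.data$covered_bases), .data$ref_id) |>
    dplyr::distinct(.data$species, .keep_all = TRUE) |>
    dplyr::select("species", "ref_id")
}

#' Per-reference coverage report
#'
#' Per-base depth is computed from aligned spans (depth >= 1 defines
#' breadth); gaps are maximal zero-depth runs, including uncovered reference
#' ends, so gap lengths and covered bases always partition the reference
#' exactly.
#'
#' @param alignments Alignment tibble (see [read_alignments()]).
#' @param ref_id Reference to report on (alignments on other references are
#'   ignored).
#' @param ref_length Reference length in bp.
#' @return A one-row tibble of class `pf_coverage`: `ref_id`, `ref_length`,
#'   `reads`, `breadth` (percent), `mean_depth`, `n_gaps`, `median_gap`,
#'   `max_gap` (bp; 0 when no gaps), plus list-columns `gaps` (gap lengths)
#'   and `depth` (per-base depth vector).
#' @export
coverage_report <- function(alignments, ref_id, ref_length) {
  ref_length <- check_count(ref_length, "ref_length")
  aln <- alignments[alignments$ref_id == ref_id, , drop = FALSE]
  if (nrow(aln) > 0 && (any(aln$start < 0) || any(aln$end > ref_length) ||
                        any(aln$start >= aln$end))) {
    rlang::abort("alignments must lie within [0, ref_length) with start < end")
  }
  depth <- if (nrow(aln) == 0) {
    integer(ref_length)
  } else {
    as.integer(IRanges::coverage(IRanges::IRanges(aln$start + 1L, aln$end),
                                 width = ref_length))
  }
  covered <- sum(depth > 0)
  r <- rle(depth == 0)
  gaps <- r$lengths[r$values]
  out <- tibble::tibble(
    ref_id = ref_id,
    ref_length = ref_length,
    reads = nrow(aln),
    breadth = 100 * covered / ref_length,
    mean_depth = mean(depth),
    n_gaps = length(gaps),
    median_gap = if (length(gaps)) stats::median(gaps) else 0,
    max_gap = if (length(gaps)) max(gaps) else 0
  )
  out$gaps <- list(as.integer(gaps))
  out$depth <- list(depth)
  class(out) <- c("pf_coverage", class(out))
  out
}

#' Breadth-of-coverage gain
#'
#' Post-capture breadth minus pre-capture breadth, in percentage points —
#' the headline per-virus metric for how much capture enrichment improved
#' genome representation.
#'
#' @param pre,post Coverage reports from [coverage_report()] on the same
#'   reference.
#' @return Gain in percentage points.
#' @export
boc_gain <- function(pre, post) {
  if (!identical(pre$ref_id, post$ref_id)) {
    rlang::abort("boc_gain() requires reports on the same reference")
  }
  post$breadth - pre$breadth
}

#' Deduplicate reads by alignment start site
#'
#' Keeps at most one record per (reference, start, orientation) — the
#' highest-quality one, first-encountered on ties.  For L-bp reads the
#' per-base depth after deduplication is bounded by 2L (one read per start
#' and orientation), i.e. a theoretical maximum of 200x for 100-bp reads.
#'
#' @param alignments Alignment tibble.
#' @return The deduplicated tibble, in original record order.
#' @export
dedup_by_start <- function(alignments) {
  alignments |>
    dplyr::mutate(.idx = dplyr::row_number()) |>
    dplyr::group_by(.data$ref_id, .data$start, .data$orientation) |>
    dplyr::arrange(dplyr::desc(.data$quality), .data$.idx, .by_group = TRUE) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.idx) |>
    dplyr::select(-".idx")
}

#' Fold enrichment in viral read fraction
#'
#' Viral read fractions are percentages of total reads; the fold change is
#' their ratio.  When no viral reads were seen pre-capture the fold is a
#' lower bound, computed with a single-read pseudo-count and rendered with a
#' `">"` prefix (the convention used when reporting capture enrichment
#' tables).
#'
#' @param pre_viral,pre_total,post_viral,post_total Read counts; totals must
#'   be positive.
#' @return A one-row tibble: `pre_fraction`, `post_fraction` (percent),
#'   `fold`, `lower_bound` (logical), `label` (e.g. `"674"` or `">13"`).
#' @examples
#' enrichment(10, 1e6, 6740, 1e6)
#' @export
enrichment <- function(pre_viral, pre_total, post_viral, post_total) {
  if (pre_total <= 0 || post_total <= 0) rlang::abort("totals must be > 0")
  if (pre_viral < 0 || post_viral < 0) rlang::abort("counts must be >= 0")
  pre_fraction <- 100 * pre_viral / pre_total
  post_fraction <- 100 * post_viral / post_total
  lower_bound <- pre_viral == 0
  denom <- if (lower_bound) 100 * 1 / pre_total else pre_fraction
  fold <- if (denom > 0) post_fraction / denom else 0
  tibble::tibble(
    pre_fraction = pre_fraction,
    post_fraction = post_fraction,
    fold = fold,
    lower_bound = lower_bound,
    label = paste0(if (lower_bound) ">" else "", format(round(fold, 1), trim = TRUE))
  )
}

#' Recovery metrics for a divergent assembled contig
#'
#' How well a contig absent from (or divergent from) the panel was still
#' captured: the percent identity of the top-scoring local alignment (HSP)
#' between the contig and any panel entry (either strand), and the breadth
#' of post-capture read coverage along the contig.
#'
#' @param contig Contig sequence (string or single-row tibble), >= 100 bp.
#' @param panel `pf_panel` or target-entry tibble; when empty the identity is
#'   reported as `NA`.
#' @param post_alignments Alignment tibble of post-capture reads mapped to
#'   the contig (`ref_id` equal to the contig id).
#' @param cluster [cluster_params()] supplying the alignment scoring.
#' @return A one-row tibble: `top_hsp_identity` (percent), `contig_breadth`
#'   (percent).
#' @export
contig_recovery <- function(contig, panel, post_alignments,
                            cluster = cluster_params()) {
  contig_tbl <- as_seq_tbl(contig, "contig")
  if (nrow(contig_tbl) != 1) rlang::abort("`contig` must be a single sequence")
  if (contig_tbl$length < 100) rlang::abort("`contig` must be at least 100 bp")
  entries <- if (inherits(panel, "pf_panel")) panel$panel else tibble::as_tibble(panel)
  top_id <- if (nrow(entries) == 0) {
    NA_real_
  } else {
    100 * max(vapply(entries$seq, function(e) {
      .pf_local_identity(contig_tbl$seq, e, cluster$rc_aware,
                         cluster$match, cluster$mismatch,
                         cluster$gap_open, cluster$gap_extend)$identity
    }, numeric(1)))
  }
  rep <- coverage_report(post_alignments, contig_tbl$id, contig_tbl$length)
  tibble::tibble(top_hsp_identity = top_id, contig_breadth = rep$breadth)
}

#' Pre/post-capture evaluation table for one reference
#'
#' Convenience wrapper combining [coverage_report()], [boc_gain()] and
#' [enrichment()] into the per-virus row reported in capture-evaluation
#' tables.
#'
#' @param pre,post Alignment tibbles for the pre- and post-capture datasets.
#' @param ref_id,ref_length Reference evaluated.
#' @param pre_total,post_total Total read counts of the two datasets
#'   (viral counts are taken as the reads aligned to `ref_id`).
#' @return A one-row tibble mirroring the standard columns: read counts and
#'   percentages, breadth pre/post, BoC gain, mean depth, median/max gap and
#'   the fold label.
#' @export
capture_eval_table <- function(pre, post, ref_id, ref_length,
                               pre_total, post_total) {
  rp_pre <- coverage_report(pre, ref_id, ref_length)
  rp_post <- coverage_report(post, ref_id, ref_length)
  enr <- enrichment(rp_pre$reads, pre_total, rp_post$reads, post_total)
  tibble::tibble(
    ref_id = ref_id,
    pre_reads = rp_pre$reads, post_reads = rp_post$reads,
    pre_pct_reads = enr$pre_fraction, post_pct_reads = enr$post_fraction,
    fold = enr$fold, fold_label = enr$label,
    pre_breadth = rp_pre$breadth, post_breadth = rp_post$breadth,
    boc_gain = boc_gain(rp_pre, rp_post),
    post_mean_depth = rp_post$mean_depth,
    post_median_gap = rp_post$median_gap, post_max_gap = rp_post$max_gap
  )
}
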