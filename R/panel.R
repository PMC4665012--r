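#' Pool target entries from all design sources into one panel
#'
#' Combines entry sets (tiled parents, neighbor subsequences, long-cluster
#' centroids, external probes), collapses byte-identical duplicates, and
#' drops external probes whose residues already occur verbatim (either
#' strand) inside a non-probe panel entry — those probes are already directly
#' represented by the tiled targets.
#'
#' @param sources A list of target-entry tibbles (or a single tibble).
#' @return An object of class `pf_panel`: `panel` (entry tibble with an
#'   `entry_id` column) and [glance()]/[tidy()] methods.  `glance()` reports
#'   `entries`, `total_bp` and per-provenance bp fractions.
#' @export
pool_entries <- function(sources) {
  if (is.data.frame(sources)) sources <- list(sources)
  panel <- dplyr::bind_rows(sources)
  if (nrow(panel) == 0) {
    panel <- empty_entries()
  }
  panel <- dplyr::distinct(panel)
  is_probe <- panel$provenance == "external_probe"
  if (any(is_probe) && any(!is_probe)) {
    backbone <- panel$seq[!is_probe]
    drop <- vapply(panel$seq[is_probe], function(p) {
      any(stringr::str_detect(backbone, stringr::fixed(p))) ||
        any(stringr::str_detect(backbone, stringr::fixed(revcomp(p))))
    }, logical(1))
    panel <- panel[!(is_probe & replace(logical(nrow(panel)), which(is_probe), drop)), ,
                   drop = FALSE]
  }
  panel$entry_id <- entry_id(panel)
  structure(list(panel = tibble::as_tibble(panel)), class = "pf_panel")
}

#' @export
print.pf_panel <- function(x, ...) {
  g <- glance(x)
  cat("<pf_panel>", g$entries, "entries,", g$total_bp, "bp\n")
  invisible(x)
}

#' @rdname pool_entries
#' @param x A `pf_panel` object.
#' @param ... Unused.
#' @export
tidy.pf_panel <- function(x, ...) x$panel

#' @rdname pool_entries
#' @export
glance.pf_panel <- function(x, ...) {
  p <- x$panel
  total <- sum(nchar(p$seq))
  by_prov <- dplyr::summarise(
    dplyr::group_by(p, .data$provenance),
    bp = sum(nchar(.data$seq)), .groups = "drop"
  )
  by_prov$fraction <- if (total > 0) by_prov$bp / total else 0
  out <- tibble::tibble(entries = nrow(p), total_bp = total)
  out$by_provenance <- list(by_prov)
  out
}

#' Tile naive probes across panel entries
#'
#' End-to-end tiling per entry: probes of `probe_length` bp at multiples of
#' `stride`, with the final probe right-anchored to the entry end when the
#' length is not a multiple of the stride (guaranteeing terminal-base
#' coverage); entries shorter than `probe_length` yield one full-entry probe.
#' Probes lying wholly inside masked (all-N) sequence are dropped.  Vendor
#' probe redistribution/uniqueness screening is deliberately not modelled.
#'
#' @param panel `pf_panel` object or target-entry tibble.
#' @param probe_length Probe length in bp (default 100).
#' @param stride Tiling stride in bp (default 100).
#' @return A probe tibble: `probe_id` (`target_id:start-end`), `target_id`,
#'   `start`, `end` (0-based half-open on the entry), `seq`.
#' @export
tile_probes <- function(panel, probe_length = 100, stride = 100) {
  probe_length <- check_count(probe_length, "probe_length")
  stride <- check_count(stride, "stride")
  entries <- if (inherits(panel, "pf_panel")) panel$panel else tibble::as_tibble(panel)
  if (!"entry_id" %in% names(entries)) entries$entry_id <- entry_id(entries)
  purrr::pmap_dfr(
    list(entries$entry_id, entries$seq),
    function(tid, seq) {
      len <- nchar(seq)
      if (len <= probe_length) {
        starts <- 0L
        ends <- len
      } else {
        starts <- seq.int(0L, len - probe_length, by = stride)
        if (utils::tail(starts, 1) + probe_length < len) {
          starts <- c(starts, len - probe_length)
        }
        ends <- starts + probe_length
      }
      probes <- substring(seq, starts + 1L, ends)
      keep <- probes != strrep("N", nchar(probes)) # drop all-N probes
      tibble::tibble(
        probe_id = paste0(tid, ":", starts, "-", ends)[keep],
        target_id = tid,
        start = starts[keep], end = ends[keep],
        seq = probes[keep]
      )
    }
  )
}

#' Offset coverage of panel target bases by a probe set
#'
#' The design-coverage metric used to assess capture panels in silico:
#' with offset 0, the fraction of target bases directly represented inside a
#' probe; with offset 100, the fraction within 100 bp of a probe.  Masked
#' (N) bases are excluded from the denominator — they are uncapturable by
#' design.
#'
#' @param panel `pf_panel` or target-entry tibble.
#' @param probes Probe tibble from [tile_probes()].
#' @param offset Extension in bp applied to each probe span on both sides
#'   (clipped at entry bounds).
#' @return Fraction in `[0, 1]`; defined as 0 for an empty panel.
#' @export
offset_coverage <- function(panel, probes, offset = 0) {
  offset <- check_count(offset, "offset", min = 0)
  entries <- if (inherits(panel, "pf_panel")) panel$panel else tibble::as_tibble(panel)
  if (nrow(entries) == 0) return(0)
  if (!"entry_id" %in% names(entries)) entries$entry_id <- entry_id(entries)
  num <- 0
  den <- 0
  for (i in seq_len(nrow(entries))) {
    seq <- entries$seq[i]
    len <- nchar(seq)
    non_n <- which(strsplit(seq, NULL)[[1]] != "N")
    den <- den + length(non_n)
    pr <- probes[probes$target_id == entries$entry_id[i], , drop = FALSE]
    if (nrow(pr) == 0 || length(non_n) == 0) next
    lo <- pmax(0L, pr$start - offset)
    hi <- pmin(len, pr$end + offset)
    cov <- IRanges::reduce(IRanges::IRanges(lo + 1L, hi))
    covered <- IRanges::overlapsAny(IRanges::IRanges(non_n, non_n), cov)
    num <- num + sum(covered)
  }
  if (den == 0) return(0)
  num / den
}
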