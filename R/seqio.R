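#' Read a FASTA file into a sequence tibble
#'
#' Sequences are uppercased and every IUPAC code outside A/C/G/T/N (as well as
#' any other character) is mapped to N.  Record ids are the first
#' whitespace-delimited token of the header; the `description` column keeps
#' the full header line (without the leading `>`), which is also where the
#' excised-span dialect of [parse_subseq_header()] lives.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `seq`, `length`, in file
#'   order.  An empty file yields a zero-row tibble.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">x some virus", "acgtR"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("FASTA file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  non_empty <- which(nzchar(trimws(lines)))
  if (length(non_empty) == 0) {
    return(tibble::tibble(
      id = character(), description = character(),
      seq = character(), length = integer()
    ))
  }
  if (!startsWith(trimws(lines[non_empty[1]]), ">")) {
    rlang::abort(paste0(
      "malformed FASTA: line ", non_empty[1], " of ", path,
      " is not a header (expected '>')"
    ))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  seqs <- normalize_residues(as.character(set))
  empty <- which(nchar(seqs) == 0)
  if (length(empty) > 0) {
    hline <- which(startsWith(trimws(lines), ">"))[empty[1]]
    rlang::abort(paste0(
      "malformed FASTA: record '", headers[empty[1]], "' (header at line ",
      hline, ") has an empty sequence"
    ))
  }
  tibble::tibble(
    id = unname(vapply(strsplit(headers, "[ \t]+"), `[[`, character(1), 1)),
    description = unname(headers),
    seq = unname(seqs),
    length = unname(nchar(seqs))
  )
}

#' Write sequences or target entries to FASTA
#'
#' Target-entry tibbles (with `start`/`end`/`provenance` columns) are written
#' with the excised-span header dialect of [render_subseq_header()]; plain
#' sequence tibbles use their `description` as header.  Output wraps at 60
#' columns.
#'
#' @param x A sequence tibble (`id`, `description`, `seq`) or target-entry
#'   tibble (`source_id`, `description`, `start`, `end`, `provenance`, `seq`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  x <- tibble::as_tibble(x)
  if (all(c("provenance", "start", "end") %in% names(x))) {
    headers <- ifelse(is.na(x$start), x$description, render_subseq_header(x))
  } else {
    headers <- x$description %||% x$id
  }
  set <- Biostrings::BStringSet(x$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Render the excised-subsequence FASTA header for target entries
#'
#' The header is the source description followed by the excised span in curly
#' braces, rendered 1-based inclusive: `desc {SQ 2444-2644}` for the 0-based
#' half-open span `[2443, 2644)`.
#'
#' @param entries Target-entry tibble; every row must have a span
#'   (non-missing `start` and `end`).
#' @return Character vector of headers.
#' @examples
#' entries <- tibble::tibble(
#'   source_id = "A28090.1",
#'   description = "gi|1249624|emb|A28090.1| HPV42 [partial] genomic sequence",
#'   start = 2443L, end = 2644L, provenance = "neighbor_subseq",
#'   seq = strrep("A", 201)
#' )
#' render_subseq_header(entries)
#' @export
render_subseq_header <- function(entries) {
  entries <- tibble::as_tibble(entries)
  if (any(is.na(entries$start) | is.na(entries$end))) {
    rlang::abort("render_subseq_header() requires a span on every entry")
  }
  paste0(entries$description, " {SQ ", entries$start + 1L, "-", entries$end, "}")
}

#' Parse the excised-subsequence header dialect
#'
#' Extracts a trailing `{SQ a-b}` (1-based inclusive) if present, returning
#' the 0-based half-open span; headers without the tag get a missing span.
#'
#' @param header Character vector of FASTA headers.
#' @return A tibble with columns `description` (header without the tag),
#'   `start`, `end` (0-based half-open; `NA` when no span).
#' @examples
#' parse_subseq_header(c("ref1 {SQ 1-100}", "ref1"))
#' @export
parse_subseq_header <- function(header) {
  m <- regmatches(header, regexec("^(.*?)\\s*\\{SQ (\\d+)-(\\d+)\\}\\s*$", header))
  out <- purrr::map(m, function(g) {
    if (length(g) == 0) return(NULL)
    a <- as.integer(g[3]); b <- as.integer(g[4])
    if (a > b) rlang::abort(paste0("invalid span {SQ ", a, "-", b, "}: start > end"))
    list(description = g[2], start = a - 1L, end = b)
  })
  tibble::tibble(
    description = purrr::map2_chr(out, header, function(o, h) if (is.null(o)) h else o$description),
    start = purrr::map_int(out, function(o) if (is.null(o)) NA_integer_ else o$start),
    end = purrr::map_int(out, function(o) if (is.null(o)) NA_integer_ else o$end)
  )
}

#' Read a panel FASTA back into target entries
#'
#' Inverse of [write_fasta()] on entry tibbles: spans are recovered from
#' `{SQ a-b}` headers.  Provenance is not encoded in FASTA; entries are
#' labelled `external_probe` by default so a re-read panel can be pooled.
#'
#' @param path FASTA path.
#' @param provenance Provenance label to assign.
#' @return A target-entry tibble.
#' @export
read_panel <- function(path, provenance = "external_probe") {
  seqs <- read_fasta(path)
  spans <- parse_subseq_header(seqs$description)
  tibble::tibble(
    source_id = vapply(strsplit(spans$description, "[ \t]+"), `[[`, character(1), 1),
    description = spans$description,
    start = spans$start,
    end = spans$end,
    provenance = provenance,
    seq = seqs$seq
  )
}

#' Write genomic intervals as 3-column BED
#'
#' Intervals are written as-is in the package's internal convention, which is
#' BED's native one: 0-based half-open, tab-separated.
#'
#' @param intervals Tibble with columns `seq_id`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("seq_id", "start", "end") %in% names(intervals)))
  utils::write.table(
    intervals[, c("seq_id", "start", "end")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
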