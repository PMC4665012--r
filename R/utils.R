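# Internal helpers shared across modules.

# Reverse complement of ACGTN strings (vectorized).
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, NULL), function(v) {
    paste(rev(v), collapse = "")
  }, character(1)))
}

# Uppercase and map every non-ACGTN IUPAC code (and anything else) to N.
normalize_residues <- function(x) {
  gsub("[^ACGTN]", "N", toupper(x))
}

# Accept a sequence argument given as a plain string, a named string, or a
# sequence tibble (first row used unless n = "all"); returns a seqs tibble.
as_seq_tbl <- function(x, arg = "seq") {
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    return(tibble::tibble(
      id = ids, description = ids,
      seq = normalize_residues(x), length = nchar(x)
    ))
  }
  if (is.data.frame(x)) {
    if (!all(c("id", "seq") %in% names(x))) {
      rlang::abort(paste0("`", arg, "` must have columns `id` and `seq`"))
    }
    out <- tibble::as_tibble(x)
    if (!"description" %in% names(out)) out$description <- out$id
    out$length <- nchar(out$seq)
    return(out)
  }
  rlang::abort(paste0("`", arg, "` must be a character vector or a sequence tibble"))
}

# One sequence as a plain string from string / tibble input.
as_seq_string <- function(x, arg = "seq") {
  tbl <- as_seq_tbl(x, arg)
  if (nrow(tbl) != 1) {
    rlang::abort(paste0("`", arg, "` must be a single sequence (got ", nrow(tbl), ")"))
  }
  stats::setNames(tbl$seq, tbl$id)
}

check_count <- function(x, arg, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != as.integer(x)) {
    rlang::abort(paste0("`", arg, "` must be a single integer >= ", min))
  }
  as.integer(x)
}

check_fraction <- function(x, arg, lo = 0, hi = 1, lo_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && x <= hi
  if (!ok) {
    rlang::abort(paste0(
      "`", arg, "` must be a single number in ",
      if (lo_open) "(" else "[", lo, ", ", hi, "]"
    ))
  }
  as.numeric(x)
}

empty_entries <- function() {
  tibble::tibble(
    source_id = character(), description = character(),
    start = integer(), end = integer(),
    provenance = character(), seq = character()
  )
}

# Stable identifier for a target entry (span rendered 1-based inclusive).
entry_id <- function(entries) {
  ifelse(
    is.na(entries$start),
    entries$source_id,
    paste0(entries$source_id, ":", entries$start + 1L, "-", entries$end)
  )
}
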