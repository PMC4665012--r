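# Shared fixture builders (all fixtures are generated in code).

seq_tbl <- function(ids, seqs) {
  tibble::tibble(id = ids, description = ids, seq = seqs, length = nchar(seqs))
}

entry_tbl <- function(source_id, seq, description = source_id,
                      start = NA_integer_, end = NA_integer_,
                      provenance = "parent_tiled") {
  tibble::tibble(
    source_id = source_id, description = description,
    start = start, end = end, provenance = provenance, seq = seq
  )
}

# A saturating alignment set: every start position, both orientations,
# duplicated `dup` times, reads of length `read_length`.
saturating_reads <- function(ref_length, read_length = 100, dup = 2) {
  grid <- expand.grid(
    start = 0:(ref_length - read_length),
    orientation = c("forward", "reverse"),
    copy = seq_len(dup),
    stringsAsFactors = FALSE
  )
  tibble::tibble(
    read_id = paste0("r", seq_len(nrow(grid))),
    ref_id = "ref",
    start = as.integer(grid$start),
    end = as.integer(grid$start + read_length),
    orientation = grid$orientation,
    quality = sample(1:40, nrow(grid), replace = TRUE)
  )
}

# Minimal SAM text for alignment-ingestion tests.
write_test_sam <- function(path, ref = "ref", ref_len = 500) {
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:", ref, "\tLN:", ref_len),
    # mapped forward, 100M at pos 1 (1-based)
    paste(c("r1", 0, ref, 1, 60, "100M", "*", 0, 0,
            strrep("A", 100), "*"), collapse = "\t"),
    # mapped reverse (flag 16), CIGAR with insertion and deletion:
    # 40M 5I 35M 10D 20M -> reference footprint 40+35+10+20 = 105
    paste(c("r2", 16, ref, 101, 50, "40M5I35M10D20M", "*", 0, 0,
            strrep("C", 100), "*"), collapse = "\t"),
    # unmapped (flag 4): dropped
    paste(c("r3", 4, "*", 0, 0, "*", "*", 0, 0, strrep("G", 50), "*"),
          collapse = "\t"),
    # secondary (flag 256): dropped
    paste(c("r4", 256, ref, 201, 10, "50M", "*", 0, 0,
            strrep("T", 50), "*"), collapse = "\t"),
    # soft-clipped: 10S80M10S -> footprint 80
    paste(c("r5", 0, ref, 301, 30, "10S80M10S", "*", 0, 0,
            strrep("A", 100), "*"), collapse = "\t")
  )
  writeLines(lines, path)
  path
}
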