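# Independent oracles used across the suite.
#
# The alignment oracle re-derives glocal/local identity from the definition:
# affine-gap DP maximizing (score, matches, -columns) lexicographically.  It
# packs the triple into one exact double key
#     key = score * 2^24 + matches * 2^12 + (4095 - columns)
# so lexicographic max is plain max() and all transitions are additions;
# fields stay well inside their widths for the <= 300 bp inputs tested here,
# and |key| << 2^53 keeps arithmetic exact.

KEY_COLS0 <- 4095 # packed (0, 0, 0)

pack_delta <- function(score, matches, cols) score * 2^24 + matches * 2^12 - cols

unpack_key <- function(k) {
  s <- floor(k / 2^24)
  rem <- k - s * 2^24
  mt <- floor(rem / 4096)
  cols <- 4095 - (rem - mt * 4096)
  list(score = as.integer(s), matches = as.integer(mt), columns = as.integer(cols))
}

oracle_rc <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, NULL)[[1]]), collapse = ""))
}

oracle_encode <- function(s) {
  m <- match(strsplit(toupper(s), NULL)[[1]], c("A", "C", "G", "T"))
  m[is.na(m)] <- 5L
  m
}

# One orientation, pattern end-to-end against free-ended subject.
oracle_glocal_dir <- function(pat, sub, ma = 1, mi = -1, go = 2, ge = 1) {
  p <- oracle_encode(pat)
  s <- oracle_encode(sub)
  m <- length(p)
  n <- length(s)
  d_open <- pack_delta(-(go + ge), 0, 1)
  d_ext <- pack_delta(-ge, 0, 1)
  H <- rep(KEY_COLS0, n + 1) # virtual start row: (0,0,0) at every j
  E <- rep(-Inf, n + 1)
  F <- rep(-Inf, n + 1)
  for (i in seq_len(m)) {
    is_match <- (p[i] < 5) & (p[i] == s)
    dsub <- pack_delta(ifelse(is_match, ma, mi), as.integer(is_match), 1)
    prev_best <- pmax(H, E, F)
    nH <- c(-Inf, prev_best[1:n] + dsub)
    nF <- pmax(pmax(H, E) + d_open, F + d_ext)
    # E scan: E[j] = max(B[j-1] + d_open, E[j-1] + d_ext), B = pmax(nH, nF)
    B <- pmax(nH, nF)
    j <- seq_len(n)
    G <- cummax(B[j] + d_open - j * d_ext)
    nE <- c(-Inf, G + j * d_ext)
    H <- nH; E <- nE; F <- nF
  }
  best <- max(H, E, F)
  u <- unpack_key(best)
  u$identity <- if (u$columns > 0) u$matches / u$columns else 0
  u
}

# Full oracle: shorter sequence is the pattern; equal-length pairs are tried
# in both roles (symmetry); optional reverse complement; forward wins ties.
oracle_glocal <- function(a, b, rc_aware = TRUE, ma = 1, mi = -1, go = 2, ge = 1) {
  cands <- list()
  add <- function(pat, sub, orient) {
    r <- oracle_glocal_dir(pat, sub, ma, mi, go, ge)
    r$orientation <- orient
    cands[[length(cands) + 1]] <<- r
  }
  strands <- if (rc_aware) c("forward", "reverse") else "forward"
  for (orient in strands) {
    if (nchar(a) <= nchar(b)) {
      add(if (orient == "reverse") oracle_rc(a) else a, b, orient)
    }
    if (nchar(b) <= nchar(a)) {
      add(if (orient == "reverse") oracle_rc(b) else b, a, orient)
    }
  }
  keys <- vapply(cands, function(r) pack_delta(r$score, r$matches, r$columns),
                 numeric(1))
  cands[[which.max(keys)]] # which.max keeps the earliest (forward) on ties
}

# Best local alignment under the same objective (restart at (0,0,0)).
oracle_local_dir <- function(a, b, ma = 1, mi = -1, go = 2, ge = 1) {
  p <- oracle_encode(a)
  s <- oracle_encode(b)
  m <- length(p)
  n <- length(s)
  d_open <- pack_delta(-(go + ge), 0, 1)
  d_ext <- pack_delta(-ge, 0, 1)
  H <- rep(KEY_COLS0, n + 1)
  E <- rep(-Inf, n + 1)
  F <- rep(-Inf, n + 1)
  best <- -Inf
  for (i in seq_len(m)) {
    is_match <- (p[i] < 5) & (p[i] == s)
    dsub <- pack_delta(ifelse(is_match, ma, mi), as.integer(is_match), 1)
    prev_best <- pmax(H, E, F)
    nH <- pmax(c(-Inf, prev_best[1:n] + dsub), KEY_COLS0)
    nH[1] <- KEY_COLS0
    nF <- pmax(pmax(H, E) + d_open, F + d_ext)
    B <- pmax(nH, nF)
    j <- seq_len(n)
    G <- cummax(B[j] + d_open - j * d_ext)
    nE <- c(-Inf, G + j * d_ext)
    real <- nH[nH != KEY_COLS0] # exclude empty restarts (cols = 0)
    if (length(real) > 0) best <- max(best, max(real))
    H <- nH; E <- nE; F <- nF
  }
  if (!is.finite(best)) return(list(score = 0, matches = 0, columns = 0, identity = 0))
  u <- unpack_key(best)
  u$identity <- if (u$columns > 0) u$matches / u$columns else 0
  u
}

oracle_local <- function(a, b, rc_aware = TRUE, ma = 1, mi = -1, go = 2, ge = 1) {
  fwd <- oracle_local_dir(a, b, ma, mi, go, ge)
  if (!rc_aware) return(fwd)
  rev <- oracle_local_dir(oracle_rc(a), b, ma, mi, go, ge)
  fk <- pack_delta(fwd$score, fwd$matches, fwd$columns)
  rk <- pack_delta(rev$score, rev$matches, rev$columns)
  if (rk > fk) rev else fwd
}

# --- small sequence/mutation helpers -------------------------------------

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

mutate_subs <- function(seq, n_subs, positions = NULL) {
  v <- strsplit(seq, NULL)[[1]]
  if (is.null(positions)) positions <- sample(length(v), n_subs)
  for (p in positions) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# --- interval / coverage / dust oracles ----------------------------------

# Boolean-array union of [start, end) intervals; returns merged tibble.
oracle_merge <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals)
  hi <- max(intervals$end)
  covered <- logical(hi)
  for (r in seq_len(nrow(intervals))) {
    covered[(intervals$start[r] + 1):intervals$end[r]] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble::tibble(
    seq_id = intervals$seq_id[1],
    start = as.integer(starts[r$values]),
    end = as.integer(ends[r$values])
  )
}

# Per-position depth by direct counting.
oracle_depth <- function(starts, ends, ref_length) {
  d <- integer(ref_length)
  for (r in seq_along(starts)) {
    idx <- (starts[r] + 1):ends[r]
    d[idx] <- d[idx] + 1L
  }
  d
}

# Brute-force DUST: flag every interval of length 4..window whose normalized
# triplet score exceeds level/10; N-containing triplets excluded.
oracle_dust <- function(seq, level = 20, window = 64) {
  v <- strsplit(seq, NULL)[[1]]
  n <- length(v)
  mask <- logical(n)
  if (n >= 4) {
    for (i in 1:(n - 3)) {
      hi <- min(n, i + window - 1)
      for (j in (i + 3):hi) {
        piece <- paste(v[i:j], collapse = "")
        tr <- substring(piece, 1:(j - i - 1), 3:(j - i + 1))
        tr <- tr[!grepl("N", tr, fixed = TRUE)]
        l <- length(tr)
        if (l >= 2) {
          cnt <- table(tr)
          if (sum(cnt * (cnt - 1) / 2) / (l - 1) > level / 10 + 1e-12) {
            mask[i:j] <- TRUE
          }
        }
      }
    }
  }
  v[mask] <- "N"
  paste(v, collapse = "")
}
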