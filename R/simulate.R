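#' Simulate a parent (reference) genome
#'
#' I.i.d. bases at the requested GC content; fully reproducible for a fixed
#' seed.
#'
#' @param length Genome length in bp.
#' @param gc GC fraction in `[0, 1]` (default 0.5).
#' @param seed Integer seed.
#' @param id Sequence id.
#' @return A one-row sequence tibble.
#' @export
simulate_parent <- function(length, gc = 0.5, seed = 1, id = "parent") {
  length <- check_count(length, "length")
  gc <- check_fraction(gc, "gc")
  seq <- withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
  tibble::tibble(id = id, description = id, seq = seq, length = length)
}

#' Mutation specification for neighbor simulation
#'
#' @param substitution_rate Per-base substitution probability in `[0, 1)`.
#' @param indel_rate Per-base probability of starting an indel in `[0, 1)`.
#' @param indel_length Mean indel length (geometric), bp.
#' @param novel_inserts Tibble with columns `position` (0-based position in
#'   the parent at which the insert is placed) and `length`; inserts are
#'   novel random sequence absent from the parent.
#' @param seed Integer seed.
#' @return A list of class `pf_mutation_spec`.
#' @export
mutation_spec <- function(substitution_rate = 0, indel_rate = 0,
                          indel_length = 3, novel_inserts = NULL, seed = 1) {
  check_fraction(substitution_rate, "substitution_rate", hi = 0.999999)
  check_fraction(indel_rate, "indel_rate", hi = 0.999999)
  if (is.null(novel_inserts)) {
    novel_inserts <- tibble::tibble(position = integer(), length = integer())
  }
  novel_inserts <- novel_inserts[order(novel_inserts$position), , drop = FALSE]
  if (nrow(novel_inserts) > 1 &&
      any(diff(novel_inserts$position) == 0)) {
    rlang::abort("novel inserts must be at distinct positions")
  }
  structure(
    list(substitution_rate = substitution_rate, indel_rate = indel_rate,
         indel_length = indel_length, novel_inserts = novel_inserts,
         seed = seed),
    class = "pf_mutation_spec"
  )
}

#' Simulate a genome neighbor with known divergence ground truth
#'
#' Applies i.i.d. substitutions and geometric-length indels uniformly along
#' the parent, plus novel random inserts at specified positions, and returns
#' both the mutated neighbor and the truth intervals a condensation run
#' should recover: the novel-insert locations plus every probe-sized window
#' whose realized identity to the parent falls below the stated threshold.
#' The truth windows are derived from the realized non-parental base mask
#' (substituted, inserted, or indel-adjacent positions), counting a window
#' divergent when its non-parental bases exceed `floor(k * (1 - threshold))`.
#' No transition/transversion bias or sequencing-error model is applied.
#'
#' @param parent Parent sequence tibble (one row).
#' @param spec [mutation_spec()].
#' @param truth_k,truth_threshold Probe window size and identity threshold
#'   used for the truth annotation (defaults 100 and 0.90).
#' @param id Neighbor id.
#' @return A list: `neighbor` (one-row sequence tibble), `truth` (interval
#'   tibble `seq_id`, `start`, `end` in neighbor coordinates, merged), and
#'   `inserts` (realized insert intervals in neighbor coordinates).
#' @export
simulate_neighbor <- function(parent, spec = mutation_spec(),
                              truth_k = 100, truth_threshold = 0.90,
                              id = paste0(parent$id[1], "_nb")) {
  parent <- as_seq_tbl(parent, "parent")
  if (nrow(parent) != 1) rlang::abort("`parent` must be a single sequence")
  if (nrow(spec$novel_inserts) > 0 &&
      any(spec$novel_inserts$position < 0 |
          spec$novel_inserts$position > parent$length)) {
    rlang::abort("novel insert positions must lie within the parent")
  }
  bases <- c("A", "C", "G", "T")
  # substitution lookup: row = original base code, col = 1..3 alternatives
  alt_base <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                    c("A", "C", "T"), c("A", "C", "G"))
  res <- withr::with_seed(spec$seed, {
    pv <- strsplit(parent$seq, NULL)[[1]]
    L <- length(pv)
    if (spec$indel_rate == 0) {
      # vectorized path: substitutions, then novel inserts spliced in
      sv <- pv
      alt <- logical(L)
      if (spec$substitution_rate > 0) {
        idx <- which(runif(L) < spec$substitution_rate)
        if (length(idx) > 0) {
          code <- match(pv[idx], bases)
          pick <- sample.int(3L, length(idx), replace = TRUE)
          sv[idx] <- alt_base[cbind(code, pick)]
          alt[idx] <- TRUE
        }
      }
      insert_spans <- list()
      if (nrow(spec$novel_inserts) > 0) {
        pieces <- list()
        apieces <- list()
        cursor <- 0L # parent position consumed so far
        emitted <- 0L
        for (r in seq_len(nrow(spec$novel_inserts))) {
          at <- spec$novel_inserts$position[r]
          len <- spec$novel_inserts$length[r]
          if (at > cursor) {
            pieces[[length(pieces) + 1]] <- sv[(cursor + 1):at]
            apieces[[length(apieces) + 1]] <- alt[(cursor + 1):at]
            emitted <- emitted + (at - cursor)
            cursor <- at
          }
          pieces[[length(pieces) + 1]] <- sample(bases, len, replace = TRUE)
          apieces[[length(apieces) + 1]] <- rep(TRUE, len)
          insert_spans[[length(insert_spans) + 1]] <- c(emitted, emitted + len)
          emitted <- emitted + len
        }
        if (cursor < L) {
          pieces[[length(pieces) + 1]] <- sv[(cursor + 1):L]
          apieces[[length(apieces) + 1]] <- alt[(cursor + 1):L]
        }
        sv <- unlist(pieces)
        alt <- unlist(apieces)
      }
      list(seq = paste(sv, collapse = ""), alt = alt, inserts = insert_spans)
    } else {
      # general path with indels: preallocated walk along the parent
      cap <- L + sum(spec$novel_inserts$length) +
        as.integer(4 * L * spec$indel_rate * max(1, spec$indel_length)) + 64L
      out <- character(cap)
      alt <- logical(cap)
      n_out <- 0L
      insert_spans <- list()
      emit <- function(chars, is_alt) {
        idx <- n_out + seq_along(chars)
        out[idx] <<- chars
        alt[idx] <<- is_alt
        n_out <<- n_out + length(chars)
      }
      ins_pos <- spec$novel_inserts$position
      ins_len <- spec$novel_inserts$length
      next_ins <- 1L
      p <- 0L
      while (TRUE) {
        while (next_ins <= length(ins_pos) && ins_pos[next_ins] == p) {
          from <- n_out
          emit(sample(bases, ins_len[next_ins], replace = TRUE), TRUE)
          insert_spans[[length(insert_spans) + 1]] <- c(from, n_out)
          next_ins <- next_ins + 1L
        }
        if (p >= L) break
        if (runif(1) < spec$indel_rate) {
          len <- 1L + stats::rgeom(1, 1 / max(1, spec$indel_length))
          if (runif(1) < 0.5) {
            emit(sample(bases, len, replace = TRUE), TRUE)
          } else {
            p <- min(L, p + len)
            next
          }
        }
        b <- pv[p + 1L]
        if (spec$substitution_rate > 0 && runif(1) < spec$substitution_rate) {
          emit(sample(alt_base[match(b, bases), ], 1), TRUE)
        } else {
          emit(b, FALSE)
        }
        p <- p + 1L
      }
      list(seq = paste(out[seq_len(n_out)], collapse = ""),
           alt = alt[seq_len(n_out)], inserts = insert_spans)
    }
  })
  neighbor <- tibble::tibble(
    id = id, description = id, seq = res$seq, length = nchar(res$seq)
  )
  inserts <- if (length(res$inserts)) {
    tibble::tibble(
      seq_id = id,
      start = vapply(res$inserts, `[`, numeric(1), 1),
      end = vapply(res$inserts, `[`, numeric(1), 2)
    )
  } else {
    tibble::tibble(seq_id = character(), start = numeric(), end = numeric())
  }
  # divergent-window truth from realized non-parental mask
  truth <- inserts
  Ln <- neighbor$length
  if (Ln >= truth_k) {
    cs <- cumsum(c(0L, as.integer(res$alt)))
    win_alt <- cs[(truth_k + 1):(Ln + 1)] - cs[1:(Ln - truth_k + 1)]
    div <- which(win_alt > floor(truth_k * (1 - truth_threshold))) - 1L
    if (length(div) > 0) {
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        seq_id = id, start = div, end = div + truth_k
      ))
    }
  }
  truth <- if (nrow(truth) > 0) merge_spans(truth) else truth
  list(neighbor = neighbor, truth = truth, inserts = inserts)
}

#' Simulate pre/post-capture alignment sets with a known enrichment factor
#'
#' Emulates the paired datasets used to evaluate capture enrichment: a
#' pre-capture (shotgun) set in which a small fraction of reads align to the
#' viral reference, and a post-capture set in which the viral read count is
#' inflated by the enrichment factor.  Read counts are the rounded expected
#' counts (placements, orientations and qualities are random), so the
#' realized enrichment equals the requested factor up to rounding.
#'
#' @param ref_length Viral reference length, bp.
#' @param n_reads Total reads per dataset.
#' @param read_length Read length, bp (default 100).
#' @param pre_viral_fraction Fraction (not percent) of viral reads
#'   pre-capture.
#' @param enrichment_factor Multiplier on the viral fraction post-capture.
#' @param seed Integer seed.
#' @param ref_id Viral reference id (default `"target"`); non-viral reads
#'   get `ref_id = "decoy"`.
#' @return A list: `pre` and `post` alignment tibbles, plus `viral_ref`.
#' @export
simulate_alignments <- function(ref_length, n_reads, read_length = 100,
                                pre_viral_fraction = 1e-4,
                                enrichment_factor = 1, seed = 1,
                                ref_id = "target") {
  ref_length <- check_count(ref_length, "ref_length")
  n_reads <- check_count(n_reads, "n_reads", min = 0)
  if (n_reads == 0) {
    empty <- tibble::tibble(
      read_id = character(), ref_id = character(), start = integer(),
      end = integer(), orientation = character(), quality = integer()
    )
    return(list(pre = empty, post = empty, viral_ref = ref_id))
  }
  make_set <- function(n_viral, tag, seed) {
    n_viral <- min(n_viral, n_reads)
    withr::with_seed(seed, {
      v_start <- sample.int(max(1L, ref_length - read_length + 1L), n_viral,
                            replace = TRUE) - 1L
      viral <- tibble::tibble(
        read_id = paste0(tag, "_v", seq_len(n_viral)),
        ref_id = ref_id,
        start = v_start,
        end = pmin(ref_length, v_start + read_length),
        orientation = sample(c("forward", "reverse"), n_viral, replace = TRUE),
        quality = sample(20:40, n_viral, replace = TRUE)
      )
      n_other <- n_reads - n_viral
      other <- tibble::tibble(
        read_id = paste0(tag, "_d", seq_len(n_other)),
        ref_id = "decoy",
        start = sample.int(1000000L, n_other, replace = TRUE) - 1L,
        orientation = sample(c("forward", "reverse"), n_other, replace = TRUE),
        quality = sample(20:40, n_other, replace = TRUE)
      )
      other$end <- other$start + read_length
      dplyr::bind_rows(viral, other[, names(viral)])
    })
  }
  pre_viral <- round(n_reads * pre_viral_fraction)
  post_viral <- round(n_reads * pre_viral_fraction * enrichment_factor)
  list(
    pre = make_set(pre_viral, "pre", seed),
    post = make_set(post_viral, "post", seed + 1L),
    viral_ref = ref_id
  )
}
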