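aln_tbl <- function(start, end, ref_id = "ref", orientation = "forward",
                    quality = 30L) {
  tibble::tibble(
    read_id = paste0("r", seq_along(start)), ref_id = ref_id,
    start = as.integer(start), end = as.integer(end),
    orientation = orientation, quality = as.integer(quality)
  )
}

test_that("coverage report arithmetic: empty, full, and split coverage", {
  empty <- coverage_report(aln_tbl(integer(), integer()), "ref", 400)
  expect_equal(empty$breadth, 0)
  expect_equal(empty$gaps[[1]], 400L)

  full <- coverage_report(aln_tbl(0, 400), "ref", 400)
  expect_equal(full$breadth, 100)
  expect_equal(full$n_gaps, 0)
  expect_equal(full$median_gap, 0)

  split <- coverage_report(aln_tbl(c(0, 200), c(100, 300)), "ref", 400)
  expect_equal(split$breadth, 50)
  expect_equal(split$gaps[[1]], c(100L, 100L))
  expect_equal(split$median_gap, 100)
  expect_equal(split$max_gap, 100)

  expect_error(coverage_report(aln_tbl(0, 500), "ref", 400), "within")
})

test_that("breadth and gap totals conserve the reference length exactly", {
  set.seed(301)
  for (i in 1:200) {
    L <- sample(50:400, 1)
    n <- sample(0:30, 1)
    st <- sample(0:(L - 10), n, replace = TRUE)
    en <- pmin(L, st + sample(5:60, n, replace = TRUE))
    rp <- coverage_report(aln_tbl(st, en), "ref", L)
    expect_equal(sum(rp$gaps[[1]]), round(L * (1 - rp$breadth / 100)))
    expect_equal(rp$depth[[1]], oracle_depth(st, en, L))
    expect_equal(rp$mean_depth, sum(en - st) / L)
  }
})

test_that("BoC gain is the breadth difference and is antisymmetric", {
  # pre-capture breadth 2.0 %, post-capture 75.6 % on a 1000-bp reference
  pre <- coverage_report(aln_tbl(0, 20), "ref", 1000)
  post <- coverage_report(aln_tbl(0, 756), "ref", 1000)
  expect_equal(pre$breadth, 2.0)
  expect_equal(post$breadth, 75.6)
  expect_equal(boc_gain(pre, post), 73.6)
  expect_equal(boc_gain(pre, pre), 0)
  expect_equal(boc_gain(pre, post), -boc_gain(post, pre))
  other <- coverage_report(aln_tbl(0, 20), "other", 1000)
  expect_error(boc_gain(pre, other), "same reference")
})

test_that("start-site deduplication keeps one best read per orientation", {
  two_fwd <- aln_tbl(c(10, 10), c(110, 110), quality = c(30L, 20L))
  dd <- dedup_by_start(two_fwd)
  expect_equal(nrow(dd), 1)
  expect_equal(dd$quality, 30L)

  both <- aln_tbl(c(10, 10), c(110, 110), orientation = c("forward", "reverse"))
  expect_equal(nrow(dedup_by_start(both)), 2)

  # quality tie -> first encountered
  tie <- aln_tbl(c(5, 5), c(105, 105), quality = c(30L, 30L))
  expect_equal(dedup_by_start(tie)$read_id, "r1")

  # idempotence and depth domination on random sets
  set.seed(311)
  for (i in 1:20) {
    n <- sample(1:60, 1)
    st <- sample(0:50, n, replace = TRUE)
    aln <- aln_tbl(st, st + 50,
                   orientation = sample(c("forward", "reverse"), n, TRUE),
                   quality = sample(1:40, n, TRUE))
    dd <- dedup_by_start(aln)
    expect_identical(dedup_by_start(dd), dd)
    expect_true(all(oracle_depth(dd$start, dd$end, 120) <=
                      oracle_depth(aln$start, aln$end, 120)))
    expect_lte(max(table(paste(dd$start, dd$orientation))), 1)
  }
})

test_that("saturating 100-bp reads give exactly 200x interior depth after dedup", {
  set.seed(321)
  sat <- saturating_reads(500, read_length = 100, dup = 3)
  dd <- dedup_by_start(sat)
  depth <- coverage_report(dd, "ref", 500)$depth[[1]]
  expect_equal(max(depth), 200)
  expect_true(all(depth[100:401] == 200))
})

test_that("fold enrichment matches the published arithmetic and conventions", {
  e <- enrichment(10, 1e6, 6740, 1e6)
  expect_equal(e$fold, 674)
  expect_equal(e$label, "674")

  lb <- enrichment(0, 1e6, 13, 1e6)
  expect_true(lb$lower_bound)
  expect_equal(lb$fold, 13)
  expect_equal(lb$label, ">13")

  # identity and scale invariance on random counts
  set.seed(331)
  for (i in 1:30) {
    pv <- sample(1:500, 1); pt <- sample(1e4:1e6, 1)
    qv <- sample(1:5000, 1); qt <- sample(1e4:1e6, 1)
    e <- enrichment(pv, pt, qv, qt)
    expect_equal(e$fold * e$pre_fraction, e$post_fraction)
    e2 <- enrichment(3 * pv, 3 * pt, 3 * qv, 3 * qt)
    expect_equal(e2$fold, e$fold)
  }
  expect_error(enrichment(1, 0, 1, 10), "totals")
})

test_that("species reference selection maximizes covered bases with lexical ties", {
  covered <- tibble::tibble(
    ref_id = c("A", "B", "C", "D"),
    species = c("sp1", "sp1", "sp2", "sp2"),
    covered_bases = c(500L, 800L, 500L, 500L)
  )
  sel <- select_species_reference(covered)
  expect_equal(sel$ref_id[sel$species == "sp1"], "B")
  expect_equal(sel$ref_id[sel$species == "sp2"], "C") # tie -> smallest id

  set.seed(341)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    cov <- tibble::tibble(
      ref_id = paste0("g", sample(1e4, n)),
      species = sample(paste0("sp", 1:4), n, replace = TRUE),
      covered_bases = sample(0:1000, n, replace = TRUE)
    )
    sel <- select_species_reference(cov)
    for (sp in unique(cov$species)) {
      expect_equal(
        cov$covered_bases[cov$ref_id == sel$ref_id[sel$species == sp]],
        max(cov$covered_bases[cov$species == sp])
      )
    }
  }
})

test_that("contig recovery reports top-HSP identity and breadth", {
  set.seed(351)
  panel_entry <- entry_tbl("ref", random_seq(800))
  panel <- pool_entries(panel_entry)
  contig_seq <- substring(panel_entry$seq, 201, 500)
  contig <- seq_tbl("contig", contig_seq)
  full <- aln_tbl(seq(0, 250, by = 50), seq(50, 300, by = 50), ref_id = "contig")
  rec <- contig_recovery(contig, panel, full)
  expect_equal(rec$top_hsp_identity, 100)
  expect_equal(rec$contig_breadth, 100)

  # unrelated contig: low identity, no crash
  rand <- seq_tbl("contig", random_seq(300))
  rec2 <- contig_recovery(rand, panel, full)
  expect_lt(rec2$top_hsp_identity, 80)

  # empty panel -> identity absent
  rec3 <- contig_recovery(rand, pool_entries(list()), full)
  expect_true(is.na(rec3$top_hsp_identity))

  # 40% divergence recovered as ~60% identity (+-3 points)
  div <- mutate_subs(contig_seq, 120)
  rec4 <- contig_recovery(seq_tbl("contig", div), panel, full[0, ])
  expect_gt(rec4$top_hsp_identity, 57)
  expect_lt(rec4$top_hsp_identity, 63)
  # consistent with the local-alignment oracle
  expect_equal(rec4$top_hsp_identity,
               100 * oracle_local(div, panel_entry$seq)$identity)
})

test_that("SAM ingestion keeps primary mapped reads and collapses CIGAR footprints", {
  skip_if_not_installed("Rsamtools")
  tf <- withr::local_tempfile(fileext = ".sam")
  write_test_sam(tf)
  aln <- read_alignments(tf)
  expect_equal(nrow(aln), 3) # unmapped and secondary dropped
  expect_equal(aln$read_id, c("r1", "r2", "r5"))
  expect_equal(aln$start, c(0L, 100L, 300L))
  expect_equal(aln$end - aln$start, c(100L, 105L, 80L))
  expect_equal(aln$orientation, c("forward", "reverse", "forward"))
})

test_that("tabular alignments round-trip and feed the evaluation table", {
  set.seed(361)
  sim <- simulate_alignments(2000, 5000, pre_viral_fraction = 0.01,
                             enrichment_factor = 20, seed = 5)
  tf <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(sim$pre, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_alignments(tf)
  expect_equal(as.data.frame(back), as.data.frame(sim$pre))

  tab <- capture_eval_table(sim$pre, sim$post, "target", 2000,
                            pre_total = nrow(sim$pre), post_total = nrow(sim$post))
  expect_equal(tab$fold, 20, tolerance = 0.01)
  expect_equal(tab$boc_gain, tab$post_breadth - tab$pre_breadth)
})
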