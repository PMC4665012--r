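test_that("merge_spans merges overlap and bookends, equals boolean-array oracle", {
  m1 <- merge_spans(tibble::tibble(seq_id = "x", start = c(0L, 50L), end = c(100L, 150L)))
  expect_equal(m1$start, 0L)
  expect_equal(m1$end, 150L)

  m2 <- merge_spans(tibble::tibble(seq_id = "x", start = c(0L, 100L), end = c(100L, 200L)))
  expect_equal(nrow(m2), 1) # bookended intervals merge

  m3 <- merge_spans(tibble::tibble(seq_id = "x", start = c(0L, 101L), end = c(100L, 200L)))
  expect_equal(nrow(m3), 2) # a 1-bp gap keeps spans separate

  expect_error(
    merge_spans(tibble::tibble(seq_id = c("x", "y"), start = c(0L, 0L), end = c(1L, 1L))),
    "same seq_id"
  )

  set.seed(81)
  for (i in 1:100) {
    n <- sample(1:30, 1)
    start <- sample(0:400, n, replace = TRUE)
    iv <- tibble::tibble(seq_id = "s", start = start,
                         end = start + sample(1:80, n, replace = TRUE))
    got <- merge_spans(iv)
    expect_equal(got, oracle_merge(iv))
    # disjoint and sorted
    if (nrow(got) > 1) expect_true(all(got$start[-1] > got$end[-nrow(got)]))
  }
})

test_that("identical neighbor condenses to nothing; alien neighbor is kept whole", {
  set.seed(91)
  parent <- seq_tbl("p", random_seq(800))
  same <- condense_neighbors(parent, seq_tbl("n", parent$seq), k = 100)
  expect_equal(glance(same)$retained_bp, 0)
  expect_equal(glance(same)$entries_out, 0)

  alien <- condense_neighbors(parent, seq_tbl("n", strrep("CA", 250)), k = 100)
  expect_equal(glance(alien)$retained_bp, 500)
  expect_equal(nrow(alien$entries), 1)
  expect_equal(alien$entries$start, 0L)
  expect_equal(alien$entries$end, 500L)
})

test_that("a novel insert is excised as one span with at most k-1 bp flanks", {
  set.seed(101)
  parent <- simulate_parent(4000, seed = 5)
  sim <- simulate_neighbor(
    parent,
    mutation_spec(novel_inserts = tibble::tibble(position = 1500L, length = 500L),
                  seed = 6),
    id = "nb"
  )
  res <- condense_neighbors(parent, sim$neighbor, k = 100)
  expect_equal(nrow(res$entries), 1)
  e <- res$entries
  # span contains the insert (neighbor coordinates [1500, 2000))
  expect_lte(e$start, 1500L)
  expect_gte(e$end, 2000L)
  # flanks bounded by k - 1
  expect_lte(1500L - e$start, 99L)
  expect_lte(e$end - 2000L, 99L)
  # boundary k-mers verified against the DP oracle: first retained offset is
  # divergent, the one before it is represented
  km_first <- substring(sim$neighbor$seq, e$start + 1, e$start + 100)
  expect_lt(oracle_glocal(km_first, parent$seq)$identity, 0.90)
  if (e$start > 0) {
    km_before <- substring(sim$neighbor$seq, e$start, e$start + 99)
    expect_gte(oracle_glocal(km_before, parent$seq)$identity, 0.90)
  }
})

test_that("excision fidelity and conservation hold on a mixed neighbor", {
  set.seed(111)
  parent <- simulate_parent(3000, seed = 7)
  sim <- simulate_neighbor(parent, mutation_spec(substitution_rate = 0.07, seed = 8),
                           id = "nb")
  res <- condense_neighbors(parent, sim$neighbor, k = 100)
  ent <- res$entries
  # entries equal the neighbor slice at their span
  expect_true(all(ent$seq == substring(sim$neighbor$seq, ent$start + 1, ent$end)))
  # per-k-mer conservation: divergent offsets covered by spans, and every
  # span position covered by a divergent k-mer interval
  cls <- panelforge:::.pf_classify_kmers(sim$neighbor$seq, parent$seq, 100L, 1L,
                                         0.90, TRUE, 1L, -1L, 2L, 1L)
  div <- which(cls == 0L) - 1L
  if (length(div) > 0) {
    spans <- oracle_merge(tibble::tibble(seq_id = "nb", start = div, end = div + 100L))
    expect_equal(ent$start, spans$start)
    expect_equal(ent$end, spans$end)
  }
  expect_equal(glance(res)$retained_bp, sum(ent$end - ent$start))
})

test_that("condensing retained entries against the same parent keeps them whole", {
  set.seed(121)
  parent <- simulate_parent(3000, seed = 9)
  sim <- simulate_neighbor(
    parent,
    mutation_spec(substitution_rate = 0.12,
                  novel_inserts = tibble::tibble(position = 1000L, length = 300L),
                  seed = 10),
    id = "nb"
  )
  first <- condense_neighbors(parent, sim$neighbor, k = 100)
  entries_as_seqs <- seq_tbl(paste0("e", seq_len(nrow(first$entries))),
                             first$entries$seq)
  second <- condense_neighbors(parent, entries_as_seqs, k = 100)
  expect_equal(glance(second)$retained_bp, sum(nchar(entries_as_seqs$seq)))
})

test_that("retained bp is monotone in the identity threshold", {
  set.seed(131)
  parent <- simulate_parent(2000, seed = 11)
  nb <- simulate_neighbor(parent, mutation_spec(substitution_rate = 0.06, seed = 12))$neighbor
  retained <- vapply(c(0.80, 0.85, 0.90, 0.95), function(t) {
    glance(condense_neighbors(parent, nb,
                              cluster_params(identity_threshold = t), k = 100))$retained_bp
  }, numeric(1))
  expect_true(all(diff(retained) >= 0))
})

test_that("species-set wrapper reports per-neighbor rows and handles edge cases", {
  set.seed(141)
  parent <- simulate_parent(1500, seed = 13)
  none <- condense_species_set(parent, seq_tbl(character(), character()))
  expect_equal(glance(none)$input_bp, 0)
  expect_equal(glance(none)$reduction_ratio, 0) # defined 0, not NaN

  nbs <- seq_tbl(paste0("n", 1:5), rep(parent$seq, 5))
  tf <- withr::local_tempfile(fileext = ".tsv")
  ten <- condense_species_set(parent, nbs, stats_file = tf)
  expect_equal(glance(ten)$retained_bp, 0)
  expect_equal(nrow(ten$stats), 5)
  expect_true(file.exists(tf))

  # short neighbor skipped with warning, still counted in input_bp
  expect_warning(
    short <- condense_neighbors(parent, seq_tbl("tiny", random_seq(40)), k = 100),
    "shorter"
  )
  expect_equal(glance(short)$input_bp, 40)
  expect_equal(glance(short)$retained_bp, 0)
})

test_that("divergence level drives the reduction ratio in the expected direction", {
  parent <- simulate_parent(2000, seed = 17)
  low <- dplyr::bind_rows(lapply(1:3, function(i) {
    simulate_neighbor(parent, mutation_spec(substitution_rate = 0.02, seed = 100 + i),
                      id = paste0("lo", i))$neighbor
  }))
  high <- dplyr::bind_rows(lapply(1:3, function(i) {
    simulate_neighbor(parent, mutation_spec(substitution_rate = 0.15, seed = 200 + i),
                      id = paste0("hi", i))$neighbor
  }))
  expect_lt(glance(condense_neighbors(parent, low, k = 100))$reduction_ratio, 0.05)
  expect_gt(glance(condense_neighbors(parent, high, k = 100))$reduction_ratio, 0.90)
})
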