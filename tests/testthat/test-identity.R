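test_that("identity basics: self, reverse complement, constructed substitutions", {
  set.seed(11)
  a <- random_seq(100)
  self <- pairwise_identity(a, a)
  expect_equal(self$identity, 1)
  expect_equal(self$orientation, "forward")

  rc <- pairwise_identity(a, oracle_rc(a))
  expect_equal(rc$identity, 1)
  expect_equal(rc$orientation, "reverse")

  # 100-mer with exactly 10 substitutions against its source window
  b <- random_seq(400)
  km <- mutate_subs(substring(b, 151, 250), 0, positions = seq(5, 95, by = 10))
  expect_equal(pairwise_identity(km, b)$identity, 0.90)
})

test_that("glocal identities match the DP oracle exactly on random pairs", {
  set.seed(23)
  for (i in 1:60) {
    la <- sample(8:90, 1)
    lb <- sample(8:90, 1)
    a <- random_seq(la)
    b <- if (runif(1) < 0.5 && lb >= la) {
      s <- random_seq(lb)
      substr(s, 1, la) <- mutate_subs(a, sample(0:4, 1))
      s
    } else {
      random_seq(lb)
    }
    if (runif(1) < 0.2) {
      av <- strsplit(a, NULL)[[1]]
      av[sample(la, min(2, la))] <- "N"
      a <- paste(av, collapse = "")
    }
    eng <- pairwise_identity(a, b)
    orc <- oracle_glocal(a, b)
    expect_identical(eng$score, orc$score)
    expect_identical(eng$matches, orc$matches)
    expect_identical(eng$columns, orc$columns)
    expect_identical(eng$orientation, orc$orientation)
  }
})

test_that("identity is symmetric for equal lengths and rc-invariant", {
  set.seed(31)
  for (i in 1:10) {
    a <- random_seq(60)
    b <- mutate_subs(a, sample(0:20, 1))
    expect_equal(pairwise_identity(a, b)$identity,
                 pairwise_identity(b, a)$identity)
    expect_equal(pairwise_identity(oracle_rc(a), b)$identity,
                 pairwise_identity(a, b)$identity)
  }
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
})

test_that("k-mer classification is exact at the 10/11-substitution boundary", {
  set.seed(47)
  parent <- random_seq(1000)
  src <- substring(parent, 301, 400)
  pos <- sample(100, 11)
  km10 <- mutate_subs(src, 0, positions = pos[1:10])
  km11 <- mutate_subs(src, 0, positions = pos)
  # brute-force window scan with the DP oracle confirms the constructed case
  expect_equal(oracle_glocal(km10, parent)$identity, 0.90)
  expect_lt(oracle_glocal(km11, parent)$identity, 0.90)
  cls <- classify_kmer_vs_parent(c(km10, km11), parent)
  expect_equal(cls$status, c("represented", "divergent"))
  # verbatim copy and alien k-mer
  cls2 <- classify_kmer_vs_parent(c(src, strrep("C", 100)), strrep("A", 1000))
  expect_equal(cls2$status[2], "divergent")
  expect_equal(classify_kmer_vs_parent(src, parent)$status, "represented")
})

test_that("bulk classification agrees with full-DP oracle classification", {
  set.seed(53)
  parent <- random_seq(600)
  k <- 60
  params <- cluster_params()
  for (rate in c(0.02, 0.08, 0.15)) {
    nb <- mutate_subs(parent, round(600 * rate))
    bulk <- panelforge:::.pf_classify_kmers(nb, parent, as.integer(k), 5L,
                                            0.90, TRUE, 1L, -1L, 2L, 1L)
    offs <- seq(0, 600 - k, by = 5)
    for (j in seq_along(offs)) {
      km <- substring(nb, offs[j] + 1, offs[j] + k)
      expect_equal(
        bulk[j] == 1L,
        oracle_glocal(km, parent)$identity >= 0.90 - 1e-12,
        info = paste("rate", rate, "offset", offs[j])
      )
    }
  }
})

test_that("greedy clustering folds copies, isolates strangers, assigns once", {
  set.seed(61)
  x <- random_seq(200)
  two <- greedy_cluster(seq_tbl(c("x1", "x2"), c(x, x)))
  expect_equal(two$centroid_id, c("x1", "x1"))
  expect_equal(two$identity[2], 1)

  y <- random_seq(200)
  sep <- greedy_cluster(seq_tbl(c("x", "y"), c(x, y)))
  expect_equal(sep$centroid_id, c("x", "y"))

  # 1 parent + mutated copies + unrelated randoms
  parent <- random_seq(400)
  copies <- vapply(1:12, function(i) mutate_subs(parent, 20), character(1))
  randos <- vapply(1:4, function(i) random_seq(380), character(1))
  entries <- seq_tbl(c("parent", paste0("c", 1:12), paste0("r", 1:4)),
                     c(parent, copies, randos))
  asg <- greedy_cluster(entries)
  expect_equal(nrow(asg), nrow(entries))
  expect_true(all(table(asg$member_id) == 1))
  # centroids assign to themselves with identity 1 forward
  self <- asg[asg$member_id == asg$centroid_id, ]
  expect_true(all(self$identity == 1 & self$orientation == "forward"))
  # 5% substitution copies fold into the parent
  expect_true(all(asg$centroid_id[asg$member_id %in% paste0("c", 1:12)] == "parent"))
  # every fold verified against the oracle threshold
  folded <- asg[asg$member_id != asg$centroid_id, ]
  for (r in seq_len(nrow(folded))) {
    oid <- oracle_glocal(entries$seq[entries$id == folded$member_id[r]],
                         entries$seq[entries$id == folded$centroid_id[r]])
    expect_gte(oid$identity, 0.90 - 1e-12)
  }
  expect_equal(select_nonparent_centroids(asg, "parent"), paste0("r", 1:4))
})

test_that("cluster count is monotonically non-increasing in identity threshold", {
  set.seed(71)
  parent <- random_seq(150)
  entries <- seq_tbl(
    paste0("e", 1:10),
    c(parent, vapply(1:9, function(i) mutate_subs(parent, sample(5:40, 1)),
                     character(1)))
  )
  n_clusters <- vapply(c(0.95, 0.9, 0.8, 0.7), function(t) {
    asg <- greedy_cluster(entries, cluster_params(identity_threshold = t))
    length(unique(asg$centroid_id))
  }, numeric(1))
  expect_true(all(diff(n_clusters) <= 0))
})

test_that("assignment TSV dump has 4-decimal identities", {
  asg <- tibble::tibble(member_id = "a", centroid_id = "b",
                        identity = 0.912345, orientation = "forward")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_assignments(asg, tf)
  expect_match(readLines(tf)[2], "0\\.9123")
})
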