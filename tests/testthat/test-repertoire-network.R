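test_that("read collapse maps unique sequences to multiplicities, order-invariantly", {
  reads <- c("ACGT", "ACGT", "ACGG")
  v <- collapse_reads(reads)
  expect_equal(v[["ACGT"]], 2L)
  expect_equal(v[["ACGG"]], 1L)
  expect_equal(sum(v), 3L)

  distinct <- c("AAAA", "CCCC", "GGGG")
  expect_true(all(collapse_reads(distinct) == 1L))
  set.seed(1)
  expect_identical(collapse_reads(reads), collapse_reads(sample(reads)))
  expect_error(collapse_reads(character(0)), "no reads")
  expect_error(collapse_reads("acgt"), "uppercase")
})

test_that("edges join equal-length sequences at Hamming distance exactly one", {
  expect_equal(nrow(build_edges(c("ACGT", "ACGG"))), 1)
  expect_equal(nrow(build_edges(c("AAAA", "TTTT"))), 0)
  expect_equal(nrow(build_edges(c("ACGT", "ACG"))), 0)  # non-indel rule
  # N-containing sequences are excluded from edge building
  expect_equal(nrow(build_edges(c("ACNT", "ACGT", "ACGG"))), 1)
})

test_that("edge construction matches the brute-force all-pairs oracle", {
  set.seed(33)
  for (i in 1:8) {
    n <- sample(c(30, 80, 200), 1)
    len <- sample(c(8, 10), 1)
    # small alphabet stretch + mutation ladder to force edge-rich graphs
    base <- paste0(sample(c("A", "C"), len, replace = TRUE), collapse = "")
    seqs <- unique(c(base, replicate(n, {
      ch <- strsplit(base, "")[[1]]
      k <- sample(1:3, 1)
      pos <- sample(len, k)
      ch[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
      paste0(ch, collapse = "")
    })))
    got <- build_edges(seqs)
    want <- oracle_edges(seqs)
    expect_identical(edge_key(got), edge_key(want))
  }
  # mixed lengths and ambiguity codes against the same oracle
  mixed <- c("ACGTA", "ACGTT", "ACGT", "ACGG", "ACNTA")
  expect_identical(edge_key(build_edges(mixed)), edge_key(oracle_edges(mixed)))
})

test_that("clusters are connected components with stable size-then-lexicographic ids", {
  v <- c("ACGT", "ACGG", "TTTT")
  cl <- find_clusters(v, build_edges(v))
  expect_equal(cl[["ACGT"]], cl[["ACGG"]])
  expect_false(cl[["TTTT"]] == cl[["ACGT"]])
  expect_equal(cl[["ACGT"]], 1L)  # larger cluster gets id 1

  path <- c("AAAA", "AAAT", "AATT")
  clp <- find_clusters(path, build_edges(path))
  expect_equal(length(unique(clp)), 1)
})

test_that("clonality reports unique percentages and cluster sizes", {
  distinct <- c("AAAA", "CCCC", "GGGG")
  r1 <- clonality(distinct)
  expect_equal(r1$pct_unique, 100)
  expect_equal(r1$n_unique, 3)

  rep5 <- rep("ACGT", 5)
  r2 <- clonality(rep5)
  expect_equal(r2$pct_unique, 20)
  expect_equal(r2$max_cluster_size, 1)

  # duplicating a read never increases pct_unique
  r3 <- clonality(c(distinct, "AAAA"))
  expect_true(r3$pct_unique <= r1$pct_unique)
})

test_that("stronger clonal expansion lowers the unique-sequence percentage", {
  rep_a <- simulate_repertoire(repertoire_sim_config(
    n_clones = 60, clone_size_exponent = 1.5, shm_rate = 1e-3, seed = 12))
  rep_b <- simulate_repertoire(repertoire_sim_config(
    n_clones = 60, clone_size_exponent = 3.0, shm_rate = 1e-3, seed = 12))
  expect_true(clonality(rep_a$reads)$pct_unique <
                clonality(rep_b$reads)$pct_unique)
})

test_that("CC subsampling returns the original graph at full size and honours bounds", {
  rep <- simulate_repertoire(repertoire_sim_config(n_clones = 25, seed = 6))
  g <- build_repertoire_graph(rep$reads)
  full <- cc_subsample(g, n_target = nrow(g$vertices), seed = 1)
  expect_equal(full$vertices, g$vertices)
  expect_equal(edge_key(full$edges), edge_key(g$edges))
  expect_error(cc_subsample(g, 0), "n_target")
  expect_error(cc_subsample(g, nrow(g$vertices) + 1), "n_target")
})

test_that("CC subsampling preserves containment and cluster structure across seeds", {
  rep <- simulate_repertoire(repertoire_sim_config(
    n_clones = 40, clone_size_exponent = 1.8, shm_rate = 5e-3, seed = 14))
  g <- build_repertoire_graph(rep$reads)
  k <- max(g$vertices$cluster_id)
  mcs <- max(tabulate(g$vertices$cluster_id))
  n_half <- max(k, floor(nrow(g$vertices) / 2))
  for (s in 1:50) {
    sub <- cc_subsample(g, n_target = n_half, repeats = 5, seed = s)
    expect_true(all(sub$vertices$sequence %in% g$vertices$sequence))
    expect_true(all(edge_key(sub$edges) %in% edge_key(g$edges)))
    expect_true(max(tabulate(sub$vertices$cluster_id)) <= mcs)
    # every original cluster stays represented when n_target >= cluster count
    expect_equal(max(sub$vertices$cluster_id), k)
  }
})

test_that("CC subsampling with fewer targets than clusters keeps the largest clusters", {
  verts <- c("AAAA", "AAAT", "AATT", "CCCC", "GGGG")  # one triple, two singletons
  g <- build_repertoire_graph(rep(verts, times = c(3, 2, 1, 1, 1)))
  sub <- cc_subsample(g, n_target = 2, seed = 3)
  expect_equal(nrow(sub$vertices), 2)
  # the 3-vertex cluster (id 1) must be among those kept
  kept_orig <- g$vertices$cluster_id[match(sub$vertices$sequence, g$vertices$sequence)]
  expect_true(1L %in% kept_orig)
})

test_that("CC subsampling is deterministic given the seed", {
  rep <- simulate_repertoire(repertoire_sim_config(n_clones = 30, seed = 9))
  g <- build_repertoire_graph(rep$reads)
  a <- cc_subsample(g, n_target = 20, seed = 42)
  b <- cc_subsample(g, n_target = 20, seed = 42)
  expect_identical(a, b)
})
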