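test_that("relative frequencies follow the per-sample normalisation", {
  m <- matrix(c(2, 3, 5), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(unname(relative_frequency(m)[, 1]), c(0.2, 0.3, 0.5))

  u <- matrix(rep(1, 8), ncol = 2, dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  expect_true(all(relative_frequency(u) == 0.25))

  z <- matrix(c(0, 1, 3), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(unname(relative_frequency(z)[, 1]), c(0, 0.25, 0.75))

  bad <- matrix(c(1, 1, 0, 0), ncol = 2, dimnames = list(c("a", "b"), c("ok", "empty")))
  expect_error(relative_frequency(bad), "zero total reads.*empty")
})

test_that("guide log2 fold changes match direct arithmetic", {
  F <- matrix(c(1e-4, 1 - 1e-4, 0, 1), ncol = 2,
              dimnames = list(c("g1", "g2"), c("plasmid", "d70_r1")))
  samples <- data.frame(sample_id = c("plasmid", "d70_r1"),
                        timepoint = c("plasmid", "d70"),
                        replicate = c(0L, 1L),
                        is_plasmid = c(TRUE, FALSE))
  lfc <- guide_log2fc(F, samples, "d70", pseudofreq = 1e-5)
  expect_equal(lfc["g1", "r1"], log2(1e-5 / 1.1e-4))
  expect_equal(lfc["g1", "r1"], -3.459432, tolerance = 1e-6)

  # identity and exact doubling, no pseudofrequency
  F2 <- matrix(c(0.25, 0.75, 0.5, 0.5), ncol = 2,
               dimnames = list(c("g1", "g2"), c("plasmid", "d70_r1")))
  lfc2 <- guide_log2fc(F2, samples, "d70", pseudofreq = 0)
  expect_equal(lfc2["g1", "r1"], 1)

  expect_error(guide_log2fc(F, samples, "d99", pseudofreq = 0), "late timepoint")
  expect_error(guide_log2fc(F, samples[2, ], "d70", pseudofreq = 0), "plasmid")
  Fz <- matrix(c(0, 1, 0.4, 0.6), ncol = 2,
               dimnames = list(c("g1", "g2"), c("plasmid", "d70_r1")))
  expect_warning(lfcz <- guide_log2fc(Fz, samples, "d70", pseudofreq = 0),
                 "zero plasmid frequency")
  expect_true(is.na(lfcz["g1", "r1"]))
})

test_that("z-standardisation uses the population sd and is idempotent", {
  lfc <- matrix(c(0, 1, 2, 3), ncol = 1,
                dimnames = list(paste0("g", 1:4), "r1"))
  z <- guide_zscore(lfc)
  expect_equal(unname(z[, 1]),
               c(-1.3416408, -0.4472136, 0.4472136, 1.3416408),
               tolerance = 1e-7)

  two <- matrix(c(1, -1), ncol = 1, dimnames = list(c("g1", "g2"), "r1"))
  expect_equal(unname(guide_zscore(two)[, 1]), c(1, -1))

  set.seed(1)
  r <- matrix(rnorm(40), ncol = 2,
              dimnames = list(paste0("g", 1:20), c("r1", "r2")))
  zr <- guide_zscore(r)
  expect_equal(unname(colMeans(zr)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(zr, 2, function(x) sqrt(mean((x - mean(x))^2)))),
               c(1, 1), tolerance = 1e-9)
  expect_equal(guide_zscore(zr), zr, tolerance = 1e-12)

  flat <- matrix(c(1, 1, 1), ncol = 1, dimnames = list(paste0("g", 1:3), "r1"))
  expect_error(guide_zscore(flat), "zero standard deviation")
})

test_that("gene scores average the guide-replicate z grid and rank with alphabetical ties", {
  lib <- data.frame(guide_id = c("A_g1", "A_g2", "B_g1", "NTC_1"),
                    gene = c("A", "A", "B", "NTC"),
                    spacer = c("GAAA", "GCCC", "GGGG", "GTTT"),
                    is_ntc = c(FALSE, FALSE, FALSE, TRUE))
  z <- matrix(c(1, 2, -1, 0), ncol = 1,
              dimnames = list(lib$guide_id, "r1"))
  tab <- gene_crispr_score(z, lib)
  expect_equal(tab$crispr_score[tab$gene == "A"], 1.5)
  expect_equal(tab$n_guides[tab$gene == "A"], 2)

  ranks <- rank_genes(data.frame(gene = c("A", "B", "C"),
                                 crispr_score = c(2, -1, 2)))
  expect_equal(ranks, c("A", "C", "B"))
  expect_equal(rank_genes(data.frame(gene = "X", crispr_score = 0)), "X")
})

test_that("library uniformity counts guides inside the fold band of the mean", {
  expect_equal(library_uniformity(rep(0.25, 4), fold = 4), 1)
  expect_equal(library_uniformity(c(0.7, 0.1, 0.1, 0.1), fold = 2), 0)
  expect_equal(library_uniformity(c(0.7, 0.1, 0.1, 0.1), fold = 1e9), 1)
  expect_error(library_uniformity(rep(0.25, 4), fold = 1), "fold")
})

test_that("scores match the naive oracle to 1e-12 on small instances", {
  set.seed(11)
  for (rep_i in 1:10) {
    n_guides <- sample(4:10, 1)
    genes <- sample(c("A", "B", "C", "NTC"), n_guides, replace = TRUE)
    lib <- data.frame(
      guide_id = paste0("g", seq_len(n_guides)), gene = genes,
      spacer = paste0("G", strrep("A", 19)), is_ntc = genes == "NTC"
    )
    counts <- matrix(sample(1:500, n_guides * 3, replace = TRUE),
                     ncol = 3,
                     dimnames = list(lib$guide_id, c("plasmid", "d70_r1", "d70_r2")))
    scr <- tiny_screen(counts, c("plasmid", "d70", "d70"), c(0L, 1L, 2L))
    res <- score_screen(lib, scr, "d70", pseudofreq = 0)
    oracle <- oracle_score_screen(counts, scr$samples, lib, "d70")
    got <- setNames(res$gene_scores$crispr_score, res$gene_scores$gene)
    expect_equal(got[names(oracle)], oracle, tolerance = 1e-12)
  }
})

test_that("scores are invariant to uniform depth rescaling of a sample", {
  lib <- data.frame(guide_id = paste0("g", 1:6),
                    gene = rep(c("A", "B", "NTC"), each = 2),
                    spacer = paste0("G", strrep("C", 19)),
                    is_ntc = rep(c(FALSE, FALSE, TRUE), each = 2))
  counts <- matrix(sample(10:100, 18), ncol = 3,
                   dimnames = list(lib$guide_id, c("plasmid", "d70_r1", "d70_r2")))
  scr <- tiny_screen(counts, c("plasmid", "d70", "d70"), c(0L, 1L, 2L))
  scaled <- counts
  scaled[, "d70_r1"] <- scaled[, "d70_r1"] * 7L
  scr2 <- tiny_screen(scaled, c("plasmid", "d70", "d70"), c(0L, 1L, 2L))
  a <- score_screen(lib, scr, "d70", pseudofreq = 0)
  b <- score_screen(lib, scr2, "d70", pseudofreq = 0)
  expect_equal(a$gene_scores$crispr_score, b$gene_scores$crispr_score,
               tolerance = 1e-12)
})

test_that("a gene whose guides all score c gets exactly c, and absent guides are a hard error", {
  lib <- data.frame(guide_id = c("g1", "g2", "g3"),
                    gene = c("A", "A", "B"),
                    spacer = paste0("G", strrep("T", 19)),
                    is_ntc = FALSE)
  z <- matrix(c(0.7, 0.7, -0.7, 0.7, 0.7, -0.7), ncol = 2,
              dimnames = list(lib$guide_id, c("r1", "r2")))
  tab <- gene_crispr_score(z, lib)
  expect_identical(tab$crispr_score[tab$gene == "A"], 0.7)

  counts <- matrix(1:4, ncol = 2,
                   dimnames = list(c("g1", "g2"), c("plasmid", "d70_r1")))
  scr <- tiny_screen(counts, c("plasmid", "d70"), c(0L, 1L))
  expect_error(score_screen(lib, scr, "d70"), "absent from the count matrix")
})
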