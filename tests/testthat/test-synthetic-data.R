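test_that("generated libraries honour their design over random feasible configs", {
  set.seed(42)
  for (i in 1:15) {
    n_genes <- sample(3:40, 1)
    maxg <- sample(2:9, 1)
    n_ntc <- sample(0:30, 1)
    n_targeting <- sample(n_genes:(n_genes * maxg), 1)
    cfg <- library_design_config(n_genes, maxg, n_ntc,
                                 total_guides = n_targeting + n_ntc, seed = i)
    lib <- generate_library(cfg)
    expect_equal(nrow(lib), cfg$total_guides)
    expect_equal(sum(lib$is_ntc), n_ntc)
    tg <- table(lib$gene[!lib$is_ntc])
    expect_equal(length(tg), n_genes)
    expect_true(all(tg >= 1 & tg <= maxg))
    expect_silent(validate_guide_library(lib))
  }
})

test_that("library generation is deterministic given the seed and rejects infeasible designs", {
  cfg <- library_design_config(5, 3, 2, total_guides = 14, seed = 99)
  expect_identical(generate_library(cfg), generate_library(cfg))
  expect_error(library_design_config(5, 3, 2, total_guides = 20),
               "infeasible")
  expect_error(library_design_config(5, 3, 0, total_guides = 4),
               "infeasible")
  single <- generate_library(library_design_config(1, 1, 0, total_guides = 1))
  expect_equal(nrow(single), 1)
  expect_false(single$is_ntc)
})

test_that("neutral screens keep expected guide frequencies flat across timepoints", {
  lib <- generate_library(library_design_config(20, 5, 5, 85, seed = 1))
  cfg <- screen_sim_config(plasmid_dispersion = 0, depth_per_sample = 5e5,
                           timepoints = c("d7", "d21"), n_replicates = 2,
                           seed = 2)
  scr <- simulate_screen(lib, cfg)
  F <- relative_frequency(scr$counts)
  # all-neutral, dispersion 0: every sample sits at the uniform design
  # frequency up to multinomial noise
  expect_true(max(abs(F - 1 / nrow(lib))) < 6 * sqrt((1 / 85) / 5e5))
})

test_that("a positively selected gene's guides rise in frequency over time", {
  lib <- generate_library(library_design_config(20, 5, 5, 85, seed = 1))
  cfg <- screen_sim_config(fitness_map = c(GENE0001 = 0.3),
                           plasmid_dispersion = 0, depth_per_sample = 1e6,
                           timepoints = c("d7", "d21"), n_replicates = 2,
                           seed = 3)
  scr <- simulate_screen(lib, cfg)
  F <- relative_frequency(scr$counts)
  idx <- lib$gene == "GENE0001"
  mean_at <- function(tp) {
    cols <- scr$samples$sample_id[scr$samples$timepoint == tp]
    mean(F[idx, cols])
  }
  f0 <- mean(F[idx, "plasmid"])
  expect_true(f0 < mean_at("d7"))
  expect_true(mean_at("d7") < mean_at("d21"))
})

test_that("simulate_screen rejects unknown genes and nonzero NTC fitness", {
  lib <- generate_library(library_design_config(5, 3, 2, 14, seed = 1))
  expect_error(simulate_screen(lib, screen_sim_config(fitness_map = c(NOPE = 1))),
               "not in the library")
  expect_error(screen_sim_config(fitness_map = c(NTC = 0.5)), "NTC")
})

test_that("noise-free two-type barcode competition follows the logistic ratio exactly", {
  g <- 0.25
  bc <- simulate_barcodes(c("A", "B"), clones_per_construct = 1,
                          growth_advantages = c(B = g),
                          timepoints = c("d0", "d5", "d10"),
                          n_replicates = 1, depth = 1e4, noise = "none")
  F <- clone_relative_abundance(bc$counts)
  ab <- construct_mean_abundance(F, bc$clone_map, bc$samples)
  days <- c(0, 5, 10)
  expected_B <- exp(g * days) / (1 + exp(g * days))
  expect_equal(unname(ab$M["B", ]), expected_B, tolerance = 1e-9)
  expect_equal(unname(colSums(ab$M)), rep(1, 3), tolerance = 1e-9)
})

test_that("barcode counts normalise to one per sample and favour the advantaged construct", {
  bc <- simulate_barcodes(c("A", "B", "C"), clones_per_construct = 5,
                          growth_advantages = c(C = 0.3),
                          n_replicates = 2, depth = 5e4, seed = 4)
  F <- clone_relative_abundance(bc$counts)
  expect_equal(unname(colSums(F)), rep(1, ncol(F)), tolerance = 1e-12)
  ab <- construct_mean_abundance(F, bc$clone_map, bc$samples)
  expect_true(all(diff(ab$M["C", ]) > 0))
})

test_that("repertoire truth tables are internally consistent", {
  cfg <- repertoire_sim_config(n_clones = 40, replacement_rate = 0.3, seed = 7)
  rep <- simulate_repertoire(cfg)
  ev <- rep$truth[!is.na(rep$truth$event_id), ]
  expect_true(nrow(ev) > 0)
  for (id in unique(ev$event_id)) {
    pair <- ev[ev$event_id == id, ]
    expect_equal(nrow(pair), 2)
    expect_identical(pair$stem[1], pair$stem[2])          # shared stem
    expect_false(pair$v_call[1] == pair$v_call[2])        # discordant V
    # 5' junction = last 3 nt of V + N-D-N-J span
    jx <- substr(pair$ancestor,
                 nchar(pair$ancestor) - pair$ndnj_span - 2,
                 nchar(pair$ancestor))
    expect_false(identical(jx[1], jx[2]))                 # altered 5' junction
  }
  expect_equal(sum(rep$truth$n_reads), length(rep$reads))
})

test_that("replacement_rate zero plants no events and SHM-free singleton clones stay unique", {
  rep0 <- simulate_repertoire(repertoire_sim_config(n_clones = 30,
                                                    replacement_rate = 0,
                                                    seed = 3))
  expect_true(all(is.na(rep0$truth$event_id)))

  cfg <- repertoire_sim_config(n_clones = 12, clone_size_exponent = 2,
                               max_clone_size = 1, shm_rate = 0, seed = 5)
  rep <- simulate_repertoire(cfg)
  expect_equal(length(rep$reads), 12)
  g <- build_repertoire_graph(rep$reads)
  expect_equal(nrow(g$vertices), 12)
  expect_equal(nrow(g$edges), 0)
})

test_that("generators are byte-identical given the same seed", {
  cfg <- repertoire_sim_config(n_clones = 10, replacement_rate = 0.2, seed = 8)
  expect_identical(simulate_repertoire(cfg), simulate_repertoire(cfg))
  bc_cfg <- function() simulate_barcodes(c("A", "B"), 3,
                                         growth_advantages = c(B = 0.1),
                                         seed = 9)
  expect_identical(bc_cfg(), bc_cfg())
})
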