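#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume:
# the guide library, a planted-effect CRISPR screen, a barcoded construct
# competition, and a clonally expanded BCR repertoire with planted IgHV
# replacement events.

suppressMessages(library(lymphoscreen))
seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Guide library: 6000 guides, 692 genes, 250 NTCs")
lib <- generate_library(library_design_config(seed = seed))
write_guide_library(lib, file.path(out, "guide_library.csv"))

message("CRISPR screen: 10 planted positive and 10 negative genes, |s| = 0.3/day, 3 replicates")
planted <- planted_screen_config(lib, n_positive = 10, n_negative = 10,
                                 s = 0.3, seed = seed)
scr <- simulate_screen(lib, planted$config)
write_counts_tsv(scr$counts, file.path(out, "screen_counts.tsv"))
write_sample_sheet(scr$samples, file.path(out, "screen_samples.tsv"))
writeLines(c(paste("positive:", paste(planted$positive, collapse = ",")),
             paste("negative:", paste(planted$negative, collapse = ","))),
           file.path(out, "screen_planted_truth.txt"))

message("Barcode competition: four constructs, one with a 0.2/day advantage")
bc <- simulate_barcodes(c("TF_WT", "TF_MUT", "CTRL_A", "CTRL_B"),
                        clones_per_construct = 10,
                        growth_advantages = c(TF_MUT = 0.2),
                        n_replicates = 2, depth = 1e5, seed = seed)
write_counts_tsv(bc$counts, file.path(out, "barcode_counts.tsv"),
                 id_column = "clone_id")
write.csv(bc$clone_map, file.path(out, "clone_map.csv"), row.names = FALSE)
write_sample_sheet(bc$samples, file.path(out, "barcode_samples.tsv"))

message("BCR repertoire: 50 clones, power-law expansion, 20% replacement rate")
rep <- simulate_repertoire(repertoire_sim_config(
  n_clones = 50, replacement_rate = 0.2, seed = seed))
write_fasta(rep$reads, file.path(out, "repertoire_reads.fasta"))
write_airr_tsv(rep$airr, file.path(out, "repertoire_airr.tsv"))
write.table(rep$truth, file.path(out, "repertoire_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("All inputs written under ", out)
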