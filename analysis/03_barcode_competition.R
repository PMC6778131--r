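#!/usr/bin/env Rscript
# Construct-level relative abundance over the competitive culture time course.

suppressMessages(library(lymphoscreen))
data_dir <- "results/data"
out <- "results/barcodes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_counts_tsv(file.path(data_dir, "barcode_counts.tsv"))
clone_map <- read.csv(file.path(data_dir, "clone_map.csv"),
                      stringsAsFactors = FALSE)
samples <- read_sample_sheet(file.path(data_dir, "barcode_samples.tsv"))

F <- clone_relative_abundance(counts)
ab <- construct_mean_abundance(F, clone_map, samples)
traj <- abundance_trajectory(ab)
write.table(traj, file.path(out, "abundance_trajectory.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("Mean construct abundance by timepoint:")
for (tp in colnames(ab$M)) {
  message("  ", tp, ": ",
          paste(sprintf("%s=%.3f", rownames(ab$M), ab$M[, tp]), collapse = " "))
}
winner <- rownames(ab$M)[which.max(ab$M[, ncol(ab$M)])]
message("Construct dominating the final timepoint: ", winner)
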