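#!/usr/bin/env Rscript
# Score the simulated CRISPR screen at day 70: normalisation, log2 fold
# change against the plasmid library, z-standardisation, gene CRISPR scores,
# ranking and library-uniformity QC.

suppressMessages(library(lymphoscreen))
data_dir <- "results/data"
out <- "results/screen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

lib <- read_guide_library(file.path(data_dir, "guide_library.csv"))
counts <- read_counts_tsv(file.path(data_dir, "screen_counts.tsv"))
samples <- read_sample_sheet(file.path(data_dir, "screen_samples.tsv"))

res <- score_screen(lib, list(counts = counts, samples = samples), "d70")

write.table(res$gene_scores, file.path(out, "gene_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$guide_stats, file.path(out, "guide_stats.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(res$qc, file.path(out, "qc.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

truth <- readLines(file.path(data_dir, "screen_planted_truth.txt"))
positive <- strsplit(sub("positive: ", "", truth[1]), ",")[[1]]
top20 <- head(res$ranked, 20)
message(sprintf("Library uniformity (4-fold band): %.1f%% of guides",
                100 * res$qc$uniformity_fold4))
message(sprintf("Planted positive genes recovered in top 20: %d/10",
                sum(positive %in% top20)))
message("Top 10 genes by CRISPR score: ", paste(head(res$ranked, 10), collapse = ", "))
ntc <- res$gene_scores$crispr_score[res$gene_scores$gene == "NTC"]
message(sprintf("NTC pseudo-gene score: %.3f", ntc))
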