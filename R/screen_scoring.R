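#' Per-sample relative guide frequencies
#'
#' Normalises raw guide read counts to the total reads of each sample:
#' `F_i = N_i / sum_i N_i`, computed column-wise. No pseudocount is applied
#' at this stage; zeros are preserved.
#'
#' @param counts Guide x sample matrix of non-negative counts (a
#'   `screen_counts$counts` matrix or equivalent).
#' @return Matrix of the same shape whose columns each sum to 1.
#' @export
relative_frequency <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  cs <- colSums(counts)
  zero <- cs == 0
  if (any(zero)) {
    stop("sample(s) with zero total reads: ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(counts, 2, cs, "/")
}

#' Per-guide log2 fold change against the plasmid library
#'
#' For each replicate with a sample at `late_timepoint`, computes
#' `log2((F_late + pseudofreq) / (F_plasmid + pseudofreq))` per guide, using
#' the single shared plasmid reference sample. With `pseudofreq = 0`, guides
#' at zero plasmid frequency are dropped with a warning (their ratio is
#' undefined).
#'
#' @param F Guide x sample relative-frequency matrix from
#'   [relative_frequency()].
#' @param samples Sample sheet data frame (`sample_id, timepoint, replicate,
#'   is_plasmid`).
#' @param late_timepoint Timepoint label of the late sample to score.
#' @param pseudofreq Pseudo-frequency added inside the ratio; `NULL` uses the
#'   default `0.5 / median(sample depth)` (supply `depths`), 0 disables it.
#' @param depths Per-sample total read counts, required only when
#'   `pseudofreq = NULL`.
#' @return Guide x replicate matrix of log2 fold changes (columns named
#'   `r<replicate>`); guides dropped under `pseudofreq = 0` carry `NA`.
#' @export
guide_log2fc <- function(F, samples, late_timepoint, pseudofreq = NULL,
                         depths = NULL) {
  plasmid_ids <- samples$sample_id[samples$is_plasmid]
  if (length(plasmid_ids) != 1) {
    stop("exactly one plasmid reference sample is required, found ",
         length(plasmid_ids))
  }
  late <- samples[!samples$is_plasmid & samples$timepoint == late_timepoint, ]
  if (nrow(late) == 0) {
    stop("no sample at late timepoint '", late_timepoint, "'")
  }
  if (is.null(pseudofreq)) {
    if (is.null(depths)) {
      stop("supply per-sample depths to use the default pseudofrequency")
    }
    pseudofreq <- 0.5 / stats::median(depths)
  }
  if (pseudofreq < 0) stop("pseudofreq must be >= 0")

  fp <- F[, plasmid_ids]
  drop <- pseudofreq == 0 & fp == 0
  if (any(drop)) {
    warning(sum(drop), " guide(s) with zero plasmid frequency dropped (pseudofreq = 0)")
  }
  lfc <- sapply(seq_len(nrow(late)), function(i) {
    fl <- F[, late$sample_id[i]]
    out <- log2((fl + pseudofreq) / (fp + pseudofreq))
    out[drop] <- NA_real_
    out
  })
  lfc <- matrix(lfc, nrow = nrow(F),
                dimnames = list(rownames(F), paste0("r", late$replicate)))
  lfc
}

#' Z-standardise guide log2 fold changes within each replicate
#'
#' Each replicate column is centred on the mean over all library guides
#' (non-targeting controls included) and scaled by the population standard
#' deviation (divisor n) of the same set.
#'
#' @param lfc Guide x replicate log2-fold-change matrix.
#' @return Matrix of z-scores, same shape; per column, mean 0 and population
#'   sd 1 over the non-`NA` guides.
#' @export
guide_zscore <- function(lfc) {
  lfc <- as.matrix(lfc)
  apply_names <- dimnames(lfc)
  z <- apply(lfc, 2, function(x) {
    ok <- !is.na(x)
    if (sum(ok) < 2) stop("need >= 2 guides per replicate to standardise")
    m <- mean(x[ok])
    s <- sqrt(mean((x[ok] - m)^2))
    if (s == 0) stop("zero standard deviation: all log2 fold changes equal")
    (x - m) / s
  })
  z <- matrix(z, nrow = nrow(lfc), dimnames = apply_names)
  z
}

#' Per-gene CRISPR scores
#'
#' The CRISPR score of gene g is the mean of its guides' z-scores over the
#' full guide x replicate grid: `score_g = 1/(R * L_g) * sum_{i,r} Z_igr`.
#' Positive scores indicate enrichment of the gene's guides at the late
#' timepoint (a fitness advantage of knockout, tumour-suppressor-like),
#' negative scores depletion. Non-targeting controls are pooled as one
#' pseudo-gene.
#'
#' @param z Guide x replicate z-score matrix from [guide_zscore()].
#' @param library `guide_library` data frame mapping guides to genes.
#' @param ntc_label Label under which NTC guides are pooled.
#' @return A `gene_score_table` data frame (`gene, crispr_score, n_guides,
#'   n_replicates`), with the per-guide z matrix in attribute `guide_z`.
#'   Genes with no scored guides are omitted with a warning.
#' @export
gene_crispr_score <- function(z, library, ntc_label = "NTC") {
  z <- as.matrix(z)
  if (!all(rownames(z) %in% library$guide_id)) {
    stop("z matrix contains guides absent from the library")
  }
  gene <- library$gene[match(rownames(z), library$guide_id)]
  R <- ncol(z)
  rows <- lapply(split(seq_len(nrow(z)), gene), function(idx) {
    vals <- z[idx, , drop = FALSE]
    ok <- !is.na(vals)
    if (!any(ok)) return(NULL)
    data.frame(
      gene = gene[idx[1]],
      crispr_score = mean(vals[ok]),
      n_guides = length(idx),
      n_replicates = R,
      stringsAsFactors = FALSE
    )
  })
  dropped <- names(rows)[vapply(rows, is.null, logical(1))]
  if (length(dropped) > 0) {
    warning("gene(s) with no scored guides omitted: ",
            paste(dropped, collapse = ", "))
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(tab) <- NULL
  attr(tab, "guide_z") <- z
  attr(tab, "ntc_label") <- ntc_label
  class(tab) <- c("gene_score_table", "data.frame")
  tab
}

#' Rank genes by CRISPR score
#'
#' Stable descending sort by score, ties broken alphabetically by gene symbol.
#'
#' @param table A `gene_score_table`.
#' @return Character vector of gene symbols, highest score first.
#' @export
rank_genes <- function(table) {
  if (nrow(table) == 0) stop("empty gene score table")
  table$gene[order(-table$crispr_score, table$gene)]
}

#' Library representation uniformity
#'
#' Fraction of guides whose plasmid frequency lies within `fold` of the mean
#' frequency `1/m` (the band `[mean/fold, mean*fold]`, inclusive). A
#' well-synthesised library keeps ~99% of guides within four-fold.
#'
#' @param F_plasmid Numeric vector of plasmid guide frequencies (sums to 1).
#' @param fold Band half-width as a fold change; must exceed 1.
#' @return Fraction in \[0, 1\].
#' @export
library_uniformity <- function(F_plasmid, fold = 4) {
  if (fold <= 1) stop("fold must be > 1")
  m <- length(F_plasmid)
  mu <- 1 / m
  mean(F_plasmid >= mu / fold & F_plasmid <= mu * fold)
}

#' Score a pooled CRISPR screen end to end
#'
#' Runs the full chain: per-sample normalisation, per-guide log2 fold change
#' of the late sample against the plasmid library, per-replicate
#' z-standardisation, and per-gene CRISPR scores, plus ranking and a library
#' uniformity QC.
#'
#' @param library `guide_library` data frame.
#' @param screen A `screen_counts` object, or a list with `counts` and
#'   `samples` in the same layout.
#' @param late_timepoint Timepoint label to score (e.g. `"d70"`).
#' @param pseudofreq Pseudo-frequency; `NULL` (default) uses
#'   `0.5 / median(sample depth)`.
#' @param ntc_label NTC pseudo-gene label.
#' @return List with `gene_scores` (a `gene_score_table`), `ranked` (gene
#'   symbols, best first), `guide_stats` (data frame of per-guide lfc and z
#'   per replicate) and `qc` (uniformity fraction at fold 4, per-sample
#'   depths, pseudofrequency used).
#' @export
score_screen <- function(library, screen, late_timepoint,
                         pseudofreq = NULL, ntc_label = "NTC") {
  counts <- screen$counts
  samples <- screen$samples
  missing <- setdiff(library$guide_id, rownames(counts))
  if (length(missing) > 0) {
    stop("library guides absent from the count matrix: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5) else "")
  }
  counts <- counts[library$guide_id, , drop = FALSE]
  depths <- colSums(counts)
  F <- relative_frequency(counts)
  lfc <- guide_log2fc(F, samples, late_timepoint,
                      pseudofreq = pseudofreq, depths = depths)
  z <- guide_zscore(lfc)
  gene_scores <- gene_crispr_score(z, library, ntc_label = ntc_label)

  plasmid_id <- samples$sample_id[samples$is_plasmid]
  pf_used <- if (is.null(pseudofreq)) 0.5 / stats::median(depths) else pseudofreq
  guide_stats <- data.frame(
    guide_id = rownames(z),
    gene = library$gene[match(rownames(z), library$guide_id)],
    stringsAsFactors = FALSE
  )
  for (cn in colnames(lfc)) guide_stats[[paste0("lfc_", cn)]] <- lfc[, cn]
  for (cn in colnames(z)) guide_stats[[paste0("z_", cn)]] <- z[, cn]

  list(
    gene_scores = gene_scores,
    ranked = rank_genes(gene_scores),
    guide_stats = guide_stats,
    qc = list(
      uniformity_fold4 = library_uniformity(F[, plasmid_id], fold = 4),
      depth_per_sample = as.list(depths),
      pseudofreq = pf_used,
      late_timepoint = late_timepoint
    )
  )
}
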