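#' Per-sample relative clone abundances
#'
#' Normalises barcode read counts to the total per sample:
#' `F_i = N_i / sum_i N_i`.
#'
#' @param counts Clone x sample matrix of non-negative counts (integer counts
#'   from sequencing, or expected counts from a noise-free simulation).
#' @return Matrix of relative abundances; each column sums to 1.
#' @export
clone_relative_abundance <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  cs <- colSums(counts)
  zero <- cs == 0
  if (any(zero)) {
    stop("empty sample(s): ", paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(counts, 2, cs, "/")
}

#' Mean construct abundance over the time course
#'
#' The mean relative abundance of construct c at time t is the mean of its
#' clones' relative abundances over all clones and replicates:
#' `M_ct = 1/(R * L_ct) * sum_{i,r} F_ictr`. Replicates in which a clone is
#' entirely absent contribute zeros, not missing values — dropout is
#' informative in a competition.
#'
#' @param F Clone x sample relative-abundance matrix from
#'   [clone_relative_abundance()].
#' @param clone_map Data frame `clone_id, construct`.
#' @param samples Sample sheet data frame `sample_id, timepoint, replicate`.
#' @param timepoint_order Optional explicit ordering of timepoint labels;
#'   defaults to first appearance in `samples`.
#' @return A `construct_abundance` list with `M` (construct x timepoint
#'   matrix), `L` (clone counts per construct x timepoint) and `R`
#'   (replicates per timepoint).
#' @export
construct_mean_abundance <- function(F, clone_map, samples,
                                     timepoint_order = NULL) {
  unmapped <- setdiff(rownames(F), clone_map$clone_id)
  if (length(unmapped) > 0) {
    stop("clones without a construct mapping: ",
         paste(utils::head(unmapped, 5), collapse = ", "))
  }
  construct <- clone_map$construct[match(rownames(F), clone_map$clone_id)]
  tps <- if (is.null(timepoint_order)) unique(samples$timepoint) else timepoint_order
  constructs <- unique(clone_map$construct)

  M <- matrix(NA_real_, nrow = length(constructs), ncol = length(tps),
              dimnames = list(constructs, tps))
  L <- matrix(0L, nrow = length(constructs), ncol = length(tps),
              dimnames = list(constructs, tps))
  R <- setNames(integer(length(tps)), tps)
  for (tp in tps) {
    cols <- samples$sample_id[samples$timepoint == tp]
    R[tp] <- length(cols)
    if (length(cols) == 0) next
    sub <- F[, cols, drop = FALSE]
    for (cn in constructs) {
      rows <- which(construct == cn)
      if (length(rows) == 0) next  # construct absent at this timepoint: missing
      L[cn, tp] <- length(rows)
      M[cn, tp] <- mean(sub[rows, , drop = FALSE])
    }
  }
  structure(list(M = M, L = L, R = R), class = "construct_abundance")
}

#' Long-format construct abundance trajectory
#'
#' @param abundance A `construct_abundance` from [construct_mean_abundance()].
#' @return Tidy data frame (`construct, timepoint, M, L, R`), sorted by
#'   timepoint (in the abundance object's order) then construct.
#' @export
abundance_trajectory <- function(abundance) {
  stopifnot(inherits(abundance, "construct_abundance"))
  tps <- colnames(abundance$M)
  if (length(tps) == 0) stop("no timepoints in abundance object")
  rows <- expand.grid(construct = rownames(abundance$M), timepoint = tps,
                      stringsAsFactors = FALSE)
  rows <- rows[order(match(rows$timepoint, tps), rows$construct), ]
  rows$M <- abundance$M[cbind(rows$construct, rows$timepoint)]
  rows$L <- abundance$L[cbind(rows$construct, rows$timepoint)]
  rows$R <- abundance$R[rows$timepoint]
  rownames(rows) <- NULL
  rows
}
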