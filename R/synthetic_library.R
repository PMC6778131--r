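#' Configuration for a synthetic guide library
#'
#' Defaults mirror a lymphoma-focused knockout library: 6000 guides covering
#' 692 target genes (at most nine guides per gene) plus 250 non-targeting
#' controls (NTCs).
#'
#' @param n_target_genes Number of target genes.
#' @param max_guides_per_gene Upper bound on guides per gene.
#' @param n_ntc Number of non-targeting control guides.
#' @param total_guides Total guides, targeting plus NTC.
#' @param seed Integer seed; the design is deterministic given it.
#' @return A `library_design_config` list.
#' @export
library_design_config <- function(n_target_genes = 692,
                                  max_guides_per_gene = 9,
                                  n_ntc = 250,
                                  total_guides = 6000,
                                  seed = 1L) {
  cfg <- list(
    n_target_genes = as.integer(n_target_genes),
    max_guides_per_gene = as.integer(max_guides_per_gene),
    n_ntc = as.integer(n_ntc),
    total_guides = as.integer(total_guides),
    seed = as.integer(seed)
  )
  n_targeting <- cfg$total_guides - cfg$n_ntc
  if (cfg$n_target_genes < 1 || cfg$max_guides_per_gene < 1 || cfg$n_ntc < 0) {
    stop("library design counts must be positive (n_ntc may be zero)")
  }
  if (n_targeting < cfg$n_target_genes) {
    stop("infeasible design: fewer targeting guides than target genes")
  }
  if (n_targeting > cfg$n_target_genes * cfg$max_guides_per_gene) {
    stop("infeasible design: total_guides exceeds n_target_genes * max_guides_per_gene + n_ntc")
  }
  class(cfg) <- "library_design_config"
  cfg
}

#' Generate a synthetic guide library
#'
#' Targeting guides are spread as evenly as the design permits (floor
#' allocation, the remainder assigned to randomly chosen genes). Spacers are
#' unique 20-nt strings with a fixed leading G, matching oligo-pool synthesis
#' convention.
#'
#' @param config A [library_design_config()].
#' @param ntc_label Gene label used for the pooled non-targeting pseudo-gene.
#' @return A `guide_library` data frame with columns
#'   `guide_id, gene, spacer, is_ntc`.
#' @export
generate_library <- function(config = library_design_config(),
                             ntc_label = "NTC") {
  stopifnot(inherits(config, "library_design_config"))
  set.seed(config$seed)
  n_genes <- config$n_target_genes
  n_targeting <- config$total_guides - config$n_ntc

  per_gene <- rep(n_targeting %/% n_genes, n_genes)
  remainder <- n_targeting - sum(per_gene)
  if (remainder > 0) {
    bump <- sample.int(n_genes, remainder)
    per_gene[bump] <- per_gene[bump] + 1L
  }
  stopifnot(all(per_gene >= 1L), all(per_gene <= config$max_guides_per_gene))

  genes <- sprintf("GENE%04d", seq_len(n_genes))
  gene_col <- c(rep(genes, per_gene), rep(ntc_label, config$n_ntc))
  guide_id <- c(
    unlist(lapply(seq_len(n_genes), function(i) {
      sprintf("%s_g%d", genes[i], seq_len(per_gene[i]))
    }), use.names = FALSE),
    sprintf("%s_%03d", ntc_label, seq_len(config$n_ntc))
  )

  spacer <- random_spacers(config$total_guides, length = 20L)

  lib <- data.frame(
    guide_id = guide_id,
    gene = gene_col,
    spacer = spacer,
    is_ntc = gene_col == ntc_label,
    stringsAsFactors = FALSE
  )
  validate_guide_library(lib, ntc_label = ntc_label)
  class(lib) <- c("guide_library", "data.frame")
  lib
}

# Unique spacers over {A,C,G,T}, first base fixed to G.
random_spacers <- function(n, length = 20L) {
  bases <- c("A", "C", "G", "T")
  draw <- function(k) {
    body <- matrix(sample(bases, k * (length - 1L), replace = TRUE),
                   nrow = k)
    paste0("G", apply(body, 1L, paste0, collapse = ""))
  }
  out <- unique(draw(n))
  while (length(out) < n) {
    out <- unique(c(out, draw(n - length(out))))
  }
  out[seq_len(n)]
}

#' Validate a guide library
#'
#' Checks guide-id uniqueness, spacer alphabet/length/uniqueness, the leading
#' G, and the `is_ntc` / NTC-sentinel correspondence.
#'
#' @param library A guide library data frame.
#' @param ntc_label NTC sentinel gene label.
#' @return The library, invisibly; errors on violation.
#' @export
validate_guide_library <- function(library, ntc_label = "NTC") {
  if (anyDuplicated(library$guide_id)) stop("guide_id values must be unique")
  if (anyDuplicated(library$spacer)) stop("spacer sequences must be unique")
  len <- nchar(library$spacer)
  if (any(len < 19L | len > 20L)) stop("spacers must be 19-20 nt")
  if (any(grepl("[^ACGT]", library$spacer))) stop("spacers must be over {A,C,G,T}")
  if (any(substr(library$spacer, 1, 1) != "G")) stop("spacer position one must be G")
  if (!identical(library$is_ntc, library$gene == ntc_label)) {
    stop("is_ntc flag must match the '", ntc_label, "' gene sentinel")
  }
  invisible(library)
}
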