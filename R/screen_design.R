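#' Cells required for a target guide representation
#'
#' `cells = n_guides * coverage / transduced_fraction`, rounded up to whole
#' cells. A 1000x coverage of a 6000-guide library at 30% transduction needs
#' 2e7 cells.
#'
#' @param n_guides Number of guides in the library.
#' @param coverage Target fold representation (cells per guide).
#' @param transduced_fraction Fraction of harvested cells carrying both Cas9
#'   and a guide, in (0, 1\].
#' @return Whole-cell count.
#' @export
cells_required <- function(n_guides, coverage, transduced_fraction) {
  if (transduced_fraction <= 0 || transduced_fraction > 1) {
    stop("transduced_fraction must be in (0, 1]")
  }
  if (coverage < 1) stop("coverage must be >= 1")
  ceiling(n_guides * coverage / transduced_fraction)
}

#' Genomic-DNA mass and PCR reaction plan for library readout
#'
#' One million human cells hold about 6.6 ug of genomic DNA, so the first
#' library PCR needs `cells/1e6 * 6.6` ug, split into
#' `ceiling(mass / max_ug_per_reaction)` reactions under a strict per-reaction
#' mass ceiling.
#'
#' @param cells Number of harvested cells.
#' @param max_ug_per_reaction Mass ceiling per PCR reaction (ug).
#' @param ug_per_million_cells Genomic DNA per 1e6 cells (ug).
#' @return List with `dna_mass_ug` and `n_pcr_reactions`.
#' @export
dna_plan <- function(cells, max_ug_per_reaction = 10,
                     ug_per_million_cells = 6.6) {
  if (cells <= 0) stop("cells must be positive")
  mass <- cells / 1e6 * ug_per_million_cells
  list(
    dna_mass_ug = mass,
    n_pcr_reactions = as.integer(ceiling(mass / max_ug_per_reaction))
  )
}

#' Full coverage plan for a screen readout
#'
#' @inheritParams cells_required
#' @inheritParams dna_plan
#' @return A `coverage_plan` list with `n_guides, coverage,
#'   transduced_fraction, cells_required, dna_mass_ug, n_pcr_reactions`.
#' @export
coverage_plan <- function(n_guides, coverage, transduced_fraction,
                          max_ug_per_reaction = 10) {
  cells <- cells_required(n_guides, coverage, transduced_fraction)
  dna <- dna_plan(cells, max_ug_per_reaction = max_ug_per_reaction)
  structure(
    list(
      n_guides = n_guides, coverage = coverage,
      transduced_fraction = transduced_fraction,
      cells_required = cells,
      dna_mass_ug = dna$dna_mass_ug,
      n_pcr_reactions = dna$n_pcr_reactions
    ),
    class = "coverage_plan"
  )
}
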