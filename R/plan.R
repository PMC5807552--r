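#' Experiment-planning arithmetic for a pooled screen
#'
#' Computes the cell numbers and PCR template mass needed to maintain library
#' representation through a pooled shRNA screen: the number of transduced
#' cells required for a target coverage, the number of cells to seed given a
#' single-copy transduction efficiency, and the genomic-DNA mass to carry into
#' the guide-amplification PCR at a given template representation.
#'
#' `transduced_cells = n_shrna * coverage`;
#' `seeded_cells = ceiling(transduced_cells / efficiency)`;
#' `pcr_template_ug = representation * n_shrna * genome_mass_pg / 1e6`.
#' The default genome mass of 6.5 pg corresponds to a diploid mouse genome.
#'
#' @param n_shrna Number of shRNAs in the library.
#' @param coverage Target cells per shRNA maintained through the screen.
#' @param efficiency Transduction efficiency as a fraction in (0, 1]; kept
#'   low so that each cell receives a single shRNA copy.
#' @param representation Genome copies per shRNA carried into the PCR.
#' @param genome_mass_pg Mass of one genome in picograms.
#' @return Object of class `experiment_plan`: a list with
#'   `transduced_cells_needed`, `seeded_cells_needed`, `pcr_template_ug`
#'   (raw) and `pcr_template_ug_rounded` (nearest microgram), plus the inputs.
#' @examples
#' plan_experiment(n_shrna = 4184, coverage = 1000, efficiency = 0.085)
#' @export
plan_experiment <- function(n_shrna, coverage = 1000, efficiency = 0.085,
                            representation = 1000, genome_mass_pg = 6.5) {
  stopifnot(n_shrna > 0, coverage > 0, efficiency > 0, efficiency <= 1,
            representation > 0, genome_mass_pg > 0)
  transduced <- n_shrna * coverage
  seeded <- ceiling(transduced / efficiency)
  mass_ug <- representation * n_shrna * genome_mass_pg * 1e-6  # pg -> ug
  structure(list(
    transduced_cells_needed = transduced,
    seeded_cells_needed = seeded,
    pcr_template_ug = mass_ug,
    pcr_template_ug_rounded = round(mass_ug),
    n_shrna = n_shrna, coverage = coverage, efficiency = efficiency,
    representation = representation, genome_mass_pg = genome_mass_pg),
    class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("screen plan for %d shRNAs:\n", x$n_shrna))
  cat(sprintf("  transduced cells needed : %s (%dx coverage)\n",
              format(x$transduced_cells_needed, big.mark = ","), x$coverage))
  cat(sprintf("  cells to seed           : %s (efficiency %.1f%%)\n",
              format(x$seeded_cells_needed, big.mark = ","),
              100 * x$efficiency))
  cat(sprintf("  PCR template            : %.2f ug (~%d ug at %dx representation)\n",
              x$pcr_template_ug, x$pcr_template_ug_rounded, x$representation))
  invisible(x)
}
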