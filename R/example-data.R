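#' Bundled worked-example data
#'
#' `fcs_particle_counts()` returns paired native/denatured FCS particle
#' numbers for a semipurified zinc-finger-array construct (five replicates)
#' and a monomeric eYFP control (three replicates), the worked example for
#' [oligomer_ratio()]. `ms_anchor_peptides()` returns four tryptic peptides
#' of the Halo-tagged zinc-finger construct with their measured MALDI m/z
#' values, the worked example for [peptide_mz()] and [fragment_ions()].
#'
#' @return A tibble (`sample`, `replicate`, `n_native`, `n_denatured`, or
#'   `sequence`, `observed_mz`).
#' @export
fcs_particle_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "fcs_particle_counts.tsv",
                package = "oligostate", mustWork = TRUE),
    col_types = readr::cols(), progress = FALSE)
}

#' @rdname fcs_particle_counts
#' @export
ms_anchor_peptides <- function() {
  readr::read_tsv(
    system.file("extdata", "ms_anchor_peptides.tsv",
                package = "oligostate", mustWork = TRUE),
    col_types = readr::cols(), progress = FALSE)
}
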