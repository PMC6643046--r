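# shared fixtures built in code

znf55 <- function() construct("ZnF", 55)

a1_frags <- function() oligostate:::assay1_fragments()

a2_ladder <- function() {
  dplyr::bind_rows(lapply(c(75, 114, 273, 543, 740), function(l) {
    dna_fragment(paste0("single-", l), l, n_sites = as.integer(l == 75))
  }))
}

# a minimal hand-built single-lane gel table
one_lane_gel <- function(d_us1 = 12, d_us2 = 160, d_shift = 60,
                         band_type = "lower_shift") {
  tibble::tibble(
    gel_id = "g1", lane_id = "L1", fragment_name = "frag",
    construct_name = "ZnF",
    band_type = c("ref_upper", "ref_lower", band_type),
    distance = c(d_us1, d_us2, d_shift), intensity = NA_real_)
}

anchor_peptides <- function() {
  tibble::tibble(
    sequence = c("SFIASEISSIER", "HQRTHTGEKPYVCR", "SDKPDLGYFFDDHVR",
                 "LLFWGTPGVLIPPAEAAR"),
    observed_mz = c(1338.61, 1767.84, 1810.76, 1908.01))
}

random_peptide <- function(len) {
  paste(sample(names(oligostate:::AA_MONO), len, replace = TRUE),
        collapse = "")
}
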