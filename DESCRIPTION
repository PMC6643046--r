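Package: oligostate
Title: Oligomeric-State Inference for Sequence-Specific DNA-Binding Proteins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative tools for determining the stoichiometry of
    protein-DNA complexes from native gel electrophoresis (EMSA band-shift
    migration analysis with reference-band normalisation and log-linear
    standard curves), equilibrium binding titrations with ligand depletion,
    fluorescence correlation spectroscopy (FCS) denaturation-ratio analysis,
    and peptide-mass-fingerprint verification of complex composition.
    Includes seeded forward simulators for every assay so the full inference
    pipeline can be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
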