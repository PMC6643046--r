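# oligostate

Quantitative inference of the oligomeric state of sequence-specific
DNA-binding proteins — how many monomers act together in a DNA-bound
complex, and whether that complex engages one or several DNA molecules at a
time. The package was built around the biophysics of PRDM9, the
meiosis-specific zinc-finger protein that marks recombination hotspots and
binds its target motif as a multimer, but every estimator is generic.

Four independent lines of evidence are implemented end to end, each with a
seeded forward simulator so the whole pipeline runs and validates without
instrument data:

1. **Native-gel (EMSA) migration stoichiometry.** Migration of a
   DNA-anchored complex is linear in `log10(MW)` (reptation). After
   in-lane reference normalisation, `(d_ref_lower − d_ref_upper) −
   (d_band − d_ref_upper)`, two estimators recover the protein mass per
   complex: *assay I* differences the supershift (two complexes) against
   the lower shift (one complex) on tandem-site probes,
   `units = dMW / MW_monomer`; *assay II* reads the complex mass off a
   free-DNA ladder, `units = (MW_complex − MW_DNA) / MW_monomer`.
2. **Equilibrium binding.** The exact depletion-aware isotherm
   `FB = ((p0 + d0 + K_D) − sqrt((p0 + d0 + K_D)² − 4 p0 d0)) / (2 d0)`
   is fitted for K_D; two-site probes get binomial occupancy fractions
   `(1−θ)², 2θ(1−θ), θ²` and an effective single-K_D fit on the summed
   shifts. Band-pattern predictors discriminate one-DNA-per-complex
   binding (4 bands with two probes) from DNA-bridging (5 bands), and
   model the restriction digest of a bound tandem probe.
3. **FCS denaturation ratios.** The 3D-diffusion autocorrelation
   `G(τ) = (1/⟨N⟩)(1 + τ/τ_d)^−1 (1 + κ^−2 τ/τ_d)^−1/2` gives particle
   numbers from amplitudes; the ratio `N_denatured/N_native` of paired
   measurements is the oligomer order.
4. **Peptide-mass fingerprinting.** In-silico tryptic digestion, `[M+H]+`
   monoisotopic masses with carbamidomethyl-C, a/b/y fragment ions, and
   tolerance-based peak matching with sequence-coverage accounting verify
   the protein content of a gel-purified complex.

All user-facing functions take data frames and return tibbles; fitted
objects have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Oligomer order from the bundled paired FCS particle counts (five
native/denatured replicates of a semipurified zinc-finger construct):

```r
counts <- fcs_particle_counts()
prdm9  <- counts[counts$sample != "eYFP", ]
oligomer_ratio(prdm9$n_native, prdm9$n_denatured)
#> Oligomer order (N_denatured / N_native): 3.34 (CI 0.41), n = 5
```

The mean ratio 3.34 with Student-t 95% half-width 0.41 says each dissolved
oligomer released about three fluorescent monomers — a trimer.

The same answer from a simulated assay-II gel (free-DNA ladder standards,
four replicate gels, ~1% migration noise):

```r
ladder <- dplyr::bind_rows(lapply(c(75, 114, 273, 543, 740), function(l)
  dna_fragment(paste0("single-", l), l, n_sites = as.integer(l == 75))))

gel <- simulate_gel("assay2", constructs = znf_constructs(), true_units = 3,
                    n_gels = 4, lane_offset_sd = 1, band_noise_sd = 1,
                    seed = 42)
assay2_stoichiometry(gel, ladder, znf_constructs()[1, ], "single-75")
#> Stoichiometry (assay_II) for eYFP-ZnF 1-11 [monomer 77 kD]
#>   3.08 units (CI 0.47), n = 4

stoichiometry_hypothesis_fit(gel, ladder, znf_constructs(), "single-75")
#> Stoichiometry hypothesis fit (observed ~ expected migration)
#> # A tibble: 3 × 5
#>   n_units slope intercept r_squared identity_deviation
#>     <dbl> <dbl>     <dbl>     <dbl>              <dbl>
#> 1       2 1.15      3.52      0.971              59.3
#> 2       3 1.01      0.299     0.973               3.19
#> 3       4 0.935    -2.37      0.973              27.2
#> Best-supported unit count: 3
```

Only the trimer hypothesis puts observed migrations on the identity line
against expectation. And the binding affinity from a simulated titration
(5 nM DNA, serial protein dilution, 5% noise):

```r
fit_kd(simulate_titration(kd = 48, dna_conc = 5, noise_cv = 0.05, seed = 7))
#> Equilibrium K_D fit (single): 45.9 nM (SE 1.3), n = 10, RSS = 0.00151
```

## Layout

- `R/` — estimators, simulators, IO and the `run_pipeline()` orchestrator
- `tests/testthat/` — unit, property and end-to-end acceptance tests
- `vignettes/oligomeric-state-inference.Rmd` — models, assumptions,
  parameter choices and limitations
- `inst/extdata/` — small worked-example tables (FCS particle counts,
  anchor peptides)
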