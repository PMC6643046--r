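---
title: "Inferring the oligomeric state of a DNA-binding protein"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the oligomeric state of a DNA-binding protein}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligostate)
```

`oligostate` determines how many protein monomers make up a DNA-bound
complex, using four mutually independent lines of evidence that were
developed around the meiotic recombination factor PRDM9 and its zinc-finger
(ZnF) array. PRDM9's ZnF domain binds recombination-hotspot DNA motifs and
multimerises through the ZnF array itself; the question the package answers
quantitatively is *how many* monomers act together — and, as a corollary,
whether the multimer engages one or several DNA molecules at a time.

This vignette explains each model, its assumptions, the tunable parameters,
and the design decisions taken where the underlying procedures left choices
open.

## 1. Migration-based stoichiometry from native gels

### Physical model

On a native polyacrylamide gel a protein–DNA complex with long flanking DNA
migrates by reptation of the DNA chain: migration distance is linear in
`log10(MW)`, independent of protein charge or conformation, because the DNA
end pulls the whole complex through the gel pores. All gel inference in the
package rests on that single log-linear law.

Raw migration distances are not comparable across lanes or gels, so each
lane carries two non-interacting reference DNAs — a long, slow *upper*
reference and a short, fast *lower* reference. `normalize_migration()`
computes

```
(d_ref_lower − d_ref_upper) − (d_band − d_ref_upper)  =  d_ref_lower − d_band
```

the lag of a band behind the fast reference. Both terms share the lane's
offset, so lane effects cancel exactly (this identity is asserted to
machine precision in the test suite). Larger normalised lag means heavier
species. Distances are in arbitrary units (pixels); the inference is
unit-free.

`fit_standard_curve()` regresses `log10(MW / MW_anchor)` on the anchored
normalised lag by ordinary least squares. Two open choices were resolved as
follows:

* **Difference, not ratio.** "Migration relative to the first lane" is
  implemented as a signed difference of normalised lags. With `log10(MW)`
  as response this is exactly the reptation law, makes the two-point case
  exact, and keeps the regression invariant to the arbitrary distance unit.
* **Fitted intercept.** The intercept is estimated rather than forced
  through the anchor point; for well-behaved data it is ≈ 0, and reporting
  it is a useful diagnostic of anchor consistency.

`estimate_mw()` inverts the curve; extrapolation beyond the standard range
is allowed but flagged, because heavy complexes resolve less well and their
estimates are noisier.

### Assay I: supershift differencing on tandem-site probes

Probes carrying two adjacent binding sites form either a single complex
(lower shift) or two complexes (supershift). The mass difference between a
lane's supershift and its lower shift is the mass of exactly one additional
complex, so `units = dMW / monomer MW`. The standards are single complexes
on probes of increasing flank length.

The standards' absolute mass is `dna_mw + S`, where S — the single-complex
protein mass — is the unknown of interest. Because the regression response
is logarithmic, S does not cancel out of the curve. The package therefore
estimates S by one-dimensional profiling: S is the value that makes
`log10(dna_mw + n_complexes · S)` most linear in the normalised lag, using
*every* band of known composition (lower shifts with one complex,
supershifts with two). Including the supershifts is essential: with single
complexes alone the profile objective is nearly flat in S at realistic
noise, and the estimate drifts to its bounds. The profiled objective is not
unimodal (the logarithm flattens again at very large S), so a coarse grid
brackets the global basin before local refinement. With this estimator the
noise-free forward model is inverted *exactly* (unit error < 1e-9 across
stoichiometries 1–6 in the test suite). A known S can be supplied instead
via `protein_mass =`.

### Assay II: free-DNA ladder

Here the standard curve is fitted on a ladder of unbound DNA fragments of
known sizes (masses from `dna_mw()`, 0.650 kD/bp) and the complex mass is
read off directly from the lower-shift lag, giving
`units = (MW_complex − MW_probe DNA) / monomer MW`. No profiling is needed
and single complexes on a short probe sit well inside the ladder range,
which is why this assay is the more accurate of the two.

Both assays report per-measurement unit counts, their mean, and a
two-sided 95% Student-t half-width `t(0.975, n−1)·sd/√n` — a convention
validated by exact reproduction of the FCS worked example's printed
summaries (3.34 ± 0.41 at n = 5 and 1.49 ± 0.66 at n = 3,
see `summarize_units()`).

`stoichiometry_hypothesis_fit()` turns the question around: for candidate
unit counts (default 2, 3, 4) it predicts each construct's migration from
the inverse standard curve and regresses observed on expected lag across
constructs; the hypothesis whose regression is closest to the identity line
(squared deviation of slope from 1 and intercept from 0) wins. At least two
constructs of distinct monomer mass are required — a single complex species
cannot discriminate. `anova_units()` provides the one-way fixed-effects
ANOVA across constructs; with zero between-group variance the F statistic
is reported as 0 rather than 0/0. Multi-factor models (tag, expression
system, construct size) are a documented extension point, not implemented.

## 2. Equilibrium binding with ligand depletion

At the probe concentrations EMSAs use (~5 nM DNA vs K_D ≈ tens of nM) the
free-protein approximation fails, so `fraction_bound()` implements the
exact two-component equilibrium — the quadratic "receptor–ligand binding in
solution" closed form — evaluated in the rationalised root form
`2·p0 / (b + sqrt(b² − 4·p0·d0))`, which is numerically stable over at
least 8 decades of concentration and degrades smoothly to the hyperbola
`p0/(p0 + kd)` as DNA becomes dilute.

`fit_kd()` minimises untransformed residuals of fraction bound over a
(typically log-spaced) protein series, matching how such titrations are
plotted and read. For two-site tandem probes:

* the per-site occupancy under depletion satisfies the same quadratic with
  the *site* concentration `2·d0` (`site_occupancy()`);
* the species fractions are binomial: `(1−θ)²`, `2θ(1−θ)`, `θ²`
  (`tandem_fractions()`), so the lower shift peaks at exactly 0.5 when half
  the sites are filled;
* `mode = "tandem_sum"` fits an effective single-K_D isotherm to the summed
  lower+supershift fraction, the pragmatic treatment used for such data.
  Sites are modelled as independent and identical — the restriction-digest
  experiment (below) supports independence — and no cooperativity parameter
  is exposed. The DNA concentration entering the tandem-sum fit is the
  molecule concentration, and the resulting effective constant is smaller
  than the per-site K_D, as expected when either of two sites can produce a
  shift. An `active_fraction` multiplier is available for lysate titrations
  where the nominal protein concentration overstates active protein.

### Band-pattern logic

`predict_band_pattern()` enumerates the species expected when the complex
is offered two probes of the same site but different length: a complex that
binds one DNA at a time gives `2 × #fragments` bands (free + shifted for
each); a complex bridging two DNAs gives `#fragments + 3` bands for two
fragments (free short, free long, and the three unordered pairs).
`digest_rearrangement()` models cutting a 232-bp tandem probe into 75- and
157-bp single-site products: a supershift resolves into two single
complexes that co-migrate with the corresponding single-site shifts — the
diagnostic signature that the two complexes on a tandem probe are
independent.

## 3. FCS denaturation ratios

`acf_model()` is the single-component 3D-diffusion autocorrelation,

```
G(τ) = (1/⟨N⟩) · (1 + τ/τ_d)^−1 · (1 + κ^−2 τ/τ_d)^−1/2
```

whose zero-lag amplitude is `1/⟨N⟩`. Denaturing an oligomer of order m
multiplies the particle number by m, so the ratio `N_denatured / N_native`
of paired measurements estimates the oligomer order directly
(`oligomer_ratio()`).

Numerical and design choices:

* **κ fixed from calibration.** Single curves constrain the structure
  parameter poorly; it is fixed from a reference-dye measurement
  (`calibrate_focal_volume()`, rhodamine-6G, D = 426 µm²/s;
  `r0 = sqrt(4·D·τ_d)`).
* **No triplet term.** The model is the pure diffusion form; sub-10-µs lags
  can simply be trimmed from the input if triplet kinetics contaminate
  them.
* **Start values** are `1/G(first lag)` and the half-decay lag; fits use
  Levenberg–Marquardt with positivity bounds, unweighted by default with
  optional per-point weights.
* **Denatured τ_d is free.** Urea changes viscosity and particle size; only
  amplitudes enter the ratio.
* **No brightness correction by default.** Fluorophore brightness can
  differ between native and denaturing buffers, which inflates monomer
  counts slightly; a `brightness_correction` multiplier is exposed and
  defaults to 1 because no calibrated value is available.
* Curves with no usable decay (amplitude drop < 20%) are rejected as
  unidentifiable rather than fitted.

## 4. Peptide-mass-fingerprint verification

The composition of a gel-purified complex is verified in silico:
`tryptic_digest()` applies the Keil rule (cleave after K/R, never before
P), `peptide_mz()` computes monoisotopic `[M+H]+` with fixed
carbamidomethylation of cysteine (+57.02146 Da), `fragment_ions()` gives
the a/b/y series, and `pmf_match()` assigns observed MALDI peaks to the
nearest theoretical peptide within a 0.25 Da tolerance (ties: smaller
error, then fewer missed cleavages), reporting signed deltas and
interval-union sequence coverage.

The 0.25 Da default absorbs the ≤0.1 Da one-sided calibration offsets seen
between measured and theoretical masses on reference peptides. One caveat
discovered while validating the worked example: of the four bundled anchor
peptides (`ms_anchor_peptides()`), the three cysteine-free ones sit 0.06 to
0.08 Da below their `[M+H]+` theory, but the cysteine-containing peptide's
recorded value matches the *neutral* monoisotopic mass of the
carbamidomethylated peptide — exactly one proton (1.007 Da) low. The
package does not bend the mass convention to absorb this: `peptide_mz()`
computes standard `[M+H]+` chemistry, and the discrepancy is visible in the
reported signed delta.

## 5. What the simulators emulate — and what they do not

Every analysis stage has a seeded forward simulator so the full pipeline is
testable without instrument data; each is a pure function of its
configuration including the seed (asserted byte-identical in the tests).

* `simulate_gel()` draws band distances from
  `intercept − slope·log10(MW) + lane offset + band noise`. Defaults
  (intercept 220, slope 60 gel units/decade) place the 75–1,460 bp design
  across ~110 gel units so ~100-bp steps stay resolvable; noise defaults
  (lane offset and band sd of 1 gel unit ≈ 1% of span) are calibration
  choices for a clean gel, not measured values. Curvature at the gel edges,
  band compression, smearing and intensity information are *not* modelled —
  passing round-trip tests show the estimators invert the reptation model,
  not that they survive arbitrary gel artefacts.
* `simulate_titration()` generates depletion-consistent fractions (single
  site, or binomial tandem fractions from the site-level quadratic) with
  multiplicative lognormal noise (CV 5% by default) renormalised to sum to
  one. Serial dilutions default to 1.5 µM halving down to ~3 nM at 5 nM
  DNA. Incubation-time drift of the equilibrium and nonspecific competitor
  partitioning are out of scope.
* `simulate_acf()` evaluates the autocorrelation model for a native and a
  denatured curve (order × particle number, its own τ_d) on an 80-point
  log-lag grid over 1 µs–1 s, with additive noise proportional to G
  (2% default). Photon-level statistics, afterpulsing and photophysics are
  not simulated.
* `simulate_peaklist()` perturbs digest masses with Gaussian calibration
  error (default sd 0.05 Da), restricts to a 700–3,500 Da window and adds
  uniform contaminant peaks.

## 6. Problem sizes and limitations

The bundled tests and the acceptance script use the design sizes above:
6 single-site + 4 tandem lanes (assay I), a 5-step ladder with up to four
constructs (assay II), 10-point titrations, 80-point correlation curves,
and 50–100 seeded replicates for the noisy recovery checks — sizes chosen
to mirror one realistic experimental campaign per claim.

Known limitations: assay I requires at least three complex bands to profile
S and degrades to DNA-only standards (with a warning) below that; the
hypothesis fit cannot discriminate from a single construct; K_D estimates
from lysate titrations inherit the nominal-concentration assumption unless
`active_fraction` is calibrated; FCS ratios are biased slightly upward if
fluorophore brightness differs between buffers; and the PMF matcher scores
proximity only — it is a verification tool, not a database-search engine.
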