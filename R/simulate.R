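# Default fragment designs for the two migration assays. Assay I uses
# single-site fragments of increasing flank length plus tandem-site
# fragments; assay II uses a free-DNA ladder and a 75-bp single-site probe.
assay1_fragments <- function() {
  singles <- c(75, 740, 856, 1053, 1147, 1460)
  tandems <- c(114, 232, 352, 468)
  dplyr::bind_rows(
    purrr::map(singles, ~ dna_fragment(paste0("single-", .x), .x, 1)),
    purrr::map(tandems, ~ dna_fragment(paste0("tandem-", .x), .x, 2)))
}

assay2_ladder_lengths <- function() c(75, 114, 273, 543, 740)

#' Simulate a native-gel band table
#'
#' Forward model of gel migration for both stoichiometry assays: each band's
#' distance is `migration_intercept - migration_slope * log10(MW)` plus a
#' lane-specific offset drawn from `N(0, lane_offset_sd^2)` and per-band
#' Gaussian noise, clipped at zero. Reference bands share their lane's
#' offset, so reference normalisation removes lane effects exactly. Complex
#' masses come from [complex_mw()] with the configured `true_units`; tandem
#' lanes carry both a lower shift (one complex) and a supershift (two
#' complexes). The same seed reproduces the identical table.
#'
#' Defaults place the 75-1460 bp fragment range across roughly 110 gel
#' units, resolving ~100-bp steps, and use noise of about 1% of the lane
#' span.
#'
#' @param assay `"assay1"` or `"assay2"`.
#' @param constructs Construct table; assay I uses the first row only,
#'   assay II simulates one complex lane per construct and gel.
#' @param true_units Generating number of monomers per complex. Default 3.
#' @param fragments Fragment table; defaults to the built-in design for the
#'   assay (assay II: the ladder plus the probe).
#' @param probe_fragment Probe fragment name for assay II complex lanes.
#'   Default `"single-75"`.
#' @param n_gels Number of replicate gels. Default 1 (assay I), 4
#'   (assay II).
#' @param migration_intercept,migration_slope Forward-model coefficients
#'   (gel units; slope per log10 kD, > 0). Defaults 220 and 60.
#' @param lane_offset_sd,band_noise_sd Noise standard deviations in gel
#'   units (>= 0). Defaults 1 and 1.
#' @param ref_lengths_bp Lengths of the slow (upper) and fast (lower)
#'   reference DNAs for assay I. Default `c(4368, 220)`.
#' @param seed Integer seed; identical seeds give identical tables.
#' @param kd_per_bp DNA mass per bp, kD.
#'
#' @return Gel band table tibble with columns `gel_id`, `lane_id`,
#'   `fragment_name`, `construct_name`, `band_type`, `distance`,
#'   `intensity`.
#' @export
simulate_gel <- function(assay = c("assay1", "assay2"),
                         constructs = znf_constructs()[1, ],
                         true_units = 3,
                         fragments = NULL,
                         probe_fragment = "single-75",
                         n_gels = if (assay == "assay1") 1L else 4L,
                         migration_intercept = 220,
                         migration_slope = 60,
                         lane_offset_sd = 1,
                         band_noise_sd = 1,
                         ref_lengths_bp = c(4368, 220),
                         seed = NULL,
                         kd_per_bp = 0.650) {
  assay <- match.arg(assay)
  check_num(true_units, "true_units", positive = TRUE, scalar = TRUE)
  check_num(migration_slope, "migration_slope", positive = TRUE,
            scalar = TRUE)
  check_num(lane_offset_sd, "lane_offset_sd", non_negative = TRUE,
            scalar = TRUE)
  check_num(band_noise_sd, "band_noise_sd", non_negative = TRUE,
            scalar = TRUE)
  check_cols(constructs, c("construct_name", "monomer_mw_kd"), "`constructs`")

  dist_of_mw <- function(mw) migration_intercept -
    migration_slope * log10(mw)

  with_seed_if(seed, {
    gels <- purrr::map(seq_len(n_gels), function(gi) {
      gel_id <- paste0("gel", gi)
      if (assay == "assay1") {
        frags <- if (is.null(fragments)) assay1_fragments() else fragments
        cons <- constructs[1, ]
        smass <- true_units * cons$monomer_mw_kd
        lanes <- purrr::map(seq_len(nrow(frags)), function(li) {
          fr <- frags[li, ]
          offset <- rnorm(1, 0, lane_offset_sd)
          mws <- c(ref_upper = dna_mw(ref_lengths_bp[1], kd_per_bp),
                   ref_lower = dna_mw(ref_lengths_bp[2], kd_per_bp),
                   lower_shift = dna_mw(fr$length_bp, kd_per_bp) + smass)
          if (fr$n_sites == 2L) {
            mws <- c(mws, supershift =
                       dna_mw(fr$length_bp, kd_per_bp) + 2 * smass)
          }
          tibble(gel_id = gel_id, lane_id = paste0("lane", li),
                 fragment_name = fr$fragment_name,
                 construct_name = cons$construct_name,
                 band_type = names(mws),
                 distance = pmax(0, dist_of_mw(unname(mws)) + offset +
                                   rnorm(length(mws), 0, band_noise_sd)),
                 intensity = NA_real_)
        })
        dplyr::bind_rows(lanes)
      } else {
        ladder_len <- assay2_ladder_lengths()
        frags <- if (is.null(fragments)) {
          dplyr::bind_rows(
            purrr::map(ladder_len,
                       ~ dna_fragment(paste0("single-", .x), .x,
                                      n_sites = as.integer(.x == 75))))
        } else fragments
        probe <- resolve_fragment(probe_fragment, frags)
        # both references are 75-bp DNAs; the upper one is loaded late and
        # travels a fixed fraction of its full-run distance
        ref_mw <- dna_mw(75, kd_per_bp)
        ladder_offset <- rnorm(1, 0, lane_offset_sd)
        ladder_mws <- dna_mw(ladder_len, kd_per_bp)
        ladder <- tibble(
          gel_id = gel_id, lane_id = "lane_ladder",
          fragment_name = paste0("single-", ladder_len),
          construct_name = NA_character_,
          band_type = "free_dna",
          distance = pmax(0, dist_of_mw(ladder_mws) + ladder_offset +
                            rnorm(length(ladder_mws), 0, band_noise_sd)),
          intensity = NA_real_)
        ladder_refs <- tibble(
          gel_id = gel_id, lane_id = "lane_ladder",
          fragment_name = "ref-75", construct_name = NA_character_,
          band_type = c("ref_upper", "ref_lower"),
          distance = pmax(0, c(0.15, 1) * dist_of_mw(ref_mw) +
                            ladder_offset + rnorm(2, 0, band_noise_sd)),
          intensity = NA_real_)
        lanes <- purrr::map(seq_len(nrow(constructs)), function(ci) {
          cons <- constructs[ci, ]
          offset <- rnorm(1, 0, lane_offset_sd)
          cx_mw <- dna_mw(probe$length_bp, kd_per_bp) +
            true_units * cons$monomer_mw_kd
          tibble(gel_id = gel_id,
                 lane_id = paste0("lane_", cons$construct_name),
                 fragment_name = c(probe$fragment_name, "ref-75", "ref-75"),
                 construct_name = c(cons$construct_name, NA, NA),
                 band_type = c("lower_shift", "ref_upper", "ref_lower"),
                 distance = pmax(0, c(dist_of_mw(cx_mw),
                                      0.15 * dist_of_mw(ref_mw),
                                      dist_of_mw(ref_mw)) + offset +
                                   rnorm(3, 0, band_noise_sd)),
                 intensity = NA_real_)
        })
        dplyr::bind_rows(ladder, ladder_refs, lanes)
      }
    })
    dplyr::bind_rows(gels)
  })
}

#' Simulate an equilibrium binding titration
#'
#' Generates fraction tables from the depletion-aware equilibrium: in
#' `single` mode the bound fraction follows [fraction_bound()]; in `tandem`
#' mode the per-site occupancy is solved from the two-site depletion
#' equilibrium ([site_occupancy()]) and converted to unbound/lower/super
#' molecule fractions with [tandem_fractions()]. Multiplicative lognormal
#' noise with coefficient of variation `noise_cv` is applied per fraction,
#' then fractions are renormalised to sum to one.
#'
#' The defaults emulate a serial-dilution titration: DNA held at 5 nM and
#' protein spanning ~1.5 uM down to ~3 nM in two-fold steps, with K_D 48 nM
#' and 5% noise.
#'
#' @param kd Generating dissociation constant, nM. Default 48.
#' @param dna_conc Total DNA (molecule) concentration, nM. Default 5.
#' @param protein_concs Protein concentrations, nM.
#' @param mode `"single"` or `"tandem"`.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0). Default 0.05.
#' @param seed Integer seed.
#'
#' @return Tibble with `protein_conc_nM`, `dna_conc_nM`, `frac_unbound`,
#'   `frac_lower`, `frac_super` (the latter all zero in single mode).
#' @export
simulate_titration <- function(kd = 48, dna_conc = 5,
                               protein_concs = 1500 / 2^(0:9),
                               mode = c("single", "tandem"),
                               noise_cv = 0.05, seed = NULL) {
  mode <- match.arg(mode)
  check_num(kd, "kd", positive = TRUE, scalar = TRUE)
  check_num(dna_conc, "dna_conc", positive = TRUE, scalar = TRUE)
  check_num(protein_concs, "protein_concs", positive = TRUE)
  check_num(noise_cv, "noise_cv", non_negative = TRUE, scalar = TRUE)

  fracs <- if (mode == "single") {
    fb <- fraction_bound(protein_concs, dna_conc, kd)
    tibble(frac_unbound = 1 - fb, frac_lower = fb, frac_super = 0)
  } else {
    theta <- site_occupancy(protein_concs, dna_conc, kd, n_sites = 2)
    tf <- tandem_fractions(theta)
    tibble(frac_unbound = tf$fraction_unbound,
           frac_lower = tf$fraction_lower,
           frac_super = tf$fraction_super)
  }

  with_seed_if(seed, {
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      m <- as.matrix(fracs)
      noise <- matrix(stats::rlnorm(length(m), -sdlog^2 / 2, sdlog),
                      nrow = nrow(m))
      m <- m * noise
      m <- m / rowSums(m)
      fracs <- as_tibble(m)
    }
    dplyr::bind_cols(
      tibble(protein_conc_nM = protein_concs, dna_conc_nM = dna_conc),
      fracs)
  })
}

#' Simulate a native/denatured FCS autocorrelation curve pair
#'
#' The native curve follows [acf_model()] with `n_native` particles; the
#' denatured curve has `oligomer_order * n_native` particles (denaturation
#' splits each oligomer into its monomers) and its own diffusion time (urea
#' changes viscosity and particle size). Additive Gaussian noise with
#' standard deviation `noise_rel_sd * G(tau)` is applied pointwise.
#'
#' @param n_native Native-state mean particle number. Default 0.3.
#' @param tau_d_native,tau_d_denatured Diffusion times, s. Defaults 1e-3
#'   and 5e-4.
#' @param oligomer_order Monomers per oligomer (>= 1). Default 3.
#' @param kappa Structure parameter. Default 5.
#' @param lags Lag-time grid, s (strictly increasing). Default: 80
#'   log-spaced points over 1e-6..1 s.
#' @param noise_rel_sd Relative noise level (>= 0). Default 0.02.
#' @param seed Integer seed.
#'
#' @return Tibble with `lag_s`, `g`, `condition` (`"native"` /
#'   `"denatured"`).
#' @export
simulate_acf <- function(n_native = 0.3, tau_d_native = 1e-3,
                         tau_d_denatured = 5e-4, oligomer_order = 3,
                         kappa = 5, lags = 10^seq(-6, 0, length.out = 80),
                         noise_rel_sd = 0.02, seed = NULL) {
  check_num(n_native, "n_native", positive = TRUE, scalar = TRUE)
  check_num(oligomer_order, "oligomer_order", scalar = TRUE)
  if (oligomer_order < 1) {
    abort("`oligomer_order` must be >= 1.",
          class = "oligostate_argument_error")
  }
  check_num(lags, "lags", positive = TRUE)
  if (is.unsorted(lags, strictly = TRUE)) {
    abort("`lags` must be strictly increasing.",
          class = "oligostate_argument_error")
  }
  check_num(noise_rel_sd, "noise_rel_sd", non_negative = TRUE, scalar = TRUE)

  g_nat <- acf_model(lags, n_native, tau_d_native, kappa)
  g_den <- acf_model(lags, oligomer_order * n_native, tau_d_denatured, kappa)
  with_seed_if(seed, {
    dplyr::bind_rows(
      tibble(lag_s = lags,
             g = g_nat + rnorm(length(lags), 0, noise_rel_sd * g_nat),
             condition = "native"),
      tibble(lag_s = lags,
             g = g_den + rnorm(length(lags), 0, noise_rel_sd * g_den),
             condition = "denatured"))
  })
}

#' Simulate a MALDI peak list from a protein sequence
#'
#' Digests the protein in silico, perturbs each theoretical peptide mass
#' with Gaussian calibration error, restricts to the instrument m/z window
#' and adds uniformly distributed contaminant peaks.
#'
#' @param protein_seq Protein sequence.
#' @param mass_error_sd Calibration error SD in Da (>= 0). Default 0.05.
#' @param n_contaminants Number of contaminant peaks. Default 4.
#' @param mz_range Instrument window, Da. Default `c(700, 3500)`.
#' @param max_missed_cleavages Digest parameter. Default 0.
#' @param carbamidomethyl Fixed Cys modification. Default `TRUE`.
#' @param seed Integer seed.
#'
#' @return Tibble with `mz` and `intensity` (arbitrary units), sorted by
#'   m/z.
#' @export
simulate_peaklist <- function(protein_seq, mass_error_sd = 0.05,
                              n_contaminants = 4, mz_range = c(700, 3500),
                              max_missed_cleavages = 0,
                              carbamidomethyl = TRUE, seed = NULL) {
  check_num(mass_error_sd, "mass_error_sd", non_negative = TRUE,
            scalar = TRUE)
  check_num(n_contaminants, "n_contaminants", non_negative = TRUE,
            scalar = TRUE)
  peps <- tryptic_digest(protein_seq, max_missed_cleavages, carbamidomethyl)
  mz <- peps$mz_mh[peps$mz_mh >= mz_range[1] & peps$mz_mh <= mz_range[2]]
  with_seed_if(seed, {
    peaks <- mz + rnorm(length(mz), 0, mass_error_sd)
    contam <- if (n_contaminants > 0)
      runif(n_contaminants, mz_range[1], mz_range[2]) else numeric()
    out <- tibble(mz = c(peaks, contam),
                  intensity = stats::rlnorm(length(peaks) +
                                              length(contam), 4, 1))
    dplyr::arrange(out, .data$mz)
  })
}
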