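test_that("simulators are pure functions of their seed", {
  g1 <- simulate_gel("assay1", constructs = znf55(), true_units = 3,
                     seed = 77)
  g2 <- simulate_gel("assay1", constructs = znf55(), true_units = 3,
                     seed = 77)
  expect_identical(g1, g2)
  g3 <- simulate_gel("assay1", constructs = znf55(), true_units = 3,
                     seed = 78)
  expect_false(identical(g1, g3))

  t1 <- simulate_titration(seed = 5)
  t2 <- simulate_titration(seed = 5)
  expect_identical(t1, t2)

  a1 <- simulate_acf(seed = 9)
  a2 <- simulate_acf(seed = 9)
  expect_identical(a1, a2)

  p1 <- simulate_peaklist("SFIASEISSIERGRATKPLMKSR", seed = 4,
                          mz_range = c(200, 3500))
  p2 <- simulate_peaklist("SFIASEISSIERGRATKPLMKSR", seed = 4,
                          mz_range = c(200, 3500))
  expect_identical(p1, p2)
})

test_that("simulator preconditions are enforced", {
  expect_error(simulate_gel("assay1", constructs = znf55(),
                            band_noise_sd = -1),
               class = "oligostate_argument_error")
  expect_error(simulate_titration(protein_concs = numeric()),
               class = "oligostate_argument_error")
  expect_error(simulate_acf(oligomer_order = 0.5),
               class = "oligostate_argument_error")
  expect_error(simulate_peaklist("GRB2"),
               class = "oligostate_argument_error")
})

test_that("the simulated gel table carries the expected layout", {
  gel <- simulate_gel("assay1", constructs = znf55(), true_units = 3,
                      seed = 1)
  expect_named(gel, c("gel_id", "lane_id", "fragment_name",
                      "construct_name", "band_type", "distance",
                      "intensity"))
  # every lane has both references; tandem lanes carry supershifts
  per_lane <- table(gel$lane_id, gel$band_type)
  expect_true(all(per_lane[, "ref_upper"] == 1))
  expect_true(all(per_lane[, "ref_lower"] == 1))
  expect_equal(sum(per_lane[, "supershift"]), 4)
  # the fast (short) reference always runs at least as far as the slow one
  refs <- tidyr::pivot_wider(
    gel[gel$band_type %in% c("ref_upper", "ref_lower"),
        c("lane_id", "band_type", "distance")],
    names_from = band_type, values_from = distance)
  expect_true(all(refs$ref_lower >= refs$ref_upper))
})

test_that("titration simulation respects mass conservation and tandem shape", {
  tt <- simulate_titration(kd = 48, dna_conc = 5, mode = "tandem",
                           noise_cv = 0, seed = 2)
  # bound protein (complexes) never exceeds the protein supplied
  theta <- site_occupancy(tt$protein_conc_nM, tt$dna_conc_nM, 48)
  expect_true(all(theta * 2 * tt$dna_conc_nM <= tt$protein_conc_nM + 1e-9))
  expect_equal(tt$frac_unbound + tt$frac_lower + tt$frac_super,
               rep(1, nrow(tt)), tolerance = 1e-12)
  # at the half-occupancy concentration the lower shift peaks near 0.5
  p_half <- uniroot(function(p) site_occupancy(p, 5, 48) - 0.5,
                    c(1, 1e4))$root
  tt_half <- simulate_titration(kd = 48, dna_conc = 5,
                                protein_concs = p_half, mode = "tandem",
                                noise_cv = 0)
  expect_equal(tt_half$frac_lower, 0.5, tolerance = 1e-6)
  # noisy fractions still sum to one after renormalisation
  tn <- simulate_titration(kd = 48, noise_cv = 0.05, seed = 3)
  expect_equal(tn$frac_unbound + tn$frac_lower + tn$frac_super,
               rep(1, nrow(tn)), tolerance = 1e-12)
})

test_that("ACF simulation encodes the oligomer order in the amplitude", {
  for (m in c(1, 3)) {
    ac <- simulate_acf(n_native = 0.3, oligomer_order = m,
                       noise_rel_sd = 0, seed = 1)
    fn <- fit_acf(ac[ac$condition == "native", ], kappa = 5)
    fd <- fit_acf(ac[ac$condition == "denatured", ], kappa = 5)
    expect_equal(fd$n_particles / fn$n_particles, m, tolerance = 1e-6)
  }
})

test_that("simulated peak lists are fully matchable at zero error", {
  prot <- "SFIASEISSIERGRATKPLMKSRHQDLVNWYKCDEFGHIKLMNPQRSTVWYAR"
  peps <- tryptic_digest(prot)
  pl <- simulate_peaklist(prot, mass_error_sd = 0, n_contaminants = 0,
                          mz_range = c(100, 3500), seed = 8)
  res <- pmf_match(pl, peps, tolerance = 0.25)
  expect_equal(length(res$unmatched_observed), 0L)
  # 0.1 Da calibration error still matches everything at 0.25 Da tolerance
  withr::with_seed(12, {
    ok <- replicate(20, {
      pl2 <- simulate_peaklist(prot, mass_error_sd = 0.1,
                               n_contaminants = 0, mz_range = c(100, 3500))
      length(pmf_match(pl2, peps, tolerance = 0.25)$unmatched_observed)
    })
    expect_lte(mean(ok > 0), 0.05)
  })
})

test_that("gel round trip stays within 0.2 units at 1%-of-span noise", {
  withr::with_seed(31, {
    meds <- replicate(15, {
      gel <- simulate_gel("assay2", constructs = znf55(), true_units = 3,
                          n_gels = 1, lane_offset_sd = 1, band_noise_sd = 1)
      suppressWarnings(
        glance(assay2_stoichiometry(gel, a2_ladder(), znf55(),
                                    "single-75"))$mean_units)
    })
    expect_lt(abs(median(meds) - 3), 0.2)
  })
})
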