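test_that("fraction bound matches the closed form and its limits", {
  expect_equal(fraction_bound(48, 5, 48), (101 - sqrt(9241)) / 10,
               tolerance = 1e-12)
  expect_equal(round(fraction_bound(48, 5, 48), 3), 0.487)
  expect_equal(fraction_bound(0, 5, 48), 0)
  expect_gt(fraction_bound(1e9, 5, 48), 0.9999)
  # dilute-DNA limit reduces to the hyperbola
  expect_equal(fraction_bound(30, 0, 50), 30 / (30 + 50), tolerance = 1e-12)
  expect_equal(fraction_bound(30, 1e-9, 50), 30 / (30 + 50),
               tolerance = 1e-6)
  expect_error(fraction_bound(-1, 5, 48),
               class = "oligostate_argument_error")
})

test_that("fraction bound is stable and monotone across 8 decades", {
  conc <- 10^seq(-3, 5, length.out = 200)
  for (d0 in c(1e-3, 5, 1e3)) {
    fb <- fraction_bound(conc, d0, 48)
    expect_true(all(is.finite(fb)))
    expect_true(all(fb >= 0 & fb <= 1))
    expect_true(all(diff(fb) > 0))
    # mass conservation: bound DNA cannot exceed available protein
    expect_true(all(fb * d0 <= conc + 1e-9))
  }
})

test_that("tandem fractions are binomial in site occupancy", {
  tf <- tandem_fractions(c(0, 0.5, 1))
  expect_equal(tf$fraction_unbound, c(1, 0.25, 0))
  expect_equal(tf$fraction_lower, c(0, 0.5, 0))
  expect_equal(tf$fraction_super, c(0, 0.25, 1))
  theta <- seq(0, 1, by = 0.001)
  tfg <- tandem_fractions(theta)
  sums <- tfg$fraction_unbound + tfg$fraction_lower + tfg$fraction_super
  expect_equal(sums, rep(1, length(theta)), tolerance = 1e-12)
  # grid-search oracle: lower-shift fraction peaks at half occupancy
  expect_equal(theta[which.max(tfg$fraction_lower)], 0.5)
  expect_equal(max(tfg$fraction_lower), 0.5)
  expect_error(tandem_fractions(1.2), class = "oligostate_argument_error")
})

test_that("K_D is recovered exactly from noise-free titrations", {
  for (kd in c(10, 48, 200)) {
    tt <- simulate_titration(kd = kd, dna_conc = 5, noise_cv = 0, seed = 1)
    fit <- fit_kd(tt)
    expect_equal(fit$kd, kd, tolerance = 1e-6)
  }
  # tandem-sum mode runs and returns a positive constant with finite SE
  tt2 <- simulate_titration(kd = 48, mode = "tandem", noise_cv = 0,
                            seed = 2)
  f2 <- fit_kd(tt2, mode = "tandem_sum")
  expect_gt(f2$kd, 0)
  expect_true(is.finite(f2$se))
})

test_that("K_D recovery stays within 10% median error at 5% noise", {
  withr::with_seed(11, {
    rel <- replicate(100, {
      tt <- simulate_titration(kd = 48, noise_cv = 0.05)
      abs(fit_kd(tt)$kd - 48) / 48
    })
    expect_lt(median(rel), 0.10)
  })
})

test_that("degenerate titrations are rejected", {
  expect_error(fit_kd(data.frame(protein_conc_nM = 1, dna_conc_nM = 5,
                                 frac_unbound = 0.5)),
               class = "oligostate_fit_error")
  sat <- data.frame(protein_conc_nM = c(10, 100, 1000), dna_conc_nM = 5,
                    frac_unbound = c(0, 0, 0))
  expect_error(fit_kd(sat), class = "oligostate_fit_error")
})

test_that("band patterns discriminate single- from multi-DNA binding", {
  frags <- rbind(dna_fragment("short-75", 75), dna_fragment("long-273", 273))
  cons <- znf55()
  m1 <- predict_band_pattern("one_dna_per_complex", frags, cons)
  m2 <- predict_band_pattern("multi_dna_per_complex", frags, cons)
  expect_equal(m1$n_bands, 4)
  expect_equal(m2$n_bands, 5)
  # one fragment: free + complex under either model
  one <- predict_band_pattern("one_dna_per_complex", frags[1, ], cons)
  expect_equal(one$n_bands, 2)
  # siteless fragments are dropped with a warning
  with_dead <- rbind(frags[1, ], dna_fragment("dead", 100, n_sites = 0))
  expect_warning(pd <- predict_band_pattern("one_dna_per_complex",
                                            with_dead, cons),
                 class = "oligostate_no_site_fragment")
  expect_equal(pd$n_bands, 2)
})

test_that("band-pattern counts follow the combinatorial rule", {
  cons <- znf55()
  for (nf in 1:2) {
    frags <- dplyr::bind_rows(lapply(seq_len(nf), function(i) {
      dna_fragment(paste0("f", i), 50 + 100 * i)
    }))
    m1 <- predict_band_pattern("one_dna_per_complex", frags, cons)
    expect_equal(m1$n_bands, 2 * nf)
    m2 <- predict_band_pattern("multi_dna_per_complex", frags, cons)
    expect_equal(m2$n_bands, if (nf == 2) nf + 3 else 2)
  }
})

test_that("restriction digest rearranges bound species as designed", {
  tandem <- dna_fragment("tandem-232-cut", 232, n_sites = 2,
                         cut_products = c(75, 157))
  cons <- znf55()
  free <- digest_rearrangement(tandem, "free")
  expect_equal(sort(free$species$mw_kd), sort(dna_mw(c(75, 157))))
  expect_equal(free$n_bands, 2)

  sup <- digest_rearrangement(tandem, "super", construct = cons,
                              n_units = 3)
  expect_equal(sup$n_bands, 2)
  expect_equal(sort(sup$species$mw_kd),
               sort(dna_mw(c(75, 157)) + 3 * 55))
  expect_true(all(sup$species$n_complexes == 1L))

  uncut <- dna_fragment("plain", 114, n_sites = 2)
  expect_error(digest_rearrangement(uncut, "super", cons),
               class = "oligostate_argument_error")
})
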