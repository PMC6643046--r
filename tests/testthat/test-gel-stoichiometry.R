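test_that("unit summaries reproduce the worked FCS-table convention", {
  s <- summarize_units(c(3.84, 3.43, 3.35, 2.95, 3.15))
  expect_equal(round(s$mean_units, 2), 3.34)
  expect_equal(round(s$ci95_half_width, 2), 0.41)
  s2 <- summarize_units(c(1.47, 1.23, 1.76))
  expect_equal(round(s2$mean_units, 2), 1.49)
  expect_equal(round(s2$ci95_half_width, 2), 0.66)
  # zero variance, single measurement, empty input
  expect_equal(summarize_units(c(2, 2, 2))$ci95_half_width, 0)
  expect_warning(s1 <- summarize_units(3), class = "oligostate_ci_undefined")
  expect_true(is.na(s1$ci95_half_width))
  expect_error(summarize_units(numeric()),
               class = "oligostate_argument_error")
})

test_that("both assays invert their forward model exactly at zero noise", {
  cons <- znf55()
  for (n in 1:6) {
    g1 <- simulate_gel("assay1", constructs = cons, true_units = n,
                       lane_offset_sd = 0, band_noise_sd = 0, seed = n)
    u1 <- assay1_stoichiometry(g1, a1_frags(), cons)$measurements$units
    expect_equal(u1, rep(n, length(u1)), tolerance = 1e-6)

    g2 <- simulate_gel("assay2", constructs = cons, true_units = n,
                       n_gels = 2, lane_offset_sd = 0, band_noise_sd = 0,
                       seed = 100 + n)
    u2 <- assay2_stoichiometry(g2, a2_ladder(), cons,
                               "single-75")$measurements$units
    expect_equal(u2, rep(n, length(u2)), tolerance = 1e-6)
  }
})

test_that("zero-noise inversion is exact for arbitrary lane offsets", {
  cons <- znf55()
  g <- simulate_gel("assay1", constructs = cons, true_units = 3,
                    lane_offset_sd = 8, band_noise_sd = 0, seed = 9)
  u <- assay1_stoichiometry(g, a1_frags(), cons)$measurements$units
  expect_equal(u, rep(3, length(u)), tolerance = 1e-6)
})

test_that("assays agree with each other as noise shrinks", {
  withr::with_seed(21, {
    for (cons_i in seq_len(nrow(znf_constructs()))) {
      cons <- znf_constructs()[cons_i, ]
      g1 <- simulate_gel("assay1", constructs = cons, true_units = 3,
                         lane_offset_sd = 0.05, band_noise_sd = 0.05)
      g2 <- simulate_gel("assay2", constructs = cons, true_units = 3,
                         n_gels = 2, lane_offset_sd = 0.05,
                         band_noise_sd = 0.05)
      m1 <- glance(assay1_stoichiometry(g1, a1_frags(), cons))$mean_units
      m2 <- glance(assay2_stoichiometry(g2, a2_ladder(), cons,
                                        "single-75"))$mean_units
      expect_lt(abs(m1 - m2), 0.15)
    }
  })
})

test_that("a free-DNA-only lane in assay II yields zero units", {
  cons <- znf55()
  gel <- simulate_gel("assay2", constructs = cons, true_units = 3,
                      n_gels = 1, lane_offset_sd = 0, band_noise_sd = 0,
                      seed = 5)
  # re-label the ladder's 75-bp free band as a protein-free complex lane
  extra <- gel[gel$band_type == "free_dna" & gel$fragment_name == "single-75", ]
  extra$band_type <- "lower_shift"
  extra$construct_name <- "ZnF"
  refs <- gel[gel$lane_id == "lane_ladder" &
                gel$band_type %in% c("ref_upper", "ref_lower"), ]
  u <- assay2_stoichiometry(dplyr::bind_rows(gel, extra), a2_ladder(),
                            cons, "single-75")
  lane_units <- u$measurements$units[u$measurements$lane_id == "lane_ladder"]
  expect_equal(lane_units, 0, tolerance = 1e-6)
})

test_that("insufficient standards or missing bands raise data errors", {
  cons <- znf55()
  g1 <- simulate_gel("assay1", constructs = cons, true_units = 3,
                     lane_offset_sd = 0, band_noise_sd = 0, seed = 2)
  single_standard <- g1[g1$lane_id %in% c("lane1", "lane7"), ]
  expect_error(
    suppressWarnings(assay1_stoichiometry(single_standard[
      !(single_standard$lane_id == "lane1" &
          single_standard$band_type == "lower_shift"), ],
      a1_frags(), cons)),
    class = "oligostate_data_error")
  no_super <- g1[g1$band_type != "supershift", ]
  expect_error(assay1_stoichiometry(no_super, a1_frags(), cons),
               regexp = "supershift", class = "oligostate_data_error")

  g2 <- simulate_gel("assay2", constructs = cons, true_units = 3,
                     n_gels = 1, lane_offset_sd = 0, band_noise_sd = 0,
                     seed = 3)
  short_ladder <- g2[!(g2$band_type == "free_dna" &
                         g2$fragment_name %in%
                         c("single-273", "single-543", "single-740")), ]
  expect_error(assay2_stoichiometry(short_ladder, a2_ladder(), cons,
                                    "single-75"),
               regexp = "ladder", class = "oligostate_data_error")
})

test_that("hypothesis fitting recovers the generating unit count", {
  cons4 <- znf_constructs()
  for (truth in c(2, 3)) {
    gel <- simulate_gel("assay2", constructs = cons4, true_units = truth,
                        n_gels = 2, lane_offset_sd = 0.5,
                        band_noise_sd = 0.5, seed = 30 + truth)
    hf <- stoichiometry_hypothesis_fit(gel, a2_ladder(), cons4, "single-75")
    expect_equal(hf$best, truth)
    # the winning hypothesis hugs the identity line
    win <- hf$fits[hf$fits$n_units == truth, ]
    expect_lt(abs(win$slope - 1), 0.1)
  }
  # single-hypothesis degenerate choice set still reports its fit
  gel <- simulate_gel("assay2", constructs = cons4, true_units = 3,
                      n_gels = 1, lane_offset_sd = 0, band_noise_sd = 0,
                      seed = 33)
  hf1 <- stoichiometry_hypothesis_fit(gel, a2_ladder(), cons4, "single-75",
                                      hypotheses = 3)
  expect_equal(nrow(hf1$fits), 1L)
  expect_equal(hf1$best, 3)
})

test_that("one-way ANOVA behaves at both extremes", {
  flat <- data.frame(construct_name = rep(c("A", "B"), each = 3),
                     units = rep(3, 6))
  out <- anova_units(flat)
  expect_equal(out$statistic[1], 0)
  expect_equal(out$p.value[1], 1)

  withr::with_seed(8, {
    sep <- data.frame(
      construct_name = rep(c("A", "B"), each = 10),
      units = c(rnorm(10, 3, 0.1), rnorm(10, 5, 0.1)))
    expect_lt(anova_units(sep)$p.value[1], 1e-3)
  })

  expect_error(anova_units(data.frame(construct_name = "A", units = 3)),
               class = "oligostate_argument_error")
  expect_error(anova_units(data.frame(
    construct_name = c("A", "A", "B"), units = c(3, 3.2, 3))),
    class = "oligostate_argument_error")
})
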