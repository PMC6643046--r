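test_that("tryptic digestion follows the Keil rule and partitions", {
  expect_equal(tryptic_digest("GRATKPLMKSR")$sequence,
               c("GR", "ATKPLMK", "SR"))
  # sequence without K/R: one peptide spanning the whole protein
  d <- tryptic_digest("ACDEFGHILMNPQSTVWY")
  expect_equal(nrow(d), 1L)
  expect_equal(d$start, 1L)
  expect_equal(d$end, 18L)
  # partition property over random proteins at 0 missed cleavages
  withr::with_seed(3, {
    for (i in 1:10) {
      prot <- random_peptide(80)
      dg <- tryptic_digest(prot)
      expect_equal(paste(dg$sequence, collapse = ""), prot)
      expect_equal(dg$start[1], 1L)
      expect_equal(dg$end[nrow(dg)], nchar(prot))
    }
  })
  # missed cleavages enumerate contiguous joins
  d1 <- tryptic_digest("GRATKPLMKSR", max_missed_cleavages = 1)
  expect_true(all(c("GRATKPLMK", "ATKPLMKSR") %in% d1$sequence))
  expect_error(tryptic_digest("GRB2"), class = "oligostate_argument_error")
})

test_that("peptide masses match independently computed monoisotopic values", {
  # frozen with an independent proteomics mass calculator
  expect_equal(peptide_mz("G"), 76.0393, tolerance = 1e-4)
  expect_equal(peptide_mz("SFIASEISSIER"), 1338.68997, tolerance = 1e-4)
  expect_equal(peptide_mz("HQRTHTGEKPYVCR"), 1768.86599, tolerance = 1e-4)
  expect_equal(peptide_mz("HQRTHTGEKPYVCR", carbamidomethyl = FALSE),
               1711.84453, tolerance = 1e-4)
  expect_equal(peptide_mz("SDKPDLGYFFDDHVR"), 1810.83949, tolerance = 1e-4)
  expect_equal(peptide_mz("LLFWGTPGVLIPPAEAAR"), 1908.07418,
               tolerance = 1e-4)
})

test_that("cysteine-free anchor peptides sit 0-0.1 Da above measured values", {
  anchors <- anchor_peptides()
  no_cys <- anchors[!grepl("C", anchors$sequence), ]
  delta <- peptide_mz(no_cys$sequence) - no_cys$observed_mz
  expect_true(all(delta >= 0 & delta <= 0.1))
  expect_true(all(abs(delta) <= 0.25))
})

test_that("mass additivity holds under concatenation", {
  withr::with_seed(5, {
    for (i in 1:10) {
      a <- random_peptide(sample(3:12, 1))
      b <- random_peptide(sample(3:12, 1))
      expect_equal(peptide_mz(paste0(a, b)),
                   peptide_mz(a) + peptide_mz(b) -
                     oligostate:::MASS_WATER - oligostate:::MASS_PROTON,
                   tolerance = 1e-9)
    }
  })
})

test_that("fragment ions obey the series relations and b/y sum rule", {
  ions <- fragment_ions("SFIASEISSIER")
  y1 <- ions$mz[ions$series == "y" & ions$index == 1]
  expect_equal(y1, 175.11895, tolerance = 1e-4)   # C-terminal R
  b2 <- ions$mz[ions$series == "b" & ions$index == 2]
  expect_equal(b2, 235.10772, tolerance = 1e-4)   # S + F
  a2 <- ions$mz[ions$series == "a" & ions$index == 2]
  expect_equal(a2, b2 - 27.994915, tolerance = 1e-9)

  withr::with_seed(6, {
    for (i in 1:10) {
      pep <- random_peptide(sample(4:15, 1))
      L <- nchar(pep)
      ii <- fragment_ions(pep)
      mh <- peptide_mz(pep)
      for (k in seq_len(L - 1)) {
        b_k <- ii$mz[ii$series == "b" & ii$index == k]
        y_rest <- ii$mz[ii$series == "y" & ii$index == L - k]
        expect_equal(b_k + y_rest, mh + oligostate:::MASS_PROTON,
                     tolerance = 1e-9)
      }
    }
  })
  expect_error(fragment_ions("G"), class = "oligostate_argument_error")
})

test_that("peak matching honours tolerance, ties and coverage accounting", {
  prot <- "SFIASEISSIERGRATKPLMKSRHQDLVNWYKCDEFGHIKLMNPQRSTVWYAR"
  peps <- tryptic_digest(prot)
  # exact self-match assigns every peak
  res <- pmf_match(peps$mz_mh, peps, tolerance = 0.25)
  expect_equal(nrow(res$matched), nrow(peps))
  expect_equal(length(res$unmatched_observed), 0L)
  expect_equal(res$coverage_percent, 100)
  # offsets beyond the tolerance never match
  res_off <- pmf_match(peps$mz_mh + 0.3, peps, tolerance = 0.25)
  expect_equal(nrow(res_off$matched), 0L)
  expect_equal(res_off$coverage_percent, 0)
  # coverage is an interval union: residues 1-30 and 41-60 of a length-100
  # protein cover exactly half
  fake <- tibble::tibble(
    sequence = c("A", "B"), start = c(1L, 41L), end = c(30L, 60L),
    missed_cleavages = 0L, mz_mh = c(1000, 2000))
  res_cov <- pmf_match(c(1000, 2000), fake, protein_length = 100)
  expect_equal(res_cov$coverage_percent, 50)
  # order invariance of the peak list
  res_rev <- pmf_match(rev(peps$mz_mh), peps, tolerance = 0.25)
  expect_equal(res_rev$coverage_percent, res$coverage_percent)
  expect_equal(nrow(res_rev$matched), nrow(res$matched))
  expect_lte(res$coverage_percent, 100)
  expect_error(pmf_match(1000, peps[0, ]),
               class = "oligostate_argument_error")
})

test_that("matches within tolerance report signed deltas bounded by it", {
  prot <- "SFIASEISSIERGRATKPLMKSRHQDLVNWYK"
  peps <- tryptic_digest(prot)
  obs <- peps$mz_mh + c(0.05, -0.1, 0.2, 0.01, -0.24)[seq_len(nrow(peps))]
  res <- pmf_match(obs, peps, tolerance = 0.25)
  expect_true(all(abs(res$matched$delta) <= 0.25))
})
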