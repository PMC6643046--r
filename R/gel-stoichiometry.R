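#' Summarise per-measurement unit counts
#'
#' Arithmetic mean with a two-sided 95% Student-t confidence half-width,
#' `t(0.975, n - 1) * sd / sqrt(n)`. With a single measurement the mean is
#' returned and the half-width is `NA` (flagged undefined).
#'
#' @param units Numeric vector of per-measurement unit counts.
#' @return Tibble with `mean_units`, `ci95_half_width`, `n`.
#' @examples
#' summarize_units(c(3.84, 3.43, 3.35, 2.95, 3.15))  # 3.34 (0.41)
#' @export
summarize_units <- function(units) {
  s <- t_summary(units)
  if (s$n == 1L) {
    warn("Only one measurement: 95% CI is undefined.",
         class = "oligostate_ci_undefined")
  }
  tibble(mean_units = s$mean, ci95_half_width = s$ci95_half_width, n = s$n)
}

new_stoichiometry_result <- function(construct, assay, measurements) {
  structure(
    list(construct_name = construct$construct_name,
         monomer_mw_kd = construct$monomer_mw_kd,
         assay = assay,
         measurements = measurements,
         summary = summarize_units(measurements$units)),
    class = "stoichiometry_result")
}

#' @export
print.stoichiometry_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Stoichiometry (%s) for %s [monomer %.4g kD]\n",
              x$assay, x$construct_name, x$monomer_mw_kd))
  cat(sprintf("  %.2f units (CI %.2f), n = %d\n",
              s$mean_units, s$ci95_half_width, s$n))
  invisible(x)
}

#' @export
#' @method tidy stoichiometry_result
tidy.stoichiometry_result <- function(x, ...) {
  dplyr::mutate(x$measurements, construct_name = x$construct_name,
                assay = x$assay, .before = 1L)
}

#' @export
#' @method glance stoichiometry_result
glance.stoichiometry_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(construct_name = x$construct_name, assay = x$assay),
    x$summary)
}

#' @export
#' @method autoplot stoichiometry_result
autoplot.stoichiometry_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$construct_name,
                                   y = .data$units)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "protein units per complex",
                  title = sprintf("%s stoichiometry (%s)",
                                  object$construct_name, object$assay))
}

# profile the unknown single-complex protein mass S: bands of known
# composition have MW = dna_mw + n_complexes * S with the same S in every
# lane (lower shift: 1 complex; supershift: 2), so S is the value making
# log10(dna_mw + n_complexes * S) most linear in the normalised migration
# distance. Supershift bands are essential for identifiability at realistic
# noise: with single complexes alone the profile is nearly flat in S.
# The RSS profile is not unimodal in S (the log flattens again at large S),
# so a coarse grid brackets the global basin before local refinement.
profile_complex_mass <- function(norm_distance, dna_mw_kd, n_complexes,
                                 upper) {
  rss <- function(s) {
    y <- log10(dna_mw_kd + n_complexes * s)
    sum(lm(y ~ norm_distance)$residuals^2)
  }
  grid <- seq(0, upper, length.out = 400L)
  vals <- vapply(grid, rss, numeric(1))
  best <- which.min(vals)
  step <- grid[2] - grid[1]
  lo <- max(0, grid[best] - step)
  hi <- min(upper, grid[best] + step)
  coarse <- optimize(rss, interval = c(lo, hi), tol = 1e-4)
  fine <- optimize(rss, interval = c(max(0, coarse$minimum - 0.5),
                                     coarse$minimum + 0.5), tol = 1e-11)
  fine$minimum
}

#' Stoichiometry from tandem-site supershift differencing (assay I)
#'
#' In assay I the standards are DNA-protein complexes themselves: single
#' complexes (lower shifts) on fragments of increasing length. After
#' reference normalisation, a standard curve of log10 complex MW against
#' migration lag is fitted; for each tandem-site lane the MW difference
#' between the supershift (two complexes) and the lower shift (one complex)
#' estimates the mass of one additional complex, and dividing by the
#' construct's monomer MW gives the unit count. One unit estimate is produced
#' per tandem lane per gel.
#'
#' The standards' absolute MW includes the unknown single-complex protein
#' mass S. By default (`protein_mass = "profile"`) S is estimated jointly by
#' one-dimensional profiling of the regression residual sum of squares over
#' every band of known composition (lower shifts carry one complex,
#' supershifts two), which makes the noise-free forward model exactly
#' invertible and keeps S identifiable at realistic noise; a known numeric S
#' may be supplied instead. Profiling needs at least three such bands; with
#' fewer, S falls back to 0 (DNA-only standards) with a warning.
#'
#' @param gel Gel band table in `assay1` layout: >= 2 lanes with lower-shift
#'   standards, >= 1 tandem lane carrying both a lower shift and a supershift,
#'   and both reference bands in every lane.
#' @param fragments Fragment table ([dna_fragment()] rows) resolving
#'   `fragment_name` to lengths.
#' @param construct A [construct()] row (or name, with `constructs`).
#' @param constructs Optional construct table for name lookup.
#' @param protein_mass `"profile"` (default) or a fixed single-complex
#'   protein mass in kD.
#' @param kd_per_bp DNA mass per bp, kD. Default `0.650`.
#'
#' @return A `stoichiometry_result`: per-measurement unit counts
#'   (tidy with [tidy()]) and their Student-t summary ([glance()]).
#' @export
assay1_stoichiometry <- function(gel, fragments, construct, constructs = NULL,
                                 protein_mass = "profile",
                                 kd_per_bp = 0.650) {
  construct <- resolve_construct(construct, constructs)
  norm <- normalize_migration(gel, c("lower_shift", "supershift"))
  norm <- dplyr::left_join(
    norm, dplyr::select(fragments, "fragment_name", "length_bp"),
    by = "fragment_name")
  if (anyNA(norm$length_bp)) {
    abort(sprintf("Fragment(s) %s not found in `fragments`.",
                  paste(unique(norm$fragment_name[is.na(norm$length_bp)]),
                        collapse = ", ")),
          class = "oligostate_data_error")
  }

  per_gel <- norm |>
    dplyr::group_by(.data$gel_id) |>
    dplyr::group_map(function(g, key) {
      lower <- dplyr::filter(g, .data$band_type == "lower_shift")
      super <- dplyr::filter(g, .data$band_type == "supershift")
      if (nrow(lower) < 2L) {
        abort(sprintf(
          "Gel %s: assay I needs >= 2 lanes with lower-shift standards.",
          key$gel_id), class = "oligostate_data_error")
      }
      if (nrow(super) == 0L) {
        abort(sprintf(
          "Gel %s: no supershift band in any tandem lane.", key$gel_id),
          class = "oligostate_data_error")
      }
      dna <- dna_mw(lower$length_bp, kd_per_bp)
      s_mass <- if (identical(protein_mass, "profile")) {
        if (nrow(lower) + nrow(super) < 3L) {
          warn(paste("Fewer than 3 complex bands: cannot profile the complex",
                     "protein mass; falling back to DNA-only standards."),
               class = "oligostate_profile_fallback")
          0
        } else {
          profile_complex_mass(
            c(lower$norm_distance, super$norm_distance),
            dna_mw(c(lower$length_bp, super$length_bp), kd_per_bp),
            n_complexes = c(rep(1, nrow(lower)), rep(2, nrow(super))),
            upper = 100 * construct$monomer_mw_kd)
        }
      } else {
        check_num(protein_mass, "protein_mass", non_negative = TRUE,
                  scalar = TRUE)
        protein_mass
      }
      curve <- fit_standard_curve(
        tibble(norm_distance = lower$norm_distance, mw_kd = dna + s_mass))
      pairs <- dplyr::inner_join(
        dplyr::select(lower, "lane_id", "fragment_name",
                      lower_d = "norm_distance"),
        dplyr::select(super, "lane_id", super_d = "norm_distance"),
        by = "lane_id")
      dmw <- withr::with_options(list(warn = -1), {
        estimate_mw(curve, pairs$super_d) - estimate_mw(curve, pairs$lower_d)
      })
      tibble(gel_id = key$gel_id, lane_id = pairs$lane_id,
             fragment_name = pairs$fragment_name,
             dmw_kd = dmw, units = dmw / construct$monomer_mw_kd,
             complex_mass_kd = s_mass, r_squared = curve$r_squared)
    }) |>
    dplyr::bind_rows()

  new_stoichiometry_result(construct, "assay_I", per_gel)
}

#' Stoichiometry from a free-DNA ladder (assay II)
#'
#' In assay II the standard curve is fitted on a ladder of unbound DNA
#' fragments of known sizes (at least three), and the complex MW is read off
#' from the lower-shift migration of the probe-bound construct. The unit
#' count is `(MW_complex - dna_mw(probe)) / monomer_mw`; one estimate per
#' complex lane per replicate gel.
#'
#' @inheritParams assay1_stoichiometry
#' @param gel Gel band table in `assay2` layout: a free-DNA ladder of >= 3
#'   sizes plus lower-shift lane(s) for the construct, references in every
#'   lane.
#' @param probe_fragment The probe fragment carrying the binding site
#'   (a [dna_fragment()] row or name resolved in `fragments`).
#'
#' @return A `stoichiometry_result`.
#' @export
assay2_stoichiometry <- function(gel, fragments, construct, probe_fragment,
                                 constructs = NULL, kd_per_bp = 0.650) {
  construct <- resolve_construct(construct, constructs)
  probe <- resolve_fragment(probe_fragment, fragments)
  norm <- normalize_migration(gel, c("free_dna", "lower_shift"))
  norm <- dplyr::left_join(
    norm, dplyr::select(fragments, "fragment_name", "length_bp"),
    by = "fragment_name")

  per_gel <- norm |>
    dplyr::group_by(.data$gel_id) |>
    dplyr::group_map(function(g, key) {
      ladder <- g |>
        dplyr::filter(.data$band_type == "free_dna") |>
        dplyr::distinct(.data$length_bp, .keep_all = TRUE)
      if (nrow(ladder) < 3L) {
        abort(sprintf(
          "Gel %s: assay II needs a free-DNA ladder of >= 3 sizes.",
          key$gel_id), class = "oligostate_data_error")
      }
      shifts <- dplyr::filter(
        g, .data$band_type == "lower_shift",
        .data$construct_name == construct$construct_name)
      if (nrow(shifts) == 0L) {
        abort(sprintf("Gel %s: no lower-shift band for construct `%s`.",
                      key$gel_id, construct$construct_name),
              class = "oligostate_data_error")
      }
      curve <- fit_standard_curve(
        tibble(norm_distance = ladder$norm_distance,
               mw_kd = dna_mw(ladder$length_bp, kd_per_bp)))
      mw_complex <- withr::with_options(list(warn = -1), {
        estimate_mw(curve, shifts$norm_distance)
      })
      units <- (mw_complex - dna_mw(probe$length_bp, kd_per_bp)) /
        construct$monomer_mw_kd
      tibble(gel_id = key$gel_id, lane_id = shifts$lane_id,
             fragment_name = shifts$fragment_name,
             mw_complex_kd = mw_complex, units = units,
             r_squared = curve$r_squared)
    }) |>
    dplyr::bind_rows()

  new_stoichiometry_result(construct, "assay_II", per_gel)
}

#' Which oligomer hypothesis best explains observed migrations?
#'
#' For each hypothesised unit count, the expected migration of every
#' construct's complex is computed from the inverse standard curve
#' (free-DNA ladder, assay II layout) and the observed lower-shift migrations
#' are regressed on the expected ones. The best hypothesis is the one lying
#' closest to the identity line, scored by the mean squared pointwise
#' deviation of observed from expected migration (reported as
#' `identity_deviation`, alongside the regression slope, intercept and
#' r-squared): only the true stoichiometry predicts migrations that line up
#' one-to-one with the observations.
#'
#' @param gel Assay II gel table containing lower shifts for >= 2 constructs
#'   of distinct monomer MW (a single complex species cannot discriminate).
#' @param fragments Fragment table.
#' @param constructs Construct table covering every `construct_name` with a
#'   lower shift in the gel.
#' @param probe_fragment Probe fragment (row or name).
#' @param hypotheses Candidate unit counts. Default `c(2, 3, 4)`.
#' @param kd_per_bp DNA mass per bp, kD.
#'
#' @return A `hypothesis_fit` object: tibble of per-hypothesis fits
#'   (`n_units`, `slope`, `intercept`, `r_squared`, `identity_deviation`)
#'   with the winning count in `$best`.
#' @export
stoichiometry_hypothesis_fit <- function(gel, fragments, constructs,
                                         probe_fragment,
                                         hypotheses = c(2, 3, 4),
                                         kd_per_bp = 0.650) {
  check_num(hypotheses, "hypotheses", positive = TRUE)
  probe <- resolve_fragment(probe_fragment, fragments)
  norm <- normalize_migration(gel, c("free_dna", "lower_shift"))
  norm <- dplyr::left_join(
    norm, dplyr::select(fragments, "fragment_name", "length_bp"),
    by = "fragment_name")

  shifts <- norm |>
    dplyr::filter(.data$band_type == "lower_shift") |>
    dplyr::inner_join(
      dplyr::select(constructs, "construct_name", "monomer_mw_kd"),
      by = "construct_name")
  if (nrow(shifts) == 0L) {
    abort("No complex (lower-shift) bands in the gel table.",
          class = "oligostate_data_error")
  }
  if (dplyr::n_distinct(shifts$monomer_mw_kd) < 2L) {
    abort(paste("Hypothesis fitting needs lower shifts from >= 2 constructs",
                "with distinct monomer MWs."),
          class = "oligostate_data_error")
  }

  # per-gel ladder curves; expected distances are gel-specific
  curves <- norm |>
    dplyr::filter(.data$band_type == "free_dna") |>
    dplyr::group_by(.data$gel_id) |>
    dplyr::group_map(function(g, key) {
      g <- dplyr::distinct(g, .data$length_bp, .keep_all = TRUE)
      if (nrow(g) < 3L) {
        abort(sprintf("Gel %s: ladder of >= 3 sizes required.", key$gel_id),
              class = "oligostate_data_error")
      }
      tibble(gel_id = key$gel_id,
             curve = list(fit_standard_curve(
               tibble(norm_distance = g$norm_distance,
                      mw_kd = dna_mw(g$length_bp, kd_per_bp)))))
    }) |>
    dplyr::bind_rows()

  fits <- purrr::map_dfr(hypotheses, function(n) {
    df <- shifts |>
      dplyr::left_join(curves, by = "gel_id") |>
      dplyr::mutate(expected = purrr::map2_dbl(
        .data$curve, .data$monomer_mw_kd,
        function(cv, m) expected_distance(
          cv, dna_mw(probe$length_bp, kd_per_bp) + n * m)))
    fit <- lm(df$norm_distance ~ df$expected)
    slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
    tss <- sum((df$norm_distance - mean(df$norm_distance))^2)
    r2 <- if (tss == 0) 1 else max(0, 1 - sum(fit$residuals^2) / tss)
    # deviation from the identity line measured pointwise: robust because
    # slope and intercept deviations live on incommensurate scales
    tibble(n_units = n, slope = slope, intercept = intercept,
           r_squared = r2,
           identity_deviation = mean((df$norm_distance - df$expected)^2))
  })

  structure(list(fits = fits,
                 best = fits$n_units[which.min(fits$identity_deviation)]),
            class = "hypothesis_fit")
}

#' @export
print.hypothesis_fit <- function(x, ...) {
  cat("Stoichiometry hypothesis fit (observed ~ expected migration)\n")
  print(x$fits)
  cat(sprintf("Best-supported unit count: %g\n", x$best))
  invisible(x)
}

#' @export
#' @method tidy hypothesis_fit
tidy.hypothesis_fit <- function(x, ...) x$fits

#' Compare unit estimates across constructs with one-way ANOVA
#'
#' Fixed-effects one-way ANOVA of per-measurement unit counts grouped by
#' construct, testing whether stoichiometry estimates differ between
#' constructs beyond experimental variation.
#'
#' @param results A list of `stoichiometry_result` objects, or a data frame
#'   with columns `construct_name` and `units`. Every group needs >= 2
#'   measurements and >= 2 groups are required.
#'
#' @return Tibble with `term`, `df`, `sumsq`, `meansq`, `statistic`,
#'   `p.value` (one row for the between-construct term, one residual row).
#' @export
anova_units <- function(results) {
  df <- if (is.data.frame(results)) {
    check_cols(results, c("construct_name", "units"), "`results`")
    as_tibble(results)
  } else {
    purrr::map_dfr(results, function(r) {
      stopifnot(inherits(r, "stoichiometry_result"))
      tibble(construct_name = r$construct_name, units = r$measurements$units)
    })
  }
  counts <- dplyr::count(df, .data$construct_name)
  if (nrow(counts) < 2L) {
    abort("ANOVA needs >= 2 construct groups.",
          class = "oligostate_argument_error")
  }
  if (any(counts$n < 2L)) {
    abort(sprintf("Every group needs >= 2 measurements (offending: %s).",
                  paste(counts$construct_name[counts$n < 2L], collapse = ", ")),
          class = "oligostate_argument_error")
  }
  fit <- aov(units ~ construct_name, data = df)
  tab <- summary(fit)[[1]]
  out <- tibble(term = trimws(rownames(tab)), df = tab$Df,
                sumsq = tab$`Sum Sq`, meansq = tab$`Mean Sq`,
                statistic = tab$`F value`, p.value = tab$`Pr(>F)`)
  # no between-group variance (e.g. all groups identical constants): F = 0;
  # the comparison needs a tolerance because constant inputs leave only
  # floating-point fuzz in both sums of squares
  total_ss <- sum(out$sumsq)
  if (!is.na(out$sumsq[1]) &&
      out$sumsq[1] <= 1e-10 * max(total_ss, mean(df$units)^2, 1e-300)) {
    out$statistic[1] <- 0
    out$p.value[1] <- 1
  }
  out
}
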