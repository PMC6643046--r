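#' Fraction of DNA bound at equilibrium, with ligand depletion
#'
#' Exact two-component receptor-ligand equilibrium in solution: with total
#' protein `p0`, total DNA `d0` and dissociation constant `kd` (all nM), the
#' bound DNA fraction is the smaller root of the binding quadratic,
#'
#' `FB = ((p0 + d0 + kd) - sqrt((p0 + d0 + kd)^2 - 4 p0 d0)) / (2 d0)`,
#'
#' evaluated in the algebraically stable form `2 p0 / (b + sqrt(b^2 - 4 p0
#' d0))` with `b = p0 + d0 + kd`, which avoids catastrophic cancellation
#' across concentration scales and reduces smoothly to the hyperbola
#' `p0 / (p0 + kd)` in the dilute-DNA limit `d0 -> 0`.
#'
#' @param p0 Total protein concentration, nM (>= 0, vectorised).
#' @param d0 Total DNA concentration, nM (>= 0; 0 gives the hyperbolic
#'   limit).
#' @param kd Dissociation constant, nM (> 0).
#'
#' @return Fraction bound in `[0, 1]`, monotone non-decreasing in `p0`.
#' @examples
#' fraction_bound(48, 5, 48)   # 0.487
#' @export
fraction_bound <- function(p0, d0, kd) {
  check_num(p0, "p0", non_negative = TRUE)
  check_num(d0, "d0", non_negative = TRUE)
  check_num(kd, "kd", positive = TRUE)
  b <- p0 + d0 + kd
  disc <- pmax(b^2 - 4 * p0 * d0, 0)
  2 * p0 / (b + sqrt(disc))
}

#' Per-site occupancy of a multi-site DNA under depletion
#'
#' For `n_sites` independent, identical sites per DNA molecule, the per-site
#' occupancy satisfies the same binding quadratic with the total site
#' concentration `n_sites * d0` in place of the DNA concentration.
#'
#' @inheritParams fraction_bound
#' @param n_sites Specific sites per DNA molecule. Default 2.
#' @return Per-site occupancy theta in `[0, 1]`.
#' @export
site_occupancy <- function(p0, d0, kd, n_sites = 2) {
  check_num(n_sites, "n_sites", positive = TRUE, scalar = TRUE)
  fraction_bound(p0, n_sites * d0, kd)
}

#' Band fractions for a two-site DNA from per-site occupancy
#'
#' Two independent identical sites give binomial species fractions:
#' unbound `(1 - theta)^2`, single complex (lower shift) `2 theta (1 -
#' theta)`, double complex (supershift) `theta^2`. They sum to one exactly,
#' and the lower-shift fraction peaks at 0.5 when half the sites are filled.
#'
#' @param theta Per-site occupancy in `[0, 1]` (vectorised).
#' @return Tibble with `theta`, `fraction_unbound`, `fraction_lower`,
#'   `fraction_super`.
#' @export
tandem_fractions <- function(theta) {
  check_num(theta, "theta")
  if (any(theta < 0 | theta > 1)) {
    abort("`theta` must lie in [0, 1].", class = "oligostate_argument_error")
  }
  tibble(theta = theta,
         fraction_unbound = (1 - theta)^2,
         fraction_lower = 2 * theta * (1 - theta),
         fraction_super = theta^2)
}

#' Fit a dissociation constant to a binding titration
#'
#' Least-squares fit of the depletion-aware [fraction_bound()] isotherm to a
#' titration of fraction bound against total protein concentration
#' (log-spaced series supported; residuals are minimised untransformed, as
#' the data are presented on a semilogarithmic axis). In `tandem_sum` mode
#' the response is the sum of lower-shift and supershift fractions, the
#' effective single-K_D treatment of a two-site probe.
#'
#' @param points Data frame with columns `protein_conc_nM`, `dna_conc_nM`
#'   and either `frac_bound`, or `frac_unbound`, or (`frac_lower`,
#'   `frac_super`). At least 3 points spanning the transition.
#' @param mode `"single"` (response: `frac_bound` or `1 - frac_unbound`) or
#'   `"tandem_sum"` (response: `frac_lower + frac_super`).
#' @param active_fraction Optional scale on nominal protein concentration
#'   for lysate titrations where only a fraction of protein is active.
#'   Default 1.
#'
#' @return A `kd_fit` object with elements `kd` (nM), `se`, `residual_ss`,
#'   `n_points`, the data and the underlying `nls` fit. Methods: [tidy()],
#'   [glance()], [autoplot()].
#' @export
fit_kd <- function(points, mode = c("single", "tandem_sum"),
                   active_fraction = 1) {
  mode <- match.arg(mode)
  check_cols(points, c("protein_conc_nM", "dna_conc_nM"), "`points`")
  check_num(active_fraction, "active_fraction", positive = TRUE,
            scalar = TRUE)
  if (nrow(points) < 3L) {
    abort("At least 3 titration points are required.",
          class = "oligostate_fit_error")
  }
  y <- if (mode == "tandem_sum") {
    check_cols(points, c("frac_lower", "frac_super"), "`points`")
    points$frac_lower + points$frac_super
  } else if ("frac_bound" %in% names(points)) {
    points$frac_bound
  } else {
    check_cols(points, "frac_unbound", "`points`")
    1 - points$frac_unbound
  }
  check_num(y, "fraction bound")
  if (all(y <= 0) || all(y >= 1)) {
    abort("Responses are all zero or all saturated; K_D is unidentifiable.",
          class = "oligostate_fit_error")
  }
  p0 <- points$protein_conc_nM * active_fraction
  d0 <- points$dna_conc_nM

  # start value: protein concentration at half-maximal response
  ord <- order(p0)
  kd0 <- tryCatch(
    approx(y[ord], p0[ord], xout = max(y) / 2, ties = mean)$y,
    error = function(e) NA_real_)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(p0)

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ fraction_bound(p0, d0, kd),
                      start = list(kd = kd0), lower = 1e-9,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(sprintf("K_D fit did not converge: %s", conditionMessage(e)),
            class = "oligostate_fit_error")
    })
  est <- summary(fit)$coefficients
  structure(
    list(kd = unname(est["kd", "Estimate"]),
         se = unname(est["kd", "Std. Error"]),
         residual_ss = sum(stats::residuals(fit)^2),
         n_points = length(y), mode = mode,
         data = tibble(protein_conc_nM = p0, dna_conc_nM = d0,
                       frac_bound = y),
         fit = fit),
    class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("Equilibrium K_D fit (%s): %.3g nM (SE %.2g), n = %d, RSS = %.3g\n",
              x$mode, x$kd, x$se, x$n_points, x$residual_ss))
  invisible(x)
}

#' @export
#' @method tidy kd_fit
tidy.kd_fit <- function(x, ...) {
  tibble(term = "kd", estimate = x$kd, std.error = x$se)
}

#' @export
#' @method glance kd_fit
glance.kd_fit <- function(x, ...) {
  tibble(kd = x$kd, se = x$se, residual_ss = x$residual_ss,
         n_points = x$n_points, mode = x$mode)
}

#' @export
#' @method autoplot kd_fit
autoplot.kd_fit <- function(object, ...) {
  df <- object$data
  grid <- tibble(
    protein_conc_nM = 10^seq(log10(max(min(df$protein_conc_nM), 1e-3)),
                             log10(max(df$protein_conc_nM)), length.out = 120),
    dna_conc_nM = stats::median(df$dna_conc_nM))
  grid$frac_bound <- fraction_bound(grid$protein_conc_nM, grid$dna_conc_nM,
                                    object$kd)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$protein_conc_nM,
                                   y = .data$frac_bound)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "total protein (nM)", y = "fraction bound",
                  title = sprintf("K_D = %.3g nM", object$kd))
}
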