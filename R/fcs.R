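#' Single-component 3D-diffusion FCS autocorrelation model
#'
#' `G(tau) = (1/n) * (1 + tau/tau_d)^-1 * (1 + kappa^-2 * tau/tau_d)^-1/2`
#' for free diffusion of a single species through a 3D Gaussian focal
#' volume with structure parameter `kappa = z0 / r0`. The zero-lag amplitude
#' `G(0) = 1/n` is the reciprocal mean particle number in the focal volume;
#' the decay is governed by the diffusion time `tau_d`. No triplet-state
#' term is included; trim lags below ~10 microseconds if triplet
#' contamination is a concern.
#'
#' @param tau Lag time(s), s (>= 0).
#' @param n Mean particle number in the focal volume (> 0).
#' @param tau_d Diffusion time, s (> 0).
#' @param kappa Structure parameter `z0/r0` (>= 1; `Inf` gives the 2D limit
#'   of the axial factor).
#'
#' @return G values, strictly decreasing in `tau`.
#' @examples
#' acf_model(0, n = 0.258, tau_d = 1e-3, kappa = 5)  # 1/0.258 = 3.876
#' @export
acf_model <- function(tau, n, tau_d, kappa = 5) {
  check_num(tau, "tau", non_negative = TRUE)
  check_num(n, "n", positive = TRUE, scalar = TRUE)
  check_num(tau_d, "tau_d", positive = TRUE, scalar = TRUE)
  if (!(is.numeric(kappa) && length(kappa) == 1L && kappa >= 1)) {
    abort("`kappa` must be a single value >= 1.",
          class = "oligostate_argument_error")
  }
  x <- tau / tau_d
  axial <- if (is.infinite(kappa)) 1 else (1 + x / kappa^2)^(-0.5)
  (1 / n) * (1 + x)^(-1) * axial
}

#' Calibrate the focal volume from a reference dye
#'
#' The lateral focal radius follows from the fitted diffusion time of a dye
#' of known diffusion coefficient (rhodamine-6G, 426 um^2/s):
#' `r0 = sqrt(4 * d_cal * tau_d_cal)`, and `z0 = kappa * r0`.
#'
#' @param tau_d_cal Fitted diffusion time of the calibration dye, s (> 0).
#' @param d_cal Known diffusion coefficient of the dye, um^2/s. Default 426.
#' @param kappa Structure parameter. Default 5.
#'
#' @return Tibble with `r0_um`, `z0_um`, `kappa`.
#' @examples
#' calibrate_focal_volume(25e-6)   # r0 = 0.2064 um
#' @export
calibrate_focal_volume <- function(tau_d_cal, d_cal = 426, kappa = 5) {
  check_num(tau_d_cal, "tau_d_cal", positive = TRUE, scalar = TRUE)
  check_num(d_cal, "d_cal", positive = TRUE, scalar = TRUE)
  if (!(is.numeric(kappa) && length(kappa) == 1L && kappa >= 1)) {
    abort("`kappa` must be a single value >= 1.",
          class = "oligostate_argument_error")
  }
  r0 <- sqrt(4 * d_cal * tau_d_cal)
  tibble(r0_um = r0, z0_um = kappa * r0, kappa = kappa)
}

#' Diffusion coefficient from diffusion time and focal radius
#'
#' `D = r0^2 / (4 * tau_d)`, the inverse of the calibration relation.
#'
#' @param tau_d Diffusion time, s (> 0).
#' @param r0 Lateral focal radius, um (> 0).
#' @return Diffusion coefficient, um^2/s.
#' @export
diffusion_coefficient <- function(tau_d, r0) {
  check_num(tau_d, "tau_d", positive = TRUE)
  check_num(r0, "r0", positive = TRUE)
  r0^2 / (4 * tau_d)
}

#' Fit the FCS autocorrelation model to a measured curve
#'
#' Nonlinear least squares of [acf_model()] over particle number and
#' diffusion time, with the structure parameter fixed from calibration
#' (single-condition curves constrain `kappa` poorly). Starting values are
#' `n0 = 1 / G(first lag)` and the lag at which G drops to half its initial
#' value.
#'
#' @param curve Data frame with columns `lag_s` (strictly increasing, > 0)
#'   and `g`; at least 10 points spanning the decay.
#' @param kappa Structure parameter from [calibrate_focal_volume()].
#'   Default 5.
#' @param weights Optional per-point weights for weighted least squares
#'   (default: unweighted).
#'
#' @return An `acf_fit` with `n_particles`, `tau_d`, `kappa_used`,
#'   `residual_ss`, `n_points`, the data and the `nls` fit. Methods:
#'   [tidy()], [glance()], [autoplot()].
#' @export
fit_acf <- function(curve, kappa = 5, weights = NULL) {
  check_cols(curve, c("lag_s", "g"), "`curve`")
  lag <- curve$lag_s
  g <- curve$g
  check_num(lag, "lag_s", positive = TRUE)
  check_num(g, "g")
  if (length(lag) < 10L) {
    abort("At least 10 lag points are required.",
          class = "oligostate_fit_error")
  }
  if (is.unsorted(lag, strictly = TRUE)) {
    abort("`lag_s` must be strictly increasing.",
          class = "oligostate_fit_error")
  }
  g0 <- g[1]
  if (g0 <= 0 || (g0 - min(g)) < 0.2 * abs(g0)) {
    abort("Curve shows no usable decay; tau_d is unidentifiable.",
          class = "oligostate_fit_error")
  }
  below <- which(g <= g0 / 2)
  tau_d0 <- if (length(below) > 0L) lag[below[1]] else stats::median(lag)
  w <- if (is.null(weights)) rep(1, length(g)) else
    check_num(weights, "weights", positive = TRUE)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      g ~ acf_model(lag, n, tau_d, kappa),
      start = list(n = 1 / g0, tau_d = tau_d0),
      lower = c(1e-12, 1e-12), weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) {
      abort(sprintf("ACF fit did not converge: %s", conditionMessage(e)),
            class = "oligostate_fit_error")
    })
  est <- coef(fit)
  structure(
    list(n_particles = unname(est["n"]), tau_d = unname(est["tau_d"]),
         kappa_used = kappa, residual_ss = sum(stats::residuals(fit)^2),
         n_points = length(g), data = as_tibble(curve[c("lag_s", "g")]),
         fit = fit),
    class = "acf_fit")
}

#' @export
print.acf_fit <- function(x, ...) {
  cat(sprintf(
    "FCS fit: <N> = %.4g, tau_d = %.4g s (kappa = %.3g, RSS = %.3g, n = %d)\n",
    x$n_particles, x$tau_d, x$kappa_used, x$residual_ss, x$n_points))
  invisible(x)
}

#' @export
#' @method tidy acf_fit
tidy.acf_fit <- function(x, ...) {
  tibble(term = c("n_particles", "tau_d"),
         estimate = c(x$n_particles, x$tau_d))
}

#' @export
#' @method glance acf_fit
glance.acf_fit <- function(x, ...) {
  tibble(n_particles = x$n_particles, tau_d = x$tau_d,
         kappa_used = x$kappa_used, residual_ss = x$residual_ss,
         n_points = x$n_points)
}

#' @export
#' @method autoplot acf_fit
autoplot.acf_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- acf_model(df$lag_s, object$n_particles, object$tau_d,
                         object$kappa_used)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$g), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lag time (s)", y = "G(tau)",
                  title = sprintf("<N> = %.3g, tau_d = %.3g s",
                                  object$n_particles, object$tau_d))
}

#' Oligomer order from paired native/denatured particle numbers
#'
#' Denaturing an oligomer multiplies the number of fluorescent particles in
#' the focal volume by the number of monomers per oligomer, so the per-pair
#' ratio `N_denatured / N_native` estimates the oligomeric order. Ratios
#' are summarised with the same two-sided 95% Student-t convention as the
#' gel assays. Only amplitudes enter the ratio; denatured-state diffusion
#' times are irrelevant here (urea changes viscosity and particle size).
#'
#' @param native,denatured Paired replicate measurements: numeric vectors of
#'   particle numbers, or lists of `acf_fit` objects (equal length, matched
#'   by position).
#' @param brightness_correction Multiplier applied to each ratio for
#'   non-identical fluorophore brightness between conditions. Default 1 (no
#'   correction).
#'
#' @return An `oligomer_ratio_result`: per-replicate tibble (`replicate`,
#'   `n_native`, `n_denatured`, `ratio`) plus `mean`, `ci95_half_width`,
#'   `n`.
#' @examples
#' oligomer_ratio(0.258, 0.990)$ratios$ratio   # 3.84
#' @export
oligomer_ratio <- function(native, denatured, brightness_correction = 1) {
  pull_n <- function(x, name) {
    if (is.list(x) && all(vapply(x, inherits, logical(1), "acf_fit"))) {
      vapply(x, function(f) f$n_particles, numeric(1))
    } else {
      check_num(x, name, positive = TRUE)
      as.numeric(x)
    }
  }
  n_nat <- pull_n(native, "native")
  n_den <- pull_n(denatured, "denatured")
  if (length(n_nat) != length(n_den)) {
    abort("`native` and `denatured` must be paired (equal length).",
          class = "oligostate_argument_error")
  }
  check_num(brightness_correction, "brightness_correction", positive = TRUE,
            scalar = TRUE)
  ratios <- tibble(replicate = seq_along(n_nat), n_native = n_nat,
                   n_denatured = n_den,
                   ratio = n_den / n_nat * brightness_correction)
  s <- t_summary(ratios$ratio)
  structure(list(ratios = ratios, mean = s$mean,
                 ci95_half_width = s$ci95_half_width, n = s$n),
            class = "oligomer_ratio_result")
}

#' @export
print.oligomer_ratio_result <- function(x, ...) {
  cat(sprintf(
    "Oligomer order (N_denatured / N_native): %.2f (CI %.2f), n = %d\n",
    x$mean, x$ci95_half_width, x$n))
  invisible(x)
}

#' @export
#' @method tidy oligomer_ratio_result
tidy.oligomer_ratio_result <- function(x, ...) x$ratios

#' @export
#' @method glance oligomer_ratio_result
glance.oligomer_ratio_result <- function(x, ...) {
  tibble(mean_ratio = x$mean, ci95_half_width = x$ci95_half_width, n = x$n)
}

#' @export
#' @method autoplot oligomer_ratio_result
autoplot.oligomer_ratio_result <- function(object, ...) {
  df <- object$ratios
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$replicate),
                                   y = .data$ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean, linetype = 2) +
    ggplot2::labs(x = "replicate", y = "N_denatured / N_native",
                  title = sprintf("Oligomer order: %.2f (CI %.2f)",
                                  object$mean, object$ci95_half_width))
}
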