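#' Fit a log-linear migration standard curve
#'
#' Ordinary least squares of `log10(mw_kd / anchor mw)` on
#' `norm_distance - anchor distance`, the reptation relation between
#' migration lag and molecular weight for linear DNA and DNA-anchored
#' complexes. The anchor (by default the first standard) only re-centres the
#' fit; the intercept is estimated, not forced through the anchor, and is
#' close to zero when the anchor lies on the line.
#'
#' @param standards Data frame with columns `norm_distance` (normalised gel
#'   units, see [normalize_migration()]) and `mw_kd` (known molecular
#'   weights, kD). At least two standards with distinct distances.
#' @param anchor Row index of the anchor standard. Default 1.
#'
#' @return A `standard_curve` object with elements `slope` (per gel unit),
#'   `intercept`, `r_squared`, `anchor_mw`, `anchor_distance`, `n`,
#'   `distance_range`, and the `standards` used.
#' @examples
#' curve <- fit_standard_curve(
#'   data.frame(norm_distance = c(50, 150), mw_kd = c(100, 1000)))
#' estimate_mw(curve, 100)   # 316.2 kD
#' @export
fit_standard_curve <- function(standards, anchor = 1L) {
  check_cols(standards, c("norm_distance", "mw_kd"), "`standards`")
  d <- standards$norm_distance
  mw <- standards$mw_kd
  check_num(d, "norm_distance")
  check_num(mw, "mw_kd", positive = TRUE)
  if (length(d) < 2L) {
    abort("At least two standards are required.",
          class = "oligostate_fit_error")
  }
  if (anyDuplicated(d)) {
    abort("Standard migration distances must be distinct.",
          class = "oligostate_fit_error")
  }
  stopifnot(anchor >= 1L, anchor <= length(d))
  x <- d - d[anchor]
  y <- log10(mw / mw[anchor])
  fit <- lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (length(d) == 2L || tss == 0) 1 else
    max(0, 1 - sum(fit$residuals^2) / tss)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, anchor_mw = mw[anchor], anchor_distance = d[anchor],
         n = length(d), distance_range = range(d),
         standards = as_tibble(standards)),
    class = "standard_curve")
}

#' Estimate molecular weight from a standard curve
#'
#' Inverts the fitted reptation regression:
#' `anchor_mw * 10^(intercept + slope * (d - anchor_distance))`.
#' Extrapolation beyond the standard range is permitted but flagged with a
#' warning, since heavier complexes resolve less well and extrapolated
#' estimates are noisier.
#'
#' @param curve A `standard_curve` from [fit_standard_curve()].
#' @param norm_distance Normalised migration distance(s).
#'
#' @return Numeric vector of molecular weights in kD (strictly increasing in
#'   `norm_distance`).
#' @export
estimate_mw <- function(curve, norm_distance) {
  stopifnot(inherits(curve, "standard_curve"))
  check_num(norm_distance, "norm_distance")
  outside <- norm_distance < curve$distance_range[1] |
    norm_distance > curve$distance_range[2]
  if (any(outside)) {
    warn(sprintf(
      "%d distance(s) outside the standard range [%.3g, %.3g]; extrapolating.",
      sum(outside), curve$distance_range[1], curve$distance_range[2]),
      class = "oligostate_extrapolation")
  }
  curve$anchor_mw *
    10^(curve$intercept + curve$slope * (norm_distance - curve$anchor_distance))
}

# inverse of estimate_mw: expected normalised distance of a given MW
expected_distance <- function(curve, mw_kd) {
  stopifnot(inherits(curve, "standard_curve"))
  check_num(mw_kd, "mw_kd", positive = TRUE)
  curve$anchor_distance +
    (log10(mw_kd / curve$anchor_mw) - curve$intercept) / curve$slope
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("Migration standard curve (log10 MW ~ normalised distance)\n")
  cat(sprintf("  slope: %.6g per gel unit, intercept: %.3g, r^2: %.4f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  %d standards, anchor %.4g kD at distance %.4g\n",
              x$n, x$anchor_mw, x$anchor_distance))
  invisible(x)
}

#' @export
#' @method tidy standard_curve
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept))
}

#' @export
#' @method glance standard_curve
glance.standard_curve <- function(x, ...) {
  tibble(r_squared = x$r_squared, n = x$n, anchor_mw = x$anchor_mw,
         anchor_distance = x$anchor_distance)
}

#' @export
#' @method autoplot standard_curve
autoplot.standard_curve <- function(object, ...) {
  df <- object$standards
  df$log_rel_mw <- log10(df$mw_kd / object$anchor_mw)
  df$x <- df$norm_distance - object$anchor_distance
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$log_rel_mw)) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linetype = 2, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "normalised migration lag (anchored gel units)",
      y = "log10 relative MW",
      title = sprintf("Standard curve (r² = %.3f)", object$r_squared))
}
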