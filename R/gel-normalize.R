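BAND_TYPES <- c("free_dna", "lower_shift", "supershift",
                "ref_upper", "ref_lower")

GEL_COLUMNS <- c("gel_id", "lane_id", "fragment_name", "construct_name",
                 "band_type", "distance", "intensity")

validate_gel_table <- function(gel) {
  check_cols(gel, GEL_COLUMNS, "Gel band table")
  bad <- which(!gel$band_type %in% BAND_TYPES)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Unknown band_type value(s) %s at row(s) %s; expected one of %s.",
      paste0('"', unique(gel$band_type[bad]), '"', collapse = ", "),
      paste(head(bad, 10L), collapse = ", "),
      paste0('"', BAND_TYPES, '"', collapse = ", ")),
      class = "oligostate_data_error")
  }
  if (any(!is.finite(gel$distance)) || any(gel$distance < 0)) {
    abort("`distance` must be finite and >= 0 for every band.",
          class = "oligostate_data_error")
  }
  dup <- gel |>
    dplyr::filter(.data$band_type %in% c("ref_upper", "ref_lower")) |>
    dplyr::count(.data$gel_id, .data$lane_id, .data$band_type) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf(
      "Duplicated reference band(s) in lane(s): %s.",
      paste(unique(paste(dup$gel_id, dup$lane_id, sep = "/")),
            collapse = ", ")),
      class = "oligostate_data_error")
  }
  invisible(gel)
}

#' Normalise band migration against in-lane reference DNA
#'
#' Each lane carries two non-interacting reference DNAs: a slow upper
#' reference and a fast lower reference. The lane-corrected migration of a
#' band is `(d_ref_lower - d_ref_upper) - (d_band - d_ref_upper)`, which is
#' algebraically `d_ref_lower - d_band`: the lag of the band behind the fast
#' reference. Larger normalised values mean heavier species. Because both
#' terms share the lane's offset, run-to-run and lane-to-lane migration
#' offsets cancel exactly.
#'
#' @param gel Gel band table (see [read_band_table()] for the schema).
#' @param band_type Band classes to normalise. Default: all non-reference
#'   classes present.
#'
#' @return Tibble with one row per normalised band: `gel_id`, `lane_id`,
#'   `fragment_name`, `construct_name`, `band_type`, `distance`,
#'   `norm_distance`.
#' @export
normalize_migration <- function(gel,
                                band_type = c("free_dna", "lower_shift",
                                              "supershift")) {
  validate_gel_table(gel)
  band_type <- match.arg(band_type, BAND_TYPES, several.ok = TRUE)

  refs <- gel |>
    dplyr::filter(.data$band_type %in% c("ref_upper", "ref_lower")) |>
    dplyr::select("gel_id", "lane_id", "band_type", "distance") |>
    tidyr::pivot_wider(names_from = "band_type", values_from = "distance")

  bands <- dplyr::filter(gel, .data$band_type %in% .env$band_type)
  if (nrow(bands) == 0L) {
    abort("No bands of the requested type(s) in the gel table.",
          class = "oligostate_data_error")
  }
  out <- dplyr::left_join(bands, refs, by = c("gel_id", "lane_id"))
  have_cols <- all(c("ref_upper", "ref_lower") %in% names(out))
  no_ref <- !have_cols ||
    anyNA(out$ref_upper) || anyNA(out$ref_lower)
  if (no_ref) {
    miss <- out[if (!have_cols) rep(TRUE, nrow(out)) else
      (is.na(out$ref_upper) | is.na(out$ref_lower)), ]
    abort(sprintf(
      "Lane(s) %s lack a reference band; both ref_upper and ref_lower are required.",
      paste(unique(paste(miss$gel_id, miss$lane_id, sep = "/")),
            collapse = ", ")),
      class = "oligostate_data_error")
  }
  out |>
    dplyr::mutate(norm_distance = (.data$ref_lower - .data$ref_upper) -
                    (.data$distance - .data$ref_upper)) |>
    dplyr::select("gel_id", "lane_id", "fragment_name", "construct_name",
                  "band_type", "distance", "norm_distance")
}
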