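#' Read and validate a gel band table
#'
#' Tab-separated, one row per band, columns `gel_id`, `lane_id`,
#' `fragment_name`, `construct_name`, `band_type`, `distance`, `intensity`.
#' `band_type` must be one of `free_dna`, `lower_shift`, `supershift`,
#' `ref_upper`, `ref_lower`. Unknown band types, missing columns and
#' duplicated reference bands within a lane are schema errors reported with
#' row numbers. Writing with [write_band_table()] and reading back is
#' lossless.
#'
#' @param path Path to a TSV file.
#' @return Validated gel band table tibble.
#' @export
read_band_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path),
          class = "oligostate_data_error")
  }
  gel <- readr::read_tsv(path, col_types = readr::cols(
    gel_id = readr::col_character(), lane_id = readr::col_character(),
    fragment_name = readr::col_character(),
    construct_name = readr::col_character(),
    band_type = readr::col_character(), distance = readr::col_double(),
    intensity = readr::col_double()), progress = FALSE)
  if (nrow(gel) == 0L) {
    abort(sprintf("Band table is empty: %s", path),
          class = "oligostate_data_error")
  }
  validate_gel_table(gel)
  gel
}

#' @rdname read_band_table
#' @param gel Gel band table to write.
#' @param path Output path.
#' @export
write_band_table <- function(gel, path) {
  validate_gel_table(gel)
  readr::write_tsv(gel, path)
  invisible(path)
}

#' Read a binding titration table
#'
#' Tab-separated with columns `protein_conc_nM`, `dna_conc_nM`,
#' `frac_unbound` and optionally `frac_lower`, `frac_super`.
#'
#' @param path Path to a TSV file.
#' @return Titration tibble.
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path),
          class = "oligostate_data_error")
  }
  tt <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  check_cols(tt, c("protein_conc_nM", "dna_conc_nM", "frac_unbound"),
             "Titration table")
  tt
}

#' Read FCS autocorrelation curves
#'
#' Comma-separated with columns `lag_s`, `g`, `condition` (`native` /
#' `denatured`) and `replicate`.
#'
#' @param path Path to a CSV file.
#' @return ACF tibble.
#' @export
read_acf_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path),
          class = "oligostate_data_error")
  }
  ac <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  check_cols(ac, c("lag_s", "g", "condition"), "ACF table")
  bad <- !ac$condition %in% c("native", "denatured")
  if (any(bad)) {
    abort(sprintf("Unknown condition value(s) at row(s) %s.",
                  paste(head(which(bad), 10L), collapse = ", ")),
          class = "oligostate_data_error")
  }
  ac
}

#' Read an observed m/z peak list
#'
#' Whitespace- or tab-delimited text with one or two columns: `mz` and an
#' optional `intensity`. A header line is detected and skipped.
#'
#' @param path Path to the peak-list file.
#' @return Tibble with `mz` and `intensity` (NA when absent).
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path),
          class = "oligostate_data_error")
  }
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, comment.char = "#"),
    error = function(e) {
      abort(sprintf("Could not parse peak list %s: %s", path,
                    conditionMessage(e)), class = "oligostate_data_error")
    })
  if (is.character(tab[[1]]) && nrow(tab) > 1L) {   # header row
    tab <- utils::read.table(path, header = TRUE, comment.char = "#")
  }
  mz <- as.numeric(tab[[1]])
  check_num(mz, "mz", positive = TRUE)
  tibble(mz = mz,
         intensity = if (ncol(tab) >= 2L) as.numeric(tab[[2]]) else
           NA_real_)
}

#' Read protein sequences from FASTA
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Named character vector of uppercase sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path),
          class = "oligostate_data_error")
  }
  seqs <- Biostrings::readAAStringSet(path)
  setNames(toupper(as.character(seqs)), names(seqs))
}
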