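#' Run the full complex-stoichiometry analysis pipeline
#'
#' Executes the configured analysis stages in order — gel stoichiometry
#' (assay I and/or II), equilibrium K_D fitting, FCS oligomer-ratio
#' estimation and peptide-mass-fingerprint matching — and collects their
#' results with provenance into a single report. Stages are optional: only
#' configured blocks run. Reports are deterministic given the configuration
#' (including any seed recorded by the data producers).
#'
#' The configuration is a JSON file or an equivalent nested list with
#' blocks:
#' \describe{
#'   \item{constructs}{list of `{name, monomer_mw_kd, tags,
#'     expression_system, pi}`}
#'   \item{fragments}{list of `{name, length_bp, n_sites, cut_products}`}
#'   \item{gel}{`{assay: "assay1"|"assay2", path, construct,
#'     probe_fragment}`; one block or a list of blocks}
#'   \item{titration}{`{path, mode: "single"|"tandem_sum"}`}
#'   \item{fcs}{`{path, calibration: {tau_d_cal_s, d_cal_um2_s, kappa}}`}
#'   \item{pmf}{`{fasta, peaks, tolerance, max_missed_cleavages}`}
#' }
#' Relative paths are resolved against the configuration file's directory.
#'
#' @param config Path to a JSON configuration file, or a nested list.
#' @param base_dir Directory against which relative paths resolve; defaults
#'   to the configuration file's directory (or the working directory for a
#'   list configuration).
#'
#' @return A `pipeline_report`: list with one element per executed stage
#'   (`gel` — list of `stoichiometry_result`s; `kd` — `kd_fit`; `fcs` —
#'   `oligomer_ratio_result`; `pmf` — `pmf_match_result`), plus
#'   `provenance` (config hash, package version, timestamp) and `warnings`.
#' @seealso [write_report()]
#' @export
run_pipeline <- function(config, base_dir = NULL) {
  if (is.character(config)) {
    if (is.null(base_dir)) base_dir <- dirname(config)
    if (!file.exists(config)) {
      abort(sprintf("Configuration file not found: %s", config),
            class = "oligostate_data_error")
    }
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  if (is.null(base_dir)) base_dir <- "."
  resolve_path <- function(p) {
    if (is.null(p)) abort("Missing input path in configuration.",
                          class = "oligostate_data_error")
    full <- if (startsWith(p, "/")) p else file.path(base_dir, p)
    if (!file.exists(full)) {
      abort(sprintf("Input path does not exist: %s", full),
            class = "oligostate_data_error")
    }
    full
  }

  constructs <- if (!is.null(config$constructs)) {
    dplyr::bind_rows(purrr::map(config$constructs, function(cc) {
      construct(cc$name, cc$monomer_mw_kd,
                tags = unlist(cc$tags) %||% character(),
                expression_system = cc$expression_system %||% NA_character_,
                pi = cc$pi %||% NA_real_)
    }))
  } else NULL
  fragments <- if (!is.null(config$fragments)) {
    dplyr::bind_rows(purrr::map(config$fragments, function(ff) {
      dna_fragment(ff$name, ff$length_bp, n_sites = ff$n_sites %||% 1,
                   cut_products = unlist(ff$cut_products))
    }))
  } else NULL

  report <- list()
  warnings <- character()
  note <- function(w) warnings[[length(warnings) + 1L]] <<- w

  if (!is.null(config$gel)) {
    blocks <- if (!is.null(config$gel$path)) list(config$gel) else config$gel
    report$gel <- purrr::map(blocks, function(blk) {
      gel <- read_band_table(resolve_path(blk$path))
      res <- withCallingHandlers(
        if (identical(blk$assay, "assay2")) {
          assay2_stoichiometry(gel, fragments, blk$construct,
                               probe_fragment = blk$probe_fragment,
                               constructs = constructs)
        } else {
          assay1_stoichiometry(gel, fragments, blk$construct,
                               constructs = constructs)
        },
        warning = function(w) {
          note(conditionMessage(w)); invokeRestart("muffleWarning")
        })
      res
    })
  }

  if (!is.null(config$titration)) {
    tt <- read_titration(resolve_path(config$titration$path))
    report$kd <- fit_kd(tt, mode = config$titration$mode %||% "single")
  }

  if (!is.null(config$fcs)) {
    ac <- read_acf_table(resolve_path(config$fcs$path))
    kappa <- config$fcs$calibration$kappa %||% 5
    if (!"replicate" %in% names(ac)) ac$replicate <- 1L
    fits <- ac |>
      dplyr::group_by(.data$condition, .data$replicate) |>
      dplyr::group_map(function(g, key) {
        list(condition = key$condition, replicate = key$replicate,
             fit = fit_acf(dplyr::arrange(g, .data$lag_s), kappa = kappa))
      })
    cond <- vapply(fits, `[[`, character(1), "condition")
    reps <- vapply(fits, function(f) as.numeric(f$replicate), numeric(1))
    nat <- fits[cond == "native"][order(reps[cond == "native"])]
    den <- fits[cond == "denatured"][order(reps[cond == "denatured"])]
    report$fcs <- oligomer_ratio(purrr::map(nat, "fit"),
                                 purrr::map(den, "fit"))
  }

  if (!is.null(config$pmf)) {
    seqs <- read_protein_fasta(resolve_path(config$pmf$fasta))
    peaks <- read_peaks(resolve_path(config$pmf$peaks))
    peps <- tryptic_digest(
      unname(seqs[1]),
      max_missed_cleavages = config$pmf$max_missed_cleavages %||% 0)
    report$pmf <- pmf_match(peaks, peps,
                            tolerance = config$pmf$tolerance %||% 0.25)
  }

  report$provenance <- list(
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("oligostate")),
    timestamp = format(Sys.time(), tz = "UTC"))
  report$warnings <- warnings
  class(report) <- "pipeline_report"
  report
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Complex-stoichiometry pipeline report\n")
  for (nm in setdiff(names(x), c("provenance", "warnings"))) {
    cat(sprintf("-- stage: %s --\n", nm))
    if (nm == "gel") purrr::walk(x$gel, print) else print(x[[nm]])
  }
  if (length(x$warnings) > 0L) {
    cat(sprintf("%d warning(s) recorded.\n", length(x$warnings)))
  }
  invisible(x)
}

#' Serialise a pipeline report to JSON and TSV
#'
#' Writes `report.json` (numeric results with units and group sizes, plus
#' provenance) and per-stage TSV tables of the tidy per-measurement data
#' into `dir`.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path to the JSON report.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(provenance = report$provenance, warnings = report$warnings)
  if (!is.null(report$gel)) {
    out$gel <- purrr::map(report$gel, function(r) {
      c(list(construct = r$construct_name, assay = r$assay,
             monomer_mw_kd = r$monomer_mw_kd),
        as.list(r$summary))
    })
    purrr::iwalk(report$gel, function(r, i) {
      readr::write_tsv(tidy(r),
                       file.path(dir, sprintf("gel_%s_units.tsv", i)))
    })
  }
  if (!is.null(report$kd)) {
    out$kd <- as.list(glance(report$kd))
    out$kd$units <- "nM"
  }
  if (!is.null(report$fcs)) {
    out$fcs <- as.list(glance(report$fcs))
    readr::write_tsv(tidy(report$fcs), file.path(dir, "fcs_ratios.tsv"))
  }
  if (!is.null(report$pmf)) {
    out$pmf <- as.list(glance(report$pmf))
    readr::write_tsv(tidy(report$pmf), file.path(dir, "pmf_matched.tsv"))
    readr::write_tsv(tibble(mz = report$pmf$unmatched_observed),
                     file.path(dir, "pmf_unmatched.tsv"))
  }
  path <- file.path(dir, "report.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
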