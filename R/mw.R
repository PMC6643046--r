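#' Molecular weight of a double-stranded DNA fragment
#'
#' Converts fragment length in base pairs to molecular weight using the
#' standard average mass of sodium-salt double-stranded DNA. The biotin
#' end-label carried by gel probes (~0.6 kD) is negligible at gel resolution
#' and is not modelled.
#'
#' @param length_bp Fragment length in base pairs (vectorised, all > 0).
#' @param kd_per_bp Mass per base pair in kilodaltons. Default `0.650`.
#'
#' @return Numeric vector of molecular weights in kD.
#' @examples
#' dna_mw(75)    # 48.75 kD
#' dna_mw(232)   # 150.8 kD
#' @export
dna_mw <- function(length_bp, kd_per_bp = 0.650) {
  check_num(length_bp, "length_bp", positive = TRUE)
  check_num(kd_per_bp, "kd_per_bp", positive = TRUE, scalar = TRUE)
  length_bp * kd_per_bp
}

#' Molecular weight of a protein-DNA complex
#'
#' Total mass of a DNA fragment carrying `n_complexes` protein complexes of
#' `n_units` monomers each: `dna_mw(length_bp) + n_complexes * n_units *
#' monomer_mw_kd`. A tandem-site fragment in its supershifted state carries
#' two complexes (`n_complexes = 2`); a lower shift carries one.
#'
#' @param length_bp DNA length in bp.
#' @param monomer_mw_kd Monomer molecular weight of the protein construct, kD.
#' @param n_units Monomers per bound complex (>= 0).
#' @param n_complexes Complexes per fragment (>= 0). Default 1.
#' @param kd_per_bp Mass per base pair in kD. Default `0.650`.
#'
#' @return Numeric vector of complex molecular weights in kD.
#' @examples
#' complex_mw(75, 55, n_units = 3)                    # 213.75 kD
#' complex_mw(114, 55, n_units = 3, n_complexes = 2)  # 404.1 kD
#' @export
complex_mw <- function(length_bp, monomer_mw_kd, n_units, n_complexes = 1,
                       kd_per_bp = 0.650) {
  check_num(monomer_mw_kd, "monomer_mw_kd", positive = TRUE)
  check_num(n_units, "n_units", non_negative = TRUE)
  check_num(n_complexes, "n_complexes", non_negative = TRUE)
  dna_mw(length_bp, kd_per_bp) + n_complexes * n_units * monomer_mw_kd
}

#' Declare a protein construct
#'
#' A construct is a tagged, possibly truncated protein variant with a known
#' monomer molecular weight. Monomer weights are inputs (e.g. from the
#' expression-construct design), never computed from sequence; the
#' isoelectric point is carried as metadata only.
#'
#' @param name Construct identifier (unique within a study).
#' @param monomer_mw_kd Monomer molecular weight in kD (> 0).
#' @param tags Character vector of fusion-tag names (e.g. `"eYFP"`, `"MBP"`,
#'   `"Halo"`), or empty.
#' @param expression_system One of `"bacterial_SN"`, `"bacterial_WC"`,
#'   `"IVE"`, `"semipure"`, or `NA`.
#' @param pi Theoretical isoelectric point (metadata only).
#'
#' @return One-row tibble with columns `construct_name`, `monomer_mw_kd`,
#'   `tags` (list-column), `expression_system`, `pi`.
#' @examples
#' construct("ZnF", 55, tags = "eYFP", expression_system = "bacterial_SN")
#' @export
construct <- function(name, monomer_mw_kd, tags = character(),
                      expression_system = NA_character_, pi = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_num(monomer_mw_kd, "monomer_mw_kd", positive = TRUE, scalar = TRUE)
  systems <- c("bacterial_SN", "bacterial_WC", "IVE", "semipure")
  if (!is.na(expression_system) && !expression_system %in% systems) {
    abort(sprintf("`expression_system` must be one of %s.",
                  paste0('"', systems, '"', collapse = ", ")),
          class = "oligostate_argument_error")
  }
  tibble(construct_name = name, monomer_mw_kd = monomer_mw_kd,
         tags = list(as.character(tags)),
         expression_system = expression_system, pi = pi)
}

#' Declare a DNA fragment
#'
#' A linear double-stranded probe carrying 0, 1 or 2 specific protein binding
#' sites, optionally with an internal restriction site splitting it into two
#' single-site products (used by [digest_rearrangement()]).
#'
#' @param name Fragment identifier.
#' @param length_bp Length in bp (> 0).
#' @param n_sites Number of specific binding sites: 0, 1 or 2.
#' @param cut_products Optional length-2 numeric vector of product sizes in
#'   bp; must sum to `length_bp` (e.g. 75 + 157 = 232).
#'
#' @return One-row tibble with columns `fragment_name`, `length_bp`,
#'   `n_sites`, `has_internal_cut_site`, `cut_products` (list-column).
#' @examples
#' dna_fragment("single-75", 75, n_sites = 1)
#' dna_fragment("tandem-232-cut", 232, n_sites = 2, cut_products = c(75, 157))
#' @export
dna_fragment <- function(name, length_bp, n_sites = 1, cut_products = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_num(length_bp, "length_bp", positive = TRUE, scalar = TRUE)
  if (!n_sites %in% 0:2) {
    abort("`n_sites` must be 0, 1 or 2.", class = "oligostate_argument_error")
  }
  has_cut <- !is.null(cut_products)
  if (has_cut) {
    check_num(cut_products, "cut_products", positive = TRUE)
    if (length(cut_products) != 2L) {
      abort("`cut_products` must give exactly two product lengths.",
            class = "oligostate_argument_error")
    }
    if (abs(sum(cut_products) - length_bp) > 1e-8) {
      abort(sprintf(
        "`cut_products` must sum to `length_bp` (%g + %g != %g).",
        cut_products[1], cut_products[2], length_bp),
        class = "oligostate_argument_error")
    }
  }
  tibble(fragment_name = name, length_bp = length_bp,
         n_sites = as.integer(n_sites), has_internal_cut_site = has_cut,
         cut_products = list(if (has_cut) as.numeric(cut_products) else NULL))
}

#' Example zinc-finger construct table
#'
#' The four truncated PRDM9 zinc-finger-array constructs measured with both
#' migration assays, with their monomer molecular weights, expression systems
#' and theoretical isoelectric points. Useful as simulator input and in
#' examples.
#'
#' @return Tibble of constructs (one per row), as built by [construct()].
#' @export
znf_constructs <- function() {
  dplyr::bind_rows(
    construct("eYFP-ZnF 1-11", 77, tags = "eYFP",
              expression_system = "bacterial_SN", pi = 8.84),
    construct("eYFP-ZnF 2-11", 62, tags = "eYFP",
              expression_system = "bacterial_SN", pi = 9.10),
    construct("ZnF 2-8", 26, expression_system = "bacterial_SN", pi = 9.38),
    construct("ZnF 2-6", 21, expression_system = "bacterial_SN", pi = 9.31)
  )
}
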