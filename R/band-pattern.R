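#' Predict the EMSA band pattern for competing DNA fragments
#'
#' Enumerates the distinct species expected when a protein complex of
#' `n_units` monomers is mixed with one or two DNA fragments carrying the
#' same binding site. Under `one_dna_per_complex` a complex engages exactly
#' one fragment, giving each free fragment plus one shift per fragment (four
#' bands for two fragments). Under `multi_dna_per_complex` a complex bridges
#' two fragments, giving the free fragments plus every unordered fragment
#' pair (five bands for two fragments). Species are distinguished by
#' molecular weight.
#'
#' @param model `"one_dna_per_complex"` or `"multi_dna_per_complex"`.
#' @param fragments Fragment table of 1-2 distinct fragments; fragments
#'   without binding sites are excluded with a warning.
#' @param construct A [construct()] row (or name, with `constructs`).
#' @param n_units Monomers per complex. Default 3.
#' @param constructs Optional lookup table.
#' @param kd_per_bp DNA mass per bp, kD.
#'
#' @return A `band_pattern`: tibble of species (`description`, `fragments`
#'   bound, `n_complexes`, `mw_kd`) and the number of distinct bands in
#'   `$n_bands`.
#' @examples
#' frags <- rbind(dna_fragment("short-75", 75), dna_fragment("long-273", 273))
#' predict_band_pattern("one_dna_per_complex", frags,
#'                      construct("ZnF", 55))$n_bands    # 4
#' @export
predict_band_pattern <- function(model = c("one_dna_per_complex",
                                           "multi_dna_per_complex"),
                                 fragments, construct, n_units = 3,
                                 constructs = NULL, kd_per_bp = 0.650) {
  model <- match.arg(model)
  construct <- resolve_construct(construct, constructs)
  check_num(n_units, "n_units", positive = TRUE, scalar = TRUE)
  check_cols(fragments, c("fragment_name", "length_bp", "n_sites"),
             "`fragments`")
  no_site <- fragments$n_sites == 0L
  if (any(no_site)) {
    warn(sprintf("Excluding fragment(s) without binding sites: %s.",
                 paste(fragments$fragment_name[no_site], collapse = ", ")),
         class = "oligostate_no_site_fragment")
    fragments <- fragments[!no_site, , drop = FALSE]
  }
  n_frag <- nrow(fragments)
  if (n_frag < 1L || n_frag > 2L) {
    abort("1-2 fragments with binding sites are required.",
          class = "oligostate_argument_error")
  }
  prot <- n_units * construct$monomer_mw_kd
  frag_names <- fragments$fragment_name
  frag_mw <- dna_mw(fragments$length_bp, kd_per_bp)

  free <- tibble(
    description = paste0("free ", frag_names),
    fragments = frag_names, n_complexes = 0L, mw_kd = frag_mw)

  bound <- if (model == "one_dna_per_complex") {
    tibble(
      description = paste0("complex on ", frag_names),
      fragments = frag_names, n_complexes = 1L, mw_kd = frag_mw + prot)
  } else {
    idx <- expand.grid(i = seq_len(n_frag), j = seq_len(n_frag))
    idx <- idx[idx$i <= idx$j, , drop = FALSE]
    tibble(
      description = paste0("complex bridging ", frag_names[idx$i], " + ",
                           frag_names[idx$j]),
      fragments = paste(frag_names[idx$i], frag_names[idx$j], sep = "+"),
      n_complexes = 1L,
      mw_kd = frag_mw[idx$i] + frag_mw[idx$j] + prot)
  }

  species <- dplyr::arrange(dplyr::bind_rows(free, bound), .data$mw_kd)
  structure(list(species = species,
                 n_bands = dplyr::n_distinct(species$mw_kd),
                 model = model),
            class = "band_pattern")
}

#' @export
print.band_pattern <- function(x, ...) {
  cat(sprintf("Predicted band pattern (%s): %d distinct band(s)\n",
              x$model, x$n_bands))
  print(x$species)
  invisible(x)
}

#' @export
#' @method tidy band_pattern
tidy.band_pattern <- function(x, ...) x$species

#' Band rearrangement after restriction digest of a bound tandem fragment
#'
#' Predicts the species present after cutting a tandem-site fragment at its
#' internal restriction site. A free fragment yields its two free products;
#' a supershifted fragment (two complexes) yields one single complex per
#' product, which co-migrate with the corresponding single-site shifts; a
#' lower-shifted fragment (one complex on either site) yields a population
#' mixture of each product free and each product carrying the complex.
#'
#' @param fragment A [dna_fragment()] row with `cut_products` defined.
#' @param bound_state `"free"`, `"lower"` or `"super"`.
#' @param construct A [construct()] row; required for bound states.
#' @param n_units Monomers per complex. Default 3.
#' @param kd_per_bp DNA mass per bp, kD.
#'
#' @return A `band_pattern` of post-digest species.
#' @export
digest_rearrangement <- function(fragment,
                                 bound_state = c("free", "lower", "super"),
                                 construct = NULL, n_units = 3,
                                 kd_per_bp = 0.650) {
  bound_state <- match.arg(bound_state)
  fragment <- resolve_fragment(fragment)
  if (!isTRUE(fragment$has_internal_cut_site)) {
    abort(sprintf("Fragment `%s` has no internal restriction site.",
                  fragment$fragment_name),
          class = "oligostate_argument_error")
  }
  products <- fragment$cut_products[[1]]
  prod_names <- paste0(fragment$fragment_name, "-", products, "bp")

  free <- tibble(description = paste0("free ", prod_names),
                 fragments = prod_names, n_complexes = 0L,
                 mw_kd = dna_mw(products, kd_per_bp))

  species <- if (bound_state == "free") {
    free
  } else {
    if (is.null(construct)) {
      abort("`construct` is required for bound states.",
            class = "oligostate_argument_error")
    }
    construct <- resolve_construct(construct)
    prot <- n_units * construct$monomer_mw_kd
    complexes <- tibble(
      description = paste0("single complex on ", prod_names),
      fragments = prod_names, n_complexes = 1L,
      mw_kd = dna_mw(products, kd_per_bp) + prot)
    if (bound_state == "super") complexes else
      dplyr::bind_rows(free, complexes)
  }
  species <- dplyr::arrange(species, .data$mw_kd)
  structure(list(species = species,
                 n_bands = dplyr::n_distinct(species$mw_kd),
                 model = paste0("digest/", bound_state)),
            class = "band_pattern")
}
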