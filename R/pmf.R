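# Monoisotopic residue masses (Da), standard IUPAC values
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276
MASS_CO <- 27.994915
MASS_CARBAMIDOMETHYL <- 57.02146

check_sequence <- function(sequence) {
  stopifnot(is.character(sequence))
  for (s in sequence) {
    if (!nzchar(s)) {
      abort("Protein/peptide sequence must be non-empty.",
            class = "oligostate_argument_error")
    }
    res <- strsplit(s, "")[[1]]
    bad <- which(!res %in% names(AA_MONO))
    if (length(bad) > 0L) {
      abort(sprintf(
        "Invalid residue(s) %s at position(s) %s.",
        paste0('"', unique(res[bad]), '"', collapse = ", "),
        paste(bad, collapse = ", ")),
        class = "oligostate_argument_error")
    }
  }
  invisible(sequence)
}

residue_masses <- function(sequence, carbamidomethyl = TRUE) {
  res <- strsplit(sequence, "")[[1]]
  m <- unname(AA_MONO[res])
  if (carbamidomethyl) m[res == "C"] <- m[res == "C"] + MASS_CARBAMIDOMETHYL
  m
}

#' Monoisotopic singly protonated peptide mass
#'
#' `[M+H]+ = sum(residue masses) + water + proton (+ 57.02146 per Cys when
#' carbamidomethylation is enabled)`. Singly protonated ions only, as for
#' MALDI peptide mass fingerprints. Carbamidomethylation of cysteine
#' (iodoacetamide alkylation) is the default fixed modification; variable
#' modifications are out of scope.
#'
#' @param sequence Peptide sequence(s), uppercase one-letter code
#'   (vectorised).
#' @param carbamidomethyl Apply fixed +57.02146 Da per cysteine? Default
#'   `TRUE`.
#'
#' @return Numeric vector of `[M+H]+` values in Da.
#' @examples
#' peptide_mz("SFIASEISSIER")   # 1338.69 Da
#' @export
peptide_mz <- function(sequence, carbamidomethyl = TRUE) {
  check_sequence(sequence)
  vapply(sequence, function(s) {
    sum(residue_masses(s, carbamidomethyl)) + MASS_WATER + MASS_PROTON
  }, numeric(1), USE.NAMES = FALSE)
}

#' In-silico tryptic digest
#'
#' Cleaves C-terminal to lysine or arginine except when the next residue is
#' proline (the standard trypsin "Keil" rule) and enumerates all peptides
#' with up to `max_missed_cleavages` internal missed cleavage sites,
#' recording 1-based positions in the parent protein and `[M+H]+` masses.
#'
#' @param protein_seq Protein sequence (uppercase one-letter code).
#' @param max_missed_cleavages Maximum missed cleavages per peptide (>= 0).
#'   Default 0.
#' @param carbamidomethyl Fixed Cys modification for the mass column.
#'
#' @return Tibble with `sequence`, `start`, `end`, `missed_cleavages`,
#'   `mz_mh`. With `max_missed_cleavages = 0` the peptides partition the
#'   input sequence.
#' @examples
#' tryptic_digest("GRATKPLMKSR")$sequence   # "GR", "ATKPLMK", "SR"
#' @export
tryptic_digest <- function(protein_seq, max_missed_cleavages = 0,
                           carbamidomethyl = TRUE) {
  check_sequence(protein_seq)
  stopifnot(length(protein_seq) == 1L)
  check_num(max_missed_cleavages, "max_missed_cleavages",
            non_negative = TRUE, scalar = TRUE)
  res <- strsplit(protein_seq, "")[[1]]
  n <- length(res)
  # cleavage after position i: K/R at i, not followed by P
  cut_after <- which(res %in% c("K", "R") &
                       c(res[-1], "") != "P" & seq_len(n) < n)
  bounds <- c(0L, cut_after, n)          # segment boundaries
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  n_seg <- length(starts)

  out <- purrr::map_dfr(seq_len(n_seg), function(i) {
    j_max <- min(n_seg, i + max_missed_cleavages)
    purrr::map_dfr(i:j_max, function(j) {
      tibble(sequence = paste(res[starts[i]:ends[j]], collapse = ""),
             start = starts[i], end = ends[j],
             missed_cleavages = j - i)
    })
  })
  out$mz_mh <- peptide_mz(out$sequence, carbamidomethyl)
  out
}

#' Match observed peaks against a theoretical digest
#'
#' Assigns each observed m/z peak to the nearest theoretical peptide within
#' the mass tolerance; ties are broken by smaller absolute mass error, then
#' by lower missed-cleavage count. Sequence coverage is the union of matched
#' peptide spans as a percentage of the protein length. The default
#' tolerance of 0.25 Da accommodates MALDI calibration offsets of up to
#' ~0.1 Da between measured and theoretical monoisotopic masses.
#'
#' @param observed Numeric vector of observed m/z values, or a data frame
#'   with an `mz` column.
#' @param peptides Theoretical digest from [tryptic_digest()] (columns
#'   `sequence`, `start`, `end`, `missed_cleavages`, `mz_mh`).
#' @param tolerance Match tolerance in Da (> 0). Default 0.25.
#' @param protein_length Protein length for the coverage denominator;
#'   defaults to the largest `end` in `peptides`.
#'
#' @return A `pmf_match_result` with `matched` (tibble: `observed_mz`,
#'   `sequence`, `start`, `end`, `mz_mh`, `delta` signed observed minus
#'   theoretical), `unmatched_observed`, `coverage_percent`, `tolerance`.
#' @export
pmf_match <- function(observed, peptides, tolerance = 0.25,
                      protein_length = NULL) {
  if (is.data.frame(observed)) {
    check_cols(observed, "mz", "`observed`")
    observed <- observed$mz
  }
  check_num(observed, "observed", positive = TRUE)
  check_num(tolerance, "tolerance", positive = TRUE, scalar = TRUE)
  check_cols(peptides, c("sequence", "start", "end", "missed_cleavages",
                         "mz_mh"), "`peptides`")
  if (nrow(peptides) == 0L) {
    abort("Empty peptide list.", class = "oligostate_argument_error")
  }
  if (is.null(protein_length)) protein_length <- max(peptides$end)

  rows <- purrr::map(observed, function(mz) {
    delta <- mz - peptides$mz_mh
    ok <- which(abs(delta) <= tolerance)
    if (length(ok) == 0L) return(NULL)
    ord <- ok[order(abs(delta[ok]), peptides$missed_cleavages[ok])]
    best <- ord[1]
    tibble(observed_mz = mz, sequence = peptides$sequence[best],
           start = peptides$start[best], end = peptides$end[best],
           mz_mh = peptides$mz_mh[best], delta = delta[best])
  })
  matched <- dplyr::bind_rows(rows)
  unmatched <- observed[vapply(rows, is.null, logical(1))]

  coverage <- if (nrow(matched) == 0L) 0 else {
    iv <- matched[order(matched$start), c("start", "end")]
    covered <- 0L; cur_s <- iv$start[1]; cur_e <- iv$end[1]
    if (nrow(iv) > 1L) {
      for (k in 2:nrow(iv)) {
        if (iv$start[k] <= cur_e + 1L) {
          cur_e <- max(cur_e, iv$end[k])
        } else {
          covered <- covered + (cur_e - cur_s + 1L)
          cur_s <- iv$start[k]; cur_e <- iv$end[k]
        }
      }
    }
    covered <- covered + (cur_e - cur_s + 1L)
    100 * covered / protein_length
  }

  structure(list(matched = matched, unmatched_observed = unmatched,
                 coverage_percent = coverage, tolerance = tolerance,
                 protein_length = protein_length),
            class = "pmf_match_result")
}

#' @export
print.pmf_match_result <- function(x, ...) {
  cat(sprintf(
    "PMF match: %d/%d peaks assigned (tol %.3g Da), coverage %.1f%%\n",
    nrow(x$matched), nrow(x$matched) + length(x$unmatched_observed),
    x$tolerance, x$coverage_percent))
  invisible(x)
}

#' @export
#' @method tidy pmf_match_result
tidy.pmf_match_result <- function(x, ...) x$matched

#' @export
#' @method glance pmf_match_result
glance.pmf_match_result <- function(x, ...) {
  tibble(n_matched = nrow(x$matched),
         n_unmatched = length(x$unmatched_observed),
         coverage_percent = x$coverage_percent, tolerance = x$tolerance)
}

#' Theoretical a/b/y fragment ions of a peptide
#'
#' For a peptide of length L and i = 1..L-1: `b_i` = sum of the first i
#' residues + proton; `a_i = b_i - CO (27.994915)`; `y_i` = sum of the last
#' i residues + water + proton. Singly charged ions.
#'
#' @param peptide_seq Peptide sequence of length >= 2.
#' @param carbamidomethyl Fixed Cys modification. Default `TRUE`.
#'
#' @return Tibble with `series` ("a"/"b"/"y"), `index`, `mz`.
#' @export
fragment_ions <- function(peptide_seq, carbamidomethyl = TRUE) {
  check_sequence(peptide_seq)
  stopifnot(length(peptide_seq) == 1L)
  m <- residue_masses(peptide_seq, carbamidomethyl)
  L <- length(m)
  if (L < 2L) {
    abort("Peptide must have length >= 2 for fragment ions.",
          class = "oligostate_argument_error")
  }
  i <- seq_len(L - 1L)
  b <- cumsum(m)[i] + MASS_PROTON
  y <- cumsum(rev(m))[i] + MASS_WATER + MASS_PROTON
  dplyr::bind_rows(
    tibble(series = "a", index = i, mz = b - MASS_CO),
    tibble(series = "b", index = i, mz = b),
    tibble(series = "y", index = i, mz = y))
}
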