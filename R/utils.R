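# internal helpers shared across modules

# stop unless x is a finite numeric vector, optionally positive / non-negative
check_num <- function(x, name, positive = FALSE, non_negative = FALSE,
                      scalar = FALSE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric vector.", name),
          class = "oligostate_argument_error")
  }
  if (scalar && length(x) != 1L) {
    abort(sprintf("`%s` must be a single number.", name),
          class = "oligostate_argument_error")
  }
  if (positive && any(x <= 0)) {
    abort(sprintf("`%s` must be > 0.", name),
          class = "oligostate_argument_error")
  }
  if (non_negative && any(x < 0)) {
    abort(sprintf("`%s` must be >= 0.", name),
          class = "oligostate_argument_error")
  }
  invisible(x)
}

check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s.", what,
                  paste0("`", missing, "`", collapse = ", ")),
          class = "oligostate_data_error")
  }
  invisible(df)
}

# two-sided 95% Student-t summary used by gel and FCS stoichiometry results;
# n = 1 yields an NA half-width (flagged, not an error)
t_summary <- function(x) {
  check_num(x, "units")
  n <- length(x)
  half <- if (n >= 2L) qt(0.975, df = n - 1L) * sd(x) / sqrt(n) else NA_real_
  tibble(mean = mean(x), ci95_half_width = half, n = n)
}

# evaluate `expr` under a private RNG stream when seed is non-NULL
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  check_num(seed, "seed", scalar = TRUE)
  withr::with_seed(as.integer(seed), expr)
}

# resolve a construct argument: one-row data frame from construct(), or a
# name looked up in a constructs table
resolve_construct <- function(construct, constructs = NULL) {
  if (is.character(construct)) {
    if (is.null(constructs)) {
      abort("Supply a `constructs` table to look up a construct by name.",
            class = "oligostate_argument_error")
    }
    hit <- constructs[constructs$construct_name == construct, , drop = FALSE]
    if (nrow(hit) != 1L) {
      abort(sprintf("Construct `%s` not found (or not unique) in the table.",
                    construct), class = "oligostate_data_error")
    }
    return(hit)
  }
  check_cols(construct, c("construct_name", "monomer_mw_kd"), "`construct`")
  if (nrow(construct) != 1L) {
    abort("`construct` must be a single construct (one row).",
          class = "oligostate_argument_error")
  }
  construct
}

resolve_fragment <- function(fragment, fragments = NULL) {
  if (is.character(fragment)) {
    if (is.null(fragments)) {
      abort("Supply a `fragments` table to look up a fragment by name.",
            class = "oligostate_argument_error")
    }
    hit <- fragments[fragments$fragment_name == fragment, , drop = FALSE]
    if (nrow(hit) != 1L) {
      abort(sprintf("Fragment `%s` not found (or not unique) in the table.",
                    fragment), class = "oligostate_data_error")
    }
    return(hit)
  }
  check_cols(fragment, c("fragment_name", "length_bp"), "`fragment`")
  if (nrow(fragment) != 1L) {
    abort("`fragment` must be a single fragment (one row).",
          class = "oligostate_argument_error")
  }
  fragment
}
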