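#' Construct a probabilistic target inhibition map (PTIM)
#'
#' A PTIM maps every subset of an `n`-target panel to a normalized sensitivity
#' in `[0, 1]`, interpreted as the steady-state probability that the tumor
#' phenotype is absent when exactly that subset of targets is inhibited. A
#' PTIM is stored as a tibble with one row per inhibition subset, in index
#' order (subset encoded with target 1 as the most significant bit).
#'
#' @param values Numeric vector of `2^n` sensitivities in `[0, 1]`, ordered by
#'   subset index, or a named list/vector keyed by `"+"`-joined target names
#'   (empty name = no inhibition).
#' @param targets Ordered character vector of target names.
#' @return A tibble of class `"ptim"` with columns `index`, `combo` and
#'   `sensitivity`, and attribute `targets`.
#' @seealso [tim()], [binarize()], [ptim_entry()], [read_ptim()]
#' @export
ptim <- function(values, targets) {
  validate_panel(targets)
  n <- length(targets)
  values <- resolve_subset_values(values, targets)
  if (length(values) != 2^n) {
    abort(sprintf("expected %d sensitivities for %d targets, got %d.",
                  2^n, n, length(values)))
  }
  if (anyNA(values) || any(values < 0 | values > 1)) {
    abort("sensitivities must lie in [0, 1].")
  }
  out <- tibble(
    index = 0:(2^n - 1L),
    combo = vapply(0:(2^n - 1L), subset_label, character(1), targets = targets),
    sensitivity = as.numeric(values)
  )
  new_inhibition_map(out, targets, "ptim")
}

#' Construct a binary target inhibition map (TIM)
#'
#' A TIM is the binary special case of a [ptim()]: each inhibition subset is
#' marked 1 when it blocks tumor proliferation at steady state and 0
#' otherwise. Monotonicity (supersets of a blocking set also block) holds for
#' TIMs generated from pathways but is not assumed for user input.
#'
#' @param bits Vector of `2^n` values in `{0, 1}` ordered by subset index, or
#'   a named list/vector as in [ptim()].
#' @inheritParams ptim
#' @return A tibble of class `"tim"` with columns `index`, `combo`, `blocked`.
#' @export
tim <- function(bits, targets) {
  validate_panel(targets)
  n <- length(targets)
  bits <- resolve_subset_values(bits, targets)
  if (length(bits) != 2^n) {
    abort(sprintf("expected %d bits for %d targets, got %d.", 2^n, n, length(bits)))
  }
  if (anyNA(bits) || !all(bits %in% c(0, 1))) {
    abort("TIM values must be 0 or 1.")
  }
  out <- tibble(
    index = 0:(2^n - 1L),
    combo = vapply(0:(2^n - 1L), subset_label, character(1), targets = targets),
    blocked = as.integer(bits)
  )
  new_inhibition_map(out, targets, "tim")
}

new_inhibition_map <- function(df, targets, class) {
  structure(df, targets = targets,
            class = c(class, "tbl_df", "tbl", "data.frame"))
}

resolve_subset_values <- function(values, targets) {
  if (!is.null(names(values))) {
    n <- length(targets)
    out <- rep(NA_real_, 2^n)
    for (i in seq_along(values)) { # by position: "" (no inhibition) is a valid key
      nm <- names(values)[i]
      parts <- if (nzchar(nm)) strsplit(nm, "+", fixed = TRUE)[[1]] else character(0)
      out[encode_subset(parts, targets) + 1L] <- as.numeric(values[[i]])
    }
    if (anyNA(out)) abort("named values must cover every inhibition subset.")
    out
  } else {
    as.numeric(unlist(values))
  }
}

#' @export
print.ptim <- function(x, ...) {
  cat("# PTIM over targets:", paste(attr(x, "targets"), collapse = ", "), "\n")
  NextMethod()
}

#' @export
print.tim <- function(x, ...) {
  cat("# TIM over targets:", paste(attr(x, "targets"), collapse = ", "), "\n")
  NextMethod()
}

#' Targets of a PTIM/TIM or model object
#' @param x A `ptim`, `tim`, pathway, Boolean network, Markov chain or cspbn.
#' @return Character vector of target names.
#' @export
panel_targets <- function(x) attr(x, "targets")

# values in subset-index order, robust to user reordering of rows
map_values <- function(x) {
  col <- if (inherits(x, "tim")) "blocked" else "sensitivity"
  v <- as.numeric(x[[col]])
  v[order(x$index)]
}

#' Look up the sensitivity of one inhibition subset
#'
#' @param x A `ptim` or `tim`.
#' @param subset Character vector of target names (empty = no inhibition).
#' @return The sensitivity (or 0/1 blocked bit) for that subset.
#' @examples
#' p <- load_fixture("table2")
#' ptim_entry(p, c("K1", "K2", "K3")) # 0.9
#' @export
ptim_entry <- function(x, subset = character(0)) {
  map_values(x)[encode_subset(subset, panel_targets(x)) + 1L]
}

#' Binarize a PTIM at a sensitivity threshold
#'
#' Entries with sensitivity `>= alpha` become blocking (bit 1). The boundary
#' convention is `>=`: a cell equal to the threshold counts as effective
#' inhibition, the only convention consistent with the embedded worked
#' examples (a 0.55 cell thresholded at 0.55 maps to 1).
#'
#' @param x A `ptim`.
#' @param alpha Threshold in `(0, 1]`.
#' @return A [tim()].
#' @export
binarize <- function(x, alpha) {
  stopifnot(inherits(x, "ptim"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1) {
    abort("`alpha` must be a single value in (0, 1].")
  }
  tim(as.integer(map_values(x) >= alpha), panel_targets(x))
}
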