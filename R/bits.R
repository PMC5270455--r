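# Bit-level conventions used throughout:
#   * a panel of n targets is an ordered character vector; target 1 is the
#     MOST significant of the n target bits,
#   * an inhibition subset is encoded as an n-bit integer index,
#   * a dynamic-model state has n + 1 bits: the n target bits shifted left by
#     one, with the tumor phenotype in the least significant bit.

validate_panel <- function(targets) {
  if (!is.character(targets) || length(targets) < 1L) {
    abort("`targets` must be a character vector with at least one name.")
  }
  if (anyDuplicated(targets) || any(!nzchar(targets))) {
    abort("target names must be unique and nonempty.")
  }
  if (length(targets) > 16L) {
    abort("at most 16 targets are supported (the 2^(n+1) state space must be enumerable).")
  }
  targets
}

#' Encode a set of target names as an inhibition-subset index
#'
#' Target 1 (the first name in the panel) is the most significant bit, so for
#' a three-target panel `c("K1","K2","K3")` the subset `{K1, K3}` encodes to
#' `101` in binary, i.e. index 5.
#'
#' @param subset Character vector of target names (possibly empty).
#' @param targets The ordered target panel.
#' @return A single integer in `[0, 2^n - 1]`.
#' @export
encode_subset <- function(subset, targets) {
  validate_panel(targets)
  if (length(subset) == 0L) return(0L)
  pos <- match(subset, targets)
  if (anyNA(pos)) {
    abort(paste0("unknown target name(s): ",
                 paste(subset[is.na(pos)], collapse = ", ")))
  }
  n <- length(targets)
  sum(bitwShiftL(1L, n - pos))
}

#' Decode an inhibition-subset index back to target names
#'
#' @param index Integer index in `[0, 2^n - 1]`.
#' @param targets The ordered target panel.
#' @return Character vector of target names (in panel order).
#' @export
decode_subset <- function(index, targets) {
  n <- length(targets)
  targets[bitwAnd(bitwShiftR(index, n - seq_len(n)), 1L) == 1L]
}

subset_label <- function(index, targets) {
  paste(decode_subset(index, targets), collapse = "+")
}

# state helpers: state is an (n+1)-bit integer, tumor in the LSB
state_target_bits <- function(state, n) bitwAnd(bitwShiftR(state, 1L), bitwShiftL(1L, n) - 1L)
state_tumor_bit <- function(state) bitwAnd(state, 1L)

state_label <- function(state, n) {
  paste(bitwAnd(bitwShiftR(state, (n + 1L) - seq_len(n + 1L)), 1L), collapse = "")
}

state_labels <- function(n) vapply(0:(2^(n + 1L) - 1L), state_label, character(1), n = n)

#' Mask a state by forcing inhibited targets to zero
#'
#' Implements the Boolean intervention function: inhibited target bits are set
#' to 0, the tumor bit is never touched.
#'
#' @param state Integer state(s) on `n + 1` bits.
#' @param cbits Inhibition subset index (n-bit integer).
#' @param n Number of targets.
#' @return Masked integer state(s).
#' @export
mask_state <- function(state, cbits, n) {
  keep <- bitwAnd(bitwNot(cbits), bitwShiftL(1L, n) - 1L)
  tb <- bitwAnd(state_target_bits(state, n), keep)
  bitwOr(bitwShiftL(tb, 1L), state_tumor_bit(state))
}

#' Reflected-binary Gray code ordering
#'
#' Returns the reflected Gray sequence over `k` bits, starting at all-zeros;
#' consecutive entries differ in exactly one bit. This is the row/column
#' ordering used by the grid layout of inhibition-response tables.
#'
#' @param k Number of bits (`k >= 0`).
#' @return A `2^k` by `k` binary matrix (zero columns when `k = 0`), one row
#'   per Gray-code label, with an attribute `"index"` giving the plain binary
#'   value of each row.
#' @examples
#' gray_order(2) # rows 00, 01, 11, 10
#' @export
gray_order <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k != round(k)) {
    abort("`k` must be a single non-negative integer.")
  }
  k <- as.integer(k)
  i <- 0:(2^k - 1L)
  g <- bitwXor(i, bitwShiftR(i, 1L))
  m <- matrix(0L, nrow = 2^k, ncol = k)
  for (b in seq_len(k)) m[, b] <- bitwAnd(bitwShiftR(g, k - b), 1L)
  structure(m, index = g)
}
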