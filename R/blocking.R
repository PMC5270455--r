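popcount <- function(x) {
  n <- 0L
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

check_monotone <- function(bits, targets) {
  n <- length(targets)
  for (i in 0:(2^n - 1L)) {
    if (bits[i + 1L] != 1L) next
    # flipping any 0-bit on must keep the map blocking
    for (b in 0:(n - 1L)) {
      j <- bitwOr(i, bitwShiftL(1L, b))
      if (j != i && bits[j + 1L] == 0L) {
        abort(sprintf(
          "TIM is not monotone: {%s} blocks but its superset {%s} does not.",
          subset_label(i, targets), subset_label(j, targets)))
      }
    }
  }
  invisible(TRUE)
}

#' Minimal blocking sets of a monotone TIM
#'
#' A blocking set is a set of targets whose joint inhibition stops tumor
#' proliferation (TIM bit 1). The minimal blocking sets are the
#' inclusion-minimal ones; they form an antichain whose monotone closure
#' reproduces the TIM.
#'
#' @param x A [tim()]; must be monotone (an error names a violating pair
#'   otherwise).
#' @return A list of character vectors (each in panel order), sorted by size
#'   then lexicographically; empty for an all-zero TIM.
#' @export
minimal_blocking_sets <- function(x) {
  stopifnot(inherits(x, "tim"))
  targets <- panel_targets(x)
  bits <- map_values(x)
  check_monotone(bits, targets)
  n <- length(targets)
  idx <- which(bits == 1L) - 1L
  minimal <- idx[vapply(idx, function(i) {
    # minimal iff removing any single member unblocks
    drop <- vapply(0:(n - 1L), function(b) {
      if (bitwAnd(i, bitwShiftL(1L, b)) == 0L) return(TRUE)
      bits[bitwAnd(i, bitwNot(bitwShiftL(1L, b))) + 1L] == 0L
    }, logical(1))
    i > 0L && all(drop)
  }, logical(1))]
  sets <- lapply(minimal, decode_subset, targets = targets)
  order_subsets(sets, targets)
}

order_subsets <- function(sets, targets) {
  if (length(sets) == 0L) return(list())
  key <- vapply(sets, function(s) paste(match(s, targets), collapse = ","), character(1))
  sets[order(lengths(sets), key)]
}

#' Feasible mutation / latent-activation patterns of a TIM
#'
#' A mutation pattern (set of constitutively activated targets driving the
#' tumor) is feasible only if inhibiting all of its members blocks the tumor;
#' otherwise the observed TIM could not have arisen from it.
#'
#' @param x A monotone [tim()].
#' @return List of nonempty target subsets with TIM bit 1, in
#'   size-then-lexicographic order.
#' @examples
#' feasible_mutation_patterns(load_fixture("figure1_tim")) # 5 patterns
#' @export
feasible_mutation_patterns <- function(x) {
  stopifnot(inherits(x, "tim"))
  targets <- panel_targets(x)
  bits <- map_values(x)
  check_monotone(bits, targets)
  idx <- setdiff(which(bits == 1L) - 1L, 0L)
  order_subsets(lapply(idx, decode_subset, targets = targets), targets)
}

#' Monotone closure of an antichain of blocking sets
#'
#' Utility inverse of [minimal_blocking_sets()]: rebuilds the TIM in which a
#' subset blocks iff it contains one of the given sets.
#'
#' @param sets List of character vectors of target names.
#' @param targets Ordered target panel.
#' @return A [tim()].
#' @export
blocking_closure <- function(sets, targets) {
  validate_panel(targets)
  n <- length(targets)
  masks <- vapply(sets, encode_subset, integer(1), targets = targets)
  bits <- vapply(0:(2^n - 1L), function(i) {
    as.integer(any(bitwAnd(i, masks) == masks))
  }, integer(1))
  if (length(masks) == 0L) bits <- rep(0L, 2^n)
  tim(bits, targets)
}
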