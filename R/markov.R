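#' Construct a Markov chain over the (n+1)-bit state space
#'
#' States are ordered `0...0` to `1...1` with the tumor phenotype in the
#' least significant bit; rows must sum to one.
#'
#' @param P Square row-stochastic matrix of size `2^(n+1)`.
#' @param targets Ordered target panel (n names).
#' @return An object of class `"markov_chain"`.
#' @export
markov_chain <- function(P, targets) {
  validate_panel(targets)
  n <- length(targets)
  N <- 2^(n + 1L)
  P <- as.matrix(P)
  if (!all(dim(P) == N)) {
    abort(sprintf("transition matrix must be %d x %d for %d targets.", N, N, n))
  }
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12)) {
    abort("rows must be nonnegative and sum to 1 (within 1e-12).")
  }
  dimnames(P) <- list(state_labels(n), state_labels(n))
  structure(list(P = P), targets = targets, class = "markov_chain")
}

#' @export
print.markov_chain <- function(x, ...) {
  cat(sprintf("Markov chain on %d states (targets: %s)\n", nrow(x$P),
              paste(panel_targets(x), collapse = ", ")))
  invisible(x)
}

#' Deterministic Markov chain of a Boolean network
#'
#' @param bn A [build_bn()] network.
#' @return A [markov_chain()] with a single 1 per row.
#' @export
bn_chain <- function(bn) {
  n <- length(panel_targets(bn))
  N <- 2^(n + 1L)
  P <- matrix(0, N, N)
  P[cbind(seq_len(N), bn$successor + 1L)] <- 1
  markov_chain(P, panel_targets(bn))
}

#' Apply a sustained target inhibition to a Markov chain
#'
#' Two equivalent treatment semantics: `"redirect"` right-multiplies by the
#' intervention matrix (`P T_c`), aggregating each transition onto its masked
#' image and keeping the masked subspace explicit; `"reset"` replaces each
#' row by the row of the state's masked image (the system is reset by the
#' drug and evolves from there). Their aggregated stationary distributions
#' coincide.
#'
#' @param chain A [markov_chain()].
#' @param inhibit Inhibited targets (character vector or subset index).
#' @param semantics `"redirect"` or `"reset"`.
#' @return A [markov_chain()].
#' @export
masked_chain <- function(chain, inhibit, semantics = c("redirect", "reset")) {
  semantics <- match.arg(semantics)
  targets <- panel_targets(chain)
  n <- length(targets)
  cb <- resolve_mask_bits(inhibit, targets)
  states <- 0:(nrow(chain$P) - 1L)
  dest <- mask_state(states, cb, n)
  P <- chain$P
  if (semantics == "reset") {
    P2 <- P[dest + 1L, , drop = FALSE]
    rownames(P2) <- rownames(P)
    return(markov_chain(P2, targets))
  }
  # redirect: collapse columns onto their masked images
  P3 <- matrix(0, nrow(P), ncol(P))
  for (j in seq_along(states)) {
    P3[, dest[j] + 1L] <- P3[, dest[j] + 1L] + P[, j]
  }
  markov_chain(P3, targets)
}

#' Aggregate a distribution onto the fixed states of an intervention
#'
#' Collects the probability mass of each preimage class onto its masked
#' image, the aggregation under which the reset and redirect semantics share
#' a stationary distribution.
#'
#' @param pi Probability vector over the `2^(n+1)` states (sums to 1).
#' @param targets Ordered target panel.
#' @param inhibit Inhibited targets.
#' @return A probability vector supported on the mask's fixed states.
#' @export
aggregate_distribution <- function(pi, targets, inhibit) {
  n <- length(targets)
  cb <- resolve_mask_bits(inhibit, targets)
  states <- 0:(length(pi) - 1L)
  dest <- mask_state(states, cb, n)
  out <- numeric(length(pi))
  for (j in seq_along(states)) out[dest[j] + 1L] <- out[dest[j] + 1L] + pi[j]
  names(out) <- state_labels(n)
  out
}

flip_kernel <- function(p, bits) {
  one <- matrix(c(1 - p, p, p, 1 - p), 2, 2, byrow = TRUE)
  Reduce(kronecker, rep(list(one), bits))
}

#' Add per-bit perturbation noise to a Markov chain
#'
#' After each transition every bit flips independently with probability `p`,
#' making the chain ergodic (strictly positive) for `p > 0`. By default all
#' `n + 1` bits (targets and tumor) are perturbed, the convention that
#' reproduces the embedded worked examples; `bits = "targets"` restricts
#' flips to the target bits.
#'
#' @param chain A [markov_chain()].
#' @param p Per-bit flip probability, `0 <= p < 0.5`.
#' @param bits `"all"` or `"targets"`.
#' @return A [markov_chain()].
#' @export
perturb <- function(chain, p, bits = c("all", "targets")) {
  bits <- match.arg(bits)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p >= 0.5) {
    abort("`p` must be a single value in [0, 0.5).")
  }
  if (p == 0) return(chain)
  n <- length(panel_targets(chain))
  Fm <- if (bits == "all") flip_kernel(p, n + 1L)
        else kronecker(flip_kernel(p, n), diag(2))
  markov_chain(chain$P %*% Fm, panel_targets(chain))
}

closed_classes <- function(P) {
  g <- igraph::graph_from_adjacency_matrix((P > 0) * 1, mode = "directed")
  sc <- igraph::components(g, mode = "strong")
  memb <- sc$membership
  closed <- vapply(seq_len(sc$no), function(k) {
    inside <- which(memb == k)
    all(P[inside, -inside, drop = FALSE] == 0)
  }, logical(1))
  lapply(which(closed), function(k) which(memb == k))
}

solve_stationary <- function(P) {
  N <- nrow(P)
  A <- t(P) - diag(N)
  A[N, ] <- 1
  b <- c(rep(0, N - 1L), 1)
  drop(solve(A, b))
}

#' Stationary distribution of a Markov chain
#'
#' Solves `pi P = pi, sum(pi) = 1` by direct linear solve. An irreducible (or
#' single-closed-class) chain needs no start state. A reducible chain is
#' analysed along the trajectory from `start`: the stationary distribution of
#' the unique closed communicating class reachable from it (an error if
#' several are reachable, since the limit would be start-dependent in a way a
#' single distribution cannot summarise).
#'
#' @param chain A [markov_chain()] (or bare row-stochastic matrix).
#' @param start Optional integer start state for reducible chains.
#' @return Named probability vector over all states.
#' @export
stationary <- function(chain, start = NULL) {
  P <- if (inherits(chain, "markov_chain")) chain$P else as.matrix(chain)
  N <- nrow(P)
  classes <- closed_classes(P)
  if (length(classes) == 1L && is.null(start)) {
    cls <- classes[[1]]
  } else if (length(classes) > 1L && is.null(start)) {
    abort(sprintf(
      "chain is reducible (%d closed classes); supply `start` for a trajectory-restricted analysis.",
      length(classes)))
  } else {
    reach <- reachable_states(P, as.integer(start))
    hit <- classes[vapply(classes, function(cl) any(cl %in% reach), logical(1))]
    if (length(hit) != 1L) {
      abort(sprintf("%d closed classes reachable from the start state.", length(hit)))
    }
    cls <- hit[[1]]
  }
  pi <- numeric(N)
  if (length(cls) == 1L) {
    pi[cls] <- 1
  } else {
    pi[cls] <- solve_stationary(P[cls, cls, drop = FALSE])
  }
  names(pi) <- rownames(P)
  pi
}

reachable_states <- function(P, start) {
  g <- igraph::graph_from_adjacency_matrix((P > 0) * 1, mode = "directed")
  as.integer(igraph::subcomponent(g, start + 1L, mode = "out"))
}

#' Trivial Markov chain realising a PTIM
#'
#' The existence construction: each inhibition index `i` gets a dedicated
#' pair of states `D1 = 2 (2^n - i - 1)` (tumor 0) and `D2 = D1 + 1` (tumor
#' 1) — the target bits are the complement of `i`, so the pair is exactly the
#' resting pair the mask `i` drives the all-active state into. Both rows of
#' the pair send mass `p_i` to `D1` and `1 - p_i` to `D2`, making the pair a
#' closed class with tumor-free stationary mass `p_i`.
#'
#' @param x A [ptim()].
#' @return A [markov_chain()].
#' @export
trivial_chain_from_ptim <- function(x) {
  stopifnot(inherits(x, "ptim"))
  targets <- panel_targets(x)
  n <- length(targets)
  vals <- map_values(x)
  N <- 2^(n + 1L)
  P <- matrix(0, N, N)
  for (i in 0:(2^n - 1L)) {
    d1 <- 2L * (2^n - i - 1L)
    p <- vals[i + 1L]
    P[d1 + 1L, d1 + 1L] <- p
    P[d1 + 1L, d1 + 2L] <- 1 - p
    P[d1 + 2L, d1 + 1L] <- p
    P[d1 + 2L, d1 + 2L] <- 1 - p
  }
  markov_chain(P, targets)
}

#' Read or write a transition matrix as whitespace-separated text
#'
#' Dense text format: a header line of binary state labels, then one row per
#' state (leading label, then probabilities).
#'
#' @param chain A [markov_chain()].
#' @param path File path.
#' @param targets Target panel for `read_chain()` (the file stores only
#'   state labels).
#' @return `read_chain()` returns a [markov_chain()]; `write_chain()`
#'   returns `path` invisibly.
#' @export
write_chain <- function(chain, path) {
  stopifnot(inherits(chain, "markov_chain"))
  df <- data.frame(state = rownames(chain$P), chain$P, check.names = FALSE)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path, targets) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          colClasses = c("character", rep("numeric", 2^(length(targets) + 1L))))
  m <- as.matrix(df[, -1, drop = FALSE])
  markov_chain(m, targets)
}

#' Steady-state inhibition profile of a Markov chain
#'
#' For every inhibition subset: apply the sustained mask (redirect form
#' `P T_c`), add perturbation `p`, and report the stationary probability of
#' tumor bit 0. With `p = 0` the chain is generally reducible and the
#' analysis is trajectory-restricted from `start` (default all-ones, every
#' target and the tumor active) — the evaluation convention for deterministic
#' and trivially constructed chains.
#'
#' @param chain A [markov_chain()].
#' @param p Perturbation probability (see [perturb()]).
#' @param start Start state used when `p = 0`; default all-ones.
#' @param bits Perturbation convention, see [perturb()].
#' @return A [ptim()].
#' @export
chain_to_ptim <- function(chain, p = 0.001, start = NULL, bits = "all") {
  targets <- panel_targets(chain)
  n <- length(targets)
  if (is.null(start)) start <- 2^(n + 1L) - 1L
  tumor0 <- seq(1L, 2^(n + 1L), by = 2L)
  vals <- vapply(0:(2^n - 1L), function(cb) {
    m <- masked_chain(chain, cb)
    if (p > 0) {
      pi <- stationary(perturb(m, p, bits))
    } else {
      pi <- stationary(m, start = start)
    }
    sum(pi[tumor0])
  }, numeric(1))
  ptim(pmin(pmax(vals, 0), 1), targets)
}
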