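#' Build a deterministic Boolean network from a directional pathway
#'
#' The network has `2^(n+1)` states: the `n` target bits (panel order, target
#' 1 most significant) plus the tumor phenotype in the least significant bit.
#' Update rules: a mutated / latently activated target becomes 1 within one
#' step regardless of its inputs; any other target becomes 1 iff at least one
#' immediate upstream activator is 1 (OR logic; within a line the activator
#' is the predecessor, a line head is activated by every line-end target of
#' the previous block); the tumor bit becomes 1 iff some line-end target of
#' the terminal block is 1 at the current step (delayed convention).
#' Off-circuit targets are driven by their assigned activator.
#'
#' @param p A [pathway()] with a nonempty mutation set. Every line head of
#'   the first block must be mutated (it has no other activator).
#' @return An object of class `"boolnet"` with the per-target activator
#'   lists, the tumor inputs and a precomputed successor table over all
#'   `2^(n+1)` states.
#' @examples
#' bn <- build_bn(load_fixture("figure2a_pathway"))
#' bn_step(bn, strtoi("1001", base = 2)) # 1110
#' @export
build_bn <- function(p) {
  stopifnot(inherits(p, "pathway"))
  targets <- panel_targets(p)
  n <- length(targets)
  activators <- setNames(vector("list", n), targets)
  for (i in seq_along(p$blocks)) {
    prev_ends <- if (i > 1L) {
      vapply(p$blocks[[i - 1L]], function(l) l[length(l)], character(1))
    } else character(0)
    for (line in p$blocks[[i]]) {
      activators[[line[1]]] <- prev_ends
      if (length(line) > 1L) {
        for (k in 2:length(line)) activators[[line[k]]] <- line[k - 1L]
      }
    }
  }
  for (t in names(p$off_circuit)) activators[[t]] <- p$off_circuit[[t]]
  mutated <- p$mutations
  orphan <- setdiff(names(activators)[lengths(activators) == 0L], mutated)
  if (length(orphan) > 0L) {
    abort(paste0("target(s) with no upstream activator and no mutation: ",
                 paste(orphan, collapse = ", ")))
  }
  last_block <- p$blocks[[length(p$blocks)]]
  tumor_inputs <- vapply(last_block, function(l) l[length(l)], character(1))
  bn <- structure(list(activators = activators, mutated = mutated,
                       tumor_inputs = tumor_inputs, pathway = p),
                  targets = targets, class = "boolnet")
  bn$successor <- bn_successor_table(bn)
  bn
}

bn_successor_table <- function(bn) {
  targets <- panel_targets(bn)
  n <- length(targets)
  states <- 0:(2^(n + 1L) - 1L)
  bit_of <- function(t) bitwAnd(bitwShiftR(states, n + 1L - match(t, targets)), 1L)
  nxt <- integer(length(states))
  for (j in seq_len(n)) {
    t <- targets[j]
    val <- if (t %in% bn$mutated) {
      rep(1L, length(states))
    } else {
      acts <- bn$activators[[t]]
      v <- rep(0L, length(states))
      for (a in acts) v <- bitwOr(v, bit_of(a))
      v
    }
    nxt <- bitwOr(nxt, bitwShiftL(val, n + 1L - j))
  }
  tum <- rep(0L, length(states))
  for (a in bn$tumor_inputs) tum <- bitwOr(tum, bit_of(a))
  bitwOr(nxt, tum)
}

#' @export
print.boolnet <- function(x, ...) {
  targets <- panel_targets(x)
  cat(sprintf("Boolean network on %d targets + tumor bit (%d states)\n",
              length(targets), 2^(length(targets) + 1L)))
  if (is.null(x$activators)) {
    cat("  all targets latently activated; tumor <- monotone survival function\n")
    return(invisible(x))
  }
  for (t in targets) {
    rule <- if (t %in% x$mutated) "1 (mutated/latent activation)"
    else paste(x$activators[[t]], collapse = " | ")
    cat(sprintf("  %s <- %s\n", t, rule))
  }
  cat(sprintf("  tumor <- %s\n", paste(x$tumor_inputs, collapse = " | ")))
  invisible(x)
}

#' Boolean network realising an arbitrary monotone TIM
#'
#' Not every monotone TIM is series-parallel (the 2-of-3 majority map is
#' not), but every monotone TIM is realised by a network in which each
#' target is latently activated (returns to 1 within one step unless
#' inhibited) and the tumor bit updates by the monotone survival function:
#' tumor active iff the currently inactive targets do not form a blocking
#' set. Under any sustained mask the attractor fixes the target bits at the
#' mask's complement and the tumor bit at one minus the TIM entry.
#'
#' @param x A monotone [tim()].
#' @return A `"boolnet"` whose [bn_to_tim()] equals `x`.
#' @export
monotone_bn <- function(x) {
  stopifnot(inherits(x, "tim"))
  targets <- panel_targets(x)
  bits <- map_values(x)
  check_monotone(bits, targets)
  n <- length(targets)
  states <- 0:(2^(n + 1L) - 1L)
  full <- bitwShiftL(1L, n) - 1L
  inactive <- bitwAnd(bitwNot(state_target_bits(states, n)), full)
  survival <- 1L - bits[inactive + 1L]
  successor <- bitwOr(bitwShiftL(full, 1L), survival)
  structure(list(activators = NULL, mutated = targets, tumor_inputs = NULL,
                 successor = successor, tim = x),
            targets = targets, class = "boolnet")
}

resolve_mask_bits <- function(inhibit, targets) {
  if (is.null(inhibit)) return(0L)
  if (is.numeric(inhibit)) return(as.integer(inhibit))
  encode_subset(inhibit, targets)
}

#' Advance a Boolean network by one step
#'
#' With an intervention mask the drugged transition is mask-after-update:
#' `f_c(F(state))`, matching the matrix form `P T_c`.
#'
#' @param bn A [build_bn()] network.
#' @param state Integer state(s) in `[0, 2^(n+1) - 1]`.
#' @param inhibit Targets inhibited this step: character vector, subset
#'   index, or `NULL` for no drug.
#' @return Next integer state(s).
#' @export
bn_step <- function(bn, state, inhibit = NULL) {
  n <- length(panel_targets(bn))
  nxt <- bn$successor[state + 1L]
  cb <- resolve_mask_bits(inhibit, panel_targets(bn))
  if (cb != 0L) nxt <- mask_state(nxt, cb, n) else nxt
}

#' Attractor of a Boolean network under sustained inhibition
#'
#' Iterates [bn_step()] with the same mask from the start state (default
#' all-ones: every target and the tumor active) until a state repeats.
#'
#' @inheritParams bn_step
#' @param start Starting state; defaults to all-ones.
#' @return Integer vector of the attractor cycle states, beginning at the
#'   first revisited state.
#' @export
attractor <- function(bn, inhibit = NULL, start = NULL) {
  n <- length(panel_targets(bn))
  if (is.null(start)) start <- 2^(n + 1L) - 1L
  seen <- integer(0)
  s <- as.integer(start)
  pos <- integer(2^(n + 1L))
  repeat {
    if (pos[s + 1L] > 0L) {
      return(seen[pos[s + 1L]:length(seen)])
    }
    seen <- c(seen, s)
    pos[s + 1L] <- length(seen)
    s <- bn_step(bn, s, inhibit)
  }
}

#' Steady-state TIM implied by a Boolean network
#'
#' For each of the `2^n` sustained inhibition combinations, the attractor
#' from the all-active state is computed; the TIM entry is 1 iff every state
#' of that attractor has tumor bit 0. Attractors mixing tumor bits are
#' conservatively scored 0 and reported in the `"mixed_cycles"` attribute.
#'
#' @param bn A [build_bn()] network.
#' @return A [tim()] with attribute `mixed_cycles` (list keyed by combo
#'   label, empty when all attractors have a pure tumor phenotype).
#' @export
bn_to_tim <- function(bn) {
  targets <- panel_targets(bn)
  n <- length(targets)
  mixed <- list()
  bits <- vapply(0:(2^n - 1L), function(cb) {
    cyc <- attractor(bn, cb)
    tb <- state_tumor_bit(cyc)
    if (all(tb == 0L)) return(1L)
    if (any(tb == 0L)) mixed[[subset_label(cb, targets)]] <<- cyc
    0L
  }, integer(1))
  out <- tim(bits, targets)
  attr(out, "mixed_cycles") <- mixed
  out
}

#' Intervention matrix T_c for an inhibition subset
#'
#' The 0/1 row-stochastic matrix with one 1 per row sending each state to its
#' masked image (inhibited targets forced to 0, tumor bit untouched).
#' Sustained treatment of a transition matrix `P` is `P %*% T_c`.
#'
#' @param targets Ordered target panel.
#' @param inhibit Inhibited targets (character vector or subset index).
#' @return A `2^(n+1)` square 0/1 matrix with binary state labels.
#' @export
intervention_matrix <- function(targets, inhibit) {
  validate_panel(targets)
  n <- length(targets)
  cb <- resolve_mask_bits(inhibit, targets)
  N <- 2^(n + 1L)
  m <- matrix(0, N, N, dimnames = list(state_labels(n), state_labels(n)))
  dest <- mask_state(0:(N - 1L), cb, n)
  m[cbind(seq_len(N), dest + 1L)] <- 1
  m
}

#' Fixed states and preimage classes of an intervention
#'
#' @inheritParams intervention_matrix
#' @return A list with `fixed` (integer states invariant under the mask,
#'   the set the masked dynamics lives on) and `preimages` (list mapping each
#'   fixed state label to the integer states that mask onto it).
#' @export
intervention_classes <- function(targets, inhibit) {
  n <- length(targets)
  cb <- resolve_mask_bits(inhibit, targets)
  states <- 0:(2^(n + 1L) - 1L)
  dest <- mask_state(states, cb, n)
  fixed <- states[dest == states]
  pre <- lapply(fixed, function(i) states[dest == i])
  names(pre) <- vapply(fixed, state_label, character(1), n = n)
  list(fixed = fixed, preimages = pre)
}

#' Export a Boolean network's state transition table
#'
#' @param bn A [build_bn()] network.
#' @param inhibit Optional sustained mask applied to every transition.
#' @return A tibble with binary `from`/`to` state labels, one row per state.
#' @export
bn_transition_table <- function(bn, inhibit = NULL) {
  n <- length(panel_targets(bn))
  states <- 0:(2^(n + 1L) - 1L)
  nxt <- bn_step(bn, states, inhibit)
  tibble(from = vapply(states, state_label, character(1), n = n),
         to = vapply(nxt, state_label, character(1), n = n))
}
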