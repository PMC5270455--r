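# Algorithm 1: a single Boolean network backbone, binarized at alpha, with
# the resting pair of every effective inhibition combination converted to a
# stochastic two-state motif carrying the PTIM sensitivity.
#
# For a combination c with sensitivity p_c whose sustained mask drives the
# all-active state into the pair (s, s+1) (s tumor-free):
#   rows s and s+1 send 1 - p_c to the tumorous partner s+1 and p_c to the
#   "success" state z = F(s) with the tumor bit forced to 0, where F is the
#   unmasked Boolean update. Under the mask, z collapses back onto s, so the
#   masked stationary tumor-free mass is exactly p_c; without the drug, z
#   rejoins the Boolean backbone and the tumor regrows.
# When two combinations share a resting pair (the deeper mask c0 owns it), a
# leak is added from the tumor-free row s to the state s with one target of
# c0 \ c re-activated; the leak pair routes 1 - p_c to its tumorous partner
# and p_c along the natural Boolean successor. Under c0 the leak collapses
# straight back onto s (no effect); under c it detours through a tumorous
# dwell, lowering the sensitivity. The leak weight is found by a
# one-dimensional search against the perturbed steady state. The backbone
# orientation is chosen to minimise the number of such couplings.

resting_pairs <- function(bn, tim_bits, targets) {
  n <- length(targets)
  out <- list()
  for (cb in 0:(2^n - 1L)) {
    if (tim_bits[cb + 1L] != 1L) next
    cyc <- attractor(bn, cb)
    s <- unique(bitwAnd(cyc, bitwNot(1L)))
    out[[length(out) + 1L]] <- list(cb = cb, s = if (length(s) == 1L) s else NA_integer_)
  }
  out
}

#' Markov chain satisfying a PTIM on a Boolean-network backbone
#'
#' Builds the deterministic Boolean network of the PTIM thresholded at
#' `alpha` (single-network, "cancer stem cell" perspective), then embeds
#' each effective inhibition combination's sensitivity as a stochastic
#' resting pair; combinations sharing a pair are resolved by a
#' one-dimensional search on a leak transition. Among the admissible
#' orientations of the inferred structure, the one with the fewest shared
#' resting pairs is used as the backbone.
#'
#' @param x A [ptim()].
#' @param alpha Binarization threshold; the thresholded TIM must admit a
#'   series-parallel pathway.
#' @param mutations Optional mutation set constraining the backbone (used as
#'   the mutation set of every candidate orientation whose first block it
#'   covers).
#' @param p Perturbation probability used for the coupled-combination
#'   searches and the final verification, default 0.001.
#' @param backbone Optional [pathway()] overriding structure inference.
#' @param epsilon Verification tolerance: the perturbed steady-state profile
#'   of the result must reproduce the PTIM within `epsilon` at every entry
#'   (error reporting the worst combination otherwise).
#' @return A [markov_chain()] whose [chain_to_ptim()] profile at `p`
#'   reproduces the input PTIM.
#' @examples
#' \donttest{
#' ch <- algorithm1_chain(load_fixture("table2"), alpha = 0.5)
#' chain_to_ptim(ch, p = 0.001)
#' }
#' @export
algorithm1_chain <- function(x, alpha, mutations = NULL, p = 0.001,
                             backbone = NULL, epsilon = 0.02) {
  stopifnot(inherits(x, "ptim"))
  targets <- panel_targets(x)
  n <- length(targets)
  t_bin <- binarize(x, alpha)
  bits <- map_values(t_bin)
  if (is.null(backbone)) {
    cands <- infer_structures(t_bin)
    if (length(cands) == 0L) {
      abort("thresholded PTIM admits no series-parallel pathway at this alpha.")
    }
    backbone <- select_backbone(cands[[1]], t_bin, mutations)
  }
  bn <- build_bn(backbone)
  if (!identical(map_values(bn_to_tim(bn)), bits)) {
    abort("backbone network does not reproduce the thresholded TIM.")
  }
  vals <- map_values(x)
  N <- 2^(n + 1L)
  P <- bn_chain(bn)$P

  pairs <- resting_pairs(bn, bits, targets)
  if (anyNA(vapply(pairs, `[[`, integer(1), "s"))) {
    abort("an attractor visits several resting pairs; no backbone embedding.")
  }
  # deepest masks first: the deepest combination owns a shared pair
  pairs <- pairs[order(-popcount(vapply(pairs, `[[`, integer(1), "cb")))]

  owner <- rep(NA_integer_, N)
  special <- rep(FALSE, N)
  zcol_of <- rep(NA_integer_, N)   # success column of an owned pair row
  leak_mass <- rep(0, N)           # mass already diverted from the success column
  coupled <- list()
  for (pr in pairs) {
    s <- pr$s
    p_c <- vals[pr$cb + 1L]
    if (is.na(owner[s + 1L])) {
      z <- bitwAnd(bn$successor[s + 1L], bitwNot(1L)) # F(s), tumor forced 0
      P[s + 1L, ] <- 0; P[s + 2L, ] <- 0
      P[s + 1L, s + 2L] <- 1 - p_c; P[s + 1L, z + 1L] <- P[s + 1L, z + 1L] + p_c
      P[s + 2L, s + 2L] <- 1 - p_c; P[s + 2L, z + 1L] <- P[s + 2L, z + 1L] + p_c
      owner[s + 1L] <- pr$cb
      zcol_of[s + 1L] <- z + 1L
      special[s + 1L] <- special[s + 2L] <- TRUE
    } else {
      coupled[[length(coupled) + 1L]] <- list(cb = pr$cb, s = s,
                                              owner = owner[s + 1L], p_c = p_c)
    }
  }

  # resolve combinations whose resting pair is owned by a deeper mask
  for (cp in coupled) {
    diff_bits <- which(bitwAnd(bitwShiftR(bitwXor(cp$owner, cp$cb),
                                          (n - seq_len(n))), 1L) == 1L &
                       bitwAnd(bitwShiftR(cp$owner, (n - seq_len(n))), 1L) == 1L)
    leak <- NA_integer_
    for (j in diff_bits) {
      cand <- bitwOr(cp$s, bitwShiftL(1L, n + 1L - j))
      if (!special[cand + 1L] && !special[cand + 2L]) { leak <- cand; break }
    }
    if (is.na(leak)) {
      abort(sprintf("no free leak state for coupled combination {%s}.",
                    subset_label(cp$cb, targets)))
    }
    zl <- bn$successor[leak + 1L] # natural Boolean successor
    P[leak + 1L, ] <- 0; P[leak + 2L, ] <- 0
    P[leak + 1L, leak + 2L] <- 1 - cp$p_c; P[leak + 1L, zl + 1L] <- P[leak + 1L, zl + 1L] + cp$p_c
    P[leak + 2L, leak + 2L] <- 1 - cp$p_c; P[leak + 2L, zl + 1L] <- P[leak + 2L, zl + 1L] + cp$p_c
    special[leak + 1L] <- special[leak + 2L] <- TRUE

    s <- cp$s
    zcol <- zcol_of[s + 1L]
    avail <- vals[cp$owner + 1L] - leak_mass[s + 1L]
    profile_at <- function(w) {
      P2 <- P
      P2[s + 1L, zcol] <- P2[s + 1L, zcol] - w
      P2[s + 1L, leak + 1L] <- P2[s + 1L, leak + 1L] + w
      m <- masked_chain(markov_chain(P2, targets), cp$cb)
      pi <- stationary(perturb(m, p))
      sum(pi[seq(1L, N, by = 2L)])
    }
    objective <- function(w) abs(profile_at(w) - cp$p_c)
    opt <- optimize(objective, interval = c(0, avail), tol = 1e-6)
    w <- opt$minimum
    # golden-section search never lands on the endpoints; prefer them when
    # they do at least as well (w = 0 keeps a binary PTIM deterministic)
    for (w_end in c(0, avail)) {
      if (objective(w_end) <= opt$objective) { w <- w_end; break }
    }
    P[s + 1L, zcol] <- P[s + 1L, zcol] - w
    P[s + 1L, leak + 1L] <- P[s + 1L, leak + 1L] + w
    leak_mass[s + 1L] <- leak_mass[s + 1L] + w
  }

  out <- markov_chain(P, targets)
  check <- map_values(chain_to_ptim(out, p = p))
  errs <- abs(check - vals)
  if (max(errs) > epsilon) {
    worst <- which.max(errs) - 1L
    abort(sprintf("steady-state search failed: combination {%s} off by %.3f (> %.3f).",
                  subset_label(worst, targets), max(errs), epsilon))
  }
  out
}

# pick the orientation of the inferred structure whose Boolean network (a)
# reproduces the TIM and (b) has the fewest combinations sharing a resting
# pair; enumeration is capped, which is ample at inference scale
select_backbone <- function(candidate, t_bin, mutations = NULL, cap = 120L) {
  bits <- map_values(t_bin)
  targets <- panel_targets(t_bin)
  orients <- enumerate_orientations(candidate, mutations = mutations)
  if (length(orients) > cap) orients <- orients[seq_len(cap)]
  best <- NULL
  best_score <- Inf
  for (pw in orients) {
    bn <- try(build_bn(pw), silent = TRUE)
    if (inherits(bn, "try-error")) next
    if (!identical(map_values(bn_to_tim(bn)), bits)) next
    prs <- resting_pairs(bn, bits, targets)
    ss <- vapply(prs, `[[`, integer(1), "s")
    if (anyNA(ss)) next
    score <- length(ss) - length(unique(ss))
    if (score < best_score) { best <- pw; best_score <- score }
    if (score == 0L) break
  }
  if (is.null(best)) {
    abort("no orientation of the inferred structure yields a consistent Boolean network.")
  }
  best
}
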