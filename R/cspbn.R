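#' Decompose a PTIM into sensitivity levels
#'
#' Clusters the PTIM's sensitivity values into plateaus of spread at most
#' `epsilon` (greedy over the sorted unique values); the plateau at the
#' bottom whose values are all `<= epsilon` is treated as experimental noise
#' around zero and discarded. Each remaining plateau `k` defines a level
#' value `v_k` (the plateau maximum), a binarization threshold `v_k -
#' epsilon` and a network selection weight `v_1, v_2 - v_1, ...` — the
#' mixture weights under which nested Boolean networks reproduce the PTIM.
#'
#' @param x A [ptim()].
#' @param epsilon Plateau half-width / noise floor, in `(0, 0.5)`.
#' @return A tibble of class `"level_decomposition"` with columns `level`,
#'   `value`, `threshold`, `weight`.
#' @examples
#' sensitivity_levels(load_fixture("table5"), epsilon = 0.05)
#' @export
sensitivity_levels <- function(x, epsilon = 0.05) {
  stopifnot(inherits(x, "ptim"))
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 0.5) {
    abort("`epsilon` must be in (0, 0.5).")
  }
  vals <- sort(unique(map_values(x)))
  clusters <- list()
  cur <- vals[1]
  for (v in vals[-1]) {
    if (v - cur[1] <= epsilon) cur <- c(cur, v)
    else { clusters[[length(clusters) + 1L]] <- cur; cur <- v }
  }
  clusters[[length(clusters) + 1L]] <- cur
  clusters <- clusters[vapply(clusters, function(cl) max(cl) > epsilon, logical(1))]
  if (length(clusters) == 0L) {
    abort("all sensitivities lie in the noise plateau; no effective inhibition.")
  }
  v <- vapply(clusters, max, numeric(1))
  out <- tibble(level = seq_along(v), value = v,
                threshold = v - epsilon,
                weight = diff(c(0, v)))
  structure(out, targets = panel_targets(x), epsilon = epsilon,
            class = c("level_decomposition", class(out)))
}

#' Build a context-sensitive probabilistic Boolean network from a PTIM
#'
#' One Boolean network per sensitivity level: level `k`'s TIM is the PTIM
#' binarized at its threshold, a series-parallel pathway consistent with it
#' is inferred and converted to a network, and the networks are combined
#' with the level weights as selection probabilities, switching probability
#' `q` and per-bit perturbation `p`. Levels may come from
#' [sensitivity_levels()] (`epsilon` given) or be specified explicitly via
#' `thresholds` and `weights`. A weight deficit `1 - sum(weights)` is
#' assigned to the last (least sensitive... most stringent) network when
#' `normalize = TRUE`.
#'
#' @param x A [ptim()].
#' @param epsilon Plateau width for automatic level detection (ignored when
#'   `thresholds` is given).
#' @param thresholds Optional explicit binarization thresholds (increasing).
#' @param weights Optional explicit selection probabilities, same length as
#'   `thresholds`.
#' @param p Per-bit perturbation probability.
#' @param q Network switching probability.
#' @param mutations Optional list of mutation hints, one per level (each a
#'   character vector), passed to the pathway of that level.
#' @param normalize Assign any weight deficit to the last network so weights
#'   sum to one.
#' @return An object of class `"cspbn"`: networks, weights, `p`, `q`, the
#'   level TIMs and the decomposition used.
#' @examples
#' \donttest{
#' model <- algorithm2_build(load_fixture("table5"), epsilon = 0.05)
#' glance(model)
#' }
#' @export
algorithm2_build <- function(x, epsilon = 0.05, thresholds = NULL,
                             weights = NULL, p = 0.001, q = 0.001,
                             mutations = NULL, normalize = TRUE) {
  stopifnot(inherits(x, "ptim"))
  targets <- panel_targets(x)
  if (is.null(thresholds)) {
    dec <- sensitivity_levels(x, epsilon)
    thresholds <- dec$threshold
    weights <- dec$weight
  } else {
    if (is.null(weights) || length(weights) != length(thresholds)) {
      abort("explicit `thresholds` require `weights` of the same length.")
    }
    dec <- tibble(level = seq_along(thresholds),
                  value = cumsum(weights), threshold = thresholds,
                  weight = weights)
  }
  if (any(diff(thresholds) <= 0)) abort("`thresholds` must be increasing.")
  if (normalize && sum(weights) < 1) {
    weights[length(weights)] <- weights[length(weights)] + (1 - sum(weights))
  }
  if (abs(sum(weights) - 1) > 1e-12) {
    abort("selection probabilities must sum to 1 (use `normalize = TRUE`).")
  }
  tims <- lapply(thresholds, function(a) binarize(x, a))
  networks <- lapply(seq_along(tims), function(k) {
    cands <- infer_structures(tims[[k]])
    if (length(cands) == 0L) {
      # monotone but not series-parallel (e.g. a majority map): fall back to
      # the direct monotone realisation
      return(monotone_bn(tims[[k]]))
    }
    mk <- if (!is.null(mutations)) mutations[[k]] else NULL
    build_bn(default_pathway(cands[[1]], mutations = mk))
  })
  structure(list(networks = networks, weights = weights, p = p, q = q,
                 tims = tims, decomposition = dec),
            targets = targets, class = "cspbn")
}

#' @export
print.cspbn <- function(x, ...) {
  cat(sprintf(
    "Context-sensitive PBN: %d networks over %d targets (p = %g, q = %g)\n",
    length(x$networks), length(panel_targets(x)), x$p, x$q))
  cat("  selection probabilities:", paste(signif(x$weights, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.cspbn <- function(x, ...) {
  tibble(
    network = seq_along(x$networks),
    weight = x$weights,
    threshold = if (!is.null(x$decomposition)) x$decomposition$threshold else NA_real_,
    blocking_sets = vapply(x$networks, function(bn) {
      sets <- minimal_blocking_sets(bn_to_tim(bn))
      paste(vapply(sets, paste, character(1), collapse = "+"), collapse = "; ")
    }, character(1))
  )
}

#' @export
glance.cspbn <- function(x, ...) {
  tibble(n_networks = length(x$networks),
         n_targets = length(panel_targets(x)),
         p = x$p, q = x$q)
}

#' Collapsed Markov chain of a context-sensitive PBN under inhibition
#'
#' One step of the collapsed (network, state) chain: with probability `q`
#' the governing network is resampled from the selection probabilities
#' (possibly landing on the same network), then the current network makes
#' its deterministic transition, the sustained mask is applied, and every
#' bit flips independently with probability `p`. Resampling (rather than
#' moving to a uniformly random other network) makes the stationary network
#' marginal exactly the selection probabilities.
#'
#' @param model A [algorithm2_build()] model (or hand-built `"cspbn"`).
#' @param inhibit Sustained inhibition (character vector or subset index).
#' @return A plain transition matrix of dimension `K * 2^(n+1)` with
#'   attribute `"targets"`; rows/columns ordered network-major.
#' @export
cspbn_chain <- function(model, inhibit = NULL) {
  targets <- panel_targets(model)
  n <- length(targets)
  N <- 2^(n + 1L)
  K <- length(model$networks)
  switch_m <- (1 - model$q) * diag(K) + model$q * matrix(model$weights, K, K, byrow = TRUE)
  Fm <- if (model$p > 0) flip_kernel(model$p, n + 1L) else diag(N)
  M <- matrix(0, K * N, K * N)
  for (k2 in seq_len(K)) {
    A <- bn_chain(model$networks[[k2]])
    A <- masked_chain(A, resolve_mask_bits(inhibit, targets))$P %*% Fm
    for (k1 in seq_len(K)) {
      rows <- (k1 - 1L) * N + seq_len(N)
      cols <- (k2 - 1L) * N + seq_len(N)
      M[rows, cols] <- switch_m[k1, k2] * A
    }
  }
  attr(M, "targets") <- targets
  M
}

#' Steady-state inhibition profile of a context-sensitive PBN
#'
#' For every inhibition subset, the collapsed chain's stationary probability
#' of tumor bit 0 (summed over networks). As `p, q -> 0` each entry
#' converges to the weight-mixture of the level TIM entries.
#'
#' @param model A `"cspbn"` model.
#' @return A [ptim()].
#' @export
cspbn_to_ptim <- function(model) {
  targets <- panel_targets(model)
  n <- length(targets)
  vals <- vapply(0:(2^n - 1L), function(cb) {
    collapsed_tumor0_mass(model, cb)
  }, numeric(1))
  ptim(pmin(pmax(vals, 0), 1), targets)
}

collapsed_tumor0_mass <- function(model, inhibit) {
  n <- length(panel_targets(model))
  N <- 2^(n + 1L)
  M <- cspbn_chain(model, inhibit)
  pi <- stationary_any(M, model, inhibit)
  tumor0 <- which(rep(seq_len(N) %% 2L == 1L, length(model$networks)))
  sum(pi[tumor0])
}

# stationary of a collapsed chain; ergodic when p > 0, otherwise restricted
# to the trajectory from (network 1, all-ones)
stationary_any <- function(M, model, inhibit) {
  if (model$p > 0 && model$q > 0 && all(model$weights > 0)) {
    return(solve_stationary(M))
  }
  n <- length(panel_targets(model))
  stationary(M, start = 2^(n + 1L) - 1L)
}

#' Mean and maximum absolute PTIM reconstruction error
#'
#' @param model_ptim,reference_ptim Two [ptim()]s over the same panel.
#' @return A tibble with columns `mean_abs` and `max_abs` over all `2^n`
#'   entries.
#' @export
ptim_error <- function(model_ptim, reference_ptim) {
  if (!identical(panel_targets(model_ptim), panel_targets(reference_ptim))) {
    abort("PTIMs are over different target panels.")
  }
  d <- abs(map_values(model_ptim) - map_values(reference_ptim))
  tibble(mean_abs = mean(d), max_abs = max(d))
}
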