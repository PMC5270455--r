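#' Steady-state sensitivity of a periodic drug regimen
#'
#' A regimen is an ordered period of intervention masks (an empty mask
#' meaning no drug that step) applied cyclically forever. The period-product
#' chain is solved for its stationary distribution at one phase boundary,
#' the distribution is propagated around the cycle, and the sensitivity is
#' the phase-averaged stationary probability of tumor bit 0. A period of
#' length one reduces exactly to the model's steady-state inhibition-profile
#' entry for that mask.
#'
#' @param model A `"cspbn"` model or a [markov_chain()].
#' @param regimen A list of masks (character vectors of inhibited targets;
#'   `character(0)` or `NULL` = no drug), or a single character vector for a
#'   sustained (period-1) regimen.
#' @param p Perturbation probability used when `model` is a raw Markov chain
#'   (a cspbn carries its own `p`/`q`).
#' @return Sensitivity in `[0, 1]`, with attribute `"phases"`: a tibble of
#'   per-phase tumor-free stationary mass.
#' @examples
#' \donttest{
#' model <- algorithm2_build(load_fixture("table5"))
#' evaluate_regimen(model, list(c("K2", "K3"))) # sustained drug, ~0.9
#' evaluate_regimen(model, list(c("K2", "K3"), c("K1", "K3"))) # alternating
#' }
#' @export
evaluate_regimen <- function(model, regimen, p = 0.001) {
  if (!is.list(regimen)) regimen <- list(regimen)
  if (length(regimen) < 1L) abort("the regimen period must have length >= 1.")
  targets <- panel_targets(model)
  n <- length(targets)
  N <- 2^(n + 1L)
  if (inherits(model, "cspbn")) {
    mats <- lapply(regimen, function(m) cspbn_chain(model, m))
    tumor0 <- which(rep(seq_len(N) %% 2L == 1L, length(model$networks)))
    ergodic <- model$p > 0
    start <- N - 1L
  } else if (inherits(model, "markov_chain")) {
    mats <- lapply(regimen, function(m) {
      perturb(masked_chain(model, resolve_mask_bits(m, targets)), p)$P
    })
    tumor0 <- which(seq_len(N) %% 2L == 1L)
    ergodic <- p > 0
    start <- N - 1L
  } else {
    abort("`model` must be a cspbn or a markov_chain.")
  }
  Q <- Reduce(`%*%`, mats)
  pi <- if (ergodic) solve_stationary(Q) else stationary(Q, start = start)
  phases <- numeric(length(mats))
  for (k in seq_along(mats)) {
    phases[k] <- sum(pi[tumor0])
    pi <- drop(pi %*% mats[[k]])
  }
  structure(mean(phases),
            phases = tibble(phase = seq_along(phases), tumor_free = phases))
}
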