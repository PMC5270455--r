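#' Generate a random directional pathway
#'
#' Samples a series-parallel survival circuit: the number of serial blocks,
#' lines per block and targets per line are drawn uniformly from the given
#' ranges, targets are auto-named `T1, T2, ...` in circuit order, and the
#' mutation set is the first block (the minimal latent-activation pattern
#' that drives the circuit). Used as the property-test generator: any
#' pathway it returns satisfies the cut-function / network-TIM consistency
#' checks.
#'
#' @param seed Optional integer seed.
#' @param n_blocks,n_lines,line_length Integer ranges `c(min, max)` for the
#'   number of serial blocks, parallel lines per block, and targets per
#'   line.
#' @param max_targets Resampled line sizes are trimmed so the panel stays at
#'   or below this size (default 10, keeping the `2^(n+1)` state space
#'   small).
#' @return A [pathway()].
#' @export
random_pathway <- function(seed = NULL, n_blocks = c(1, 3), n_lines = c(1, 3),
                           line_length = c(1, 3), max_targets = 10L) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    L <- sample(n_blocks[1]:n_blocks[2], 1L)
    shape <- lapply(seq_len(L), function(i) {
      a <- sample(n_lines[1]:n_lines[2], 1L)
      vapply(seq_len(a), function(j) sample(line_length[1]:line_length[2], 1L),
             integer(1))
    })
    if (sum(unlist(shape)) <= max_targets) break
  }
  nm <- paste0("T", seq_len(sum(unlist(shape))))
  k <- 0L
  blocks <- lapply(shape, function(b) {
    lapply(b, function(len) {
      out <- nm[k + seq_len(len)]
      k <<- k + len
      out
    })
  })
  # latent activations: the line heads of the first block (mid-line targets
  # must stay switchable by upstream cuts)
  pathway(blocks, mutations = vapply(blocks[[1]], `[[`, character(1), 1L))
}

#' Generate a layered synthetic PTIM with known ground truth
#'
#' Builds a PTIM as a weighted sum of nested TIMs: level 1 is the cut
#' function of the base pathway; each further level adds one extra parallel
#' line (a new target) to a random block, making blocking strictly harder,
#' so the level TIMs are nested and the mixture is recoverable by the
#' level-decomposition of [sensitivity_levels()] up to the noise amplitude.
#'
#' @param seed Optional integer seed.
#' @param base Optional base [pathway()]; default [random_pathway()].
#' @param levels Increasing cumulative sensitivities in `(0, 1]`, one per
#'   level (the planted level values; weights are their differences).
#' @param noise Uniform noise half-width added to every entry (clipped to
#'   `[0, 1]`); must be below half the smallest level gap.
#' @return A [ptim()] with attributes `"level_tims"`, `"level_values"` and
#'   `"pathways"` (the ground truth).
#' @export
random_ptim <- function(seed = NULL, base = NULL,
                        levels = c(0.5, 0.8, 1), noise = 0) {
  if (!is.null(seed)) set.seed(seed)
  levels <- sort(levels)
  if (any(levels <= 0 | levels > 1)) abort("`levels` must lie in (0, 1].")
  gaps <- diff(c(0, levels))
  if (noise < 0 || (noise > 0 && noise >= min(gaps) / 2)) {
    abort("`noise` must be below half the minimum level gap.")
  }
  if (is.null(base)) base <- random_pathway(max_targets = 6L)
  paths <- list(base)
  for (k in seq_along(levels)[-1]) {
    prev <- paths[[k - 1L]]
    blocks <- prev$blocks
    bi <- sample(length(blocks), 1L)
    new_t <- paste0("T", length(unlist(blocks)) + 1L)
    blocks[[bi]] <- c(blocks[[bi]], list(new_t))
    paths[[k]] <- pathway(blocks, mutations = prev$mutations)
  }
  targets <- panel_targets(paths[[length(paths)]])
  tims <- lapply(paths, pathway_tim, targets = targets)
  vals <- Reduce(`+`, Map(function(tm, w) w * map_values(tm), tims, gaps))
  if (noise > 0) {
    vals <- pmin(pmax(vals + runif(length(vals), -noise, noise), 0), 1)
  }
  out <- ptim(vals, targets)
  attr(out, "level_tims") <- tims
  attr(out, "level_values") <- levels
  attr(out, "pathways") <- paths
  out
}
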