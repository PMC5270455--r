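#' Worst-case number of steady-state experiments to orient a pathway
#'
#' Upper bound on the number of steady-state target-expression measurements
#' needed to decipher all directionalities of a series-parallel structure:
#' ordering the `L` serial blocks costs at most `L - 1` experiments, and the
#' within-block target order costs at most
#' `max(max_j b_j - 2, ceil((sum_j b_j - a) / (a - 1)) - 1)` for the worst
#' block (per-block term clamped at zero, and the second inner term only
#' applies to blocks with more than one line).
#'
#' @param structure A [block_structure()], [pathway()] or inferred candidate.
#' @return Integer bound (>= 0).
#' @examples
#' s <- load_fixture("figure4_structure")
#' worst_case_bound(s) # 6
#' @export
worst_case_bound <- function(structure) {
  blocks <- structure_blocks(structure)
  inner <- vapply(blocks, function(b) {
    a <- length(b)
    t1 <- max(b) - 2
    t2 <- if (a > 1L) ceiling((sum(b) - a) / (a - 1)) - 1 else -Inf
    max(0, t1, t2)
  }, numeric(1))
  as.integer(max(inner) + (length(blocks) - 1L))
}

#' Expected number of steady-state experiments to orient a pathway
#'
#' Bound on the expectation: ordering `L >= 2` serial blocks by random pivot
#' queries costs `(2L - 1)/3` in expectation (0 for `L = 1`), and the worst
#' block's within-line resolution costs `max_j (2 b_j - 4)/3`, clamped at
#' zero.
#'
#' @inheritParams worst_case_bound
#' @return Numeric bound (>= 0).
#' @examples
#' expected_bound(load_fixture("figure4_structure")) # 13/3 = 4.33
#' @export
expected_bound <- function(structure) {
  blocks <- structure_blocks(structure)
  inner <- vapply(blocks, function(b) max(0, (2 * max(b) - 4) / 3), numeric(1))
  L <- length(blocks)
  order_term <- if (L >= 2L) (2 * L - 1) / 3 else 0
  max(inner) + order_term
}

# exact expected pivot cost over all pivot sequences, by the recurrence
# E(m) = 1 + (2/m) * sum_{k<m} E(k); closed form (2m - 1)/3 for m >= 2
pivot_expected_cost <- function(m) {
  if (m <= 1L) return(0)
  e <- numeric(m + 1L) # e[k+1] = E(k)
  for (k in 2:m) e[k + 1L] <- 1 + 2 / k * sum(e[seq_len(k)])
  e[m + 1L]
}

sample_pivot_cost <- function(m) {
  if (m <= 1L) return(0L)
  k <- sample.int(m, 1L) - 1L # pivot position: k blocks upstream
  1L + sample_pivot_cost(k) + sample_pivot_cost(m - 1L - k)
}

#' Simulate the discovery of a pathway's directional orientation
#'
#' Monte-Carlo model of the sequential steady-state experiments that resolve
#' a structure's directionalities, in two phases. Phase 1 orders the serial
#' blocks by random-pivot queries: inhibiting one unresolved block and reading
#' the steady-state expressions splits the remaining blocks into upstream
#' (still expressed) and downstream (dark) groups, which are resolved
#' recursively; the expected cost is `(2m - 1)/3` for `m >= 2` blocks and the
#' worst case is `m - 1`. Phase 2 orders the targets within each line: a line
#' of length `b >= 3` needs `b - 2` position queries, the first of which is
#' free with probability 1/3 (information carried over from phase 1); queries
#' are batched across up to `a_i - 1` lines of a block per experiment.
#'
#' @inheritParams worst_case_bound
#' @param runs Number of simulated runs (>= 1).
#' @param seed Optional integer seed fixing the random stream.
#' @return A tibble of class `"orientation_sim"` with columns `experiments`
#'   and `runs` (the histogram), and attributes `mean`, `max` and `counts`
#'   (the per-run counts).
#' @examples
#' sim <- simulate_orientation_discovery(load_fixture("figure4_structure"),
#'                                       runs = 200, seed = 1)
#' attr(sim, "max")
#' @export
simulate_orientation_discovery <- function(structure, runs = 10000L, seed = NULL) {
  blocks <- structure_blocks(structure)
  if (runs < 1L) abort("`runs` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  L <- length(blocks)
  counts <- vapply(seq_len(runs), function(r) {
    total <- sample_pivot_cost(L)
    for (b in blocks) {
      pending <- pmax(b - 2L, 0L)
      need <- pending > 0L
      if (any(need)) {
        free <- runif(sum(need)) < 1 / 3
        pending[need] <- pending[need] - as.integer(free)
        cap <- max(1L, length(b) - 1L)
        while (any(pending > 0L)) {
          hit <- utils::head(which(pending > 0L), cap)
          pending[hit] <- pending[hit] - 1L
          total <- total + 1L
        }
      }
    }
    total
  }, integer(1))
  hist <- as_tibble(table(experiments = counts))
  hist$experiments <- as.integer(hist$experiments)
  names(hist)[2] <- "runs"
  structure(hist, mean = mean(counts), max = max(counts), counts = counts,
            class = c("orientation_sim", class(hist)))
}

#' @export
print.orientation_sim <- function(x, ...) {
  cat(sprintf("Orientation-discovery simulation: mean %.4f, max %d over %d runs\n",
              attr(x, "mean"), attr(x, "max"), sum(x$runs)))
  NextMethod()
}

#' @rdname autoplot.ptim
#' @export
autoplot.orientation_sim <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$experiments, y = .data$runs)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "steady-state experiments", y = "simulation runs") +
    ggplot2::theme_minimal()
}
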