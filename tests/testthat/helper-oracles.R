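# Independent brute-force oracles kept deliberately separate from the
# package's own code paths.

# all inclusion-minimal blocking subsets by direct enumeration over 2^n sets
oracle_minimal_sets <- function(tim_obj) {
  targets <- panel_targets(tim_obj)
  n <- length(targets)
  bits <- tim_obj$blocked[order(tim_obj$index)]
  subsets <- lapply(0:(2^n - 1L), function(i) {
    targets[bitwAnd(bitwShiftR(i, n - seq_len(n)), 1L) == 1L]
  })
  blocking <- which(bits == 1L)
  keep <- vapply(blocking, function(bi) {
    s <- subsets[[bi]]
    !any(vapply(blocking, function(bj) {
      t <- subsets[[bj]]
      length(t) < length(s) && all(t %in% s)
    }, logical(1)))
  }, logical(1))
  out <- subsets[blocking[keep]]
  out[lengths(out) > 0L | vapply(out, length, integer(1)) == 0L]
}

# exact expected pivot cost: full enumeration over equally likely pivot
# positions at every recursion level
oracle_pivot_expectation <- function(m) {
  if (m <= 1L) return(0)
  mean(vapply(0:(m - 1L), function(k) {
    1 + oracle_pivot_expectation(k) + oracle_pivot_expectation(m - 1L - k)
  }, numeric(1)))
}

# evaluate a cut function by direct path search: the tumor survives iff some
# block still has a fully uninhibited line
oracle_cut <- function(blocks, inhibited) {
  blocked <- vapply(blocks, function(b) {
    all(vapply(b, function(line) any(line %in% inhibited), logical(1)))
  }, logical(1))
  as.integer(any(blocked))
}

expect_same_map <- function(a, b, tol = 0) {
  va <- if ("blocked" %in% names(a)) a$blocked[order(a$index)] else a$sensitivity[order(a$index)]
  vb <- if ("blocked" %in% names(b)) b$blocked[order(b$index)] else b$sensitivity[order(b$index)]
  if (tol == 0) expect_equal(as.numeric(va), as.numeric(vb))
  else expect_lt(max(abs(va - vb)), tol)
}

random_ergodic_chain <- function(targets) {
  N <- 2^(length(targets) + 1L)
  P <- matrix(runif(N * N, min = 0.01), N, N)
  markov_chain(P / rowSums(P), targets)
}
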