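state <- function(s) strtoi(s, base = 2)

test_that("reset semantics copies the masked-image row", {
  withr::local_seed(1)
  targets <- paste0("K", 1:4)
  ch <- random_ergodic_chain(targets)
  p2 <- masked_chain(ch, c("K1", "K2"), semantics = "reset")
  for (r in c("00000", "10000", "01000", "11000")) {
    expect_equal(p2$P[r, ], ch$P["00000", ])
  }
  for (r in c("00001", "10001", "01001", "11001")) {
    expect_equal(p2$P[r, ], ch$P["00001", ])
  }
})

test_that("redirect semantics equals right-multiplication by the intervention matrix", {
  withr::local_seed(2)
  targets <- c("K1", "K2", "K3")
  ch <- random_ergodic_chain(targets)
  for (cb in c(0L, 3L, 5L, 7L)) {
    p3 <- masked_chain(ch, cb, semantics = "redirect")
    expect_equal(p3$P, unname(ch$P %*% intervention_matrix(targets, cb)),
                 ignore_attr = TRUE)
  }
  # identity mask leaves the chain unchanged
  expect_equal(masked_chain(ch, 0L)$P, ch$P)
  # deterministic chains: redirect equals the masked Boolean step table
  bn <- build_bn(load_fixture("figure2a_pathway"))
  PT <- masked_chain(bn_chain(bn), "K2")$P
  expect_equal(which(t(PT) == 1) - 16 * (0:15) - 1L,
               bn_step(bn, 0:15, inhibit = "K2"))
})

test_that("aggregated reset stationary equals redirect stationary (200 random chains)", {
  withr::local_seed(99)
  worst <- 0
  for (rep in 1:200) {
    targets <- paste0("K", seq_len(sample(2:4, 1)))
    ch <- random_ergodic_chain(targets)
    cb <- sample(0:(2^length(targets) - 1L), 1)
    pi2 <- stationary(masked_chain(ch, cb, semantics = "reset"))
    pi3 <- stationary(masked_chain(ch, cb, semantics = "redirect"))
    agg <- aggregate_distribution(pi2, targets, cb)
    worst <- max(worst, max(abs(agg - pi3)))
  }
  expect_lt(worst, 1e-10)
})

test_that("aggregation preserves mass and collapses onto fixed states", {
  targets <- c("K1", "K2", "K3")
  pi <- rep(1 / 16, 16)
  agg <- aggregate_distribution(pi, targets, c("K1", "K2", "K3"))
  expect_equal(sum(agg), 1)
  expect_equal(unname(agg[state("0000") + 1L]), 0.5)
  expect_equal(unname(agg[state("0001") + 1L]), 0.5)
  expect_true(all(agg[-(state(c("0000", "0001")) + 1L)] == 0))
})

test_that("perturbation keeps rows stochastic and p = 0 is the identity", {
  withr::local_seed(3)
  ch <- random_ergodic_chain(c("K1", "K2"))
  expect_identical(perturb(ch, 0)$P, ch$P)
  pt <- perturb(ch, 0.01)
  expect_equal(unname(rowSums(pt$P)), rep(1, 8), tolerance = 1e-14)
  expect_true(all(pt$P > 0))
  pt2 <- perturb(ch, 0.01, bits = "targets")
  expect_equal(unname(rowSums(pt2$P)), rep(1, 8), tolerance = 1e-14)
})

test_that("stationary distributions match closed forms", {
  # rank-one two-state chain
  for (phat in c(0.2, 0.7)) {
    P <- matrix(c(phat, 1 - phat, phat, 1 - phat), 2, 2, byrow = TRUE)
    expect_equal(unname(timdyn:::solve_stationary(P)), c(phat, 1 - phat))
  }
  # doubly stochastic chains are uniform
  withr::local_seed(4)
  targets <- c("K1", "K2")
  A <- matrix(runif(64), 8, 8)
  # symmetrise then normalise (keeps double stochasticity)
  A <- (A + t(A)) / 2
  for (i in 1:500) { A <- A / rowSums(A); A <- t(t(A) / colSums(A)) }
  pi <- stationary(markov_chain(A / rowSums(A), targets))
  expect_equal(unname(pi), rep(1 / 8, 8), tolerance = 1e-6)
  # a permutation chain with two cycles is reducible: start state required
  P <- diag(8)[c(2, 3, 4, 1, 6, 7, 8, 5), ]
  expect_error(stationary(markov_chain(P, targets)), "reducible")
  pi <- stationary(markov_chain(P, targets), start = 0L)
  expect_equal(unname(pi), rep(c(1 / 4, 0), each = 4))
})

test_that("the trivial construction satisfies any PTIM exactly at p = 0", {
  t2 <- load_fixture("table2")
  tc <- trivial_chain_from_ptim(t2)
  expect_same_map(chain_to_ptim(tc, p = 0), t2)
  withr::local_seed(5)
  for (rep in 1:5) {
    targets <- paste0("K", seq_len(sample(1:3, 1)))
    x <- ptim(runif(2^length(targets)), targets)
    expect_same_map(chain_to_ptim(trivial_chain_from_ptim(x), p = 0), x)
  }
  # degenerate entries: p_i = 1 makes the tumor-free state absorbing
  one <- trivial_chain_from_ptim(ptim(c(1, 0.5), "K1"))
  expect_equal(one$P["10", "10"], 1)
  expect_equal(one$P["00", c("00", "01")], c(0.5, 0.5), ignore_attr = TRUE)
})

test_that("deterministic network chains converge to the binary map as p -> 0", {
  bn <- build_bn(load_fixture("figure2a_pathway"))
  ch <- bn_chain(bn)
  prof <- chain_to_ptim(ch, p = 1e-6)
  expect_same_map(binarize(prof, 0.5), bn_to_tim(bn))
  expect_lt(max(abs(prof$sensitivity - bn_to_tim(bn)$blocked)), 1e-3)
})

test_that("the embedded hand-built chain reproduces the printed steady states", {
  t3 <- load_fixture("table3")
  expect_equal(unname(rowSums(t3$P)), rep(1, 16)) # exact transcription
  prof <- chain_to_ptim(t3, p = 0.001)
  t4 <- load_fixture("table4")
  expect_same_map(prof, t4, tol = 5e-3)
  # matched perturbation convention agrees to printed precision
  expect_lt(max(abs(prof$sensitivity - t4$sensitivity)), 1e-4)
  # at p = 0 the six uncoupled combinations reproduce the input map exactly
  p0 <- chain_to_ptim(t3, p = 0)
  t2 <- load_fixture("table2")
  uncoupled <- setdiff(0:7, 6L) # {K1,K2} is resolved through the leak pair
  expect_equal(p0$sensitivity[uncoupled + 1L], t2$sensitivity[uncoupled + 1L])
})

test_that("the resting-pair construction meets its steady-state contract", {
  t2 <- load_fixture("table2")
  ch <- algorithm1_chain(t2, alpha = 0.5)
  prof <- chain_to_ptim(ch, p = 0.001)
  expect_same_map(prof, t2, tol = 0.01)
  expect_same_map(prof, load_fixture("table4"), tol = 0.02)
  # a binary PTIM reduces to a deterministic chain
  bits <- load_fixture("figure1_tim")$blocked
  chb <- algorithm1_chain(ptim(bits, c("K1", "K2", "K3")), alpha = 0.5)
  expect_true(all(chb$P %in% c(0, 1)))
  expect_equal(rowSums(chb$P == 1), rep(1, 16), ignore_attr = TRUE)
})

test_that("chain text serialisation round-trips", {
  t3 <- load_fixture("table3")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_chain(t3, f)
  back <- read_chain(f, panel_targets(t3))
  expect_equal(back$P, t3$P)
})
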