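test_that("sensitivity levels of the toy heterogeneous map match the printed weights", {
  dec <- sensitivity_levels(load_fixture("table5"), epsilon = 0.05)
  expect_equal(nrow(dec), 3L)
  expect_equal(dec$weight, c(0.65, 0.25, 0.10))
  expect_equal(dec$value, c(0.65, 0.90, 1.00))
  # the level TIMs are the printed triplet
  t5 <- load_fixture("table5")
  for (k in 1:3) {
    expect_same_map(binarize(t5, dec$threshold[k]),
                    load_fixture(paste0("table6_bn", k)))
  }
})

test_that("degenerate level decompositions behave", {
  targets <- c("K1", "K2")
  expect_equal(sensitivity_levels(ptim(rep(1, 4), targets))$weight, 1)
  expect_error(sensitivity_levels(ptim(rep(0.01, 4), targets), 0.05),
               "noise plateau")
})

test_that("the heterogeneous-clone model reproduces the printed simulated map", {
  model <- algorithm2_build(load_fixture("table5"), epsilon = 0.05,
                            p = 0.001, q = 0.001)
  expect_equal(model$weights, c(0.65, 0.25, 0.10))
  out <- cspbn_to_ptim(model)
  expect_same_map(out, load_fixture("table7"), tol = 0.01)
  expect_equal(ptim_entry(out, "K3"), 0.6495, tolerance = 0.01)
  td <- tidy(model)
  expect_equal(td$weight, model$weights)
  expect_equal(glance(model)$n_networks, 3L)
})

test_that("explicit thresholds and weights reproduce the kinase-screen model", {
  t8 <- load_fixture("table8")
  model <- algorithm2_build(t8, thresholds = c(0.3, 0.55, 0.8),
                            weights = c(0.5, 0.25, 0.25))
  for (k in 1:3) {
    expect_same_map(bn_to_tim(model$networks[[k]]),
                    load_fixture(paste0("table", 8 + k)))
  }
  out <- cspbn_to_ptim(model)
  expect_same_map(out, load_fixture("table12"), tol = 0.01)
  err <- ptim_error(out, t8)
  expect_lt(abs(err$mean_abs - 0.043), 0.005)
  expect_lt(abs(err$max_abs - 0.2), 0.01)
})

test_that("collapsed chains are proper and carry the selection marginal", {
  model <- algorithm2_build(load_fixture("table5"))
  M <- cspbn_chain(model, "K3")
  expect_equal(rowSums(M), rep(1, nrow(M)), tolerance = 1e-12)
  pi <- timdyn:::solve_stationary(M)
  expect_equal(sum(pi), 1, tolerance = 1e-12)
  marg <- vapply(1:3, function(k) sum(pi[(k - 1) * 16 + 1:16]), numeric(1))
  expect_equal(marg, model$weights, tolerance = 0.02) # within O(p + q)
})

test_that("model maps converge to the weight-mixture of level TIMs as p, q -> 0", {
  withr::local_seed(21)
  for (rep in 1:3) {
    x <- random_ptim(base = random_pathway(max_targets = 3L),
                     levels = c(0.4, 0.75, 1))
    model <- algorithm2_build(x, epsilon = 0.05, p = 1e-5, q = 1e-5)
    mix <- Reduce(`+`, Map(function(tm, w) w * tm$blocked,
                           model$tims, model$weights))
    out <- cspbn_to_ptim(model)
    expect_lt(max(abs(out$sensitivity - mix)), 1e-3)
  }
})

test_that("ptim_error is a symmetric metric pair", {
  t8 <- load_fixture("table8")
  t12 <- load_fixture("table12")
  e <- ptim_error(t12, t8)
  expect_lt(abs(e$mean_abs - 0.043), 5e-4)
  expect_equal(e$max_abs, 0.2, tolerance = 1e-12)
  expect_equal(ptim_error(t8, t12), e)
  expect_equal(unlist(ptim_error(t8, t8)), c(mean_abs = 0, max_abs = 0))
  shifted <- ptim(pmin(t8$sensitivity * 0 + 0.25 + t8$sensitivity * 0, 1),
                  panel_targets(t8))
  base <- ptim(rep(0.05, 64), panel_targets(t8))
  e2 <- ptim_error(shifted, base)
  expect_equal(e2$mean_abs, 0.2)
  expect_equal(e2$max_abs, 0.2)
})

test_that("level recovery on planted synthetic maps", {
  withr::local_seed(31)
  for (rep in 1:4) {
    x <- random_ptim(levels = c(0.5, 0.8, 1), noise = 0.01)
    dec <- sensitivity_levels(x, epsilon = 0.05)
    expect_equal(nrow(dec), 3L)
    expect_lt(max(abs(dec$value - c(0.5, 0.8, 1))), 0.011)
    expect_lt(max(abs(dec$weight - c(0.5, 0.3, 0.2))), 0.025)
  }
})
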