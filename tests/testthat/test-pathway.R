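test_that("cut function follows the survival-path semantics", {
  p <- load_fixture("figure2a_pathway") # (K1 || K2) -> K3
  expect_equal(cut_function(p, "K3"), 1L)
  expect_equal(cut_function(p, "K1"), 0L)
  expect_equal(cut_function(p, c("K1", "K2")), 1L)
  expect_equal(cut_function(p, c("K1", "K2", "K3")), 1L)
  expect_error(cut_function(p, "XX"), "unknown")
})

test_that("cut function agrees with a direct path-search oracle", {
  for (seed in 1:6) {
    p <- random_pathway(seed = seed, max_targets = 7L)
    targets <- panel_targets(p)
    for (i in 0:(2^length(targets) - 1L)) {
      sub <- decode_subset(i, targets)
      expect_equal(cut_function(p, sub), oracle_cut(p$blocks, sub))
    }
  }
})

test_that("structure inference recovers the toy parallel-serial circuit", {
  cand <- infer_structures(load_fixture("figure1_tim"))
  expect_length(cand, 1L)
  shapes <- lapply(cand[[1]]$blocks, lengths)
  expect_setequal(vapply(shapes, paste, character(1), collapse = ","),
                  c("1,1", "1"))
  expect_same_map(pathway_tim(cand[[1]]), load_fixture("figure1_tim"))
})

test_that("structure inference factors the kinase screen maps", {
  c10 <- infer_structures(load_fixture("table10"))[[1]]
  labels <- vapply(c10$blocks, function(b) {
    paste(sort(vapply(b, paste, character(1), collapse = ".")), collapse = "|")
  }, character(1))
  expect_setequal(labels, c("PSMB5", "IGF1R", "HDAC1", "AKT2|TGFBR2.EGFR"))
  expect_equal(c10$off_circuit, character(0))

  c9 <- infer_structures(load_fixture("table9"))[[1]]
  expect_length(c9$blocks, 5L) # five serial singleton blocks
  expect_true(all(lengths(c9$blocks) == 1L))
  expect_equal(c9$off_circuit, "EGFR")
})

test_that("a TIM blocked by every single target yields singleton serial blocks", {
  targets <- paste0("T", 1:4)
  tm <- blocking_closure(as.list(targets), targets)
  cand <- infer_structures(tm)[[1]]
  expect_length(cand$blocks, 4L)
  expect_true(all(lengths(cand$blocks) == 1L))
})

test_that("non-series-parallel monotone TIMs are reported as unrepresentable", {
  # 2-of-3 majority: not read-once
  maj <- blocking_closure(list(c("K1", "K2"), c("K1", "K3"), c("K2", "K3")),
                          c("K1", "K2", "K3"))
  out <- infer_structures(maj)
  expect_length(out, 0L)
  expect_length(attr(out, "uncovered"), 3L)
})

test_that("inference inverts the cut function of random pathways", {
  for (seed in 1:8) {
    p <- random_pathway(seed = seed, max_targets = 8L)
    tm <- pathway_tim(p)
    cand <- infer_structures(tm)
    expect_gte(length(cand), 1L)
    expect_same_map(pathway_tim(cand[[1]], panel_targets(tm)), tm)
    # same multiset of block shapes up to the serial-line/serial-blocks
    # canonical form: total target count is preserved
    expect_equal(n_structure_targets(cand[[1]]$structure) +
                   length(cand[[1]]$off_circuit),
                 length(panel_targets(tm)))
  }
})

test_that("orientation counts follow L! prod b! and match enumeration", {
  expect_equal(count_models(load_fixture("figure4_structure")),
               factorial(6) * factorial(3)) # 4320
  expect_equal(count_models(block_structure(list(1))), 1)
  expect_equal(count_models(block_structure(list(1, 1))), 2)

  fig1 <- infer_structures(load_fixture("figure1_tim"))[[1]]
  ors <- enumerate_orientations(fig1, mutations = c("K1", "K2"))
  expect_length(ors, 2L) # the two printed orientations
  for (o in ors) expect_same_map(pathway_tim(o, panel_targets(o)),
                                 load_fixture("figure1_tim"))

  for (seed in 1:4) {
    p <- random_pathway(seed = seed, n_blocks = c(1, 3), n_lines = c(1, 2),
                        line_length = c(1, 2), max_targets = 5L)
    cand <- infer_structures(pathway_tim(p))[[1]]
    expect_length(enumerate_orientations(cand), count_models(cand))
  }
})

test_that("an infeasible mutation set yields no orientations", {
  fig1 <- infer_structures(load_fixture("figure1_tim"))[[1]]
  expect_length(enumerate_orientations(fig1, mutations = "K1"), 0L)
})

test_that("pathway JSON round-trips", {
  p <- load_fixture("figure2a_pathway")
  f <- withr::local_tempfile(fileext = ".json")
  write_pathway(p, f)
  q <- read_pathway(f)
  expect_equal(q$blocks, p$blocks)
  expect_equal(q$mutations, p$mutations)
  expect_equal(panel_targets(q), panel_targets(p))
})
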