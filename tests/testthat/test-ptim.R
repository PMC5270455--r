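test_that("gray_order reproduces the reflected-binary sequence", {
  g1 <- gray_order(1)
  expect_equal(as.vector(g1), c(0L, 1L))
  g2 <- gray_order(2)
  expect_equal(apply(g2, 1, paste, collapse = ""), c("00", "01", "11", "10"))
  g3 <- gray_order(3)
  expect_equal(apply(g3, 1, paste, collapse = ""),
               c("000", "001", "011", "010", "110", "111", "101", "100"))
  expect_error(gray_order(-1), "non-negative")
})

test_that("gray sequences start at zero, are distinct and unit-Hamming", {
  for (k in 1:6) {
    g <- gray_order(k)
    expect_equal(nrow(g), 2^k)
    expect_equal(g[1, ], rep(0L, k))
    expect_equal(anyDuplicated(attr(g, "index")), 0L)
    d <- rowSums(abs(g[-1, , drop = FALSE] - g[-nrow(g), , drop = FALSE]))
    expect_true(all(d == 1))
  }
})

test_that("subset encoding puts target 1 in the most significant bit", {
  targets <- c("K1", "K2", "K3")
  expect_equal(encode_subset(c("K1", "K3"), targets), 5L) # p_5 convention
  expect_equal(encode_subset(character(0), targets), 0L)
  expect_equal(decode_subset(5L, targets), c("K1", "K3"))
  expect_error(encode_subset("K9", targets), "unknown")
})

test_that("embedded PTIM entries match the printed grids", {
  t2 <- load_fixture("table2")
  expect_equal(ptim_entry(t2, c("K1", "K2", "K3")), 0.9)
  expect_equal(ptim_entry(t2), 0)
  expect_equal(ptim_entry(load_fixture("table5"), "K3"), 0.65)
  # six-kinase grid: row 2 (HDAC1), column 7 (IGF1R+TGFBR2)
  t8 <- load_fixture("table8")
  expect_equal(ptim_entry(t8, c("IGF1R", "TGFBR2", "HDAC1")), 0.76)
})

test_that("ptim validates its invariants", {
  expect_error(ptim(c(0, 1.2), "K1"), "\\[0, 1\\]")
  expect_error(ptim(c(0, 1, 0), "K1"), "expected 2")
  expect_error(ptim(rep(0.5, 4), c("K1", "K1")), "unique")
  expect_error(tim(c(0, 0.5), "K1"), "0 or 1")
})

test_that("grid and flat JSON serialisation round-trip", {
  withr::local_seed(42)
  targets <- c("A", "B", "C", "D", "E")
  x <- ptim(runif(2^5), targets)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_ptim(x, csv)
  write_ptim(x, js)
  expect_equal(read_ptim(csv)$sensitivity, x$sensitivity, tolerance = 1e-12)
  expect_equal(panel_targets(read_ptim(csv)), targets)
  expect_equal(read_ptim(js)$sensitivity, x$sensitivity, tolerance = 1e-12)

  # 1 x 2 grid over a single target
  one <- ptim(c(0, 1), "K1")
  write_ptim(one, csv)
  back <- read_ptim(csv)
  expect_equal(ptim_entry(back, "K1"), 1)
  expect_equal(ptim_entry(back), 0)
})

test_that("grid layout splits the panel with columns first", {
  m <- ptim_to_grid(load_fixture("table2"))
  expect_equal(colnames(m), c("", "K2", "K1+K2", "K1"))
  expect_equal(rownames(m), c("", "K3"))
  expect_equal(m["K3", "K1+K2"], 0.9)
})

test_that("binarize uses >= alpha and reproduces the printed thresholded maps", {
  t8 <- load_fixture("table8")
  expect_same_map(binarize(t8, 0.3), load_fixture("table9"))
  expect_same_map(binarize(t8, 0.55), load_fixture("table10"))
  expect_same_map(binarize(t8, 0.8), load_fixture("table11"))
  # boundary: the 0.55 cell maps to 1 at alpha = 0.55
  expect_equal(ptim_entry(binarize(t8, 0.55), "HDAC1"), 1L)
})

test_that("binarize is antitone in alpha and all-ones in the alpha -> 0 limit", {
  withr::local_seed(7)
  x <- ptim(runif(16), paste0("T", 1:4))
  alphas <- sort(runif(5, 0.05, 0.95))
  for (i in seq_along(alphas)[-1]) {
    hi <- binarize(x, alphas[i])$blocked
    lo <- binarize(x, alphas[i - 1])$blocked
    expect_true(all(hi <= lo))
  }
  tiny <- binarize(x, 1e-12)
  expect_equal(tiny$blocked, as.integer(x$sensitivity > 0))
})
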