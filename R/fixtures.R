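# Embedded worked-example datasets: a three-target toy panel (K1, K2, K3)
# and a six-kinase canine osteosarcoma screen panel (IGF1R, PSMB5, TGFBR2,
# AKT2, EGFR, HDAC1). Grids are stored row-major in the Gray-coded layout
# (columns = first half of the panel) and converted through grid_to_map(),
# so every fixture passes the same validators as user input.

fixture_grid3 <- function(row0, row1, binary = FALSE) {
  grid_to_map(rbind(row0, row1), c("K1", "K2"), "K3", binary = binary)
}

kinase_panel <- c("IGF1R", "PSMB5", "TGFBR2", "AKT2", "EGFR", "HDAC1")

fixture_grid6 <- function(rows, binary = FALSE) {
  grid_to_map(rows, kinase_panel[1:3], kinase_panel[4:6], binary = binary)
}

table8_grid <- function() rbind(
  c(0.11, 0.38, 1, 1, 1, 1, 0.68, 0.60),
  c(0.55, 0.64, 1, 1, 1, 1, 0.76, 0.68),
  c(0.64, 0.64, 1, 1, 1, 1, 0.76, 0.76),
  c(0.17, 0.52, 1, 1, 1, 1, 0.68, 0.68),
  c(0.58, 0.64, 1, 1, 1, 1, 0.76, 0.76),
  c(0.73, 0.76, 1, 1, 1, 1, 0.88, 0.84),
  c(0.64, 0.73, 1, 1, 1, 1, 0.84, 0.76),
  c(0.47, 0.57, 1, 1, 1, 1, 0.76, 0.68))

table12_grid <- function() rbind(
  c(0.00, 0.50, 0.99, 0.99, 0.99, 1.00, 0.75, 0.75),
  c(0.75, 0.75, 1.00, 0.99, 0.99, 1.00, 0.75, 0.75),
  c(0.75, 0.75, 1.00, 0.99, 0.99, 1.00, 0.75, 0.75),
  c(0.00, 0.50, 0.99, 0.99, 0.99, 1.00, 0.75, 0.75),
  c(0.75, 0.75, 1.00, 0.99, 0.99, 1.00, 0.75, 0.75),
  c(0.75, 0.75, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00),
  c(0.75, 0.75, 1.00, 0.99, 0.99, 1.00, 1.00, 0.75),
  c(0.50, 0.75, 1.00, 0.99, 0.99, 1.00, 0.75, 0.75))

table3_chain <- function() {
  targets <- c("K1", "K2", "K3")
  P <- matrix(0, 16, 16)
  set_row <- function(from, to) {
    for (d in names(to)) P[strtoi(from, base = 2) + 1L,
                           strtoi(d, base = 2) + 1L] <<- to[[d]]
  }
  set_row("0000", c("0001" = 0.1, "0010" = 0.12, "1100" = 0.78))
  set_row("0001", c("0001" = 0.1, "1100" = 0.9))
  for (r in c("0010", "0011")) set_row(r, c("0011" = 0.2, "1101" = 0.8))
  for (r in c("0100", "0101")) set_row(r, c("0101" = 0.3, "1110" = 0.7))
  for (r in c("1000", "1001")) set_row(r, c("1001" = 0.35, "1110" = 0.65))
  for (r in c("1100", "1101")) set_row(r, c("1101" = 0.45, "1110" = 0.55))
  for (r in c("0110", "0111", "1010", "1011", "1110", "1111")) {
    set_row(r, c("1111" = 1))
  }
  markov_chain(P, targets)
}

fixture_builders <- list(
  # toy three-target examples
  figure1_tim = function() fixture_grid3(c(0, 0, 1, 0), c(1, 1, 1, 1), binary = TRUE),
  figure2a_pathway = function() pathway(
    list(list("K1", "K2"), list("K3")), mutations = c("K1", "K2")),
  figure2b_pathway = function() pathway(
    list(list("K3"), list("K1", "K2")), mutations = "K3",
    targets = c("K1", "K2", "K3")),
  table1 = function() intervention_matrix(c("K1", "K2", "K3"), c("K1", "K2")),
  table2 = function() fixture_grid3(c(0, 0, 0.8, 0), c(0.55, 0.65, 0.9, 0.7)),
  table3 = table3_chain,
  table4 = function() fixture_grid3(c(0.002003, 0.002994, 0.800463, 0.002995),
                                    c(0.549716, 0.649251, 0.89785, 0.698992)),
  table5 = function() fixture_grid3(c(0.02, 0.01, 0.98, 0.03),
                                    c(0.65, 0.89, 1, 0.9)),
  table6_bn1 = function() fixture_grid3(c(0, 0, 1, 0), c(1, 1, 1, 1), binary = TRUE),
  table6_bn2 = function() fixture_grid3(c(0, 0, 1, 0), c(0, 1, 1, 1), binary = TRUE),
  table6_bn3 = function() fixture_grid3(c(0, 0, 1, 0), c(0, 0, 1, 0), binary = TRUE),
  table7 = function() fixture_grid3(c(0.0017, 0.0029, 0.9964, 0.0029),
                                    c(0.6495, 0.8982, 0.9981, 0.8982)),
  # 13-target structure used for the experiment-design example
  figure4_structure = function() block_structure(
    list(c(1, 1, 1, 1), 1, 1, c(1, 3), 1, c(1, 1))),
  # six-kinase canine osteosarcoma screen example
  table8 = function() fixture_grid6(table8_grid()),
  table9 = function() fixture_grid6((table8_grid() >= 0.3) * 1, binary = TRUE),
  table10 = function() fixture_grid6((table8_grid() >= 0.55) * 1, binary = TRUE),
  table11 = function() fixture_grid6((table8_grid() >= 0.8) * 1, binary = TRUE),
  table12 = function() fixture_grid6(table12_grid())
)

#' Load an embedded worked-example dataset
#'
#' The package embeds the worked examples its methods are demonstrated on: a
#' three-target toy panel (PTIMs, the hand-built Markov chain and its
#' perturbed steady-state profile, the level TIM triplet), the 13-target
#' series-parallel structure used by the experiment-design bounds, and the
#' six-kinase canine osteosarcoma drug-screen PTIM with its thresholded TIMs
#' and model-generated profile.
#'
#' @param name One of the names listed by `load_fixture()` called without
#'   arguments (e.g. `"table2"`, `"figure4_structure"`, `"table8"`).
#' @return The validated object (a `ptim`, `tim`, `pathway`,
#'   `block_structure`, `markov_chain` or matrix, depending on the fixture).
#' @export
load_fixture <- function(name) {
  if (missing(name)) return(names(fixture_builders))
  if (!name %in% names(fixture_builders)) {
    abort(paste0("unknown fixture `", name, "`; available: ",
                 paste(names(fixture_builders), collapse = ", ")))
  }
  fixture_builders[[name]]()
}
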