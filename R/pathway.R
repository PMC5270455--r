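#' Series-parallel block structure
#'
#' The abstract shape of a tumor-survival circuit: `L` blocks in series, block
#' `i` containing `a_i` parallel lines, line `j` containing `b_ji` targets.
#' The tumor survives while every block still has at least one fully
#' uninhibited line.
#'
#' @param line_lengths A list with one element per block; each element an
#'   integer vector of line lengths (all `>= 1`).
#' @return An object of class `"block_structure"`.
#' @examples
#' # six serial blocks, one of them two parallel lines with lengths 1 and 3
#' block_structure(list(c(1, 1, 1, 1), 1, 1, c(1, 3), 1, c(1, 1)))
#' @export
block_structure <- function(line_lengths) {
  if (!is.list(line_lengths)) line_lengths <- as.list(line_lengths)
  if (length(line_lengths) < 1L) abort("need at least one block.")
  blocks <- lapply(line_lengths, function(b) {
    b <- as.integer(b)
    if (length(b) < 1L || any(is.na(b)) || any(b < 1L)) {
      abort("every block needs at least one line of length >= 1.")
    }
    b
  })
  structure(list(blocks = blocks), class = "block_structure")
}

#' @export
print.block_structure <- function(x, ...) {
  cat(sprintf("Series-parallel structure: L = %d blocks, %d targets\n",
              length(x$blocks), n_structure_targets(x)))
  for (i in seq_along(x$blocks)) {
    cat(sprintf("  block %d: %d line(s), lengths %s\n", i,
                length(x$blocks[[i]]), paste(x$blocks[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Total number of targets placed on a structure's survival lines
#' @param structure A [block_structure()].
#' @return Integer count.
#' @export
n_structure_targets <- function(structure) sum(unlist(structure$blocks))

#' Directional pathway over a target panel
#'
#' An oriented series-parallel circuit: ordered serial blocks, each a set of
#' parallel lines, each line an ordered (upstream to downstream) vector of
#' target names; plus the set of initially mutated / latently activated
#' targets and any off-circuit targets (present in the panel but on no
#' survival line) with their assigned upstream activators.
#'
#' @param blocks List of blocks; each block a list of character-vector lines.
#' @param mutations Nonempty character vector of mutated/latently activated
#'   targets.
#' @param off_circuit Named character vector mapping each off-circuit target
#'   to its upstream activator (may be empty).
#' @param targets Optional explicit panel order; defaults to circuit order
#'   followed by off-circuit targets.
#' @return An object of class `"pathway"`.
#' @export
pathway <- function(blocks, mutations, off_circuit = character(0), targets = NULL) {
  if (!is.list(blocks) || length(blocks) < 1L) abort("need at least one block.")
  blocks <- lapply(blocks, function(b) {
    if (!is.list(b)) b <- list(b)
    lapply(b, as.character)
  })
  circuit <- unlist(blocks)
  off <- as.character(off_circuit)
  all_t <- c(circuit, names(off_circuit))
  if (anyDuplicated(all_t)) abort("each target may appear only once in the pathway.")
  if (is.null(targets)) targets <- all_t
  validate_panel(targets)
  if (!setequal(targets, all_t)) {
    abort("`targets` must name exactly the circuit plus off-circuit targets.")
  }
  mutations <- as.character(mutations)
  if (length(mutations) < 1L) abort("`mutations` must be nonempty.")
  if (!all(mutations %in% targets)) abort("unknown target in `mutations`.")
  if (length(off) > 0L && !all(off %in% circuit)) {
    abort("off-circuit activators must be on-circuit targets.")
  }
  structure(list(blocks = blocks, mutations = mutations,
                 off_circuit = off_circuit),
            targets = targets, class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  fmt_line <- function(l) paste(l, collapse = " > ")
  chain <- vapply(x$blocks, function(b) {
    paste0("[", paste(vapply(b, fmt_line, character(1)), collapse = " || "), "]")
  }, character(1))
  cat("Directional pathway:", paste(chain, collapse = " -> "), "\n")
  cat("  mutations:", paste(x$mutations, collapse = ", "), "\n")
  if (length(x$off_circuit)) {
    cat("  off-circuit:", paste(sprintf("%s (from %s)", names(x$off_circuit),
                                        x$off_circuit), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Abstract block structure of a directional pathway
#' @param p A [pathway()].
#' @return The underlying [block_structure()] (orientation forgotten).
#' @export
pathway_structure <- function(p) {
  block_structure(lapply(p$blocks, function(b) lengths(b)))
}

#' Evaluate the cut function of a pathway on an inhibition subset
#'
#' The tumor is blocked (cut function 1) iff some block is fully cut: every
#' line of that block contains at least one inhibited target. Off-circuit
#' targets never affect the result.
#'
#' @param p A [pathway()], or a candidate structure returned by
#'   [infer_structures()].
#' @param subset Character vector of inhibited targets.
#' @return 0 or 1.
#' @export
cut_function <- function(p, subset) {
  blocks <- p$blocks
  targets <- panel_targets(p)
  if (is.null(targets)) targets <- unique(c(unlist(blocks), names(p$off_circuit)))
  if (!all(subset %in% targets)) {
    abort(paste0("unknown target(s): ",
                 paste(setdiff(subset, targets), collapse = ", ")))
  }
  for (b in blocks) {
    lines <- if (is.list(b)) b else list(b)
    if (all(vapply(lines, function(l) any(l %in% subset), logical(1)))) return(1L)
  }
  0L
}

#' TIM induced by a pathway's cut function
#'
#' @param p A [pathway()] or [infer_structures()] candidate.
#' @param targets Panel to evaluate over; defaults to the pathway's panel.
#' @return A [tim()].
#' @export
pathway_tim <- function(p, targets = NULL) {
  own <- panel_targets(p)
  if (is.null(own)) own <- unique(c(unlist(p$blocks), names(p$off_circuit)))
  if (is.null(targets)) targets <- own
  n <- length(targets)
  bits <- vapply(0:(2^n - 1L), function(i) {
    # targets outside the pathway's own panel behave as off-circuit
    cut_function(p, intersect(decode_subset(i, targets), own))
  }, integer(1))
  tim(bits, targets)
}

# -- structure inference ------------------------------------------------------

# x, y interchangeable (same serial line): never co-occur in a minimal
# blocking set, and swapping one for the other maps the antichain onto itself.
same_line <- function(x, y, sets) {
  for (s in sets) if (x %in% s && y %in% s) return(FALSE)
  key <- vapply(sets, function(s) paste(sort(s), collapse = "\r"), character(1))
  for (s in sets) {
    if (x %in% s) {
      sw <- paste(sort(c(setdiff(s, x), y)), collapse = "\r")
      if (!sw %in% key) return(FALSE)
    }
    if (y %in% s) {
      sw <- paste(sort(c(setdiff(s, y), x)), collapse = "\r")
      if (!sw %in% key) return(FALSE)
    }
  }
  TRUE
}

#' Infer series-parallel structures consistent with a TIM
#'
#' Factors the minimal blocking sets of a monotone TIM into serial blocks of
#' parallel lines: targets that never co-occur in a minimal blocking set and
#' are swap-interchangeable share a line; minimal sets touching the same set
#' of lines form a block, whose family must be the full one-per-line product.
#' Blocks consisting of a single line are canonically split into serial
#' singleton blocks (an equivalent representation of the same cut function).
#' Every candidate is verified against the TIM on all `2^n` subsets before it
#' is returned. Targets belonging to no minimal blocking set are reported as
#' off-circuit.
#'
#' @param x A monotone [tim()] with at least one blocking set.
#' @return A list of candidates (a single canonical candidate when the TIM is
#'   series-parallel), each a list with elements `blocks` (list of blocks,
#'   each a list of unordered character-vector lines), `structure`
#'   (a [block_structure()]), `off_circuit` (character vector) and `targets`.
#'   An empty list (with attribute `"uncovered"` diagnosing the minimal sets
#'   that no series-parallel candidate reproduces) when no exact
#'   representation exists.
#' @export
infer_structures <- function(x) {
  stopifnot(inherits(x, "tim"))
  targets <- panel_targets(x)
  sets <- minimal_blocking_sets(x)
  if (length(sets) == 0L) abort("TIM has no blocking set; nothing to infer.")
  fail <- function() structure(list(), uncovered = sets)
  u <- unique(unlist(sets))

  # union-find over the interchangeability relation
  parent <- seq_along(u)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(u)) for (j in seq_len(i - 1L)) {
    if (same_line(u[i], u[j], sets)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  line_id <- vapply(seq_along(u), find, integer(1))
  lines <- split(u, line_id)

  line_of <- setNames(rep(seq_along(lines), lengths(lines)), unlist(lines))
  sigs <- vapply(sets, function(s) {
    ids <- sort(unique(line_of[s]))
    if (length(ids) != length(s)) return(NA_character_) # touches a line twice
    paste(ids, collapse = ",")
  }, character(1))
  if (anyNA(sigs)) return(fail())

  blocks <- list()
  used_lines <- integer(0)
  for (sg in unique(sigs)) {
    ids <- as.integer(strsplit(sg, ",")[[1]])
    if (any(ids %in% used_lines)) return(fail())
    used_lines <- c(used_lines, ids)
    fam <- sets[sigs == sg]
    if (length(fam) != prod(lengths(lines)[ids])) return(fail())
    blocks[[length(blocks) + 1L]] <- unname(lines[ids])
  }

  # canonical form: a single-line block is the same cut function as serial
  # singleton blocks; split it
  canon <- list()
  for (b in blocks) {
    if (length(b) == 1L) {
      for (t in b[[1]]) canon[[length(canon) + 1L]] <- list(t)
    } else {
      canon[[length(canon) + 1L]] <- b
    }
  }

  cand <- structure(
    list(blocks = canon,
         structure = block_structure(lapply(canon, lengths)),
         off_circuit = setdiff(targets, u)),
    targets = targets, class = "tim_structure")
  if (!identical(map_values(pathway_tim(cand, targets)), map_values(x))) {
    return(fail())
  }
  list(cand)
}

#' @export
print.tim_structure <- function(x, ...) {
  chain <- vapply(x$blocks, function(b) {
    paste0("[", paste(vapply(b, paste, character(1), collapse = "."),
                      collapse = " || "), "]")
  }, character(1))
  cat("Inferred structure:", paste(chain, collapse = " - "), "\n")
  if (length(x$off_circuit)) {
    cat("  off-circuit:", paste(x$off_circuit, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of distinct directional models of a structure
#'
#' Block order and the within-line target order are the directional degrees
#' of freedom, giving `L! * prod over lines of b!` distinct discrete dynamic
#' models.
#'
#' @param structure A [block_structure()], [pathway()] or
#'   [infer_structures()] candidate.
#' @return An exact integer (as double for large counts).
#' @export
count_models <- function(structure) {
  blocks <- structure_blocks(structure)
  factorial(length(blocks)) * prod(factorial(unlist(blocks)))
}

structure_blocks <- function(structure) {
  if (inherits(structure, "block_structure")) return(structure$blocks)
  if (inherits(structure, "pathway") || inherits(structure, "tim_structure")) {
    return(lapply(structure$blocks, lengths))
  }
  abort("cannot interpret `structure`.")
}

permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' Enumerate directional pathways of an inferred structure
#'
#' Yields every orientation — each permutation of the serial blocks crossed
#' with each within-line target ordering — as a [pathway()] with the given
#' mutation set. The number of results equals [count_models()]. Off-circuit
#' targets are wired to a line-end target of the last block (a documented
#' default; off-circuit wiring never affects TIM-level behavior).
#'
#' @param candidate An [infer_structures()] candidate (or a [pathway()] whose
#'   orientation degrees of freedom are to be re-enumerated).
#' @param mutations Mutation set `M` to attach to each pathway; defaults to
#'   the targets of whichever block comes first in each orientation. An `M`
#'   that is not a blocking set of the structure is infeasible: an empty list
#'   is returned.
#' @return List of [pathway()] objects.
#' @export
enumerate_orientations <- function(candidate, mutations = NULL) {
  blocks <- candidate$blocks
  if (inherits(candidate, "pathway")) {
    blocks <- lapply(blocks, function(b) lapply(b, identity))
  }
  targets <- panel_targets(candidate)
  off <- if (inherits(candidate, "pathway")) names(candidate$off_circuit) else candidate$off_circuit
  if (!is.null(mutations) &&
      cut_function(list(blocks = blocks, off_circuit = NULL), mutations) == 0L) {
    return(list())
  }
  # per-block: list of line-permutation combinations
  block_variants <- lapply(blocks, function(b) {
    per_line <- lapply(b, permutations)
    grid <- expand_index_grid(lengths(per_line))
    lapply(grid, function(ix) {
      lapply(seq_along(b), function(j) per_line[[j]][[ix[j]]])
    })
  })
  out <- list()
  for (ord in permutations(seq_along(blocks))) {
    grid <- expand_index_grid(lengths(block_variants)[ord])
    for (ix in grid) {
      bl <- lapply(seq_along(ord), function(k) block_variants[[ord[k]]][[ix[k]]])
      m <- if (is.null(mutations)) vapply(bl[[1]], `[[`, character(1), 1L) else mutations
      last_end <- bl[[length(bl)]][[1]]
      oc <- setNames(rep(last_end[length(last_end)], length(off)), off)
      out[[length(out) + 1L]] <- pathway(bl, m, oc, targets = targets)
    }
  }
  out
}

expand_index_grid <- function(sizes) {
  if (length(sizes) == 0L) return(list(integer(0)))
  grid <- list(integer(0))
  for (s in sizes) {
    grid <- unlist(lapply(grid, function(g) lapply(seq_len(s), function(i) c(g, i))),
                   recursive = FALSE)
  }
  grid
}

#' Read or write a directional pathway as JSON
#'
#' The JSON form is
#' `{"blocks": [[["K1"],["K2"]], [["K3"]]], "mutations": [...],
#' "off_circuit": {"E1": "K3"}, "targets": [...]}` — blocks are lists of
#' lines, each line an ordered list of target names.
#'
#' @param p A [pathway()].
#' @param path File path.
#' @return `read_pathway()` returns a [pathway()]; `write_pathway()` returns
#'   `path` invisibly.
#' @export
write_pathway <- function(p, path) {
  stopifnot(inherits(p, "pathway"))
  oc <- as.list(p$off_circuit)
  jsonlite::write_json(
    list(blocks = p$blocks, mutations = p$mutations,
         off_circuit = if (length(oc)) oc else setNames(list(), character(0)),
         targets = panel_targets(p)),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_pathway
#' @export
read_pathway <- function(path) {
  x <- jsonlite::read_json(path)
  blocks <- lapply(x$blocks, function(b) lapply(b, function(l) unlist(l)))
  oc <- unlist(x$off_circuit)
  if (is.null(oc)) oc <- character(0)
  pathway(blocks, mutations = unlist(x$mutations), off_circuit = oc,
          targets = unlist(x$targets))
}

#' Default orientation of an inferred structure
#'
#' Convenience wrapper returning one concrete [pathway()]: blocks in inferred
#' order, lines in listed order, mutations defaulting to the first block.
#'
#' @inheritParams enumerate_orientations
#' @return A [pathway()].
#' @export
default_pathway <- function(candidate, mutations = NULL) {
  blocks <- candidate$blocks
  targets <- panel_targets(candidate)
  if (is.null(mutations)) {
    mutations <- vapply(blocks[[1]], function(l) l[[1]], character(1))
  }
  last_block <- blocks[[length(blocks)]]
  last_end <- last_block[[1]][length(last_block[[1]])]
  off <- candidate$off_circuit
  oc <- setNames(rep(last_end, length(off)), off)
  pathway(blocks, mutations, oc, targets = targets)
}
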