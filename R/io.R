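# Grid layout: the panel is split into column targets (the first ceiling(n/2)
# names, most significant bits) and row targets (the rest); both axes are
# ordered by the reflected Gray sequence over their bits, so neighbouring
# rows/columns differ by a single inhibition.

grid_split <- function(targets) {
  n <- length(targets)
  k_col <- ceiling(n / 2)
  list(col = targets[seq_len(k_col)],
       row = if (k_col < n) targets[(k_col + 1L):n] else character(0))
}

gray_labels <- function(group_targets) {
  k <- length(group_targets)
  g <- gray_order(k)
  vapply(seq_len(nrow(g)), function(r) {
    paste(group_targets[g[r, ] == 1L], collapse = "+")
  }, character(1))
}

#' Lay a PTIM/TIM out as a Gray-coded grid matrix
#'
#' @param x A `ptim` or `tim`.
#' @return A numeric matrix with Gray-coded row/column labels (target names
#'   joined by `"+"`, empty label = no inhibition); cell `(r, c)` holds the
#'   value for the union of the row and column subsets.
#' @export
ptim_to_grid <- function(x) {
  targets <- panel_targets(x)
  sp <- grid_split(targets)
  vals <- map_values(x)
  gc <- attr(gray_order(length(sp$col)), "index")
  gr <- attr(gray_order(length(sp$row)), "index")
  n_row_bits <- length(sp$row)
  m <- matrix(0, nrow = length(gr), ncol = length(gc),
              dimnames = list(gray_labels(sp$row), gray_labels(sp$col)))
  for (r in seq_along(gr)) for (cc in seq_along(gc)) {
    m[r, cc] <- vals[bitwOr(bitwShiftL(gc[cc], n_row_bits), gr[r]) + 1L]
  }
  m
}

grid_to_map <- function(m, col_targets, row_targets, binary = FALSE) {
  targets <- c(col_targets, row_targets)
  validate_panel(targets)
  n <- length(targets)
  if (nrow(m) != 2^length(row_targets) || ncol(m) != 2^length(col_targets)) {
    abort("grid dimensions must be 2^|row targets| by 2^|column targets|.")
  }
  gc <- attr(gray_order(length(col_targets)), "index")
  gr <- attr(gray_order(length(row_targets)), "index")
  vals <- numeric(2^n)
  for (r in seq_along(gr)) for (cc in seq_along(gc)) {
    vals[bitwOr(bitwShiftL(gc[cc], length(row_targets)), gr[r]) + 1L] <- m[r, cc]
  }
  if (binary) tim(vals, targets) else ptim(vals, targets)
}

parse_group_labels <- function(labels) {
  k <- round(log2(length(labels)))
  if (2^k != length(labels)) abort("grid axis length must be a power of two.")
  if (k == 0L) return(character(0))
  sets <- lapply(labels, function(l) {
    if (!nzchar(l)) character(0) else strsplit(l, "+", fixed = TRUE)[[1]]
  })
  nms <- unique(unlist(sets))
  if (length(nms) != k) {
    abort(sprintf("grid axis labels name %d targets but encode %d bits.",
                  length(nms), k))
  }
  g <- gray_order(k)
  # recover panel order: bit b's membership pattern across the Gray sequence
  ord <- character(k)
  for (b in seq_len(k)) {
    pat <- g[, b] == 1L
    hit <- nms[vapply(nms, function(nm) {
      identical(vapply(sets, function(s) nm %in% s, logical(1)), pat)
    }, logical(1))]
    if (length(hit) != 1L) abort("grid axis labels do not follow a Gray sequence.")
    ord[b] <- hit
  }
  ord
}

#' Read a PTIM from a grid CSV or flat JSON file
#'
#' The grid CSV carries Gray-coded inhibition labels in its header row and
#' first column (target names joined by `"+"`, empty label = no inhibition)
#' and decimal sensitivities in its cells. The flat JSON form is
#' `{"targets": [...], "values": {"K1+K3": 0.7, "": 0, ...}}` and is
#' layout-free.
#'
#' @param path File path; `.json` is read as flat JSON, anything else as a
#'   grid CSV.
#' @return A [ptim()].
#' @seealso [write_ptim()]
#' @export
read_ptim <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path)
    return(ptim(lapply(x$values, as.numeric), unlist(x$targets)))
  }
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  row_labels <- raw[[1]]
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  if (anyNA(m)) abort("grid contains non-numeric cells.")
  col_targets <- parse_group_labels(colnames(m))
  row_targets <- parse_group_labels(row_labels)
  grid_to_map(m, col_targets, row_targets)
}

#' Write a PTIM to a grid CSV or flat JSON file
#'
#' @param x A `ptim` or `tim`.
#' @param path Output path; `.json` selects the flat JSON form, anything else
#'   the Gray-coded grid CSV.
#' @return `path`, invisibly. `read_ptim(write_ptim(x, path))` restores `x`.
#' @export
write_ptim <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    # written by hand: jsonlite cannot emit the empty-string key that the
    # no-inhibition subset uses
    vals <- map_values(x)
    labels <- vapply(0:(length(vals) - 1L), subset_label, character(1),
                     targets = panel_targets(x))
    pairs <- paste0('"', labels, '": ', sprintf("%.17g", vals),
                    collapse = ", ")
    txt <- paste0('{"targets": ',
                  jsonlite::toJSON(panel_targets(x)),
                  ', "values": {', pairs, "}}")
    writeLines(txt, path)
  } else {
    m <- ptim_to_grid(x)
    df <- data.frame(rownames(m), m, check.names = FALSE)
    colnames(df) <- c("", colnames(m))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Plot a PTIM/TIM as a Gray-coded heat map
#'
#' @param object A `ptim` or `tim`.
#' @param ... Unused.
#' @return A ggplot object laying the map out exactly as its grid form.
#' @export
autoplot.ptim <- function(object, ...) {
  m <- ptim_to_grid(object)
  df <- tidyr::expand_grid(row = rownames(m), col = colnames(m))
  df$row <- factor(df$row, levels = rev(rownames(m)))
  df$col <- factor(df$col, levels = colnames(m))
  df$value <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sub("^0\\.", ".", sprintf("%.2g", .data$value))),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "sensitivity") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ptim
#' @export
autoplot.tim <- function(object, ...) {
  p <- ptim(map_values(object), panel_targets(object))
  autoplot(p) + ggplot2::labs(fill = "blocked")
}
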