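#' @title SVG rendering of the similarity matrix and tagged tree
#' @name viz
#' @description Renders the similarity matrix as a colour-coded heatmap
#'   (dark blue = strong non-random similarity, white = neutral, red =
#'   random similarity) and the tagged tree with suspicious branches
#'   stroked red. Output is plain SVG text, parseable by any XML reader.
NULL

PALETTE_ANCHORS <- list(neg = c(255, 0, 0),      # score -1: red
                        mid = c(255, 255, 255),  # score  0: white
                        pos = c(0, 0, 139))      # score +1: dark blue
MISSING_COLOR <- "#BEBEBE"

#' Map similarity scores to colours
#'
#' Linear interpolation per RGB channel between the anchors
#' `-1 -> red`, `0 -> white`, `+1 -> dark blue`. Defined on `[-1, 1]`;
#' `NA` maps to grey.
#'
#' @param s Numeric vector of scores in `[-1, 1]`.
#' @param anchors Optional list with `neg`, `mid`, `pos` RGB triplets
#'   (0-255) replacing the default palette.
#' @return Character vector of `#RRGGBB` colours.
#' @export
score_color <- function(s, anchors = PALETTE_ANCHORS) {
  if (any(!is.na(s) & (s < -1 - 1e-9 | s > 1 + 1e-9)))
    abort_input("scores must lie in [-1, 1]")
  s <- pmin(pmax(s, -1), 1)
  out <- character(length(s))
  for (i in seq_along(s)) {
    if (is.na(s[i])) { out[i] <- MISSING_COLOR; next }
    rgb3 <- if (s[i] >= 0) {
      anchors$mid + s[i] * (anchors$pos - anchors$mid)
    } else {
      anchors$mid + (-s[i]) * (anchors$neg - anchors$mid)
    }
    out[i] <- sprintf("#%02X%02X%02X", round(rgb3[1]), round(rgb3[2]),
                      round(rgb3[3]))
  }
  out
}

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

svg_doc <- function(body, width, height) {
  c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'),
            round(width), round(height), round(width), round(height)),
    body, "</svg>")
}

legend_svg <- function(x, y, width = 120, height = 12) {
  n <- 60
  stops <- seq(-1, 1, length.out = n)
  cols <- score_color(stops)
  cw <- width / n
  cells <- sprintf('<rect x="%.2f" y="%.2f" width="%.2f" height="%d" fill="%s"/>',
                   x + (seq_len(n) - 1) * cw, y, cw + 0.05, height, cols)
  labs <- sprintf('<text x="%.2f" y="%.2f" font-size="9" text-anchor="middle">%s</text>',
                  x + c(0, width / 2, width), y + height + 10,
                  c("-1", "0", "+1"))
  c(cells, labs)
}

#' Render the similarity matrix as an SVG heatmap
#'
#' An `N x N` grid of coloured cells with taxon labels on both axes,
#' missing entries grey, and a colour-bar legend spanning `[-1, 1]`.
#'
#' @param sm A [similarity_matrix()].
#' @param path Output SVG path.
#' @param order Optional taxon ordering: character vector of labels, or a
#'   `phylo` tree whose leaf order is used. Default: matrix input order.
#' @param cell Cell size in pixels.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(sm, path, order = NULL, cell = 14) {
  taxa <- sm$taxa
  if (inherits(order, "phylo")) order <- order$tip.label
  if (!is.null(order)) {
    if (!setequal(order, taxa))
      abort_input("ordering must be a permutation of the matrix taxa")
    taxa <- order
  }
  idx <- match(taxa, sm$taxa)
  V <- sm$values[idx, idx, drop = FALSE]
  n <- length(taxa)
  lab_w <- max(nchar(taxa)) * 7 + 10
  x0 <- lab_w; y0 <- lab_w
  body <- character(0)
  for (i in seq_len(n)) {
    cols <- score_color(V[i, ])
    body <- c(body, sprintf(
      '<rect x="%.1f" y="%.1f" width="%d" height="%d" fill="%s"/>',
      x0 + (seq_len(n) - 1) * cell, y0 + (i - 1) * cell, cell, cell, cols))
  }
  body <- c(body,
    sprintf('<text x="%.1f" y="%.1f" font-size="10" text-anchor="end">%s</text>',
            x0 - 4, y0 + (seq_len(n) - 0.3) * cell, svg_escape(taxa)),
    sprintf(paste0('<text x="%.1f" y="%.1f" font-size="10" text-anchor="end" ',
                   'transform="rotate(90 %.1f %.1f)">%s</text>'),
            x0 + (seq_len(n) - 0.3) * cell, y0 - 4,
            x0 + (seq_len(n) - 0.3) * cell, y0 - 4, svg_escape(taxa)))
  leg_y <- y0 + n * cell + 16
  body <- c(body, legend_svg(x0, leg_y))
  doc <- svg_doc(body, x0 + n * cell + 20, leg_y + 40)
  writeLines(doc, path)
  invisible(path)
}

# rectangular layout coordinates for a phylo tree
tree_layout <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  root <- n + 1L
  el <- tree$edge.length
  if (is.null(el) || any(is.na(el))) el <- rep(1, nrow(tree$edge))
  xpos <- rep(0, nn)
  pre <- ape::reorder.phylo(tree, "cladewise")
  o <- match(paste(pre$edge[, 1], pre$edge[, 2]),
             paste(tree$edge[, 1], tree$edge[, 2]))
  for (r in seq_len(nrow(pre$edge))) {
    p <- pre$edge[r, 1L]; ch <- pre$edge[r, 2L]
    xpos[ch] <- xpos[p] + el[o[r]]
  }
  # leaves at ranks 1..n; internal y = midpoint of child span (recursive)
  ypos <- rep(NA_real_, nn)
  ypos[seq_len(n)] <- seq_len(n)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  child_y <- function(node) {
    ch <- kids[[as.character(node)]]
    ys <- vapply(ch, function(c2) if (is.na(ypos[c2])) child_y(c2) else ypos[c2],
                 numeric(1))
    ypos[node] <<- mean(range(ys))
    ypos[node]
  }
  child_y(root)
  list(x = xpos, y = ypos)
}

#' Render a tagged tree as SVG
#'
#' Rectangular layout; suspicious branches stroked red, others black; the
#' branch score printed at each branch to 2 decimals. Polytomies are
#' drawn as multifurcations with each child edge coloured independently.
#'
#' @param tagged A [tag_tree()] result.
#' @param path Output SVG path.
#' @param width,height Canvas size in pixels (height defaults to scale
#'   with the number of leaves).
#' @return `path`, invisibly.
#' @export
render_tagged_tree <- function(tagged, path, width = 640, height = NULL) {
  tree <- tagged$tree
  n <- length(tree$tip.label)
  if (is.null(height)) height <- 40 + n * 22
  lay <- tree_layout(tree)
  lab_w <- max(nchar(tree$tip.label)) * 7 + 16
  plot_w <- width - lab_w - 20
  xs <- 10 + lay$x / max(lay$x, 1e-9) * plot_w
  ys <- 20 + (lay$y - 1) / max(1, n - 1) * (height - 60)
  body <- character(0)
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1L]; ch <- tree$edge[r, 2L]
    col <- if (isTRUE(tagged$edge_suspicious[r])) "#FF0000" else "#000000"
    body <- c(body,
      sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="%s" stroke-width="1.5"/>',
              xs[p], ys[p], xs[p], ys[ch], col),
      sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="%s" stroke-width="1.5"/>',
              xs[p], ys[ch], xs[ch], ys[ch], col))
    if (!is.na(tagged$edge_scores[r]))
      body <- c(body, sprintf(
        '<text x="%.1f" y="%.1f" font-size="9" fill="%s" text-anchor="middle">%.2f</text>',
        (xs[p] + xs[ch]) / 2, ys[ch] - 3, col, tagged$edge_scores[r]))
  }
  body <- c(body, sprintf(
    '<text x="%.1f" y="%.1f" font-size="11">%s</text>',
    xs[seq_len(n)] + 5, ys[seq_len(n)] + 4, svg_escape(tree$tip.label)))
  writeLines(svg_doc(body, width, height), path)
  invisible(path)
}
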