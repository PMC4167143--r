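#' @title Branch tagging on a guide tree
#' @name treetag
#' @description Projects the pairwise similarity matrix onto a user tree.
#'   Terminal branches are tagged with the mean similarity between the
#'   leaf and all other taxa; internal branches with the mean similarity
#'   over all pairs crossing the branch's bipartition. Branches with a
#'   negative mean are flagged suspicious: their split is supported by
#'   sequence similarity indistinguishable from random, however high the
#'   bootstrap value may be.
NULL

#' Read a newick tree
#'
#' Thin wrapper over [ape::read.tree()] that keeps branch lengths and
#' internal labels for pass-through and raises a classed input error on
#' malformed files.
#'
#' @param path Path to a newick file (or a literal newick string via
#'   `text`).
#' @param text Optional newick string instead of a file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text) && !file.exists(path))
    abort_input("file not found: %s", path)
  tree <- tryCatch(
    suppressWarnings(
      if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)),
    error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    abort_input("malformed newick input")
  if (anyDuplicated(tree$tip.label))
    abort_input("duplicate leaf labels in tree")
  tree
}

# leaf index set below each edge (aligned with tree$edge rows)
edge_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  node_sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) node_sets[[i]] <- i
  for (r in seq_len(nrow(po$edge))) {
    p <- po$edge[r, 1L]; ch <- po$edge[r, 2L]
    node_sets[[p]] <- c(node_sets[[p]], node_sets[[ch]])
  }
  lapply(tree$edge[, 2L], function(ch) sort(node_sets[[ch]]))
}

#' Enumerate non-trivial bipartitions of a tree
#'
#' Each internal edge of the unrooted topology induces one split; the two
#' edges incident to the root of a rooted input induce the same split and
#' are deduplicated. Polytomies are supported.
#'
#' @param tree A `phylo`.
#' @return A list of bipartitions, each a list with `sideA` and `sideB`
#'   character vectors (disjoint; union = all leaves). For a fully
#'   bifurcating unrooted tree of `N` leaves the list has `N - 3`
#'   elements.
#' @export
bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  sets <- edge_tip_sets(tree)
  out <- list(); seen <- character(0)
  for (s in sets) {
    if (length(s) < 2L || length(s) > n - 2L) next
    canon <- if (1L %in% s) setdiff(seq_len(n), s) else s
    key <- paste(canon, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(sideA = tree$tip.label[canon],
                                    sideB = tree$tip.label[setdiff(seq_len(n), canon)])
  }
  out
}

check_matrix_arg <- function(matrix) {
  if (inherits(matrix, "similarity_matrix")) return(matrix)
  if (is.matrix(matrix) && !is.null(rownames(matrix)))
    return(structure(list(taxa = rownames(matrix), values = matrix,
                          n_pairs = NA), class = "similarity_matrix"))
  abort_input("expected a similarity_matrix or a labelled square matrix")
}

#' Terminal branch score
#'
#' Mean pairwise similarity between a terminal taxon and all other taxa;
#' missing entries are excluded from both sum and count.
#'
#' @param matrix A [similarity_matrix()] (or labelled square matrix).
#' @param taxon Leaf label.
#' @return The mean, a number in `[-1, 1]`.
#' @export
terminal_score <- function(matrix, taxon) {
  sm <- check_matrix_arg(matrix)
  i <- match(taxon, sm$taxa)
  if (is.na(i)) abort_input("taxon '%s' not in matrix", taxon)
  vals <- sm$values[i, -i]
  if (all(is.na(vals)))
    abort_degenerate("all entries missing for taxon '%s'", taxon)
  mean(vals, na.rm = TRUE)
}

#' Internal branch score
#'
#' Mean similarity over all cross-split pairs `X in sideA, Y in sideB`
#' (within-side pairs are not included).
#'
#' @param matrix A [similarity_matrix()].
#' @param bipartition List with `sideA` and `sideB` label vectors.
#' @return The mean over the `|A| * |B|` cross terms.
#' @export
internal_score <- function(matrix, bipartition) {
  sm <- check_matrix_arg(matrix)
  a <- match(bipartition$sideA, sm$taxa)
  b <- match(bipartition$sideB, sm$taxa)
  if (anyNA(a) || anyNA(b))
    abort_input("bipartition taxa missing from matrix: %s",
                paste(c(bipartition$sideA[is.na(a)],
                        bipartition$sideB[is.na(b)]), collapse = ", "))
  if (length(intersect(a, b)))
    abort_input("bipartition sides overlap")
  cross <- sm$values[a, b, drop = FALSE]
  if (all(is.na(cross)))
    abort_degenerate("all cross-split entries missing")
  mean(cross, na.rm = TRUE)
}

#' Tag all branches of a tree with similarity scores
#'
#' Every terminal branch receives [terminal_score()]; every internal edge
#' of the unrooted topology (non-trivial bipartition, scored once even
#' when the input is rooted) receives [internal_score()]. A branch is
#' suspicious iff its score is strictly negative. Matrix taxa absent from
#' the tree are ignored with a warning; tree leaves absent from the
#' matrix are an error.
#'
#' @param tree A `phylo` (from [read_newick()]); may be rooted or
#'   unrooted, and may contain polytomies.
#' @param matrix A [similarity_matrix()].
#' @return A `tagged_tree`: list with
#'   \describe{
#'     \item{tree}{the input `phylo`, internal-branch scores written to
#'       `node.label` (2 decimals)}
#'     \item{reports}{data frame of branch reports: `branch` (leaf label,
#'       or the smaller bipartition side joined by `|`), `kind`
#'       (`terminal`/`internal`), `score`, `suspicious`}
#'     \item{edge_scores, edge_suspicious}{per-edge vectors aligned with
#'       `tree$edge`, used by [render_tagged_tree()]}
#'   }
#' @export
tag_tree <- function(tree, matrix) {
  sm <- check_matrix_arg(matrix)
  missing_from_matrix <- setdiff(tree$tip.label, sm$taxa)
  if (length(missing_from_matrix))
    abort_input("tree leaves absent from matrix: %s",
                paste(missing_from_matrix, collapse = ", "))
  extra <- setdiff(sm$taxa, tree$tip.label)
  if (length(extra)) {
    warning(sprintf("matrix taxa not in tree ignored: %s",
                    paste(extra, collapse = ", ")))
    keep <- match(tree$tip.label, sm$taxa)
    sm <- structure(list(taxa = sm$taxa[keep],
                         values = sm$values[keep, keep, drop = FALSE],
                         n_pairs = sm$n_pairs), class = "similarity_matrix")
  }

  n <- length(tree$tip.label)
  sets <- edge_tip_sets(tree)
  edge_scores <- rep(NA_real_, nrow(tree$edge))
  reports <- list(); seen <- character(0)

  for (r in seq_len(nrow(tree$edge))) {
    s <- sets[[r]]
    if (length(s) == 1L || length(s) == n - 1L) {
      leaf <- tree$tip.label[if (length(s) == 1L) s else setdiff(seq_len(n), s)]
      sc <- terminal_score(sm, leaf)
      edge_scores[r] <- sc
      if (!(leaf %in% seen)) {
        seen <- c(seen, leaf)
        reports[[length(reports) + 1L]] <-
          data.frame(branch = leaf, kind = "terminal", score = sc)
      }
    } else if (length(s) >= 2L && length(s) <= n - 2L) {
      canon <- if (1L %in% s) setdiff(seq_len(n), s) else s
      bp <- list(sideA = tree$tip.label[canon],
                 sideB = tree$tip.label[setdiff(seq_len(n), canon)])
      sc <- internal_score(sm, bp)
      edge_scores[r] <- sc
      side <- if (length(bp$sideA) <= length(bp$sideB)) bp$sideA else bp$sideB
      key <- paste(sort(canon), collapse = ",")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        reports[[length(reports) + 1L]] <-
          data.frame(branch = paste(side, collapse = "|"),
                     kind = "internal", score = sc)
      }
    }
  }

  reports <- do.call(rbind, reports)
  reports$suspicious <- reports$score < 0

  ann <- tree
  node_lab <- rep("", tree$Nnode)
  for (r in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[r, 2L]
    if (ch > n && !is.na(edge_scores[r]) &&
        length(sets[[r]]) >= 2L && length(sets[[r]]) <= n - 2L)
      node_lab[ch - n] <- sprintf("%.2f", edge_scores[r])
  }
  ann$node.label <- node_lab

  structure(list(tree = ann, reports = reports, edge_scores = edge_scores,
                 edge_suspicious = !is.na(edge_scores) & edge_scores < 0),
            class = "tagged_tree")
}

#' @export
print.tagged_tree <- function(x, ...) {
  cat(sprintf("Tagged tree: %d branch reports, %d suspicious\n",
              nrow(x$reports), sum(x$reports$suspicious)))
  print(head(x$reports, 10L))
  invisible(x)
}

#' Write branch reports as TSV
#'
#' @param tagged A [tag_tree()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_branch_reports <- function(tagged, path) {
  df <- tagged$reports
  df$score <- sprintf("%.4f", df$score)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the annotated tree as newick
#'
#' Internal-branch scores are carried as internal node labels; each leaf
#' additionally carries its terminal score in a newick comment block
#' `[&R=...]`.
#'
#' @param tagged A [tag_tree()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_newick <- function(tagged, path) {
  nwk <- ape::write.tree(tagged$tree)
  term <- tagged$reports[tagged$reports$kind == "terminal", ]
  for (i in seq_len(nrow(term))) {
    lab <- term$branch[i]
    tag <- sprintf("%s[\\&R=%.4f]", lab, term$score[i])  # \\& = literal & in sub()
    nwk <- sub(paste0("(?<=[(,])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", lab),
                      "(?=[:,)])"),
               tag, nwk, perl = TRUE)
  }
  writeLines(nwk, path)
  invisible(path)
}
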