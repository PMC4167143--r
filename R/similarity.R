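#' @title Pairwise similarity matrix
#' @name similarity
#' @description Collapses pair sign profiles into a symmetric matrix of
#'   mean profile values over non-globally-invariant sites. Positive
#'   entries indicate predominantly non-random similarity; negative
#'   entries similarity indistinguishable from random.
NULL

#' Globally invariant site mask
#'
#' A site is globally invariant iff every taxon carries the identical
#' canonical state there (under fifth-state gap coding an all-gap column
#' is invariant); any neutral residue (ambiguity code, or gap under
#' ambiguous mode) makes the column variable. Invariant sites are
#' excluded from the pairwise means.
#'
#' @param aln An alignment.
#' @param gap_mode `"fifth_state"` or `"ambiguous"`.
#' @return Logical vector of length `M`; `TRUE` = invariant.
#' @export
global_invariant_mask <- function(aln, gap_mode = c("fifth_state", "ambiguous")) {
  gap_mode <- match.arg(gap_mode)
  codes <- encode_classes(aln, gap_mode)$codes
  apply(codes, 2L, function(col) !anyNA(col) && all(col == col[1]))
}

#' Mean profile value over non-invariant sites
#'
#' @param profile A [pair_profile()].
#' @param mask Logical invariant mask from [global_invariant_mask()].
#' @return Arithmetic mean of the profile over sites where `mask` is
#'   `FALSE`. Errors (degenerate pair) when no site survives the mask.
#' @export
pair_similarity <- function(profile, mask) {
  values <- if (inherits(profile, "pair_profile")) profile$values else profile
  if (length(values) != length(mask))
    abort_input("profile and mask lengths differ (%d vs %d)",
                length(values), length(mask))
  keep <- !mask
  if (!any(keep))
    abort_degenerate("no non-invariant sites for this pair")
  mean(values[keep])
}

#' Pairwise similarity matrix of an alignment
#'
#' Computes the sign profile and its masked mean for all `N(N-1)/2`
#' unordered pairs. The diagonal is fixed at `+1` by display convention
#' (a self-comparison is meaningless under the test) and is excluded from
#' all downstream statistics. Degenerate pairs (no non-invariant site)
#' propagate as `NA` with a warning, never as silent zeros.
#'
#' @param aln An alignment.
#' @param params [window_params()].
#' @param scheme [scoring_scheme()]; default chosen by alphabet.
#' @param gap_mode `"fifth_state"` or `"ambiguous"`.
#' @param edge_normalize See [pair_profile()].
#' @param workers Number of worker processes for pair-level parallelism
#'   (forked; results are identical to serial because every pair owns a
#'   deterministic permutation stream).
#' @return A `similarity_matrix`: list with `taxa`, `values` (`N x N`
#'   symmetric numeric matrix), and `n_pairs` (number of pairwise
#'   computations performed).
#' @export
similarity_matrix <- function(aln, params = window_params(),
                              scheme = default_scheme(aln$alphabet),
                              gap_mode = c("fifth_state", "ambiguous"),
                              edge_normalize = c("window", "coverage"),
                              workers = 1L) {
  gap_mode <- match.arg(gap_mode)
  edge_normalize <- match.arg(edge_normalize)
  N <- length(aln$taxa)
  if (N < 2L) abort_input("need at least 2 taxa")
  if (params$window_size > ncol(aln$residues))
    abort_input("window width %d exceeds alignment length %d",
                params$window_size, ncol(aln$residues))

  enc <- encode_classes(aln, gap_mode)
  smat <- build_score_matrix(scheme, enc$states)
  codes <- enc$codes
  codes[is.na(codes)] <- 0L
  mask <- global_invariant_mask(aln, gap_mode)

  pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 2L], pairs[, 1L]), , drop = FALSE]

  one_pair <- function(r) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    values <- cpp_pair_profile(codes[i, ], codes[j, ], smat,
                               params$window_size, params$flank,
                               params$n_permutations, params$alpha,
                               params$seed, pair_index(i, j),
                               edge_normalize == "coverage")
    tryCatch(pair_similarity(values, mask),
             alignoise_degenerate_error = function(e) NA_real_)
  }

  vals <- if (workers > 1L) {
    unlist(parallel::mclapply(seq_len(nrow(pairs)), one_pair,
                              mc.cores = workers, mc.preschedule = TRUE))
  } else {
    vapply(seq_len(nrow(pairs)), one_pair, numeric(1))
  }

  S <- matrix(NA_real_, N, N, dimnames = list(aln$taxa, aln$taxa))
  for (r in seq_len(nrow(pairs))) {
    S[pairs[r, 1L], pairs[r, 2L]] <- vals[r]
    S[pairs[r, 2L], pairs[r, 1L]] <- vals[r]
  }
  diag(S) <- 1
  if (anyNA(vals))
    warning(sprintf("%d degenerate pair(s) scored as missing", sum(is.na(vals))))
  structure(list(taxa = aln$taxa, values = S, n_pairs = nrow(pairs)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("Pairwise similarity matrix: %d taxa (%d pairs)\n",
              length(x$taxa), x$n_pairs))
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("  off-diagonal range: [%.3f, %.3f], mean %.3f%s\n",
              min(off, na.rm = TRUE), max(off, na.rm = TRUE),
              mean(off, na.rm = TRUE),
              if (anyNA(off)) sprintf(", %d missing", sum(is.na(off))) else ""))
  invisible(x)
}

#' Write a similarity matrix as TSV
#'
#' Header row of taxa, one labelled row per taxon, 4-decimal values;
#' missing entries written as `NA`.
#'
#' @param sm A [similarity_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(sm, path) {
  vals <- matrix(sprintf("%.4f", sm$values), nrow = length(sm$taxa))
  vals[is.na(sm$values)] <- "NA"
  lines <- c(paste(c("taxon", sm$taxa), collapse = "\t"),
             vapply(seq_along(sm$taxa), function(i)
               paste(c(sm$taxa[i], vals[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Write a similarity matrix in square PHYLIP-style layout
#'
#' First line: taxon count; then one row per taxon, label padded to 10
#' characters, followed by the N values.
#'
#' @inheritParams write_similarity_tsv
#' @return `path`, invisibly.
#' @export
write_similarity_phylip <- function(sm, path) {
  n <- length(sm$taxa)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               v <- sprintf("%.4f", sm$values[i, ])
               v[is.na(sm$values[i, ])] <- "NA"
               paste0(formatC(sm$taxa[i], width = -10), paste(v, collapse = "  "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
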