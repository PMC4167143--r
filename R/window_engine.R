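#' @title Sliding-window Monte Carlo test
#' @name window_engine
#' @description For each pair of aligned sequences, every window of `w`
#'   consecutive sites is scored and compared against scores of synthetic
#'   windows resampled from the local sequence neighbourhood. Windows whose
#'   observed score beats at least `1 - alpha` of the permutations vote
#'   `+1` (non-random similarity) on every site they cover, otherwise `-1`;
#'   per-site sums of votes normalized by the window size give the pair's
#'   sign profile in `[-1, 1]`.
NULL

#' Window and resampling parameters
#'
#' @param window_size Width `w` of the sliding window (sites); default 6.
#'   The step is fixed at 1.
#' @param flank Neighbourhood flank `f`: columns added on each side of the
#'   window when building the resampling pools (clipped at the alignment
#'   ends); defaults to `window_size`.
#' @param n_permutations Monte Carlo permutations per window; default 100.
#'   Must be at least `ceiling(1/alpha)` so the criterion is resolvable.
#' @param alpha Significance level of the window test; default 0.05 (the
#'   observed score must beat 95% of the permutation scores).
#' @param seed Master seed for the permutation streams. Each
#'   (pair, window) combination derives its own stream from
#'   (seed, canonical pair index, window start), so results do not depend
#'   on evaluation order.
#' @return A `window_params` object.
#' @export
window_params <- function(window_size = 6L, flank = window_size,
                          n_permutations = 100L, alpha = 0.05, seed = 1L) {
  window_size <- as.integer(window_size)
  flank <- as.integer(flank)
  n_permutations <- as.integer(n_permutations)
  if (window_size < 1L || window_size > 64L)
    abort_input("window_size must be in 1..64")
  if (flank < 0L) abort_input("flank must be non-negative")
  if (alpha <= 0 || alpha >= 1) abort_input("alpha must be in (0, 1)")
  if (n_permutations < ceiling(1 / alpha))
    abort_input("n_permutations must be >= ceiling(1/alpha) = %d",
                ceiling(1 / alpha))
  structure(list(window_size = window_size, flank = flank,
                 n_permutations = n_permutations, alpha = alpha,
                 seed = as.numeric(seed)),
            class = "window_params")
}

#' Enumerate sliding windows
#'
#' All windows of width `w` at step 1 over `M` sites.
#'
#' @param M Number of alignment sites.
#' @param w Window width, `1 <= w <= M`.
#' @return A data frame with 1-based inclusive `start` and `end` columns
#'   and `M - w + 1` rows.
#' @export
windows <- function(M, w) {
  if (w > M) abort_input("window width %d exceeds alignment length %d", w, M)
  if (w < 1L) abort_input("window width must be positive")
  start <- seq_len(M - w + 1L)
  data.frame(start = start, end = start + w - 1L)
}

# canonical pair index: position of the unordered pair {i, j} (i < j,
# 1-based positions in the taxon list) in the enumeration of all pairs
pair_index <- function(i, j) {
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  (j - 1) * (j - 2) / 2 + i
}

resolve_pair <- function(aln, taxonX, taxonY) {
  ix <- match(taxonX, aln$taxa)
  iy <- match(taxonY, aln$taxa)
  if (is.na(ix) || is.na(iy))
    abort_input("taxon not in alignment: %s",
                paste(c(taxonX, taxonY)[c(is.na(ix), is.na(iy))], collapse = ", "))
  if (ix == iy) abort_input("a pair needs two distinct taxa")
  sort(c(ix, iy))
}

#' Permutation null scores for one window
#'
#' Each permutation builds a synthetic window pair by drawing, for each
#' sequence independently, `w` residue classes uniformly with replacement
#' from that sequence's residues inside the window extended by `flank`
#' columns on each side; the null score is the window score of the
#' synthetic pair. Neutral residues stay in the pools and contribute 0
#' wherever drawn.
#'
#' @param aln An [as_alignment()] object.
#' @param taxonX,taxonY Taxon labels of the pair.
#' @param window_start 1-based start site of the window.
#' @param params [window_params()].
#' @param scheme [scoring_scheme()]; defaults to the alphabet's default.
#' @param gap_mode `"fifth_state"` or `"ambiguous"`.
#' @return Numeric vector of length `n_permutations`, identical across
#'   calls with the same seed.
#' @export
null_scores <- function(aln, taxonX, taxonY, window_start,
                        params = window_params(),
                        scheme = default_scheme(aln$alphabet),
                        gap_mode = c("fifth_state", "ambiguous")) {
  gap_mode <- match.arg(gap_mode)
  M <- ncol(aln$residues)
  w <- params$window_size
  if (window_start < 1L || window_start > M - w + 1L)
    abort_input("window start %d out of range", window_start)
  idx <- resolve_pair(aln, taxonX, taxonY)
  enc <- encode_classes(aln, gap_mode)
  smat <- build_score_matrix(scheme, enc$states)
  codes <- enc$codes
  codes[is.na(codes)] <- 0L
  cpp_null_scores(codes[idx[1], ], codes[idx[2], ], smat,
                  as.integer(window_start - 1L), w, params$flank,
                  params$n_permutations, params$seed,
                  pair_index(idx[1], idx[2]))
}

#' Verdict of one window test
#'
#' The window votes `+1` (non-random similarity) iff the observed score is
#' strictly better than at least `1 - alpha` of the permutation scores;
#' ties count against significance, so a window whose observed score merely
#' equals the nulls votes `-1`.
#'
#' @param observed Observed window score.
#' @param nulls Numeric vector of permutation scores.
#' @param alpha Significance level.
#' @return `+1` or `-1`.
#' @export
window_verdict <- function(observed, nulls, alpha = 0.05) {
  if (!length(nulls)) abort_input("empty null distribution")
  if (sum(observed > nulls) >= (1 - alpha) * length(nulls) - 1e-9) 1 else -1
}

#' Sign profile of a sequence pair
#'
#' Slides the window along the full alignment; every site accumulates the
#' `+1`/`-1` verdicts of the windows covering it, and site sums are
#' normalized by the window size (so edge sites covered by fewer than `w`
#' windows have `|value| <= k/w`). The profile is symmetric in the two
#' taxa: the pair is canonicalized before seeding the permutation streams.
#'
#' @inheritParams null_scores
#' @param edge_normalize `"window"` (divide every site by `w`; default) or
#'   `"coverage"` (divide by the number of windows covering the site).
#' @return A `pair_profile`: list with `taxon_pair` and `values`
#'   (numeric, length `M`, all in `[-1, 1]`).
#' @export
pair_profile <- function(aln, taxonX, taxonY, params = window_params(),
                         scheme = default_scheme(aln$alphabet),
                         gap_mode = c("fifth_state", "ambiguous"),
                         edge_normalize = c("window", "coverage")) {
  gap_mode <- match.arg(gap_mode)
  edge_normalize <- match.arg(edge_normalize)
  if (params$window_size > ncol(aln$residues))
    abort_input("window width %d exceeds alignment length %d",
                params$window_size, ncol(aln$residues))
  idx <- resolve_pair(aln, taxonX, taxonY)
  enc <- encode_classes(aln, gap_mode)
  smat <- build_score_matrix(scheme, enc$states)
  codes <- enc$codes
  codes[is.na(codes)] <- 0L
  values <- cpp_pair_profile(codes[idx[1], ], codes[idx[2], ], smat,
                             params$window_size, params$flank,
                             params$n_permutations, params$alpha,
                             params$seed, pair_index(idx[1], idx[2]),
                             edge_normalize == "coverage")
  structure(list(taxon_pair = aln$taxa[idx], values = values),
            class = "pair_profile")
}

#' @export
print.pair_profile <- function(x, ...) {
  cat(sprintf("Pair profile %s vs %s: %d sites, mean %.3f\n",
              x$taxon_pair[1], x$taxon_pair[2], length(x$values),
              mean(x$values)))
  invisible(x)
}

#' Write a pair profile as TSV
#'
#' @param profile A [pair_profile()].
#' @param path Output path; columns `site` (1-based) and `value`.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(site = seq_along(profile$values),
                   value = sprintf("%.6f", profile$values))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
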