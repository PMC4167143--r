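#' @title Per-site pair scoring schemes
#' @name scoring
#' @description Match/mismatch scoring for nucleotides and substitution
#'   matrices (BLOSUM62, PAM250, PAM500) for amino acids, including the
#'   gap contract under both gap-handling modes.
NULL

# PAM500 log-odds scores extrapolated from the Dayhoff rate model by
# matrix exponentiation (see tools/make_pam500.R; the same generator
# reproduces the published PAM250 to within rounding).
PAM500 <- matrix(c(
0L, 0L, 0L, 0L, -1L, 0L, 0L, 1L, 0L, 0L, -1L, 0L, 0L, -1L, 0L, 0L, 0L, -3L, -2L, 0L,
0L, 2L, 0L, 0L, -2L, 1L, 0L, -1L, 1L, -1L, -1L, 2L, 0L, -2L, 0L, 0L, 0L, 2L, -2L, -1L,
0L, 0L, 1L, 1L, -2L, 1L, 1L, 0L, 1L, -1L, -1L, 0L, -1L, -2L, 0L, 0L, 0L, -2L, -1L, 0L,
0L, 0L, 1L, 1L, -2L, 1L, 1L, 1L, 1L, -1L, -1L, 0L, -1L, -2L, 0L, 0L, 0L, -3L, -2L, -1L,
-1L, -2L, -2L, -2L, 9L, -2L, -2L, -1L, -2L, -1L, -3L, -2L, -2L, -1L, -1L, 0L, -1L, -4L, 1L, -1L,
0L, 1L, 1L, 1L, -2L, 1L, 1L, 0L, 1L, -1L, -1L, 1L, 0L, -2L, 0L, 0L, 0L, -2L, -2L, -1L,
0L, 0L, 1L, 1L, -2L, 1L, 1L, 0L, 1L, -1L, -1L, 0L, -1L, -2L, 0L, 0L, 0L, -3L, -2L, -1L,
1L, -1L, 0L, 1L, -1L, 0L, 0L, 2L, 0L, -1L, -1L, 0L, -1L, -2L, 0L, 1L, 0L, -3L, -2L, 0L,
0L, 1L, 1L, 1L, -2L, 1L, 1L, 0L, 2L, -1L, -1L, 0L, -1L, -1L, 0L, 0L, 0L, -1L, 0L, -1L,
0L, -1L, -1L, -1L, -1L, -1L, -1L, -1L, -1L, 1L, 2L, -1L, 1L, 1L, -1L, 0L, 0L, -2L, 0L, 1L,
-1L, -1L, -1L, -1L, -3L, -1L, -1L, -1L, -1L, 2L, 3L, -1L, 2L, 2L, -1L, -1L, 0L, -1L, 1L, 1L,
0L, 2L, 0L, 0L, -2L, 1L, 0L, 0L, 0L, -1L, -1L, 2L, 0L, -2L, 0L, 0L, 0L, -1L, -2L, -1L,
0L, 0L, -1L, -1L, -2L, 0L, -1L, -1L, -1L, 1L, 2L, 0L, 2L, 1L, -1L, -1L, 0L, -2L, 0L, 1L,
-1L, -2L, -2L, -2L, -1L, -2L, -2L, -2L, -1L, 1L, 2L, -2L, 1L, 6L, -2L, -1L, -1L, 1L, 5L, 0L,
0L, 0L, 0L, 0L, -1L, 0L, 0L, 0L, 0L, -1L, -1L, 0L, -1L, -2L, 2L, 0L, 0L, -3L, -2L, 0L,
0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, -1L, 0L, -1L, -1L, 0L, 0L, 0L, -1L, -1L, 0L,
0L, 0L, 0L, 0L, -1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, -1L, 0L, 0L, 0L, -2L, -1L, 0L,
-3L, 2L, -2L, -3L, -4L, -2L, -3L, -3L, -1L, -2L, -1L, -1L, -2L, 1L, -3L, -1L, -2L, 15L, 1L, -3L,
-2L, -2L, -1L, -2L, 1L, -2L, -2L, -2L, 0L, 0L, 1L, -2L, 0L, 5L, -2L, -1L, -1L, 1L, 7L, -1L,
0L, -1L, 0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L, 1L, -1L, 1L, 0L, 0L, 0L, 0L, -3L, -1L, 1L
), nrow = 20, byrow = TRUE, dimnames = list(AA_STATES, AA_STATES))

substitution_matrix <- function(name = c("BLOSUM62", "PAM250", "PAM500")) {
  name <- match.arg(name)
  if (name == "PAM500") return(PAM500)
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  m <- get(name, env)[AA_STATES, AA_STATES]
  storage.mode(m) <- "integer"
  m
}

#' Create a pair scoring scheme
#'
#' `kind = "match_mismatch"` scores identical canonical states
#' `match_score` and differing ones `mismatch_score` (nucleotide default).
#' `kind = "matrix"` uses an amino acid substitution matrix. The gap
#' behaves as a fifth, identity-matchable state when the gap mode is
#' `"fifth_state"`: gap-vs-gap scores `match_score`, gap-vs-residue scores
#' `gap_penalty` (default `mismatch_score`).
#'
#' @param kind `"match_mismatch"` or `"matrix"`.
#' @param matrix_name `"BLOSUM62"`, `"PAM250"` or `"PAM500"` (matrix kind).
#' @param match_score,mismatch_score Numeric scores for the
#'   match/mismatch scheme and for the gap contract; `match_score` must
#'   exceed `mismatch_score`.
#' @param gap_penalty Score of a gap against a residue under fifth-state
#'   coding; defaults to `mismatch_score`.
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(kind = c("match_mismatch", "matrix"),
                           matrix_name = c("BLOSUM62", "PAM250", "PAM500"),
                           match_score = 1, mismatch_score = -1,
                           gap_penalty = mismatch_score) {
  kind <- match.arg(kind)
  if (match_score <= mismatch_score)
    abort_input("match_score must exceed mismatch_score")
  scheme <- list(kind = kind, match_score = match_score,
                 mismatch_score = mismatch_score, gap_penalty = gap_penalty)
  if (kind == "matrix") {
    scheme$matrix_name <- match.arg(matrix_name)
    scheme$matrix <- substitution_matrix(scheme$matrix_name)
    stopifnot(isSymmetric(unname(scheme$matrix)))
  }
  structure(scheme, class = "scoring_scheme")
}

#' Default scheme for an alphabet
#'
#' Match/mismatch for nucleotides, BLOSUM62 for amino acids.
#'
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @param ... Passed to [scoring_scheme()].
#' @return A `scoring_scheme`.
#' @export
default_scheme <- function(alphabet, ...) {
  if (alphabet == "nucleotide") scoring_scheme("match_mismatch", ...)
  else scoring_scheme("matrix", "BLOSUM62", ...)
}

# Full numeric score matrix over the canonical state set of the run
# (including GAP as the last state under fifth_state); consumed by the
# compiled window engine.
build_score_matrix <- function(scheme, states) {
  k <- length(states)
  has_gap <- states[k] == GAP_STATE
  m <- matrix(NA_real_, k, k, dimnames = list(states, states))
  if (scheme$kind == "match_mismatch") {
    m[] <- scheme$mismatch_score
    diag(m) <- scheme$match_score
    if (has_gap) {
      m[GAP_STATE, ] <- scheme$gap_penalty
      m[, GAP_STATE] <- scheme$gap_penalty
      m[GAP_STATE, GAP_STATE] <- scheme$match_score
    }
  } else {
    core <- setdiff(states, GAP_STATE)
    miss <- setdiff(core, rownames(scheme$matrix))
    if (length(miss))
      abort_internal("state(s) %s missing from %s", paste(miss, collapse = ","),
                     scheme$matrix_name)
    m[core, core] <- scheme$matrix[core, core]
    if (has_gap) {
      m[GAP_STATE, ] <- scheme$gap_penalty
      m[, GAP_STATE] <- scheme$gap_penalty
      m[GAP_STATE, GAP_STATE] <- scheme$match_score
    }
  }
  m
}

#' Score one aligned site of a sequence pair
#'
#' Residue classes come from [residue_class()]. A neutral class against
#' anything scores 0.
#'
#' @param a,b Residue classes (state characters or `"neutral"`).
#' @param scheme A [scoring_scheme()].
#' @param gap_penalty Override of the scheme's gap-vs-residue score.
#' @return A single numeric score.
#' @export
site_score <- function(a, b, scheme = scoring_scheme(),
                       gap_penalty = scheme$gap_penalty) {
  if (identical(a, "neutral") || identical(b, "neutral")) return(0)
  if (a == GAP_STATE || b == GAP_STATE) {
    if (a == GAP_STATE && b == GAP_STATE) return(scheme$match_score)
    return(gap_penalty)
  }
  if (scheme$kind == "match_mismatch") {
    return(if (a == b) scheme$match_score else scheme$mismatch_score)
  }
  if (!(a %in% rownames(scheme$matrix)) || !(b %in% rownames(scheme$matrix)))
    abort_internal("no %s entry for states %s/%s", scheme$matrix_name, a, b)
  as.numeric(scheme$matrix[a, b])
}

#' Score a pair of equal-length residue runs
#'
#' Sum of [site_score()] over the columns of the run.
#'
#' @param x,y Character vectors of residues (not classes), equal length,
#'   or single strings.
#' @param scheme A [scoring_scheme()].
#' @param alphabet Alphabet of the residues.
#' @param gap_mode Gap handling, see [residue_class()].
#' @param gap_penalty Override of the gap-vs-residue score.
#' @return A single numeric score.
#' @export
window_score <- function(x, y, scheme = scoring_scheme(),
                         alphabet = "nucleotide",
                         gap_mode = "fifth_state",
                         gap_penalty = scheme$gap_penalty) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
  if (length(y) == 1L && nchar(y) > 1L) y <- strsplit(y, "")[[1]]
  if (length(x) != length(y))
    abort_internal("runs differ in length (%d vs %d)", length(x), length(y))
  ca <- vapply(x, residue_class, "", alphabet = alphabet, gap_mode = gap_mode)
  cb <- vapply(y, residue_class, "", alphabet = alphabet, gap_mode = gap_mode)
  sum(mapply(site_score, ca, cb,
             MoreArgs = list(scheme = scheme, gap_penalty = gap_penalty)))
}
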