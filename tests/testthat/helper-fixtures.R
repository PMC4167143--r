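# Fixture builders and independent oracles shared across test files.

rand_aln <- function(n = 2, M = 100, states = c("A", "C", "G", "T"),
                     seed = 1, labels = NULL) {
  set.seed(seed)
  if (is.null(labels)) labels <- paste0("T", seq_len(n))
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(states, M, replace = TRUE), collapse = ""), "")
  as_alignment(setNames(seqs, labels), alphabet = "nucleotide")
}

write_temp_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  path
}

# --- independent window-test oracle -----------------------------------
# Exact null distribution of the window score under resampling with
# replacement from the two pools, by w-fold convolution of the per-site
# score distribution. Works on raw residue characters with plain
# match/mismatch (+1/-1) scoring; independent of the package's engine.

site_score_dist <- function(xpool, ypool) {
  sc <- as.vector(outer(xpool, ypool, function(a, b) ifelse(a == b, 1, -1)))
  agg <- tapply(rep(1 / length(sc), length(sc)), sc, sum)
  data.frame(score = as.numeric(names(agg)), prob = as.numeric(agg))
}

convolve_dist <- function(d1, d2) {
  s <- outer(d1$score, d2$score, `+`)
  p <- outer(d1$prob, d2$prob, `*`)
  agg <- tapply(as.vector(p), as.vector(s), sum)
  data.frame(score = as.numeric(names(agg)), prob = as.numeric(agg))
}

exact_null_dist <- function(xpool, ypool, w) {
  site <- site_score_dist(xpool, ypool)
  out <- site
  for (i in seq_len(w - 1)) out <- convolve_dist(out, site)
  out
}

# verdict in the limit of infinite permutations: +1 iff the observed score
# strictly beats at least 1 - alpha of the null mass
exact_verdict <- function(observed, dist, alpha = 0.05) {
  if (sum(dist$prob[dist$score < observed - 1e-9]) >= 1 - alpha - 1e-12) 1 else -1
}

# observed match/mismatch window score, computed directly on characters
naive_window_score <- function(xrun, yrun) sum(ifelse(xrun == yrun, 1, -1))

# --- brute-force cross-split mean --------------------------------------
brute_internal_mean <- function(values, a_idx, b_idx) {
  tot <- 0; k <- 0L
  for (i in a_idx) for (j in b_idx) {
    tot <- tot + values[i, j]; k <- k + 1L
  }
  tot / k
}

rand_symmetric_matrix <- function(taxa, seed) {
  set.seed(seed)
  n <- length(taxa)
  V <- matrix(0, n, n, dimnames = list(taxa, taxa))
  V[upper.tri(V)] <- runif(n * (n - 1) / 2, -1, 1)
  V <- V + t(V)
  diag(V) <- 1
  structure(list(taxa = taxa, values = V, n_pairs = n * (n - 1) / 2),
            class = "similarity_matrix")
}
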