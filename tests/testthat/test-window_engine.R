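test_that("window enumeration covers the alignment at step 1", {
  w53 <- windows(5, 3)
  expect_equal(w53$start, 1:3)
  expect_equal(w53$end, 3:5)
  expect_equal(nrow(windows(4, 4)), 1L)
  expect_equal(nrow(windows(10, 1)), 10L)
  expect_error(windows(3, 4), class = "alignoise_input_error")
})

test_that("window parameters are validated", {
  expect_error(window_params(n_permutations = 10, alpha = 0.05),
               class = "alignoise_input_error")
  expect_error(window_params(window_size = 0), class = "alignoise_input_error")
  expect_error(window_params(alpha = 1), class = "alignoise_input_error")
  expect_silent(window_params(n_permutations = 20, alpha = 0.05))
})

test_that("null scores are deterministic and reflect single-state pools", {
  aln <- as_alignment(c(x = strrep("A", 30), y = strrep("A", 30)))
  prm <- window_params(window_size = 4, n_permutations = 50, seed = 9)
  nulls <- null_scores(aln, "x", "y", 10, prm)
  expect_length(nulls, 50)
  expect_true(all(nulls == 4))  # single-state pools: every draw matches
  expect_identical(nulls, null_scores(aln, "x", "y", 10, prm))
  # a different window start uses a different stream
  aln2 <- rand_aln(2, 30, seed = 2, labels = c("x", "y"))
  expect_false(identical(null_scores(aln2, "x", "y", 5, prm),
                         null_scores(aln2, "x", "y", 6, prm)))
})

test_that("the Monte Carlo null matches exhaustive enumeration", {
  # X neighbourhood half A half C, Y all G: site score is -1 always for
  # Y=G vs X in {A,C}; with w = 2 every null must be exactly -2, and with
  # a mixed Y pool empirical frequencies must match the convolution oracle
  x <- paste(rep(c("A", "C"), 15), collapse = "")
  y <- strrep("G", 30)
  aln <- as_alignment(c(x = x, y = y))
  prm <- window_params(window_size = 2, flank = 2, n_permutations = 4000,
                       seed = 3)
  nulls <- null_scores(aln, "x", "y", 10, prm)
  expect_true(all(nulls == -2))

  aln2 <- rand_aln(2, 30, states = c("A", "C"), seed = 8,
                   labels = c("x", "y"))
  start <- 12
  nulls2 <- null_scores(aln2, "x", "y", start, prm)
  lo <- start - 2; hi <- start + 1 + 2  # window 2 + flank 2 each side
  dist <- exact_null_dist(aln2$residues[1, lo:hi], aln2$residues[2, lo:hi], 2)
  for (k in seq_len(nrow(dist))) {
    emp <- mean(nulls2 == dist$score[k])
    se <- sqrt(dist$prob[k] * (1 - dist$prob[k]) / 4000)
    expect_lt(abs(emp - dist$prob[k]), 4 * se + 1e-12)
  }
})

test_that("the window verdict applies the strict 95% rule", {
  expect_equal(window_verdict(10, rep(0, 100), 0.05), 1)
  expect_equal(window_verdict(5, rep(5, 100), 0.05), -1)  # ties never count
  nulls <- c(rep(-1, 94), rep(99, 6))
  expect_equal(window_verdict(0, nulls, 0.05), -1)  # beats 94 of 100: not enough
  expect_equal(window_verdict(0, c(rep(-1, 95), rep(99, 5)), 0.05), 1)
  expect_error(window_verdict(0, numeric(0)), class = "alignoise_input_error")
})

test_that("pair profiles are symmetric in their arguments", {
  aln <- rand_aln(3, 120, seed = 5, labels = c("a", "b", "c"))
  prm <- window_params(seed = 11)
  p1 <- pair_profile(aln, "a", "c", prm)
  p2 <- pair_profile(aln, "c", "a", prm)
  expect_identical(p1$values, p2$values)
  expect_equal(p1$taxon_pair, p2$taxon_pair)
})

test_that("identical compositionally diverse sequences profile at +1", {
  set.seed(13)
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  aln <- as_alignment(c(p = s, q = s))
  prm <- window_params(seed = 2)
  prof <- pair_profile(aln, "p", "q", prm)
  w <- prm$window_size
  interior <- (w):(400 - w + 1)
  expect_true(all(prof$values[interior] == 1))
  # edge sites covered by k < w windows are bounded by k/w
  for (k in seq_len(w - 1)) {
    expect_equal(prof$values[k], k / w)
    expect_equal(prof$values[400 - k + 1], k / w)
  }
  # coverage normalization brings the edges to +/-1 as well
  prof_cov <- pair_profile(aln, "p", "q", prm, edge_normalize = "coverage")
  expect_true(all(prof_cov$values == 1))
})

test_that("iid random pairs profile negative", {
  aln <- rand_aln(2, 1000, seed = 21, labels = c("u", "v"))
  prof <- pair_profile(aln, "u", "v", window_params(seed = 4))
  expect_lt(mean(prof$values), 0)
  expect_true(all(prof$values >= -1 & prof$values <= 1))
})

test_that("profiles respect the [-1, 1] bounds on gappy data", {
  a <- simulate_alignment(setup_b_tree(0.9),
                          sim_model(ins_rate = 0.05, del_rate = 0.05),
                          300, seed = 6)
  prm <- window_params(seed = 8)
  for (gm in c("fifth_state", "ambiguous")) {
    prof <- pair_profile(a, "L1", "RB4", prm, gap_mode = gm)
    expect_true(all(prof$values >= -1 & prof$values <= 1))
  }
})

test_that("profile TSV export is readable", {
  aln <- rand_aln(2, 50, seed = 1, labels = c("a", "b"))
  prof <- pair_profile(aln, "a", "b", window_params(seed = 1))
  f <- tempfile(fileext = ".tsv")
  write_profile_tsv(prof, f)
  df <- read.delim(f)
  expect_equal(nrow(df), 50)
  expect_equal(df$value, as.numeric(sprintf("%.6f", prof$values)))
})
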