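test_that("newick parsing and bipartition enumeration", {
  t4 <- read_newick(text = "((A,B),(C,D));")
  expect_equal(length(t4$tip.label), 4L)
  bps <- bipartitions(t4)
  expect_length(bps, 1L)  # root-edge duplicates collapse to one split
  expect_setequal(bps[[1]]$sideA, c("C", "D"))
  expect_setequal(bps[[1]]$sideB, c("A", "B"))

  t6 <- read_newick(text = "((A,B),(C,(D,(E,F))));")
  keys <- vapply(bipartitions(t6), function(b)
    paste(sort(b[[which.min(lengths(b))]]), collapse = ","), "")
  expect_true("A,B" %in% keys)
  expect_true("E,F" %in% keys)
  expect_length(keys, 3L)  # N - 3 for a bifurcating 6-taxon tree

  tp <- read_newick(text = "(A,B,C,(D,E));")
  bpp <- bipartitions(tp)
  expect_length(bpp, 1L)
  expect_setequal(bpp[[1]][[which.min(lengths(bpp[[1]]))]], c("D", "E"))

  expect_error(read_newick(text = "((A,B),C"), class = "alignoise_input_error")
})

test_that("terminal scores average a taxon against all others", {
  taxa <- c("A", "B", "C", "D", "E", "F")
  V <- matrix(0.5, 6, 6, dimnames = list(taxa, taxa)); diag(V) <- 1
  sm <- structure(list(taxa = taxa, values = V, n_pairs = 15),
                  class = "similarity_matrix")
  expect_equal(terminal_score(sm, "A"), 0.5)  # constant case
  V["A", c("B", "C", "D", "E", "F")] <- c(0.8, 0.6, -0.2, 0.0, -0.7)
  V[, "A"] <- V["A", ]
  sm$values <- V
  expect_equal(terminal_score(sm, "A"), 0.1)  # hand mean of the 5 values
  expect_error(terminal_score(sm, "Z"), class = "alignoise_input_error")
  # missing entries drop out of sum and count
  V["A", "B"] <- NA; V["B", "A"] <- NA
  sm$values <- V
  expect_equal(terminal_score(sm, "A"), mean(c(0.6, -0.2, 0.0, -0.7)))
})

test_that("internal scores equal the brute-force cross-split mean", {
  taxa <- c("A", "B", "C", "D", "E", "F")
  for (seed in 1:25) {
    sm <- rand_symmetric_matrix(taxa, seed)
    bp <- list(sideA = c("A", "B"), sideB = c("C", "D", "E", "F"))
    got <- internal_score(sm, bp)
    want <- brute_internal_mean(sm$values, match(bp$sideA, taxa),
                                match(bp$sideB, taxa))
    expect_equal(got, want, tolerance = 1e-12)
    # side swap invariance
    expect_equal(internal_score(sm, list(sideA = bp$sideB, sideB = bp$sideA)),
                 got, tolerance = 1e-15)
  }
  sm <- rand_symmetric_matrix(taxa, 99)
  expect_equal(internal_score(sm, list(sideA = "A", sideB = taxa[-1])),
               terminal_score(sm, "A"))  # trivial split = terminal mean
  expect_error(internal_score(sm, list(sideA = c("A", "B"), sideB = c("B", "C"))),
               class = "alignoise_input_error")
})

test_that("tagging scores every branch once and flags negatives exactly", {
  taxa <- paste0("t", 1:8)
  sm <- rand_symmetric_matrix(taxa, 7)
  set.seed(7)
  tree <- ape::rtree(8, tip.label = taxa)
  tt <- tag_tree(tree, sm)
  internal <- tt$reports[tt$reports$kind == "internal", ]
  expect_equal(nrow(internal), 8 - 3)  # N - 3 splits, root edge deduplicated
  expect_equal(nrow(tt$reports[tt$reports$kind == "terminal", ]), 8)
  expect_identical(tt$reports$suspicious, tt$reports$score < 0)
  # rerooting leaves the split scores unchanged
  tre2 <- ape::root(tree, outgroup = "t5", resolve.root = TRUE)
  tt2 <- tag_tree(tre2, sm)
  key <- function(x) {
    i <- x$reports$kind == "internal"
    sort(round(x$reports$score[i], 12))
  }
  expect_equal(key(tt2), key(tt))
})

test_that("uniformly positive matrices tag nothing", {
  taxa <- c("A", "B", "C", "D")
  V <- matrix(0.9, 4, 4, dimnames = list(taxa, taxa)); diag(V) <- 1
  sm <- structure(list(taxa = taxa, values = V, n_pairs = 6),
                  class = "similarity_matrix")
  tt <- tag_tree(read_newick(text = "((A,B),(C,D));"), sm)
  expect_true(all(tt$reports$score == 0.9))
  expect_false(any(tt$reports$suspicious))
  # zero is not suspicious
  V[] <- 0; diag(V) <- 1; sm$values <- V
  tt0 <- tag_tree(read_newick(text = "((A,B),(C,D));"), sm)
  expect_false(any(tt0$reports$suspicious))
})

test_that("negative cross-split terms flag the joining branch", {
  # setup-B-like: L1, L2 random-like against everyone else
  taxa <- c("L1", "L2", "RB1", "RB2", "RB3", "RB4")
  V <- matrix(0.6, 6, 6, dimnames = list(taxa, taxa))
  V[c("L1", "L2"), c("RB1", "RB2", "RB3", "RB4")] <- -0.4
  V[c("RB1", "RB2", "RB3", "RB4"), c("L1", "L2")] <- -0.4
  diag(V) <- 1
  sm <- structure(list(taxa = taxa, values = V, n_pairs = 15),
                  class = "similarity_matrix")
  tt <- tag_tree(read_newick(text = "((L1,L2),(RB1,RB2),(RB3,RB4));"), sm)
  rep_l <- tt$reports[tt$reports$branch == "L1|L2", ]
  expect_equal(rep_l$kind, "internal")
  expect_equal(rep_l$score, -0.4)
  expect_true(rep_l$suspicious)
  rb <- tt$reports[tt$reports$branch == "RB1|RB2", ]
  expect_false(rb$suspicious)
})

test_that("taxon mismatches are handled per contract", {
  taxa <- c("A", "B", "C", "D", "E")
  sm <- rand_symmetric_matrix(taxa, 3)
  expect_error(tag_tree(read_newick(text = "((A,B),(C,Z));"), sm),
               "Z", class = "alignoise_input_error")
  # matrix taxa not in the tree: warning, scores use the remaining taxa
  expect_warning(tt <- tag_tree(read_newick(text = "((A,B),(C,D));"), sm), "E")
  expect_equal(nrow(tt$reports), 5L)  # 4 terminal + 1 internal
})

test_that("annotated newick round-trips with scores attached", {
  taxa <- c("A", "B", "C", "D")
  sm <- rand_symmetric_matrix(taxa, 11)
  tt <- tag_tree(read_newick(text = "((A:1,B:1):0.5,(C:1,D:1):0.5);"), sm)
  tsv <- tempfile(fileext = ".tsv"); nwk <- tempfile(fileext = ".nwk")
  write_branch_reports(tt, tsv)
  df <- read.delim(tsv)
  expect_equal(nrow(df), nrow(tt$reports))
  write_annotated_newick(tt, nwk)
  txt <- readLines(nwk)
  expect_equal(sum(gregexpr("\\[&R=", txt)[[1]] > 0), 4L)  # one per leaf
  reparsed <- ape::read.tree(text = gsub("\\[[^]]*\\]", "", txt))
  expect_setequal(reparsed$tip.label, taxa)
})
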