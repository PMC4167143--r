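test_that("simulation is deterministic and leaves the caller's RNG alone", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  a1 <- simulate_alignment(setup_a_tree(0.5), sim_model(), 300, seed = 42)
  after <- runif(1)
  expect_identical(before, after)  # caller stream untouched
  a2 <- simulate_alignment(setup_a_tree(0.5), sim_model(), 300, seed = 42)
  expect_identical(a1$residues, a2$residues)
  a3 <- simulate_alignment(setup_a_tree(0.5), sim_model(), 300, seed = 43)
  expect_false(identical(a1$residues, a3$residues))
})

test_that("degenerate inputs behave as contracted", {
  tree <- read_newick(text = "(a:0,b:0,(c:0,d:0):0);")
  a <- simulate_alignment(tree, sim_model(), 200, seed = 1)
  expect_true(all(a$residues == rep(a$residues[1, ], each = 4)))
  expect_error(sim_model(p_inv = 1), class = "alignoise_input_error")
  expect_error(sim_model(alpha_shape = 0), class = "alignoise_input_error")
  expect_error(simulate_alignment(tree, sim_model(), 0, seed = 1),
               class = "alignoise_input_error")
})

test_that("without indels the output length is exact", {
  a <- simulate_alignment(setup_b_tree(0.7), sim_model(), 1234, seed = 5)
  expect_equal(dim(a), c(6L, 1234L))
  expect_false(any(a$residues == "-"))
})

test_that("pairwise divergence matches the closed-form mixture expectation", {
  # two taxa, total path 0.5; rate mixture: invariant w.p. 0.3, else
  # Gamma(1). P(differ) = (1 - p_inv) * 3/4 * (1 - (1 + beta*d/alpha)^-alpha)
  d <- 0.5; alpha <- 1.0; p_inv <- 0.3; M <- 50000
  expected <- (1 - p_inv) * 0.75 * (1 - (1 + (4 / 3) * d / alpha)^(-alpha))
  tree <- read_newick(text = sprintf("(x:%g,y:%g);", d / 2, d / 2))
  a <- simulate_alignment(tree, sim_model(alpha_shape = alpha, p_inv = p_inv),
                          M, seed = 77)
  observed <- mean(a$residues[1, ] != a$residues[2, ])
  se <- sqrt(expected * (1 - expected) / M)
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("long branches converge to the stationary frequencies", {
  freqs <- c(0.35, 0.15, 0.35, 0.15)  # A C G T
  tree <- read_newick(text = "(x:25,y:25);")
  a <- simulate_alignment(tree, sim_model(freqs = freqs, p_inv = 0),
                          50000, seed = 13)
  counts <- table(factor(a$residues[1, ], levels = c("A", "C", "G", "T")))
  expect_gt(suppressWarnings(chisq.test(counts, p = freqs)$p.value), 0.001)
})

test_that("amino acid simulation uses the 20-state alphabet", {
  tree <- read_newick(text = "(x:1,y:1,z:1);")
  a <- simulate_alignment(tree, sim_model("amino_acid", p_inv = 0), 2000,
                          seed = 3)
  expect_equal(a$alphabet, "amino_acid")
  expect_gt(length(unique(as.vector(a$residues))), 15)
})

test_that("the indel process produces a consistent padded alignment", {
  m <- sim_model(ins_rate = 0.05, del_rate = 0.05, indel_max = 10)
  a <- simulate_alignment(setup_b_tree(0.9), m, 500, seed = 21)
  expect_true(all(nchar(apply(a$residues, 1, paste, collapse = "")) ==
                    ncol(a$residues)))
  expect_gt(sum(a$residues == "-"), 0)
  keys <- attr(a, "column_keys")
  expect_equal(length(keys), ncol(a$residues))
  expect_false(anyDuplicated(keys) > 0)
  # no all-gap columns: every column is observed in at least one leaf
  expect_true(all(colSums(a$residues != "-") >= 1))
  # determinism with indels on
  b <- simulate_alignment(setup_b_tree(0.9), m, 500, seed = 21)
  expect_identical(a$residues, b$residues)
})

test_that("grids enumerate cells deterministically", {
  g <- setup_grid("setupA", bl2_values = c(0.1, 0.9), replicates = 3,
                  length = 100, seed = 5)
  expect_equal(nrow(g$index), 6L)
  expect_length(g$alignments, 6L)
  expect_true(all(g$index$seed > 0 & g$index$seed < 2^31))
  expect_setequal(g$alignments[[1]]$taxa, c("L1", "S1", "L2", "S2"))
  g2 <- setup_grid("setupA", bl2_values = c(0.1, 0.9), replicates = 3,
                   length = 100, seed = 5)
  expect_identical(g$alignments[[4]]$residues, g2$alignments[[4]]$residues)
  gb <- setup_grid("setupB", bl2_values = 0.5, replicates = 1, length = 50,
                   seed = 2)
  expect_setequal(gb$alignments[[1]]$taxa,
                  c("L1", "L2", "RB1", "RB2", "RB3", "RB4"))
})

test_that("simulated FASTA carries a parameter sidecar", {
  m <- sim_model()
  a <- simulate_alignment(setup_a_tree(0.3), m, 80, seed = 9)
  f <- tempfile(fileext = ".fa")
  write_simulated_fasta(a, f, m, seed = 9)
  expect_true(file.exists(f))
  sidecar <- read.delim(paste0(f, ".params.tsv"))
  expect_equal(sidecar$value[sidecar$key == "seed"], "9")
  expect_identical(read_fasta(f)$residues, a$residues)
})
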