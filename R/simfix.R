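#' @title Sequence-evolution simulator
#' @name simfix
#' @description Generates alignments along a tree under an equal-
#'   exchangeability substitution model (Jukes-Cantor for nucleotides;
#'   F81-type with configurable stationary frequencies, covering the
#'   20-state amino acid case), with gamma-distributed among-site rate
#'   variation plus a proportion of invariant sites, and an optional
#'   simple indel process. Presets reproduce the 4-taxon and 6-taxon
#'   long-branch study designs at desk scale.
NULL

#' Simulation model
#'
#' Substitution follows an equal-exchangeability (F81-type) model: on a
#' branch of length `t` at site rate `r`, the state is kept with
#' probability `exp(-beta * t * r)` and otherwise redrawn from the
#' stationary frequencies, where `beta = 1 / (1 - sum(freqs^2))`
#' normalizes branch lengths to expected substitutions per site. With
#' uniform nucleotide frequencies this is exactly Jukes-Cantor. Site
#' rates are 0 with probability `p_inv`, else Gamma(`alpha_shape`) with
#' mean 1.
#'
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @param alpha_shape Gamma shape of among-site rate variation
#'   (default 1.0).
#' @param p_inv Proportion of invariant sites, in `[0, 1)` (default 0.3).
#' @param freqs Stationary state frequencies (default uniform over the
#'   canonical states).
#' @param ins_rate,del_rate Insertion/deletion events per site per unit
#'   branch length (default 0: no indels).
#' @param indel_max Maximum indel length; lengths are uniform on
#'   `1..indel_max` (default 20).
#' @return A `sim_model` list.
#' @export
sim_model <- function(alphabet = c("nucleotide", "amino_acid"),
                      alpha_shape = 1.0, p_inv = 0.3, freqs = NULL,
                      ins_rate = 0, del_rate = 0, indel_max = 20L) {
  alphabet <- match.arg(alphabet)
  states <- alphabet_spec(alphabet)$canonical
  if (is.null(freqs)) freqs <- rep(1 / length(states), length(states))
  if (length(freqs) != length(states) || any(freqs <= 0))
    abort_input("freqs must be %d positive values", length(states))
  freqs <- freqs / sum(freqs)
  if (alpha_shape <= 0) abort_input("alpha_shape must be positive")
  if (p_inv < 0 || p_inv >= 1) abort_input("p_inv must be in [0, 1)")
  if (ins_rate < 0 || del_rate < 0) abort_input("indel rates must be >= 0")
  structure(list(alphabet = alphabet, states = states, freqs = freqs,
                 alpha_shape = alpha_shape, p_inv = p_inv,
                 ins_rate = ins_rate, del_rate = del_rate,
                 indel_max = as.integer(indel_max)),
            class = "sim_model")
}

#' 4-taxon long-terminal-branch preset tree
#'
#' Two elongated, non directly related terminal branches (`L1`, `L2`, both
#' length `bl2`) with short sisters (`S1` at `bl3`, `S2` at `rb`) across a
#' very short internal branch `bl1`.
#'
#' @param bl2 Length of the two elongated terminal branches.
#' @param bl1 Internal branch length (default 0.01).
#' @param bl3,rb Short terminal branch lengths (default 0.1).
#' @return A `phylo` tree with tips `L1, S1, L2, S2`.
#' @export
setup_a_tree <- function(bl2, bl1 = 0.01, bl3 = 0.1, rb = 0.1) {
  read_newick(text = sprintf("((L1:%g,S1:%g):%g,L2:%g,S2:%g);",
                             bl2, bl3, bl1, bl2, rb))
}

#' 6-taxon long-internal-branch preset tree
#'
#' Two elongated internal branches (both `bl2`, the stems above the
#' `(L1,RB1)` and `(L2,RB2)` cherries) separated by a short internal
#' branch `bl1`; terminal branches constant (`L1`/`L2` at `bl3`, the rest
#' at `rb`).
#'
#' @param bl2 Length of the two elongated internal branches.
#' @param bl1 Central internal branch length (default 0.01).
#' @param bl3 Terminal branch length of `L1` and `L2` (default 0.01).
#' @param rb Remaining terminal branch lengths (default 0.1).
#' @return A `phylo` tree with tips `L1, L2, RB1..RB4`.
#' @export
setup_b_tree <- function(bl2, bl1 = 0.01, bl3 = 0.01, rb = 0.1) {
  read_newick(text = sprintf(
    "(((L1:%g,RB1:%g):%g,RB3:%g):%g,(L2:%g,RB2:%g):%g,RB4:%g);",
    bl3, rb, bl2, rb, bl1, bl3, rb, bl2, rb))
}

#' Simulate an alignment along a tree
#'
#' The root sequence is drawn from the stationary frequencies; each site
#' carries a rate multiplier (0 with probability `p_inv`, else
#' Gamma-distributed with mean 1) and evolves down every branch under the
#' model's transition probabilities for branch length x site rate. With
#' indels enabled, insertion and deletion events are placed along each
#' branch (Poisson with mean rate x length x current sequence length),
#' with lengths uniform on `1..indel_max`; the output is padded with gap
#' characters into a true alignment whose column homology is recorded.
#'
#' @param tree A `phylo` or a newick string.
#' @param model A [sim_model()].
#' @param length Root sequence length (sites).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return An `alignment`. When indels are on, attribute
#'   `"column_keys"` holds the homology key of every output column and
#'   `M` may exceed `length`; without indels `M == length` exactly.
#' @export
simulate_alignment <- function(tree, model = sim_model(), length = 1000L,
                               seed = 1L) {
  if (is.character(tree)) tree <- read_newick(text = tree)
  if (!inherits(tree, "phylo")) abort_input("tree must be a phylo or newick")
  if (length < 1L) abort_input("length must be >= 1")
  if (is.null(tree$edge.length)) abort_input("tree must have branch lengths")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)

  k <- length(model$states)
  beta <- 1 / (1 - sum(model$freqs^2))
  draw_rates <- function(m) {
    r <- rgamma(m, shape = model$alpha_shape, rate = model$alpha_shape)
    r[runif(m) < model$p_inv] <- 0
    r
  }
  n <- length(tree$tip.label)
  root <- n + 1L
  pre <- ape::reorder.phylo(tree, "cladewise")
  indels <- model$ins_rate > 0 || model$del_rate > 0

  M0 <- as.integer(length)
  root_states <- sample.int(k, M0, replace = TRUE, prob = model$freqs)
  root_rates <- draw_rates(M0)

  evolve <- function(states, rates, t) {
    m <- base::length(states)
    if (m == 0L || t <= 0) return(states)
    keep <- runif(m) < exp(-beta * t * rates)
    nres <- sum(!keep)
    if (nres) states[!keep] <- sample.int(k, nres, replace = TRUE,
                                          prob = model$freqs)
    states
  }

  if (!indels) {
    seqs <- vector("list", n + tree$Nnode)
    seqs[[root]] <- root_states
    for (r in seq_len(nrow(pre$edge))) {
      p <- pre$edge[r, 1L]; ch <- pre$edge[r, 2L]
      seqs[[ch]] <- evolve(seqs[[p]], root_rates, pre$edge.length[r])
    }
    res <- matrix("", n, M0)
    for (i in seq_len(n)) res[i, ] <- model$states[seqs[[i]]]
    return(new_alignment(tree$tip.label, res, model$alphabet))
  }

  # with indels: sequences carry per-site homology keys; a master key
  # order (grown by splicing at insertion points) defines output columns
  env <- new.env()
  env$master <- seq_len(M0)           # ordered column keys
  env$rates <- root_rates             # rate by key
  env$next_key <- M0 + 1L

  apply_indels <- function(states, keys, t) {
    m <- base::length(states)
    n_ins <- rpois(1L, model$ins_rate * t * m)
    n_del <- rpois(1L, model$del_rate * t * m)
    for (ev in sample(rep(c("I", "D"), c(n_ins, n_del)))) {
      m <- base::length(states)
      if (ev == "D") {
        if (m == 0L) next
        len <- sample.int(model$indel_max, 1L)
        at <- sample.int(m, 1L)
        drop <- at:min(m, at + len - 1L)
        states <- states[-drop]; keys <- keys[-drop]
      } else {
        len <- sample.int(model$indel_max, 1L)
        at <- if (m == 0L) 0L else sample.int(m + 1L, 1L) - 1L  # insert after position `at`
        new_keys <- seq.int(env$next_key, length.out = len)
        env$next_key <- env$next_key + len
        new_rates <- draw_rates(len)
        env$rates[new_keys] <- new_rates
        anchor <- if (at == 0L) 0L else match(keys[at], env$master)
        env$master <- append(env$master, new_keys, after = anchor)
        states <- append(states, sample.int(k, len, replace = TRUE,
                                            prob = model$freqs), after = at)
        keys <- append(keys, new_keys, after = at)
      }
    }
    list(states = states, keys = keys)
  }

  node_seq <- vector("list", n + tree$Nnode)
  node_seq[[root]] <- list(states = root_states, keys = seq_len(M0))
  for (r in seq_len(nrow(pre$edge))) {
    p <- pre$edge[r, 1L]; ch <- pre$edge[r, 2L]
    t <- pre$edge.length[r]
    cur <- node_seq[[p]]
    st <- evolve(cur$states, env$rates[cur$keys], t)
    node_seq[[ch]] <- apply_indels(st, cur$keys, t)
  }

  # keep only columns observed in at least one leaf
  leaf_keys <- unique(unlist(lapply(seq_len(n), function(i) node_seq[[i]]$keys)))
  cols <- env$master[env$master %in% leaf_keys]
  res <- matrix("-", n, base::length(cols))
  for (i in seq_len(n)) {
    s <- node_seq[[i]]
    res[i, match(s$keys, cols)] <- model$states[s$states]
  }
  aln <- new_alignment(tree$tip.label, res, model$alphabet)
  attr(aln, "column_keys") <- cols
  aln
}

# bounded deterministic per-cell seed (< 2^31)
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + index * 16807) %% 2147483647) + 1L
}

#' Simulate a grid of alignments over branch elongations
#'
#' One cell per (BL2 value, replicate), each simulated with a
#' deterministic seed derived from the master seed, reproducing the
#' long-branch study grids at configurable scale.
#'
#' @param preset `"setupA"` (4 taxa, elongated terminals) or `"setupB"`
#'   (6 taxa, elongated internals).
#' @param bl2_values Branch elongation grid (default the study grid
#'   `seq(0.1, 1.5, by = 0.2)`).
#' @param replicates Alignments per grid point (default 10).
#' @param length Sites per alignment (default 5000).
#' @param seed Master seed.
#' @param model A [sim_model()] (default nucleotide, `alpha_shape = 1`,
#'   `p_inv = 0.3`, no indels — the study conditions).
#' @param ... Extra arguments to the preset tree builder (`bl1`, `bl3`,
#'   `rb`).
#' @return A list with `index` (data frame: `bl2`, `replicate`, `seed`)
#'   and `alignments` (list, same row order).
#' @export
setup_grid <- function(preset = c("setupA", "setupB"),
                       bl2_values = seq(0.1, 1.5, by = 0.2),
                       replicates = 10L, length = 5000L, seed = 1L,
                       model = sim_model(), ...) {
  preset <- match.arg(preset)
  builder <- if (preset == "setupA") setup_a_tree else setup_b_tree
  index <- expand.grid(replicate = seq_len(replicates), bl2 = bl2_values)
  index <- index[, c("bl2", "replicate")]
  index$seed <- derive_seed(seed, seq_len(nrow(index)))
  alignments <- lapply(seq_len(nrow(index)), function(r) {
    simulate_alignment(builder(index$bl2[r], ...), model, length,
                       seed = index$seed[r])
  })
  list(index = index, alignments = alignments)
}

#' Write an alignment with a simulation-parameter sidecar
#'
#' Emits aligned FASTA plus `<path>.params.tsv` holding the model
#' parameters and seed.
#'
#' @param aln Alignment from [simulate_alignment()].
#' @param path FASTA output path.
#' @param model,seed The simulation settings to record.
#' @return `path`, invisibly.
#' @export
write_simulated_fasta <- function(aln, path, model, seed) {
  write_fasta(aln, path)
  df <- data.frame(
    key = c("alphabet", "alpha_shape", "p_inv", "ins_rate", "del_rate",
            "indel_max", "seed", "n_taxa", "n_sites"),
    value = c(model$alphabet, model$alpha_shape, model$p_inv, model$ins_rate,
              model$del_rate, model$indel_max, seed, base::length(aln$taxa),
              ncol(aln$residues)))
  write.table(df, paste0(path, ".params.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
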