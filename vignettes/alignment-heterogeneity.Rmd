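---
title: "Detecting heterogeneous sequence divergence and inflated branch support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting heterogeneous sequence divergence and inflated branch support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alignoise)
```

## The problem

Alignment masking tools (Gblocks, trimAl, BMGE and relatives) remove whole
columns of a multiple sequence alignment, so they are largely blind to
*taxonomically* heterogeneous signal: a single saturated or misaligned
sequence degrades every pairwise comparison it participates in while most
columns still look acceptable. Such sequences are exactly the ones that
produce long-branch attraction and confidently supported but wrong nodes.
`alignoise` targets this failure mode: it quantifies, for **every pair** of
sequences, how much of their alignment looks like non-random similarity and
how much is indistinguishable from noise, and then projects those pairwise
scores onto a tree to ask whether each branch is actually supported by
pairwise signal.

## The statistic

For a pair of aligned sequences \(X, Y\) and a window of \(w\) consecutive
sites, the observed window score is the sum of per-site scores
(match/mismatch \(\pm 1\) for nucleotides; BLOSUM62, PAM250 or PAM500 for
amino acids). The null model asks: *could a score this good arise from the
local composition alone?* Each permutation resamples, independently for
\(X\) and \(Y\), \(w\) residues uniformly with replacement from that
sequence's residues inside the window extended by a flank of \(f\) columns
on each side, and scores the synthetic window. The window votes \(+1\) iff
the observed score is strictly better than at least \(1-\alpha\) of the
permutation scores, else \(-1\). Every site accumulates the votes of the
windows covering it; sums are divided by \(w\), giving a per-site profile
in \([-1, 1]\).

The pair similarity \(S_{XY}\) is the arithmetic mean of the profile over
all sites that are not **globally invariant** (columns where every taxon
carries the identical canonical state; any ambiguity code makes a column
variable, as does a gap under ambiguous gap handling). Two iid random
sequences give \(S \approx \alpha - (1 - \alpha) = -0.9\) at
\(\alpha = 0.05\); identical, compositionally diverse sequences give
\(S \to +1\).

Given a guide tree, terminal branches are tagged with
\(R_A = \frac{1}{N-1}\sum_{Y \neq A} S_{AY}\) and each internal branch with
the mean of \(S_{XY}\) over all pairs crossing its bipartition
(within-side pairs excluded). A branch is *suspicious* iff \(R < 0\):
the split rests on similarity indistinguishable from random, regardless of
its bootstrap value. Pairwise scores are treated as independent replicates
in these means; they are not strictly independent when some taxa are close
relatives, and no covariance correction is attempted.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `window_size` (w) | 6 sites | width of the sliding window (step fixed at 1) |
| `flank` (f) | `w` | columns of neighbourhood on each side of the window feeding the resampling pools |
| `n_permutations` | 100 | Monte Carlo samples per window; must be \(\ge 1/\alpha\) so the criterion is resolvable |
| `alpha` | 0.05 | window-level significance; the observed score must strictly beat \(1-\alpha\) of the nulls |
| `seed` | 1 | master seed; each (pair, window) derives its own stream |
| `gap_mode` | `fifth_state` | gap as a matchable fifth state, or `ambiguous` (`-N`): gaps contribute 0 |
| match / mismatch | +1 / −1 | symmetric by design so constant-signal and constant-noise windows are mirror images; configurable |

The window size, flank and permutation count are genuinely open design
choices: the window test is inherited from a sliding-window masking
tradition whose published descriptions do not fix them numerically. We
default to a local neighbourhood (3\(w\) columns of pool per sequence) and
100 permutations, the smallest round count at which the 95% criterion is
meaningful with some resolution; the package's property tests validate the
defaults against monotonicity and oracle-agreement criteria rather than
against any particular binary.

## Numerical and tie-breaking choices

* **Ties count against significance.** A window whose observed score merely
  equals the permutation scores votes −1. This makes single-state
  (constant) windows vote −1 — "indistinguishable from random" — and is the
  conservative reading of *strictly better than 95%*.
* **Edge normalization.** Sites near the alignment ends are covered by
  fewer than \(w\) windows but are still divided by \(w\), so
  \(|v| \le k/w\) there. This follows the normalize-by-window-size rule
  verbatim; `edge_normalize = "coverage"` divides by the covering-window
  count instead.
* **Resampling is per-sequence, with replacement.** Pools are built
  independently for each sequence from its own window-plus-flank residues.
  This conditions the test on each sequence's local composition, which is
  the property the null is meant to preserve. Neutral residues stay in the
  pools and contribute 0 wherever drawn, keeping observed and null scores
  on the same scale.
* **Reproducible streams.** The engine seeds an xorshift128+ generator per
  (pair, window) from a splitmix64 hash of (master seed, canonical pair
  index, window start). Profiles are therefore exactly symmetric in the
  pair, independent of evaluation order, and byte-identical between serial
  and parallel runs.
* **Degenerate pairs** (no non-invariant site, e.g. two identical
  sequences alone) are reported as missing values with a warning, never as
  silent zeros; renders show them grey.
* **The diagonal is displayed as +1** by convention and excluded from all
  statistics — the test is meaningless for a self-comparison.
* **Gap contract under matrix scoring.** BLOSUM/PAM tables carry no gap
  row; under fifth-state coding gap-vs-gap scores `match_score` and
  gap-vs-residue scores `gap_penalty` (default `mismatch_score`), mirroring
  the nucleotide fifth-state contract.
* **PAM500** is not shipped by standard toolkits; the package generates it
  from the Dayhoff rate model by matrix exponentiation (1 PAM = 1%
  expected substitutions; scores \(= \mathrm{round}(10 \log_{10}
  P_{ab}(n)/f_b)\)). The same generator reproduces the published PAM250 to
  within rounding, which the test suite checks.

## The simulator

`simulate_alignment()` evolves sequences along a tree under an
equal-exchangeability (F81-type) model — exactly Jukes–Cantor for uniform
nucleotide frequencies — with among-site rate variation drawn from a
continuous \(\Gamma(\alpha)\) (mean 1) plus a proportion \(\rho_{inv}\) of
invariant sites. Defaults (\(\alpha = 1.0\), \(\rho_{inv} = 0.3\), no
indels) are the conditions of the long-branch simulation designs the
package reproduces:

* **`setup_a_tree(bl2)`** — 4 taxa, two elongated, non directly related
  terminal branches `L1`, `L2` (length BL2 over the grid 0.1–1.5), short
  sisters `S1`, `S2`, and a very short internal branch (0.01).
* **`setup_b_tree(bl2)`** — 6 taxa; two elongated *internal* branches (the
  stems above the `(L1,RB1)` and `(L2,RB2)` cherries) separated by a short
  internal branch. The figure defining this topology is only described
  verbally; we chose the arrangement in which the two long internal
  branches are separated by the short central branch and `L1`, `L2` are
  paraphyletic with respect to the remaining taxa, so that long-branch
  attraction would wrongly join them.

`setup_grid()` runs a (BL2 × replicate) grid with per-cell seeds derived
deterministically from the master seed. The package's acceptance checks
use desk-scale grids — 5,000 sites and 10 replicates per grid point —
rather than the original design's 250,000 sites and 100 replicates; the
monotone decay of \(S_{L1,L2}\) with BL2 is already unambiguous at this
size (Spearman \(\rho = -1\) in our runs).

The optional indel process places Poisson-distributed insertion and
deletion events per branch (rate × branch length × current length) with
lengths uniform on \(1..\texttt{indel\_max}\), tracking true column
homology. Two deliberate simplifications: indel lengths are uniform rather
than following a heavy-tailed (Lavalette-type) law, and amino acid
simulation uses equal exchangeabilities rather than an empirical matrix —
the properties the tests rely on (presence of misalignable gaps;
qualitative saturation) do not depend on either refinement.

**What passing tests do and do not show.** The simulator emulates
saturation-driven loss of pairwise signal under rate heterogeneity. It does
not emulate alignment error from realignment, compositional
heterogeneity across lineages, or site-specific selective constraint, so
good behaviour here does not guarantee calibrated verdicts on real data —
the method remains a descriptive screen, not a test with nominal error
rates.

## Limitations

* The window verdict is a fixed-level Monte Carlo test applied to many
  overlapping windows; profile values are strongly autocorrelated and the
  pair mean \(S_{XY}\) has no simple sampling distribution. Interpret
  magnitudes comparatively (within one matrix), not as probabilities.
* Cross-split means treat pairs as independent replicates (see above).
* Branch tagging never *confirms* a branch: positive scores mean the
  underlying pairwise similarity is non-random, not that the split is
  correct. In our simulations the tagger is optimistic — wrong but
  weakly-saturated placements can go untagged — mirroring the behaviour of
  the approach it implements.
* Amino acid data saturate much later under matrix scoring; strongly
  divergent protein sequences may keep positive scores even when
  misplaced.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes, from scratch
with the given seed: the 61-taxon pair count (1830), the five-partition
supermatrix length (5082), the Monte Carlo vs exhaustive-enumeration
verdict agreement (≥ 99%), the random-pair and identical-pair similarity
levels, the setup-A Spearman rho, the brute-force tree-tagging check, and
serial/parallel determinism. Problem sizes are the desk-scale defaults
stated above.
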