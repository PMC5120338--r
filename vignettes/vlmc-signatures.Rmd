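---
title: "Alignment-free sample comparison with variable-length Markov chain signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free sample comparison with variable-length Markov chain signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlmcsig)
```

## The problem

Comparing transcriptomic or metatranscriptomic sequencing samples by
alignment is expensive and fails outright when most reads come from
organisms without reference genomes.  Alignment-free methods instead
summarise each sample by its *k*-tuple (k-mer) frequency vector and
compare samples through dissimilarities on those vectors.  Raw k-tuple
counts, however, are dominated by the nucleotide composition of the
underlying community; the informative part is the *deviation* of the
observed counts from what a background model of the community's sequence
composition predicts.  This package models that background either with a
fixed-order Markov chain (FOMC) or with a variable-length Markov chain
(VLMC) whose memory length adapts to the data, and builds the
background-normalised dissimilarities d2S and d2* on the centered
counts.

## Counting

`count_tuples()` slides windows of every length `1..max_k` over each
read and, by default, its reverse complement, so that the signature is
strand-symmetric (`count(w) == count(reverse_complement(w))` exactly).
Windows containing any character outside A/C/G/T contribute nothing —
skipping is deterministic, unlike randomised base assignment — and input
is case-insensitive with U read as T so RNA-coded reads work unchanged.
Counts are held sparsely per length (only observed tuples); dense
`4^k` vectors are materialised per requested `k` by
`frequency_vector()`.  The default `max_k = 11` exists to serve a
context tree of depth 10: a depth-`d` context needs length-`(d+1)`
extension counts for its transition probabilities, which is also why the
pipeline enforces `k <= max_depth - 1` for background-normalised
measures.

## Background models

### Fixed order

An order-`r` chain (`fomc()`) estimates each transition as the
extension-count ratio `P(x|w) = count(wx) / sum_y count(wy)`.  Contexts
never observed with an extension receive the uniform transition so
probabilities stay defined; such contexts can only be reached by tuples
whose own probability is zero or near-zero, so the convention is
inconsequential in practice but keeps every quantity finite.

Tuple probabilities are computed by the chain rule with *increasing*
order at the start: position `i <= r` conditions on the full available
history using the order-`(i-1)` empirical transitions, after which the
fixed order-`r` transitions take over.  The alternative — starting from
the empirical r-tuple frequency — disagrees with the chain product at
order `1/read_length`, because end-of-read windows break the telescoping
between r-tuple counts and extension totals.  With the chain-rule
convention the order-`r` model is *exactly* the depth-`r` truncation of
the context-tree family, a relationship the test suite asserts to
1e-12, and every `4^k` probability profile sums to 1 by construction.
The empirical r-tuple distribution is still stored on the model (it
seeds `simulate()`); only the probability queries use the chain-rule
start.

With 4 nucleotide states an order-`r` chain has `4^r * 3` free
transition parameters — 48 at `r = 2`, 192 at `r = 3` — so fixed-order
models can only grow in factor-of-4 jumps, which is the motivation for
letting the data choose variable context lengths.

### Variable length

`vlmc()` proceeds in three steps.

1. **Full prefix tree** (`build_prefix_tree()`): one node per observed
   tuple of length `1..max_depth` (children of context `w` are the
   one-character-*longer* contexts `uw`; the parent of a context is its
   one-shorter suffix, so the tree is prefix-closed upward by the
   containment of occurrences).  Node transitions are extension-count
   ratios as above; the root carries the single-nucleotide frequencies.
   `min_count` defaults to 1 — the full observed tree — and is exposed
   for denoising very deep trees.

2. **KL pruning** (`prune_tree()`): each non-root node carries the
   count-weighted Kullback–Leibler statistic
   `delta(uw) = N(uw) * sum_x P(x|uw) log(P(x|uw) / P(x|w))`
   (natural logarithm; `0 log 0 = 0`; `N(uw)` is the node's transition
   total).  Because `count(wx) >= count(uwx)` on self-consistent counts,
   a zero in the parent forces a zero in the child and the statistic is
   always finite; nodes with `N = 0` are defined to have `delta = 0`.
   Pruning is greedy and bottom-up: in each sweep every *current
   terminal* node (no children left in the tree, not merely
   depth-equals-max) with `delta < K` is removed, and sweeps repeat to a
   fixed point, enabling multi-level pruning.  `K = 0` removes nothing;
   `K = Inf` leaves only the root, whose probabilities are the i.i.d.
   single-nucleotide product.  The greedy result need not be globally
   optimal; exact dynamic-programming tree selection is out of scope.

3. **Probability queries** (`tuple_probability()`,
   `probability_profile()`): each position conditions on the *longest
   suffix* of its preceding bases that is still a node of the pruned
   tree.  This is an autoregressive factorisation, so the `4^k` profile
   sums to 1 for every pruned tree.

### Choosing the pruning threshold

The read-based AIC is `-2 * logPL + 2 * 3 * card(tree)`, where `card`
counts non-root nodes (3 free parameters each) and `logPL` is the log
pseudo-likelihood: the sum over reads and positions of the log
transition probability of each base given its longest-suffix context.
The first base of a read contributes no term; reads are split at
ambiguous characters, and the conditioning history never crosses a
split.  Forward-strand reads as written enter the likelihood, while the
model itself is fitted from double-stranded counts; both choices are
configurable.  Natural logarithms are used throughout — the AIC
convention — and `logLik()`/`AIC()` methods expose the same quantities
through the standard S3 generics.

No closed form links `K` to the AIC, so `select_threshold()` does a
local search: it estimates the density of all per-node KL statistics
with a Gaussian kernel (normal-reference bandwidth), anchors the search
at the highest density peak and the first two inflexion points to its
right (sign changes of the numerically differentiated second
derivative; missing inflexions fall back to doublings of the peak), lays
a 7-point grid spanning ±25% around each anchor, adds `K = 0`, and
returns the candidate minimising the AIC with ties broken toward the
smaller `K` (the simpler, smaller tree).  Grid size and span are
exposed; the defaults reflect that the AIC surface is smooth in `K`
between consecutive distinct statistics.  Trees with fewer than 10 nodes
skip the density machinery and scan all distinct statistics
exhaustively.  `plot()` on an auto-fitted model shows the density, the
anchors and the AIC over the candidates.

Two properties of this selector are worth knowing.  On data with genuine
low-order structure (e.g. an order-1 chain with `P(x|x) = 0.7`), the
depth-1 statistics are orders of magnitude above the noise, the selected
`K` lands between the two scales, and the fitted tree keeps exactly the
depth-1 contexts while pruning essentially all deeper ones — the test
suite checks transition recovery to 0.02 and >= 95% deep pruning.  On
featureless i.i.d. data, however, AIC minimisation never yields a tiny
tree: pruning a node pays off only when `delta < 3`, and among thousands
of candidate nodes the chi-square tail always leaves a crowd of deep
noise nodes.  The probabilities those extra nodes produce remain close
to the i.i.d. product; the tree is just larger than a hand-built model
would be.

## Dissimilarities

`center_counts()` forms `C~_i = C_i - N * P_i` with `P_i` from the
sample's own fitted background (own-sample backgrounds follow from the
definition of the measures; a foreign background is allowed for
exploration and triggers a warning, not an error).  On the centered
vectors:

* `d2s()` — self-standardised: terms `C~_X C~_Y / sqrt(C~_X^2 + C~_Y^2)`,
  normalised by the Cauchy–Schwarz bound and mapped to [0, 1] as
  `(1 - cor)/2`.  `0/0` terms (tuple unobserved and expected nowhere)
  are defined as 0, the limit of vanishing counts.
* `d2star()` — expectation-standardised: denominators
  `sqrt(N_X P_X,i) * sqrt(N_Y P_Y,i)`.  A tuple with zero expectation
  but non-zero centered count is a hard error (the model contradicts the
  data it supposedly fitted); zero-expectation tuples with zero centered
  counts are skipped.
* `d2()` — the cosine form of the classical count-correlation statistic,
  mapped to [0, 1] like the others so results tabulate together.
* `lp_dissimilarity()` — L1 (Ma), L2 (Eu), L-infinity (Ch) on
  frequency-normalised vectors `C/N`; frequencies rather than raw counts
  make samples of unequal sequencing depth comparable.

All three normalised measures are symmetric, zero on identical input and
bounded in [0, 1]; the suite fuzzes these contracts over 1000 randomised
count/model pairs.  `dissimilarity_matrix()` assembles the symmetric
zero-diagonal matrix for any measure at any `k` (the pipeline exposes
`k = 2..9`, the range where these signatures are typically informative;
the functions accept any `k`).

## Clustering and tree comparison

`upgma()` delegates to average-linkage `stats::hclust()` — which *is*
unweighted pair-group averaging of the original distances — after
ordering labels lexicographically so equal-distance ties resolve
deterministically; merge heights are half the mean cross-pair
dissimilarity and the output is ultrametric.  It is validated against
hand-computed 3- and 4-leaf examples and against an independent
implementation on random matrices.

`triples_distance()` categorises every 3-leaf subset by which pair
coalesces below the triplet's deepest coalescence — or as *unresolved*
when all three meet at one multifurcating node — and counts
disagreements; a resolved-vs-unresolved disagreement counts.  The
implementation uses one MRCA-depth table per tree; an independent oracle
that prunes each tree to every triplet validates it on random tree
pairs.  Note that a binary clustering tree compared against a polytomous
reference can never reach distance 0: every triplet inside a reference
polytomy is unresolved there and resolved in the binary tree.
Group-structure recovery should therefore be read off clade membership
(are the group's samples a clade?) rather than raw triples distance.
`symmetric_difference()` counts clades present in exactly one tree.
`random_tree_null()` calibrates an observed distance against random
sequentially-joined trees (uniform pair choice, seeded) with the add-one
permutation p-value — the reference tools report only bounds like
"p < 0.001", so the estimator choice is ours.

## The community simulator

`simulate_experiment()` emulates a benchmark differential-expression
design: a mock catalog of `n_genomes x genes_per_genome` random gene
sequences; a basic fold-change vector with exactly 20% of genes at fold
4, 20% at fold 1/4 and 60% at 1; group centers perturbing that vector by
`exp(Normal(0, sigma_group^2))` per gene; per-sample vectors perturbing
their center by `exp(Normal(0, sigma_sample^2))`; per-gene read counts
as `round(NegBin(mean = nb_mean, size = nb_dispersion) * expression)`;
and error-free 76 bp substrings at uniform positions and strands.
Everything derives deterministically from one master seed.

Parameter choices where the reference design is silent:

* `sigma_group = 0.3`, `sigma_sample = 0.1` — separable but overlapping
  groups: between-group variation three times the within-group
  replicate noise on the log scale.
* `nb_dispersion = nb_mean / 3` — the default of the RNA-seq simulator
  this design emulates; it keeps the depth coefficient of variation at
  2 per sqrt(mean) instead of letting overdispersion grow quadratically
  with depth.
* Gene lengths uniform on 200–1500 bp (typical bacterial transcripts)
  and per-genome GC evenly spaced over 0.35–0.65, mirroring the
  compositional spread of gut-bacterial genomes so genome-level
  signatures differ.

What the generator does **not** emulate: sequencing error, real gene
homology and codon-usage structure (genes are i.i.d. random sequences at
a genome-specific GC), rRNA contamination, and library-preparation
biases.  The codon-usage point matters for interpreting results below.

## Known limitations

**Deep backgrounds on small synthetic catalogs absorb the signal.**  A
catalog of 500 random genes is about 0.4 Mb; at a few-fold read
coverage, most depth-7 contexts occur at essentially unique catalog
positions, their next-base distributions are nearly deterministic, and
the read-based AIC — correctly, from a pure prediction standpoint —
retains most of the full tree.  Such a background reproduces the
sample's own k-tuple profile almost exactly, the centered counts reduce
to sampling noise, and between-sample structure disappears from d2S.
The package's test suite demonstrates both sides at the reduced
benchmark scale (3 groups x 5 samples, 500 genes, mean depth 50): a
fixed-order background recovers all three expression groups as clades,
while the AIC-selected VLMC background does not.  Real transcriptomes
are different in exactly the relevant way: shared codon usage and
homology make deep contexts recur across many positions, their
transition distributions stay mixed, pruning bites, and the selected
tree is far smaller than the saturated one.  VLMC backgrounds should
therefore be used on genuinely diverse communities, and results on
max-entropy synthetic catalogs read as a stress test of the worst case.
Against heterogeneous whole-genome (metagenomic) data the adaptive
background is similarly reported to lose its edge; the method targets
expressed sequence.

**In-sample AIC.**  The pseudo-likelihood is evaluated on the same reads
the model was fitted from; at high coverage, overlapping reads multiply
the effective evidence for deep contexts.  A held-out or
coverage-deflated criterion would prune more aggressively; the read-based
AIC is kept because it is the method's definition.

## Problem sizes used by the tests

The test suite and the acceptance script keep inputs small by design:
oracle comparisons use reads of tens of bases at `k <= 4`; model
equivalence and normalisation checks use ~1e4-base read sets; chain
recovery uses 1e5 bases at depth 10; and the end-to-end community runs
use 500-gene catalogs at mean depth 50 with context depth 7.  These
sizes exercise every code path; the implementation itself is vectorised
over integer-coded tuples and handles depth-10 trees from millions of
bases.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_experiment(n_genomes = 5, genes_per_genome = 100,
                           n_groups = 3, samples_per_group = 5,
                           nb_mean = 50, seed = 1)
res <- run_pipeline(list(samples = sim$samples, k = 6,
                         measures = "d2s", models = "fomc:1",
                         max_depth = 7))
res$results
plot(upgma(res$matrices[[1]]))
```
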