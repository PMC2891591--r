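---
title: "Detecting conserved RNA helices in fixed alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved RNA helices in fixed alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(transat)
```

## The problem

A functional RNA molecule folds into base-paired helices, and selection
preserves the *pairing* far longer than it preserves the underlying
sequence: when one side of a pair mutates, a compensatory mutation on the
other side restores a canonical pair (AU, UA, GC, CG, GU, UG). Given a
fixed multiple alignment of homologous RNA sequences and a rooted
phylogenetic tree with branch lengths, `transat` asks, for every candidate
helix: *do these column pairs evolve like base-paired positions or like
independent unpaired positions?* Because each helix is scored on its own
rather than as part of one globally consistent secondary structure, the
method can report transient, alternative and pseudoknotted helices that
single-structure prediction is forced to discard.

## Candidate helices

Every aligned sequence is stripped of its gaps and scanned for maximal runs
of at least 4 consecutive canonical pairs whose innermost pair encloses at
least 3 unpaired nucleotides. Runs of complementary positions lie along
anti-diagonals of the pairing matrix, so a single linear sweep per diagonal
finds all maximal stacks. The positions of each stack are then projected
back onto alignment columns through the sequence's gap pattern; stacks from
different sequences that land on exactly the same set of column pairs are
merged, and the number of sequences proposing a helix is reported as its
`support`.

```{r enumerate}
enumerate_sequence_helices("GGGGAAAACCCC")
```

## Phylogenetic score

Two reversible continuous-time Markov models drive the scoring: a 4-state
nucleotide model for unpaired columns and a 16-state dinucleotide model for
column pairs, whose equilibrium concentrates on the six canonical pairs and
whose rates favour compensatory double substitutions between canonical
pairs. Felsenstein's pruning algorithm computes, for a helix $h$ with
column pairs $(i_1,j_1),\dots,(i_L,j_L)$, the length-normalised
log-likelihood ratio

$$ S(h) = \frac{1}{L}\sum_{k=1}^{L}\Big[\log P_\text{paired}(i_k, j_k)
   - \log P_\text{unpaired}(i_k) - \log P_\text{unpaired}(j_k)\Big], $$

with natural logarithms. A positive score means the joint dinucleotide
model explains the two columns better than independent evolution does --
the statistical footprint of covariation.

Gaps are treated as missing data: a gap in an unpaired column contributes a
vector of ones; a two-sided gap at a column pair likewise; a one-sided gap
(or an N opposite an observed base) restricts the 16 states to the
*non-canonical* states that share the observed base, encoding the
observation that the partner of a deleted position is itself unpaired.

Transition matrices $P(t) = e^{Qt}$ are computed by spectral decomposition
of the symmetrised rate matrix (exact for reversible models) and memoised
per branch length; pruning is vectorised over columns with per-column
scaling so long branches and many columns stay numerically stable.

## Empirical null and p-values

A raw score has no natural scale, so significance comes from an empirical
null: the alignment's columns are shuffled uniformly at random *within
bins* of equal gap count and primary-sequence conservation decile. This
destroys covariation while preserving the gap structure, base composition
and conservation profile that also inflate scores. Helices are re-detected
and re-scored in each of `shuffles` (default 500) shuffled alignments and
all null scores are pooled. The right-tail p-value of an observed score $s$
is the add-one estimator $p = (\#\{s_\text{null} \ge s\} + 1)/(n+1)$,
which can never return 0 and is conservative at the resolution limit of
the null. P-values of overlapping helices are positively correlated --
they share columns -- so they are well calibrated marginally but not
jointly independent.

An optional hook (`realign_cmd`) can re-align the gap-stripped sequences
with an external sequence-only aligner before shuffling, so that
structure-informed gap placement cannot leak into the null; it is off by
default.

## Worked example on simulated data

The package ships a simulator used for validation: a random nested
structure, a maximally balanced binary tree with equal branch lengths, and
root-to-leaf propagation under the same substitution models (paired
positions evolve jointly as one 16-state site; there is no indel process).

```{r example}
models <- load_default_models()
st <- random_structure(120)
sim <- evolve_alignment(st, n_seqs = 10, total_tree_length = 4,
                        models = models, seed = 7)
fit <- transat_predict(sim$alignment, sim$tree, models,
                       shuffles = 100, seed = 42)
fit
head(tidy(fit)[, c("helix", "length", "support", "score", "p_value")])
glance(fit)
```

Evaluation against the generating structure uses the union of known and
predicted base pairs as the universe, and a helix counts as recovered when
at least 70% of its pairs are true pairs:

```{r evaluate}
compute_metrics(classify_helices(tidy(fit), sim$structure, p_hat = 0.05))
```

```{r arcplot, fig.width = 7, fig.height = 3}
autoplot(fit)  # known pairs arc above the axis, novel significant below
```

## Benchmark design

`artificial_dataset_driver()` reproduces the simulation design used to
study the method's operating range: 10 sequences per alignment, sequence
lengths drawn from nine bins (100-199 up to 900-999), total tree lengths
0.5, 1, 2, 4, 8 and 16. The *tree experiment* evolves 10 structures per
bin at all six tree lengths (540 alignments), the *length experiment* 50
structures per bin at tree length 4 (450 alignments), 990 alignments in
total. Detection is near-perfect at tree length 4 and degrades toward
tree length 0.5, where few substitutions -- and hence few compensatory
pairs -- have accumulated: conservation alone carries no pairing signal.

## Substitution models shipped with the package

The original method used rate matrices estimated from curated rRNA
alignments; those numeric matrices are not available here, so the package
ships *constructed stand-ins* (`inst/extdata/models/*_synthetic.txt`,
plain text): a GTR-style 4-state model with transition/transversion ratio
4, and a 16-state model placing 92% of equilibrium mass on canonical
pairs with elevated exchangeability between canonical pairs (compensatory
double substitutions) and strongly reduced rates for other double
substitutions. Both are reversible, and both are scaled to one expected
event per site per unit branch length, which fixes the unit of all branch
lengths. Any file pair matching `unpaired*.txt` / `paired*.txt` in a
directory passed to `load_default_models()` can replace them; detailed
balance and row sums are validated on load.

## Limitations

* The alignment and tree are taken as fixed and error-free; alignment
  errors masquerade as covariation.
* The simulator has no indel process and no structure-aware alignment
  step, so benchmark alignments are easier than curated real ones.
* Helix scores assume columns outside the helix are independent; the
  p-values of overlapping helices are correlated.
* With the default 500 shuffles, the smallest attainable p-value is
  bounded by the pooled null size; rare-helix alignments give coarse
  p-values (a warning is raised below 1000 pooled scores).
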