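---
title: "Selection stability: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection stability: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
what the procedures assume, which knobs matter, what the synthetic data can
and cannot show, and where the design was genuinely open — and why we chose
what we chose.

## The problem

Expression studies produce *p ≫ n* information systems: each sample is a
vector of thousands of gene expression values with one class label. Two
distinct selection goals must be kept apart. *Minimal-optimal* selection
seeks the smallest gene set maximising a classifier's accuracy; it greedily
collapses blocks of redundant genes and inherits the classifier's biases.
*All-relevant* selection seeks every gene carrying information about the
class, including redundant ones — the goal that supports mechanistic
interpretation. In p ≫ n data, false associations as strong as true ones
arise by chance, so both kinds of selector return some chance correlates,
and a single run on the full data cannot reveal which selections are
trustworthy. The package's answer is resampling: run the selector on B
bootstrap resamples and ask which genes are selected more consistently than
an exchangeable-selection null allows.

## The self-consistency statistic

Given a B × p selection indicator, let p̂ be its grand mean (the mean
fraction of genes selected). Under the null that the method distributes its
selections interchangeably over genes, each gene's selection count is
Binomial(B, p̂). Each gene gets the exact upper-tail p-value
P(X ≥ count); the Holm–Bonferroni step-down at α = 0.01 across all p genes
controls the family-wise error. Rejected genes form the *significantly
self-consistent selections* (SCS). Reports give c (mean per-iteration count
of selected genes that are SCS), f (mean per-iteration count of selected
genes), and c/f ∈ [0, 1].

Numerical notes, all unit-tested against independent oracles:

* The binomial tail is exact (no normal approximation), which is
  well-defined and conservative at B = 30.
* Only the upper tail is tested: under-selection is not evidence of
  inconsistency.
* p̂ pooled over the whole matrix equals the mean of per-iteration selected
  fractions (rows have equal length), so no switch between the two is
  needed.
* Degenerate matrices behave sensibly: all-false gives p̂ = 0 and an empty
  SCS; all-true gives p̂ = 1, every tail probability 1, and an empty SCS.
* c is computed per iteration and averaged, which is why reported c values
  are fractional.

The family-wise error control is verified by simulation on i.i.d.
Bernoulli(q) selection matrices (the `generate_null_selection_matrix()`
oracle) at q ∈ {0.01, 0.1, 0.5}, B = 30, p = 2000.

## Importance sources

Both providers satisfy one contract — `f(dataset, seed)` returns one finite
score per gene, higher = more important — so selectors and sources compose
freely.

**Random Ferns.** A depth-D fern applies the same D random (gene,
threshold) tests to every sample, partitioning it into 2^D leaves that hold
additively smoothed class-probability vectors of the in-bag samples; the
ensemble votes by summed log probabilities (maximum a posteriori, ties to
the lowest class index). Importance of a gene is the mean, over ferns using
it, of the drop in out-of-bag correct-class *probability* when the gene's
values are permuted within that fern's OOB set. Choices:

* *Probability scale, not log.* The measure is defined as a difference of
  correct-class probabilities; probabilities also keep every per-sample
  contribution bounded in [−1, 1], whereas log contributions explode when a
  permutation routes an OOB sample to a near-zero-probability leaf.
* *Laplace +1 smoothing* of leaf class counts avoids log 0 in voting and is
  the conventional fern practice.
* *Full-size bootstrap bags per fern*, so OOB sets are well-defined; one
  permutation per (fern, gene) pair, seeds derived from the run seed.
* *Depth D* (default 5, range 1–7 in practice) trades bias for variance:
  2^D leaves must stay populated from n in-bag samples. *Ensemble size K*
  (default 5000 for importance use) controls score stability; tests assert
  that variance of a planted gene's score falls as K grows.
* A gene used in no fern scores exactly 0; a constant gene contributes
  exactly 0; ferns with empty OOB sets are skipped.

**CART forest.** A bagged forest of Gini-impurity CART trees with
√p-feature subsampling per split, grown by the package's own Rcpp grower so
that per-tree structures are available exactly. Measures: `gini` — summed
count-weighted impurity decrease per gene over all splits, divided by the
number of trees (non-negative; sums over genes to the forest's total
impurity decrease exactly, asserted in tests); `raw` — mean over trees of
the OOB accuracy drop after permuting the gene within the tree's OOB set
(trees not using the gene contribute 0); `normalised` — raw divided by the
standard error of the per-tree differences (sd/√n_trees; a plain-sd
denominator is available via `norm_denominator = "sd"` since both
conventions appear in the literature), with 0 wherever the sd is 0.
Importance runs default to 5000 trees — large ensembles are needed so every
gene gets a fair chance to enter the model; validation-classifier fits are
a separate, smaller knob (below).

## Selectors

**Boruta** (all-relevant). Each iteration appends freshly permuted shadow
copies of all genes still in play, scores the combined system, and credits
a *hit* to each undecided gene strictly exceeding the best shadow score
(ties are not hits). Hit counts are tested against Binomial(iterations,
1/2) with two one-sided exact tests at α = 0.01, Bonferroni-corrected
across the currently undecided genes; upper-tail significance confirms,
lower-tail rejects and removes the gene *and its shadow* from the system.
Confirmed genes and their shadows stay (their shadows keep feeding the
null). After `max_iterations` (default 100, the conventional limit),
undecided genes count as not selected. With a single iteration nothing can
reach significance, so the selection is empty by construction.

**Shadow t-test selector** (all-relevant). A fixed number of iterations
(default 20); each records every real gene's importance and the mean
importance of all shadows. Per gene, a one-sided two-sample t-test asks
whether its mean importance exceeds the mean shadow importance; p < 0.05
selects, with *no* multiplicity correction — that is the procedure's
definition, and its false-positive appetite is part of what the benchmark
measures. Welch's unequal-variance form is the default (`var_equal = TRUE`
restores the pooled test): the gene-score and shadow-mean samples have very
different variances, making the pooled assumption untenable. If both
samples are degenerate with equal means the p-value is defined as 1.

**Recursive feature elimination** (minimal-optimal). Subset sizes follow
the power-of-two schedule — from p, keep the largest power of 2 strictly
below the current count, down to 4 — with each size's error estimated by
`n_boot` (default 10) bootstrap rounds of a random-forest classifier and
the current genes re-ranked once per step by the importance provider. The
recorded subset with minimal error wins; ties go to the smallest subset,
and importance ties at a cut keep lower column indices. Validation forests
default to 1000 trees (`n_trees_eval`); the full-fidelity setting of
50000 is configurable but changes estimates, not behaviour.

**Regularised random forest** (minimal-optimal). The CART grower with a
penalty: a gene not yet in the ensemble-wide used set F has its Gini gain
multiplied by λ ∈ (0, 1] (default 0.8, the conventional regularisation
strength; λ = 1 is an ordinary forest). The selection is F itself — the
genes used in at least one split. Two open points were settled as follows:

* *Scope of F*: ensemble-global (the cited regularised-forest method), with
  `penalty_scope = "tree"` exposing the per-tree alternative.
* *Candidate set under regularisation*: with plain √p subsampling, a
  penalised duplicate of an informative gene wins any split whose random
  draw happens to miss the original, so redundancy would never actually be
  suppressed. Under λ < 1 the genes of F therefore always compete at every
  split (candidates = mtry random ∪ F); a penalised newcomer must beat the
  incumbents, not just the random draw. This restores the intended
  behaviour — selections shrink markedly relative to λ = 1 and identical
  copies of a gene rarely both enter — and leaves the λ = 1 path a
  standard forest (which is what `forest_importance()` uses).

## Bootstrap design and evaluation

One `BootstrapPlan` (default B = 30 resamples drawn uniformly with
replacement, out-of-bag complements recorded) is shared by every method in
a benchmark: that is what makes per-iteration errors paired. Resampling is
deliberately *not* class-stratified — plain uniform resampling is the
stated procedure — but a resample that loses all but one class would be
unusable, so such draws are redrawn with an incremented derived seed and a
warning; the event is only likely when a class is very small.

Post-selection error: per iteration, a `randomForest` classifier (default
1000 trees; 50000 is the full-fidelity setting) is trained on the resample
restricted to that iteration's selected genes and tested on the out-of-bag
samples, which took part in neither selection nor training — the
no-leakage contract is asserted structurally on every iteration. An empty
selection degrades to predicting the training majority class; an empty OOB
set records NA and is excluded from tests.

Method comparison: the best method is the one with the lowest mean error;
every other method is tested with a paired one-sided Wilcoxon signed-rank
test on per-iteration differences (zero differences dropped; exact null
when |differences| are tie-free and B ≤ 50, otherwise the normal
approximation with tie and continuity correction), Holm-corrected across
the compared methods at α = 0.01. The signed-rank test is the paired member
of the Mann–Whitney–Wilcoxon family, and a non-parametric test is needed
because per-iteration errors are far from normal.

## The synthetic generator: what it emulates, what it does not

`synthetic_spec()` defaults emulate the shape of a classic two-class
colon-tumour microarray set — 62 samples, 2000 genes, unbalanced classes
40:22 — with 20 planted relevant genes at δ = 1, two ρ = 0.8 redundant
copies each, and Gaussian noise. Relevant genes have class-conditional
means separated by δ noise-SD units (equally spaced centres for >2
classes); redundant copies are ρ·parent + √(1−ρ²)·fresh noise on the
latent scale; shifts are applied on the latent Gaussian scale for both the
Gaussian and lognormal options so δ has a single interpretation. The
ground-truth partition is exact and machine-readable, which is what lets
tests measure recall, ground-truth false discoveries and null calibration
directly.

What it does *not* emulate: probe-level noise, batch effects, spike-in
calibration, heavy-tailed real microarray distributions, or the pervasive
correlation structure of real transcriptomes (redundancy here is confined
to explicit parent–copy blocks). Passing tests therefore demonstrate
correctness and calibration of the machinery, not performance claims on
real microarray data.

One consequence deserves emphasis, because the test suite measures it
honestly: with n = 60 and hundreds of genes, several generative-noise genes
carry genuine in-sample class associations (the expected maximum |t| over
~500 null genes is near 4). An all-relevant selector with a
binomial-accrual design has high power against any gene whose sample
association is real, whether or not the generator planted it, so a handful
of such chance correlates is *confirmed by design*; likewise the shadow
t-test selector's uncorrected per-gene testing selects the upper tail of
the chance-association distribution, putting its null selection rate above
the nominal 5%. Both behaviours are the p ≫ n pathologies the stability
framework exists to expose, and both are visible in the acceptance suite's
simulations rather than hidden by fixture choices.

## Reproducibility machinery

Every stochastic operation takes an explicit integer seed; a run seed is
expanded into per-stage and per-iteration seeds with one fixed rule
(`derive_seed()`, a Lehmer step modulo 2³¹ − 1), so whole benchmarks are
bit-reproducible — the determinism tests hash the written artifacts. All
indices are 1-based, as everywhere in R. Artifacts are plain text:
selection matrices as TSV with a `#method=` header, reports and the run
manifest as JSON; the manifest records seed, B, grid parameters and
versions, from which a run can be repeated exactly.

## Problem sizes used in the shipped analyses

The analysis scripts and the acceptance computations use a 60 × 500
benchmark with 10 planted genes at δ = 2, B = 15 bootstrap iterations,
2000-fern importance, 200-tree RFE validation forests and 500-tree
post-selection validation forests; the SCS null calibration uses B = 30,
p = 2000 with 500–1000 replicates. These sizes were chosen so a full desk
run completes in minutes while every statistic retains enough resolution to
be meaningful; all of them are parameters, and the full-fidelity settings
(B = 30, 5000-fern/50000-tree ensembles, p up to 12533) are plain argument
changes.

## Known limitations

* The ferns and forest importance permutation is done once per
  (learner, gene) pair; averaging several permutations would reduce
  importance variance at proportional cost.
* The regularised forest implements plain regularisation only (no
  importance-guided per-gene penalties).
* Classification only; no regression forests.
* The shadow t-test selector's nominal level is per-gene and uncorrected by
  definition; it should not be used where family-wise control is the goal —
  that is precisely what the SCS layer is for.
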