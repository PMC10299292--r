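---
title: "Screening genes coherent with an anchor gene: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening genes coherent with an anchor gene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorScreen)
```

## The problem

Given a case/control log2 expression matrix and one *anchor* gene of prior
interest (in the motivating application, the m6A methyltransferase METTL3 in
Alzheimer's disease brain), we want the genes whose expression is *coherent*
with the anchor: differentially expressed in disease, co-varying with the
anchor across case samples, associated with clinical severity, and useful
together with the anchor as a two-gene diagnostic. anchorScreen chains four
statistical stages, each usable on its own, and a synthetic-data generator
that plants known ground truth so every stage can be tested offline.

## Stage 1 — dual differential expression

Two screens are intersected:

1. **case vs control**, and
2. **anchor-high vs anchor-low within cases**, splitting the case group at
   the anchor's median expression (samples exactly at the median go to
   "low", a deterministic convention).

For each gene the effect is `log2FC = mean(A) − mean(B)` on the log2 scale;
significance comes from Welch's *t* by default. A `"moderated"` mode shrinks
gene-wise pooled variances toward their median with a configurable prior
degrees of freedom (`s²_post = (d₀ s₀² + d s²)/(d₀ + d)`), a deliberately
simple stand-in for the limma moderated *t*: in our tests its −log₁₀ *p*
ranking agrees with limma's at Spearman ρ > 0.98, which is all the screen
needs (thresholding, not inference). Filters are **strict** inequalities
`|log2FC| > 0.3` and `p < 0.05`, on raw p-values by default; BH adjustment is
available behind a flag. Degenerate genes never yield NaN: both groups
constant and equal gives p = 1, a zero-variance gene with a real shift gets
the machine-epsilon floor.

## Stage 2 — ant-colony seriation and the neighbour-frequency screen

The core statistic orders genes so that co-varying profiles sit adjacent.
Pairwise gene distances are **squared Euclidean** over the case samples
(screens run "in disease" because the coherence of interest is a disease
property; `aco_samples = "all"` widens the scope). Profiles are z-scored per
gene before the distance by default, making d(i,j) = 2(n−1)(1−r_ij) a pure
pattern dissimilarity; `standardize = FALSE` restores raw-scale distances.

A canonical **ant system** searches for the minimum-length *open path*
through all genes (a linear "gene sequence"; a cycle objective is available
for comparison): each of `n_ants` ants starts at a uniformly random gene and
repeatedly picks the next unvisited gene with probability ∝ τᵢⱼ^α ·
(1/(dᵢⱼ+ε))^β; after each iteration pheromone evaporates, τ ← (1−ρ)τ, and
every ant deposits q/length on its edges. Defaults are the textbook settings
— one ant per gene, α = 1, β = 2, ρ = 0.5, q = 100, τ₀ = 1, 200 iterations —
because the procedure being reproduced specifies none. The inner loop is
C++ with a package-internal xorshift64* RNG, so a run is bit-reproducible
from its seed and leaves R's RNG untouched.

One ordering can be a coincidence, so the run is repeated (default 10 times;
run *r* uses seed `seed + r`) and each gene is scored by the **neighbour
frequency**: the number of runs in which it lies within `window` positions
of the anchor (default 5 per side — the "vicinity" is a free parameter of
this reconstruction, stated prominently because the original leaves it
undefined). Genes reaching `min_count` (default 5 of 10) are retained; the
default is ≥ 5 rather than > 5 because the published retention table lists
frequency-5 genes, and `strict_count = TRUE` switches to the stricter
reading of the accompanying text.

Two oracle routes keep this honest in the tests: an exhaustive
permutation optimizer (`brute_force_order`, n ≤ 10) that ACO must match but
never beat, and pure-R positional scans for the frequency counts.

## Stage 3 — clinical association

Candidates passing the frequency screen are fitted by closed-form simple OLS
against MMSE (Mini-Mental State Examination, 0–30, lower = worse) and NFT
(neurofibrillary tangle burden, higher = worse), on case samples by default
since controls carry no meaningful NFT. "Best fit" is operationalized as
highest MMSE R² with NFT R² breaking ties, because the headline association
of the motivating study is candidate-vs-MMSE. The expected sign pattern —
positive MMSE slope, negative NFT slope for a down-regulated protective
candidate — is asserted in tests on planted data.

## Stage 4 — two-gene diagnostic

The (anchor, candidate) expression pairs feed a margin classifier. No SVM
library is assumed; the package implements a **least-squares SVM**
(Suykens' formulation: solve `[0 1ᵀ; 1 K + I/C][b; α] = [0; y]`), with
linear and RBF kernels, the RBF bandwidth set by the median pairwise
distance heuristic and C = 1 by default. Features stay on the log2 scale so
that thresholds are in expression units. Performance is the mean of
stratified 10-fold cross-validated rank-based (Mann–Whitney) AUCs; a 60/40
stratified split evaluation is also reported since the original describes
both. The **anchor threshold** is empirical, not model-derived: the largest
t such that every sample with anchor expression strictly below t is a case,
i.e. the minimum anchor expression among controls (NA when the axis minimum
is a control). This operationalizes "below the line, probability of disease
close to 100%" exactly, by construction.

## The synthetic world

`synthetic_config()` states the world once:

* cohort structure 74 controls / 87 cases (a second, 9/22 configuration with
  7/8/7 mild/moderate/severe strata mirrors the validation-cohort shape);
* log2-scale Gaussian noise, `noise_sd = 1` — a typical per-gene spread for
  log2 microarray intensities;
* anchor and planted genes shifted by `case_shift = −1` in cases
  (downregulation, matching the motivating biology) — a clearly detectable
  but not trivial one-noise-SD effect;
* planted genes share the anchor's latent case-group factor with weight
  `planted_corr = 0.9`, giving *population* correlation exactly 0.9 within
  cases while controls stay independent — the screen orders case samples
  only, so coherence is planted only where the method looks;
* MMSE = 2·(candidate expression) + ε and NFT = 12 − candidate + ε for case
  samples (`clinical_noise_sd = 1`), controls near the healthy MMSE ceiling
  of 29 with NFT ≈ 0; slopes are signed so that low candidate expression
  means low MMSE and high NFT. MMSE is clamped to [0, 30] — inactive at
  these scales, stated for safety;
* gene names borrow a published list of 20 m6A regulator symbols purely as
  realistic identifiers; the default clinical driver is named NDUFA10 to
  mirror the narrative the pipeline reconstructs.

What the generator does **not** emulate: probe-level structure, batch and
brain-region effects, heavy-tailed noise, correlated null genes. A green
planted-recovery test therefore establishes that the pipeline recovers the
statistical signal it assumes — not that the original study's gene lists
are correct, which would require the real GEO cohorts.

## Numerical and design choices

* "Euclidean square degree" is read as squared Euclidean distance; ε = 1e−12
  guards the heuristic term against zero distances.
* Ant-system best-so-far length is non-increasing by construction and is
  revalidated against a pure-R `path_length` on every tested run.
* Brute-force ties break to the lexicographically smallest order, making the
  oracle deterministic.
* The global pipeline seed fans out at fixed offsets (generator `+0`, ACO
  `+100`, CV `+200`, split `+300`), so stages are individually reproducible.
* The LS-SVM replaces the usual SMO-trained SVM: it is exact, deterministic,
  dependency-free, and its decision scores feed the same rank-based AUC; the
  known behavioural difference (every point carries weight) is irrelevant to
  AUC ranking at these sample sizes.
* Empty DEG intersections or empty candidate sets complete the pipeline
  with explicit flags rather than errors, so null datasets are a supported
  input, not a crash.

## Known limitations

The published headline numbers (thousands of DEGs, the exact retention
table, AUC 0.915, the x = 9 threshold) are functions of the real cohorts
and cannot be checked offline; the acceptance suite instead verifies the
properties those numbers rely on: oracle-level ACO optimality at small n,
planted-coherence recovery, filter-rule fidelity, type-I/power behaviour of
the DEG screen, clinical slope recovery, diagnostic AUC on separable planted
data, and end-to-end selection of the planted driver. The moderated-t mode
is an approximation, the window and retention defaults are this package's
documented readings of an under-specified procedure, and the ant system is
the canonical one — the original mentions an unspecified "improvement" that
cannot be reconstructed from its description.
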