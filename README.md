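# anchorScreen

Screening case/control gene-expression data for genes *coherent* with an
anchor gene — co-regulated with it, differentially expressed in disease,
tracking clinical severity, and diagnostic alongside it. The motivating use
case is the m6A methyltransferase **METTL3** in Alzheimer's disease brain
expression cohorts, where the screen surfaces respiratory-chain candidates
such as NDUFA10; the machinery is generic in the anchor and the data.

The pipeline chains four stages over a log2 expression matrix `X` (genes ×
samples) with case/control labels:

1. **Dual differential expression.** DEGs of case vs control and of
   anchor-high vs anchor-low cases (split at the anchor's median
   expression), each filtered at strict `|log2FC| > 0.3` and `p < 0.05`
   (Welch *t* by default, an empirical-Bayes moderated *t* optionally), then
   intersected.
2. **Ant-colony seriation.** Genes are ordered into a minimum-length open
   path under squared-Euclidean profile distances
   `d(i,j) = Σ_s (x_is − x_js)²` (case samples, z-scored profiles) by a
   canonical ant system: transition probability ∝ τ_ij^α (1/(d_ij+ε))^β,
   evaporation τ ← (1−ρ)τ, deposit q/length. The run repeats 10 times with
   derived seeds; each gene's **neighbour frequency** is the number of runs
   it lands within `window = 5` positions of the anchor, and genes with
   count ≥ 5 survive the screen.
3. **Clinical association.** Survivors are ranked by the R² of simple OLS
   fits of their expression to MMSE (primary) and NFT (tie-break) over case
   samples.
4. **Two-gene diagnostic.** A least-squares SVM on (anchor, top candidate)
   expression, scored by mean stratified 10-fold cross-validated
   Mann–Whitney AUC, plus the empirical anchor threshold *t* = the minimum
   anchor expression among controls, below which every sample is a case.

A synthetic-data generator plants ground truth (correlated gene block,
clinically coupled driver gene) so the full pipeline is testable with no
downloads.

## Worked example

```r
library(anchorScreen)
report <- run_pipeline(pipeline_config(seed = 3))
report
```

```
anchorScreen run report (seed 3)
  data: 100 genes, 74 controls / 87 cases
  DEGs case-vs-control: 14 (2 up / 12 down); anchor split: 11; intersection: 9
  candidates past frequency screen: 8; chosen candidate: NDUFA10
  mean 10-fold CV AUC: 0.866; split AUC: 0.824; anchor threshold: 7.705
```

Reading this: of 100 simulated genes, 14 pass the case/control filter
(mostly down-regulated, as planted), 11 pass the anchor median-split filter,
and 9 survive the intersection — the 7 planted coherent genes, the planted
clinical driver among them, plus the anchor's own record. After ten
ant-colony orderings, 8 genes sit near METTL3 in at least 5 runs;
the MMSE fit ranks the planted driver NDUFA10 first. The two-gene classifier
separates cases from controls with mean CV AUC ≈ 0.87 at the default planted
effect of −1 noise-SD (≈ 0.96 at −2), and every sample whose METTL3
expression falls below 7.7 log2 units is a case.

The same screen runs from the command line:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "coherence-screen.R", package = "anchorScreen"))')" \
  run --simulate --seed 3 --outdir out/
# or on your own data:
#   ... run --expression expr.tsv --phenotype pheno.tsv --anchor METTL3 --outdir out/
```

`out/` then holds every intermediate table (DEG tables with filter verdicts,
the 10 gene sequences, neighbour frequencies, clinical fits, per-fold AUCs)
as TSV plus a machine-readable `report.json`.

## Vignette

`vignettes/anchor-coherence-screening.Rmd` documents the models, every
tunable parameter with its default and rationale, what the synthetic world
does and does not emulate, and the package's documented readings of the
under-specified parts of the procedure it reconstructs.
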