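# lncprop

Network-propagation prioritization of disease-associated long non-coding
RNAs (lncRNAs).

Most lncRNAs have no known disease role, and screening them one by one is
impractical. `lncprop` ranks candidate lncRNAs for a disease by combining
two widely used assumptions:

* **ceRNA competition** — lncRNAs that share miRNA response elements
  compete for the same miRNA pool, so lncRNAs with many shared, validated
  miRNA partners are functionally coupled ("guilt by association");
* **phenotype association** — diseases with similar clinical phenotypes
  involve similar molecular players, so knowledge about one disease's
  lncRNAs carries information about a phenotypically similar disease.

It is aimed at computational biologists with per-disease paired
lncRNA/miRNA expression matrices (e.g. tumor RNA-seq/miRNA-seq), a list of
experimentally validated miRNA–lncRNA interactions, curated known disease
lncRNAs, and a disease phenotype similarity matrix.

## Method

For each disease:

1. **Competing network.** Pearson co-expression is computed for every
   validated miRNA–lncRNA pair present in the expression data; pairs with
   Benjamini–Hochberg FDR ≤ 0.05 define each lncRNA's significant partner
   set. Every lncRNA pair *(a, b)* sharing *x ≥ 1* of their *K* and *M*
   partners out of an *N*-miRNA universe is tested with the hypergeometric
   upper tail

   *P = P(X ≥ x), X ~ Hypergeom(N, K, M)*,

   BH-corrected across all tested pairs; surviving edges are weighted
   *−log₁₀ P*.

2. **Propagation.** Known disease lncRNAs seed a random walk with restart
   on the network: *s ← (1 − r) W s + r e*, with column-normalized weighted
   adjacency *W*, uniform restart vector *e* over the seeds, and restart
   probability *r = 0.7*. The fixed point *S<sub>jk</sub>* scores every
   network lncRNA *k* for disease *j*.

3. **Integration.** Scores are combined across diseases through the
   phenotype similarity matrix *P*:

   *S<sub>ik</sub> = Σ<sub>j</sub> P<sub>ij</sub> · S<sub>jk</sub>*,

   and candidates are ranked by *S<sub>ik</sub>*. A disease with few or no
   seeds of its own still receives a ranking through the other diseases.

Evaluation is leave-one-out cross-validation: each known seed is held out,
the disease is re-propagated and re-integrated, and the held-out lncRNA is
ranked against all non-seed candidates; performance is the Mann–Whitney
AUC. Robustness controls reproduce the standard battery: phenotype
ablation (identity *P*), phenotype permutation, random non-disease seed
sets, disease-count subsampling, and cross-disease-only prediction.

## Worked example

`worked_fixture()` is a hand-sized two-disease instance (12 lncRNAs, 7
miRNAs) whose networks are exactly enumerable: each disease module forms a
5-clique with edge p-value C(3,3)·C(4,0)/C(7,3) = 1/35.

```r
library(lncprop)
fx  <- worked_fixture()
fit <- lncprop(fx)
fit
#> Network-propagation lncRNA prioritization
#> Call: lncprop(lncrna = fx)
#> 2 disease(s), candidate universe of 8 lncRNA(s)
#>   D1            5 nodes    10 edges  3 seed(s)
#>   D2            5 nodes    10 edges  3 seed(s)

head(predict(fit, "D1"), 5)
#>   rank lncrna     score
#> 1    1    L04 0.4589147
#> 2    2    L01 0.2868217
#> 3    3    L02 0.2868217
#> 4    4    L06 0.1720930
#> 5    5    L07 0.1720930
```

L04 tops disease D1's list because it is a known lncRNA of both diseases:
its integrated score 0.459 = 0.287 (its seed-level propagation score in D1)
+ 0.6 × 0.287 (the same evidence transferred from the phenotypically
similar D2). The transfer also shows up in cross-validation: holding L04
out of D1's seed set still ranks it first, purely from D2's evidence.

For realistic experiments, `generate_corpus(synth_spec(rng_seed = 1))`
builds a five-disease corpus with planted ceRNA modules, phenotype blocks,
background (non-disease) modules and decoy interactions; `loocv()`,
`ablate_phenotype()`, `permute_phenotype()`, `random_seed_control()`,
`subsample_diseases()` and `cross_disease_only()` run the full evaluation
battery on the fitted object. A file-based workflow with the same stages is
available through `cmd_network()` / `cmd_prioritize()` / `cmd_evaluate()` /
`cmd_simulate()` and the thin command-line wrapper in `inst/cli/lncprop`.

## Package layout

* `R/io.R` — strict TSV readers/writers for expression, interactions,
  seeds, phenotype matrices, networks and rankings.
* `R/cerna.R` — co-expression filtering, hypergeometric shared-partner
  test, BH correction, network construction.
* `R/propagate.R`, `R/integrate.R` — restart walk and phenotype
  integration.
* `R/evaluate.R` — LOOCV, ROC/AUC machinery and the robustness battery.
* `R/synthetic.R` — the corpus generator and the worked fixture.
* `R/lncprop.R`, `R/cli.R` — the model-fitting interface and the
  file-based command layer.

See the vignette (`vignettes/prioritizing-disease-lncrnas.Rmd`) for the
modelling assumptions, parameter choices and known limitations.
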