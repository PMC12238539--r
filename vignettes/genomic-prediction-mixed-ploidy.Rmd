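---
title: "Genomic prediction with multi-allelic variants in mixed-ploidy panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with multi-allelic variants in mixed-ploidy panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polygp)
```

## The problem

Genomic prediction (GP) trains a statistical model on a genotyped and
phenotyped population and predicts trait values of new individuals from their
markers alone. In outcrossing polyploid crops such as switchgrass this is
complicated by three features that most GP software sidesteps:

* **Mixed ploidy.** Diversity panels mix tetraploids and octoploids. Variant
  callers genotype tetraploids against a tetraploid reference with two allele
  copies per call and octoploids with four, so calls of different lengths must
  be reconciled before they can enter one model.
* **Multi-allelic variants.** A substantial fraction of loci carry more than
  one alternative allele (SNPs, indels, and spanning deletions `*` at the same
  position). Splitting them record-by-record destroys the joint genotype;
  dropping them discards signal.
* **Population structure.** Panels assembled from many collection sites carry
  strong structure. A model can look accurate while only predicting which
  gene pool an individual belongs to, so raw accuracy overstates what the
  markers contribute.

`polygp` implements a complete, testable pipeline for this setting: genotype
encoding, ridge-regression BLUP (rrBLUP) with a population-structure
baseline, factor comparisons via balanced down-sampling, and coefficient-based
candidate-gene interpretation — together with a seeded panel simulator so
every stage can be validated without any external data.

## Genotype encoding

**Pseudo-diploid collapsing.** Four-allele (octoploid) calls are collapsed to
diploid pairs: `A,A,A,A` becomes `A/A`, `T,T,T,T` becomes `T/T`, and every
mixed composition (`A,T,T,T`, `A,A,T,T`, `A,A,A,T`) becomes the single
heterozygous class `A/T`. Allele dosage within heterozygotes is deliberately
discarded; the model treats all heterozygotes as one class. If a collapsed
call has more than two distinct alleles the two most frequent are kept, with
frequency ties broken by the canonical allele order (reference first, then
alternatives in declared order).

**Per-alternative-allele expansion.** A locus with $m$ alternative alleles is
expanded into $m$ indicator columns. Within the column for alternative $a$,
an individual's code depends only on how many copies of $a$ the collapsed
pair carries:

| copies of $a$ | code | meaning |
|---|---|---|
| 0 | 1 | homozygous "reference" with respect to $a$ |
| 1 | 0 | heterozygous |
| 2 | -1 | homozygous alternative |

Every other allele — the reference and all other alternatives — counts as
reference, so at a locus with reference `A` and alternatives `(T, G, AT)` the
call `G/AT` codes `1` in the `T` column and `0` in both the `G` and `AT`
columns. With $m = 1$ this is the ordinary bi-allelic $\{1, 0, -1\}$ coding.
Columns are classified separately: substitution alternatives give
(multi-allelic) SNP columns, length-changing alternatives and `*` give indel
columns; an equal-length multi-base substitution counts as a SNP.

**Filtering and imputation.** Columns are kept when minor allele frequency is
strictly above 0.05 and the missing fraction strictly below 0.20, with MAF
computed on collapsed codes over non-missing individuals as
$\min(p, 1-p)$, $p = (2 n_{-1} + n_0) / (2 n_\text{obs})$. Remaining missing
codes are then imputed by a seeded draw from the column's empirical code
distribution. This imputation is intentionally simple: it preserves marginal
code frequencies exactly and is deterministic under the seed, but unlike
haplotype-model imputation it ignores linkage information between loci. The
filter guarantees it touches less than 20% of any column. Filtering happens
after the multi-allelic expansion (per encoded column, i.e. as the model sees
features); `filter_columns()` takes explicit thresholds should the
pre-expansion reading be wanted.

## The prediction model and its baseline

`fit_rrblup()` solves the mixed model

$$y = \mathbf{1}\mu + M u + \varepsilon, \qquad
  u \sim N(0, \sigma_u^2 I), \quad \varepsilon \sim N(0, \sigma_e^2 I),$$

with the variance ratio $\lambda = \sigma_e^2/\sigma_u^2$ REML-estimated by a
one-dimensional search in $\log\lambda$ over the spectral decomposition of
the marker kernel $MM^\top$ (search interval $[10^{-9}, 10^9]$, tolerance
$10^{-6}$ on $\log\lambda$). At the estimated $\lambda$ the effects are the
ridge solution; numerically they are computed through the SVD of the
column-centered marker matrix, which stays exact even when REML drives
$\lambda$ to the search floor and $MM^\top$ is singular. Constant phenotypes
yield a flagged degenerate fit with zero effects rather than an error.

The **population-structure baseline** fits the same model on the first five
principal components of the marker matrix (column-centered, unscaled). Model
performance is reported as the squared Pearson correlation between observed
and predicted values, $r^2_g$ for the marker model and $r^2_p$ for the PC
baseline, and their difference

$$r^2_i = r^2_g - r^2_p$$

measures what the markers add beyond structure. Constant predictions are
scored $r^2 = 0$ (flagged) so structure-only traits remain comparable.

**Evaluation scheme.** `stratified_split()` holds out 20% of individuals as a
test set (486 individuals split 389/97) and pre-assigns the training
individuals to 5 folds for each of 10 replicate runs; hold-out and folds are
stratified on trait quintiles so all sets share the trait distribution, with
a largest-remainder apportionment making the overall test size exact. Within
`run_cv_experiment()`, each replicate fits on 4 folds and predicts the fifth,
pools the predictions over all 5 validation folds, and computes one $r^2$ per
replicate per model (not a mean of per-fold $r^2$). Medians over the 10
replicates are the headline numbers. Marker coefficients are averaged over
the 5 fold-fits of a replicate and then across replicates; their absolute
values are the variant importances.

Two design points were genuinely open and are resolved as follows:

* **PC leakage.** Whether baseline PCs should be computed once globally or
  per training fold is ambiguous; the default (`pc_scope = "train_fold"`)
  computes them from training-fold rows only and projects held-out rows onto
  those axes, avoiding information leakage. `pc_scope = "global"` reproduces
  the laxer reading.
* **Test-set metrics.** The model refit on the full training set does not
  depend on fold assignments, so $r^2_{*,\text{test}}$ is constant across
  replicates; it is stored once per replicate to keep one tidy row per
  replicate.

## Factor comparisons

`balanced_downsample_runs()` removes marker-count confounding when comparing
marker sets of different sizes: the larger set is down-sampled uniformly
without replacement to the smaller set's size 100 times (seeded), a
user-supplied experiment is evaluated per subset, and the median over
replicates summarises the balanced performance. `compare_model_families()`
then tests paired per-replicate accuracies (the pairing unit is the replicate
run under identical splits, so differences are attributable to the factor
under test) with a two-sided Wilcoxon signed-rank test — exact for up to 25
non-zero pairs via a dynamic program over the positive-rank-sum distribution
(midranks under ties, zeros dropped), normal approximation beyond.

`gene_coverage()` counts genes *harboring* a marker (position inside the
1-based inclusive gene interval) and genes *adjacent* to one (intergenic
marker whose single closest gene lies strictly within 3.5 kb of the nearer
boundary; equidistant ties count both; strand is ignored since the window is
symmetric). `coverage_zscore()` places an observed count in a down-sampled
null distribution, $z = (x - \bar x_\text{null}) / s_\text{null}$ with the
sample standard deviation, two-sided normal $p$.

## Interpretation

Variants whose importance ranks above the 95th (or 99th) empirical percentile
— linear-interpolation definition, ties at the threshold included — are
"important"; `map_variants_to_genes()` associates them with harboring genes
or, for intergenic variants, the single closest gene within 3.5 kb.
`benchmark_enrichment()` tests the resulting gene set against a benchmark
list with a two-sided Fisher's exact test over a gene universe. The universe
defaults to all genes visible to the marker panel (harboring or within the
window of any column): genes the panel cannot see can never be identified, so
including them would inflate enrichment. The reported odds ratio is the
sample odds ratio $ad/bc$.

`allele_phenotype_comparison()` contrasts phenotypes across the three code
classes of one column with unpaired two-sided rank-sum tests. Rank-sum (not
signed-rank) is the coherent choice for unequal, unpaired groups even where
field figures label such contrasts "signed-rank". Classes are labelled with
compact letters assigned greedily from the highest-mean class; singleton
classes are summarised but not lettered.

## The panel simulator

`simulate_panel()` generates panels with the statistical structure the
analysis assumes, so that every downstream claim is testable:

* **Structure.** Individuals belong to `n_subpops` subpopulations whose
  allele frequencies diverge from ancestral frequencies under a
  Balding–Nichols-style model: subpopulation frequencies are Dirichlet with
  concentration $(1-F_{st})/F_{st}$ times the ancestral vector, reducing to
  the classic Beta marginals for bi-allelic loci and to the ancestral
  frequencies exactly at $F_{st} = 0$. The subpopulations model *major gene
  pools*, not collection sites: panels of this kind are gathered from dozens
  of sites, but those sites cluster into a handful of genetic groups, which
  is also what a five-PC structure baseline presumes. Defaults: 8 gene pools
  at $F_{st} = 0.05$.
* **Mixed ploidy.** A fraction `ploidy_mix` (default 223/486 ≈ 46%) of
  individuals are octoploid and receive 4-allele calls; the rest are
  tetraploid with 2-allele calls.
* **Variants.** `frac_multiallelic` of loci draw 2..`max_alt_alleles`
  alternatives, mixed SNP/indel per coin flip, so all five variant classes
  occur. Genes (default ~1 per 15 kb, matching a gene-dense crop genome) are
  non-overlapping intervals on one chromosome.
* **Genetics and confounding.** Additive effects are assigned on *encoded*
  columns (post-expansion, exactly the features the model sees) that lie
  within or near `n_causal_genes` designated causal genes —
  `causal_scope = "gene_body"` restricts them to gene bodies. The phenotype
  is genetic value + subpopulation mean shift + Gaussian noise, with the
  three components rescaled so their variance shares equal `heritability`,
  `structure_effect`, and the remainder. Marker divergence (`fst`) and the
  phenotypic structure confound (`structure_effect`) are deliberately
  independent dials: group mean shifts are scaled to their variance share
  regardless of marker differentiation. A second, structure-only trait (all
  marker effects zero) is emitted for null calibration: its $r^2_i$ should
  vanish.
* **Missingness and reproducibility.** Calls are masked uniformly at
  `missing_rate` (default 12.5%, a typical reduced-representation rate), and
  every random stage draws from a named stream derived from the master seed,
  so panels are byte-identical across runs.

What the simulator does *not* emulate: linkage disequilibrium between loci
(each locus is drawn independently, so prediction of simulated traits works
only through the causal columns themselves, not through linked proxies),
coalescent ancestry, epistasis, and allele-dosage effects within collapsed
heterozygote classes. Passing the pipeline's tests on simulated panels
therefore demonstrates the statistical machinery is correct under the model's
own assumptions — not that any particular real trait is predictable.

## What the test suite establishes, and at what scale

The acceptance-style checks run the whole pipeline on simulated panels at
desk scale (chosen once, as the package's own validation sizes):

* *Null calibration* — structure-only traits at $n = 300$, 600 loci,
  `structure_effect = 0.3`, 10 seeds: the median $r^2_{i,CV}$ sits within
  ±0.05 of zero.
* *Signal recovery* — causal traits at $h^2 = 0.5$ give median
  $r^2_{i,CV} > 0.1$, and the median $r^2_{g,CV}$ is non-decreasing in
  $h^2 \in \{0, 0.25, 0.5, 0.75\}$ (10 seeds per level at $n = 250$,
  400 loci).
* *Coverage effect* — with causal effects placed in gene bodies, a
  gene-concentrated marker panel beats a uniform panel of equal size on
  median $r^2_i$ in at least 8 of 10 seeds.
* *Enrichment calibration* — planted causal genes are recovered (Fisher
  $p < 0.05$ at the 95th percentile in ≥ 8/10 seeds), while benchmarks drawn
  independently of the causal genes give $p$-values that are never
  stochastically smaller than uniform (one-sided Kolmogorov–Smirnov over 50
  seeds). The one-sided form is used deliberately: two-sided Fisher exact
  $p$-values are discrete and conservative on small gene tables, so exact
  uniformity is not the correct null expectation, but any *excess* of small
  $p$-values would indicate spurious enrichment.
* *Micro-oracles* — the encoding table, the 389/97 split, the REML solver
  against an independent brute-force ridge solve (50 random instances,
  $10^{-8}$), and closed-form values of the signed-rank, z-score and
  odds-ratio statistics.

## Limitations

Heritabilities of real panel traits are unknown; simulator defaults are free
parameters, not estimates. The pseudo-diploid collapse discards octoploid
allele dosage by design, matching the analysed pipeline rather than improving
on it. Imputation ignores linkage. Down-sampled subsets are uniform over
columns and do not preserve the genic/intergenic ratio. Raw Wilcoxon
$p$-values are reported without multiple-testing correction across traits,
mirroring the comparison machinery this package reproduces.
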