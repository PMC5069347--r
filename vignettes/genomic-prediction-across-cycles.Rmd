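---
title: "Genomic and pedigree-based prediction across hybrid rye breeding cycles: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic and pedigree-based prediction across hybrid rye breeding cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In hybrid rye breeding, inbred selection candidates (S2 lines, still carrying
substantial residual heterozygosity) are evaluated as testcrosses to testers
from the opposite heterotic pool, in multi-location alpha-lattice trials. A
prediction model trained on phenotyped lines should predict the testcross
performance of unphenotyped candidates — within the same selection cycle
(CV1) and, more importantly for cycle-length reduction, in subsequent cycles
that share only a subset of parents with the training material (CV2/CV3).

`ryegp` implements this analysis end to end: a synthetic multi-cycle
breeding-program generator standing in for the proprietary commercial data,
SNP quality control and LD analysis, pedigree- and marker-based relationship
matrices, the two-stage phenotypic analysis, REML fitting of the two
prediction models, and the replicated cross-validation designs.

# Models

## Two-stage phenotypic analysis

Stage 1 analyses each location.tester trial separately as a resolvable
incomplete-block design:

    value ~ genotype (fixed) + replicate (fixed) + (1 | replicate:block),

giving adjusted entry means (GLS estimates at the average replicate level)
and their standard errors; single-replicate traits reduce to block-adjusted
means. Outliers are removed per trial by an iterative maximum-studentized-
deviate (Grubbs) sweep on the plot residuals at alpha = 0.05, refitting after
each sweep. Two genuinely open design points — the stage at which outliers
are removed and whether replicates are fixed or random — are resolved here
as stage-1 removal and fixed replicates.

Stage 2 combines the stage-1 means of one cycle and trait across trials:

    blue ~ genotype (fixed) + (1 | loc_tester) + (1 | genotype:loc_tester),
    residual variance proportional to se^2

with weights `1/se^2` — the diagonal approximation of the stage-1
precision, the standard weighting for stage-wise analysis of series of
trials. The genotype-fixed fit uses a profile REML written for this
package: the location.tester grouping makes the marginal covariance
block-diagonal with diagonal-plus-rank-one blocks, so each evaluation is a
Sherman–Morrison solve and a single Cholesky of the genotype information
matrix; the two variance ratios are searched by Nelder–Mead on the log scale
to a 1e-8 objective tolerance. (A general-purpose sparse mixed-model fit of
the same model was an order of magnitude slower at 260 genotypes; the
structure-aware fit is exact for this model.) The genotype-random companion
fit — used only for variance components — goes through `lme4::lmer` with the
same weights.

Progeny-mean heritability is

    h2 = var_g / (var_g + vbar_delta / 2),

with `var_g` from the genotype-random fit and `vbar_delta` the mean variance
of a difference of two genotype BLUEs from the genotype-fixed fit (computed
exactly over all pairs from the coefficient covariance matrix). With a single
trial the interaction is inestimable; the fit pins both random terms at zero
and flags the result.

## Relationship matrices

The additive relationship matrix `A` is built by the tabular method on the
selfing-free pedigree, with the diagonal of a line with `x` recorded selfing
generations replaced by

    A_ii = sum_{S=0}^{x} (1/2)^S + A_gh (1/2)^{x+1},

`A_gh` being the relationship of its parents. Lines are recorded at `x = 1`:
although the S2 genotype arises from two selfing generations, the testcross seed is
modeled as deriving from S1 plants. Whether that convention or `x = 2` is
biologically exact for a given program is not decidable here, so the
generator records it as a configuration switch (`selfing_x`), with `x = 1`
the default. Unknown parents are unrelated and non-inbred. The expected
kinship is `K = A/2`.

The realized kinship is half the usual allele-frequency-centered genomic
relationship,

    U = (W W') / (4 sum_j p_j (1 - p_j)),  W = dosage - 2 p,

so that `U` is on the same kinship scale as `K` and can replace it in an
otherwise identical model (self-kinship of partially inbred lines around
0.75–1). Several realized-kinship estimators are in circulation; the
half-VanRaden form is adopted here, as an explicit assumption, so that U
shares K's scale. Frequencies are computed once from all lines jointly, so `U` is
identical across cross-validation scenarios.

## Prediction models and REML

Both models are single-kernel mixed models on the stage-2 BLUEs,

    y = X beta + t + e,   t ~ N(0, K sigma_t^2)  (PBLUP)
                          t ~ N(0, U sigma_u^2)  (GBLUP),

with a fixed selection-cycle effect (reference coding, earliest cycle as
reference) and i.i.d. residuals. The restricted likelihood is profiled in
`lambda = sigma_e^2 / sigma_kernel^2` through one eigendecomposition of the
calibration-set kernel and maximized by Brent search over `log lambda` in
`[log 1e-6, log 1e6]` (tolerance 1e-8; boundary solutions flagged).
Unphenotyped lines receive the conditional-mean BLUP
`K[all, CS] (K[CS, CS] + lambda I)^{-1} (y - X beta)` — the standard BLUP
extension, chosen because it is equivalent to carrying empty records in the
incidence matrix and is checkable against a dense Henderson MME solve (the
package ships that oracle, `solve_mme_oracle()`, and the test suite verifies
1e-8 agreement on random instances). Cycles absent from a calibration set
inherit the reference fixed-effect value; correlation-based accuracies are
invariant to this within-cycle constant. Kernels that fail positive
semidefiniteness receive a minimal logged ridge (>= 1e-6, warning above
1e-3).

## Cross-validation and accuracy

One fold plan — ten replicates of a random fivefold partition per cycle — is
shared by every scenario, model and trait, so all comparisons are paired at
the fold level. Calibration sets: CV1 uses the validation cycle's other four
folds; CV2.x samples `n_cs / x` lines from each of `x` other cycles; CV3
samples equally from all cycles with the validation fold excluded from its
own cycle's pool (at the maximum size this is 208 lines per cycle). All
forward and backward cycle pairs are produced and labelled; CV2.2 enumerates
all pairs of non-validation cycles since only the aggregate is of interest.

Predictive ability is the Pearson correlation between predicted and observed
testcross BLUEs in the validation set; accuracy divides it by the square
root of the validation cycle's progeny-mean heritability. Accuracies above 1
can arise by sampling noise and are flagged, not clipped. Model comparisons
apply Fisher's Z (`atanh`) to the fold-level predictive abilities — not to
the corrected accuracies, which can exceed 1 where `atanh` is undefined —
and a paired two-sided t-test per scenario and trait.

# The synthetic breeding program

No real data accompany this package (the emulated program is proprietary),
so the generator is a first-class, tested module whose defaults *are* the
study conditions:

* 4 cycles x 260 S2 lines, progenies of crosses between distinct parents of
  a 203-parent pool; consecutive cycles share 8–21 parents; zero-truncated
  Poisson(mean 2) lines per cross, capped at 24.
* Each line: an independent F1 of its cross, selfed twice by single-seed
  descent; meiosis under Haldane's model (Poisson crossovers, no
  interference); genotype reported at S2, pedigree recorded at `x = 1`.
* Genome: 2000 SNPs on 7 chromosomes x 150 cM, positions uniform.
* Founders: recombinant mosaics (expected segment 20 cM) of an 8-haplotype
  ancestral pool with target allele frequencies Uniform(0.05, 0.95). The
  narrow pool gives the short-range ancestral LD of an elite outcrossing
  pool — about 80 % of marker pairs within 1 cM at r2 <= 0.2, decaying to
  r2 ~ 0.005 beyond 20 cM — which is what lets marker-based prediction track
  large-effect alleles across cycles.
* Traits: a polygenic yield-like trait (GDY: 200 QTL, no QTL above 2 % of
  genetic variance, target h2 0.86, 2 replicates), an oligogenic height-like
  trait (PHT: 20 QTL at minor allele frequencies 0.02–0.2, largest
  contribution at least 12 %, h2 0.91) and a single-replicate kernel-weight-
  like trait (TKW: oligogenic, h2 0.90). Placing oligogenic QTL at low
  frequencies makes them effectively family-specific — the hypothesized
  genetic architecture that breaks across-cycle pedigree prediction while
  genome-wide markers retain persistent LD with the causal alleles.
* Trials: each cycle in its own 8 locations split between its two testers
  (locations confounded with testers, the dominant allocation of the
  emulated program), alpha-lattice blocks of 26 plots, genotype x
  location.tester variance at half the genotypic variance, block variance at
  half the plot error variance, and the plot error calibrated so the
  progeny-mean h2 hits its target under the balanced-design approximation
  `vbar_delta = 2 (sigma_gxl^2 / L + sigma_e^2 / (L R))`. Testers act only
  through the location.tester unit (specific combining ability assumed
  negligible). Targets above `1 / (1 + ratio/L)` are rejected as
  unattainable rather than silently truncated.
* Missingness: 2 % of entries at random plus a 5 % subset of SNPs at an
  elevated rate, giving the missingness filter real targets.

Every operation draws from a child stream derived from one root seed and a
string key (`derive_seed()`), so partial reruns reproduce exactly.

What the generator does **not** emulate: selection between cycles (lines
were sampled, not selected), cytoplasmic male sterility and restorer
biology, dominance and epistasis, genotype x year effects distinct from
location effects, chip-specific artifacts beyond missingness, and
linkage-map error. Passing tests therefore demonstrate that the *analysis
machinery* is correct and that the *directional* phenomena (accuracy gains
from aggregating cycles, the pedigree/marker gap and its architecture
dependence, the relatedness gradient) emerge under the stated population
structure — not that real-data accuracies would take the same values.

# Numerical choices

* Stage-2 and kernel REML tolerances: 1e-8 on the objective; variance-ratio
  search bounds `[1e-6, 1e6]`.
* Grubbs critical values from the t-distribution; the test is skipped for
  fewer than 3 residuals and degenerate (zero-variance) samples.
* Monomorphic markers are skipped (and counted) in LD; dropped from `U`.
* PCoA via classical scaling (`cmdscale`); negative eigenvalues are reported
  but excluded from coordinates.
* Ties and degenerate folds: validation sets with constant predictions or
  observations yield `NA` with an explanatory note rather than a value.

# Directional checks: operationalization

The headline findings are directional and are tested as such on the default
program with the shared 10 x 5 fold plan (problem sizes: 1040 lines, 2000
SNPs, two traits — the polygenic/oligogenic contrast):

(a) mean CV3 accuracy non-decreasing in calibration size over
{208, 416, 624, 832}; (b) forward across-cycle GBLUP above PBLUP with the
larger gap for the oligogenic trait — forward prediction is the quantity of
interest, and the direction a breeding program actually uses; (c) CV1 at
least CV2.1 per trait; (d) within-cycle mean maximum kinship above
across-cycle. Each check asserts the grand-mean inequality and that at least
8 of the 10 cross-validation replicates agree individually — a fixed
majority-sign criterion chosen for power at 10 replicates.

# Known limitations

* The *relative size* of the GBLUP–PBLUP gap between the oligogenic and the
  polygenic trait depends on the single 20-QTL architecture draw: rare
  causal alleles weaken pedigree prediction across cycles, but they also
  weaken marker prediction (chip markers are common, so LD with rare causal
  alleles is imperfect), and which model loses more varies between
  realizations. The gap itself — markers beating pedigree across cycles —
  is stable; its ordering across architectures is not, and the directional
  check on that ordering can fail for individual realizations of the
  default program.

* The stage-2 interaction variance and the weighted residual scale are only
  weakly separable when stage-1 standard errors are nearly constant; their
  sum, the BLUEs and h2 are stable regardless.
* PBLUP across-cycle predictions can be entirely flat when a calibration
  set shares no pedigree links with the validation fold; such folds are
  reported as degenerate rather than as zero accuracy.
* The generator's founders are unrelated and non-inbred by construction;
  real elite parents are themselves partially inbred and related, so
  absolute kinship levels (not their ordering) differ from real programs.
* Desk-scale defaults (2000 SNPs rather than ~10k; two traits carried
  through the cross-validation study) keep a full run in minutes on one
  CPU; all module contracts are size-free.
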