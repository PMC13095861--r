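---
title: "Dynamic fusion of SNP and dynamic connectivity data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic fusion of SNP and dynamic connectivity data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Psychiatric disorders are heritable, and the brain's functional architecture
is not static: functional network connectivity (FNC) between intrinsic
connectivity networks (ICNs) moves through recurring connectivity *states*
over the course of a scan. Most imaging-genomics fusion links one genotype
matrix to one static connectivity summary, which silently assumes that the
genetic correlates of connectivity are the same in every state.

`dynfuse` implements the alternative: one fixed SNP dosage matrix is fused
*separately* with the subject-level connectivity summary of each dynamic
state, via parallel joint ICA (jICA) decompositions. Comparing the resulting
component sets across the parallel fusions then quantifies, per component
and per modality, whether a SNP or connectivity pattern is *state-invariant*
(it recurs in every fusion) or *state-variant* (it is specific to one
state's fusion). State-variant SNP components are the interesting object:
multivariate genetic factors that only become visible when the genotype data
is anchored to a particular regime of brain dynamics.

## Pipeline and models

### Windowed connectivity

Per subject, ICN time courses are post-processed (linear detrend, despiking
by clipping at median ± 4 MAD, optional nuisance regression of realignment
parameters, zero-phase 5th-order Butterworth band-pass at 0.01–0.15 Hz,
column re-standardization) and a tapered sliding window is slid at stride
1 TR. The taper is a rectangle of `window_trs = 20` ones convolved with a
Gaussian of `sigma_trs = 3` TRs (support ± 3σ), normalized to sum 1. The
convention of a 20-TR rectangle is standard in the dynamic-FNC literature;
the despiking rule, the filter order, and σ = 3 are not fixed by that
convention, so they are explicit arguments with the defaults above.

Within each window the taper-weighted covariance is regularized through a
graphical lasso (L1-penalized precision, diagonal unpenalized, penalty
`glasso_lambda = 0.1` on the correlation scale), inverted back to a
covariance, converted to correlation, and Fisher r-to-z transformed into a
vector over the $p(p-1)/2$ network pairs (1378 pairs for the canonical
53-ICN parcellation). Correlations are capped at $|r| = 1 - 10^{-6}$ before
`atanh` so degenerate windows stay finite. At `glasso_lambda = 0` the
estimator reduces exactly to tapered Pearson correlation; the test suite
exploits this as an oracle. The penalized precision solver is a compiled
block coordinate-descent routine written for the many-small-solves regime
of per-window estimation.

### States

K-means (squared Euclidean, k-means++ seeding, 10 restarts keeping the best
inertia) is fit to the pooled windows of all subjects for each candidate
`k_range = 2:8`; the number of states is chosen by the elbow of the inertia
curve. "Elbow" is implemented as the k maximizing the second difference of
inertia, the simplest discrete-curvature reading of that criterion; the
scanned range and the statistic are configurable because the convention is
not universal. Each window is then hard-assigned to its nearest centroid
(ties to the lowest index), and a subject's windows within a state are
averaged into the subject's state-average dFNC (sa-dFNC). Subjects that
never visit a state are absent from that state's matrix, so the fusion
sample sizes legitimately differ across states. Validation-cohort windows
are assigned to the *discovery* centroids and never re-clustered.

### Covariate control

Before fusion, each connectivity feature is residualized (OLS with
intercept, categorical covariates dummy-coded dropping one level) on age,
sex and site; each SNP dosage on sex, site and the top 4 genotype principal
components (computed by SVD of the column-standardized dosage matrix, with
a deterministic sign convention) to control population stratification.

### Joint ICA

Each state's fusion z-scores every feature, rescales each modality block by
$1/\sqrt{p_\text{block}}$ so both blocks carry equal expected energy, and
concatenates them into $X$ (subjects × features). The shared model order
$C$ is the median of per-matrix scree-knee estimates (knee = farthest point
from the chord through the first and last scree points, on the unit
square), raised if needed until at least `floor_variance = 0.75` of the
variance of every sa-dFNC matrix is retained. The order is fixed across
the parallel fusions so that across-state matching compares like with like.

jICA factorizes $X = A S$: SVD-based PCA reduces $X$ to $C$ whitened rows
over features, and Infomax ICA (logistic nonlinearity, natural-gradient
block updates, initial learning rate $0.00065/\ln C$, annealed by 0.9
whenever successive weight updates turn by more than 60°, stopping at a
squared weight change below $10^{-6}$ or 512 iterations) unmixes them into
source rows $S$ (components × features). Sources are standardized to unit
variance, signed so every row has positive skewness, ordered by explained
data variance, and $A = X S^{+}$. $A S$ equals the rank-$C$ PCA
reconstruction of $X$ by construction, which the tests assert. The Infomax
hyperparameters follow common practice for this algorithm family; none is
dictated by the method itself.

The logistic nonlinearity extracts super-Gaussian (positive excess
kurtosis) sources, so components are flagged by the excess kurtosis of
their joint source row (threshold 0 by default, configurable) and only
flagged components proceed to validation. A three-fold stability check
(subjects partitioned, fusion rerun per subset, greedy |r| matching to the
full-sample components) reports per-component mean ± SD matched |r|.

### Across-state similarity

For each component of each fusion, its SNP and dFNC source sub-vectors are
correlated with those of every component of the other fusions; the
per-other-fusion best |r| values are averaged into the component's
across-state similarity per modality. Matching is directional and *with
replacement* — a component of fusion B may be the best counterpart of
several components of A — because "most similar counterpart" is a per-row
argmax, not a bijection. The headline counterpart is chosen by the mean of
the SNP and dFNC similarities; both per-modality matches are also recorded,
since which modality should drive the choice is genuinely ambiguous. The
default reporting cutoffs (invariant ≥ 0.85, variant ≤ 0.40) are labeling
conveniences, always printed alongside the output and configurable.

### Validation and association

Discovery dFNC sources are projected onto the validation cohort's
(residualized) sa-dFNC features by the Moore–Penrose pseudo-inverse,
$A_\text{val} = X_\text{val} S_\text{dFNC}^{+}$ (singular values below
$\max(\dim) \cdot \varepsilon \cdot \sigma_{\max}$ treated as zero). Each
projected loading is residualized on age, sex, site and mean framewise
displacement, then tested between cases and controls with a
pooled-variance two-sample t ($df = n_1 + n_2 - 2$); Welch's variant is
available behind a flag, since "two-sample t-test" does not by itself fix
the variance assumption. Effect size is $r^2 = t^2/(t^2 + df)$. BH-FDR is
computed *jointly across every component of every fusion* (140 tests at
order 35 with four states), and significance is $q < 0.05$.

Partial correlations of the projected loadings with cognitive scores (both
groups; age, sex, diagnosis, site removed) and symptom scores (patients
only; age, sex, site removed) use residual-on-residual Pearson correlation
with $df = n - 2 - n_\text{covariates}$, reported uncorrected and labeled
as such — this stage is descriptive, not confirmatory.

### Interpretation

Within each significant component the SNP and dFNC source sub-vectors are
z-scored *within their own block* (they live on different scales after
balancing) and features beyond $|z| > 3$ are retained, annotated with ICN
labels/functional domains and, if a user map is supplied, genes. Gene-set
overlap between components is Jaccard ($|A \cap B| / |A \cup B|$, reported
as a percentage; overlap coefficient behind a flag). Domain-level summaries
aggregate retained pairs into domain × domain counts split by sign and flag
hub ICNs. Pathway enrichment is deliberately out of scope: it requires an
external annotation database.

## The synthetic generator

The generator exists so every stage has a recoverable ground truth without
any data download. It emulates:

* **Joint sources.** `n_components` rows over the concatenated
  SNP + pair feature space, drawn sparse-Laplace (Laplace weights zeroed
  with probability 0.7 for SNPs, 0.5 for pairs). Sparse-Laplace rows have
  excess kurtosis $6/p_\text{active} - 3 > 0$, i.e. they are genuinely
  super-Gaussian, and the all-zero columns provide genuinely null SNPs.
* **Genotypes.** A continuous liability $A S_\text{SNP} + \text{noise}$
  (block-level noise variance set by `snr`, default 2) is discretized per
  SNP at the empirical quantiles $(1-m)^2$ and $(1-m)^2 + 2m(1-m)$ of its
  liability, with $m$ drawn from `maf_range` (default 0.05–0.5). This
  preserves the target minor allele frequency by construction, keeps null
  SNPs in Hardy–Weinberg proportions, and lets the planted loading–dosage
  correlation survive discretization.
* **State dynamics.** Per state, a two-factor correlation structure
  (factor scale 1.3, giving typical within-block $|r| \approx$ 0.3–0.5) is
  the centroid; subjects follow a Markov chain over states with mean dwell
  `dwell_mean = 50` TRs and uniform off-diagonal transitions. Within a
  state, time points are drawn i.i.d. from a zero-mean multivariate normal
  whose correlation is the centroid plus a subject-specific perturbation
  proportional to the subject's planted dFNC signal (per-pair SD fixed at
  0.08 correlation units — strong enough to be recoverable from ~90
  averaged windows, weak enough not to blur the state separation), repaired
  to positive definiteness by eigenvalue clipping at $10^{-6}$ and
  re-normalization to unit diagonal.
* **Case–control effects.** An additive shift of `effect_size` SD on the
  designated components' loadings for the case half of subjects, matching
  the two-sample contrast of the validation stage. A validation cohort is
  generated from the same *template* truth (same sources and centroids,
  fresh subjects), the way an independent cohort samples the same
  population.
* **Covariates.** Age, sex, site, mean framewise displacement are drawn
  independently of the planted structure; seven cognitive and two symptom
  scores are weak linear functions of a planted loading so the association
  stage has signal. All randomness flows from one integer seed through a
  counter-based substream per subject, so per-subject data are reproducible
  regardless of generation order.

What the generator does **not** emulate — and therefore what green tests do
not establish about real data: linkage disequilibrium between SNPs,
hemodynamic autocorrelation and scanner noise in the time courses,
continuous imputation dosages, site-dependent measurement effects, and any
nonlinear genotype–connectivity coupling. Passing round-trip tests show the
estimators recover the planted linear model at realistic noise levels; they
do not validate the biological model.

## Numerical choices and degenerate inputs

* Correlation saturation: $|r|$ capped at $1 - 10^{-6}$ before Fisher z.
* Graphical-lasso failures are collected per window; a window is dropped
  (with a warning if ≥ 1% of windows fail) rather than poisoning a subject.
* Empty K-means clusters trigger reseeded restarts (up to 10) before
  erroring; duplicated windows provably do not move the optimum.
* Assignment ties break to the lowest state index, making runs reproducible.
* Zero-variance features are dropped with warnings (fusion input, genotype
  PCA) or errors naming the column (post-filter time courses).
* The ICA sign/order ambiguity is fixed by positive source skewness and
  explained-variance ordering; all cross-run comparisons use absolute
  correlations with greedy matching, never index identity.
* Pseudo-inverse rank cutoff: $\max(\dim) \cdot \varepsilon \cdot
  \sigma_{\max}$.
* A subject's sa-dFNC is computed from however many windows it has in a
  state (even one); but states visited by too few validation subjects
  (fewer than 10, or with a diagnostic group below 2) are skipped in the
  testing stage rather than producing unstable statistics.

## Problem sizes in the test suite

The default synthetic study is 200 subjects × 300 SNPs × 10 ICNs
(45 pairs) × 400 TRs with 4 states — the largest configuration that keeps
a full round trip (windowing, clustering over ~73,000 windows, four
fusions) comfortable on a laptop-class single core. ICA recovery checks use
500 subjects at SNR 2 over 10 seeds; FDR calibration uses 50 null
replicates of 4 × 35 components at n = 400; the power check plants a
0.5-SD shift on components 2 and 5 of a 35-component, 1378-pair projection
at n = 400 over 20 seeds. These sizes are scaled-down analogues of the
study designs this method targets (tens of thousands of discovery
subjects, roughly 13,000 SNPs, 53 ICNs / 1378 pairs), chosen so planted
effects sit at comparable detectability rather than at matched absolute
dimensions.

## Known limitations

* Modality balancing by $1/\sqrt{p_\text{block}}$ equalizes block energy
  but not information content; adaptive weighting is out of scope.
* The elbow statistics (states and scree knee) are conventions; both are
  exposed and logged because reasonable alternatives (gap statistic, AIC)
  can disagree.
* The super-Gaussianity screen is a kurtosis threshold at 0; heavier
  screening rules would need a reference distribution for source kurtosis.
* Fuzzy/meta-state clustering, parallel ICA/mCCA/IVA fusion engines, LD
  pruning and GWAS locus selection, and pathway enrichment are explicitly
  not implemented.
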