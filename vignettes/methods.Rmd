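---
title: "Hidden variable inference for QTL mapping with pcaqtl: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hidden variable inference for QTL mapping with pcaqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcaqtl)
```

## The statistical setting

A molecular QTL analysis regresses each column of a processed phenotype
matrix $Y$ ($n$ samples $\times$ $p$ features) on each of its local SNP
dosages, adjusting for covariates:

$$Y[,j] \sim S_j[,l] + X_1 + X_{\mathrm{inferred}},$$

keeping the two-sided $t$-test p-value of the dosage coefficient at
$\mathrm{df} = n - (K_{\mathrm{cov}} + 2)$. $X_1$ holds measured
covariates (genotype PCs for population structure, platform, sex, ...);
$X_{\mathrm{inferred}}$ stands in for everything unmeasured — batch
structure, cell composition, technical drift — that shapes many features
at once. Because such shared structure dominates the leading variance
directions of $Y$, principal components are a natural, fast and
interpretable choice for $X_{\mathrm{inferred}}$. `pcaqtl` builds the
full workflow around that choice and supplies the simulation machinery
to test it.

Two usage variants are provided. `pca_direct` runs PCA on the
(transformed) phenotype matrix itself and *afterwards* drops any known
covariate that the top $K$ PCs capture with unadjusted $R^2 \ge 0.9$
(keeping it would duplicate a regressor the PCs already supply).
`pca_resid` first regresses $X_1$ out of every feature and takes PCs of
the residuals, keeping $X_1$ unfiltered. `pca_direct` is the default:
it is simpler, performs equivalently in our benchmark, and the known
covariates cannot distort the PCs — a hedge in case they are not real
confounders. The filter uses *unadjusted* $R^2$: the question is how
much of the covariate the PCs reproduce, not a parsimony-adjusted fit.

## Transforms

Three phenotype transforms are supported before inference:
`center_scale` (each feature to mean 0, sd 1, with the $n-1$
denominator), `int_within_feature`, and `int_within_sample`. The inverse
normal transform maps ranks to normal quantiles with the Blom offset
$\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$, average ranks for ties. The
rank-based INT literature admits several offsets and does not force one;
Blom is the convention adopted here, recorded as a package choice rather
than an external requirement. INT output depends only on ranks, so it is
invariant to any strictly monotone transform of its input — the property
the tests assert. Centering always precedes scaling, and PCA should
virtually always be run with both (`center = TRUE, scale = TRUE`):
unscaled features let high-variance features dominate the components.

## PCA and the sign convention

`runPCA()` is the singular value decomposition of the centered/scaled
matrix (via `prcomp`), reporting $r = \min(n-1, p)$ components,
$\mathrm{pve}_k = s_k^2 / \sum_i s_i^2$. SVD determines each component
only up to sign, which differs across linear-algebra backends; each
component is therefore flipped so its largest-magnitude loading is
positive, making scores byte-reproducible. When the input is
rank-deficient (for example an exactly duplicated feature) the trailing
components carry numerically zero variance; their scores are noise and
orthogonality is only meaningful among components with
$\mathrm{pve} > 0$.

## Choosing the number of components

**Elbow.** Draw the chord from the first scree point $(1,
\mathrm{pve}_1)$ to the last $(r, \mathrm{pve}_r)$; the scree point
farthest (perpendicular distance) from this chord is the elbow — the
first component sitting on the flat part. $K$ is the number of
components *before* it, so a scree like $(0.6, 0.3, 0.01, \dots)$ gives
$K = 2$ and $(0.9, 0.01, \dots)$ gives $K = 1$. Exact distance ties
resolve to the smallest index, and a perfectly flat or linear scree —
no elbow at all — yields $K = 0$; workflow consumers floor at 1 when a
method needs at least one component.

**Buja–Eyuboglu permutation test.** Parallel analysis: permute each
feature column independently ($B = 20$ times by default), which destroys
inter-feature correlation while preserving marginals, and recompute the
pve spectrum. Component $k$ is retained when its observed
$\mathrm{pve}_k$ exceeds the empirical $1-\alpha$ quantile
($\alpha = 0.05$, type-1 quantile) of its $B$ permuted values; selection
stops at the first failure so the retained PCs always form a prefix —
matching how top-$K$ PCs are consumed downstream. Both parameters are
config-exposed and echoed in the returned diagnostics, so any other
defaults can be matched exactly. On pure noise this selects $K \le 2$ in
the overwhelming majority of runs; on planted factor structure it finds
every factor whose variance share clears the permutation null. In
practice BE selects at least as many components as the elbow — BE asks
"more than chance", the elbow asks "dominant" — and BE is best read as
an upper bound on a reasonable $K$.

Choosing $K$ by maximizing downstream discoveries is deliberately not
offered: it is expensive, statistically circular, and tends to inflate
$K$ far beyond the components that carry real structure.

## The HCP baseline

Hidden Covariates with Prior couples the low-rank reconstruction of $Y$
to the known covariates:

$$\min_{Z, B, U}\; \|Y - ZB\|_F^2 + \lambda_1 \|Z - X_1 U\|_F^2
  + \lambda_2 \|B\|_F^2 + \lambda_3 \|U\|_F^2 .$$

Each block has a closed-form minimizer given the others, so cyclic
updates ($Z \to B \to U$ per sweep) descend monotonically; iteration
stops when the relative objective change drops below `tol` (default
1e-6) or at `maxIter` (default 100). Initialization is deterministic —
$Z^{(0)}$ is the top-$K$ PC scores, $B^{(0)}, U^{(0)}$ their closed-form
responses — so a fit is bit-reproducible. Defaults
$\lambda = (1, 1, 1)$ are an unremarkable starting point, config-exposed
and logged; no hyperparameter search is attempted. With $\lambda_1 = 0$
and $K$ above the rank of $Y$ the component scale is unidentifiable
(warned); as $\lambda_1 \to \infty$ the components are pulled into the
column span of $X_1$, a limit the tests verify via principal angles.

## The QTL engine

`mapQTL()` residualizes both phenotypes and dosages on
$[\mathbf{1}, X]$ once (Frisch–Waugh–Lovell), then each (feature, SNP)
pair is a simple regression of residual on residual with
$\mathrm{df} = n - (K_{\mathrm{cov}} + 2)$ — algebraically identical to
the full per-pair OLS fit, which is what the oracle tests assert against
`lm()`. Numerical policies: exactly collinear covariate columns are
pruned (first of a dependent set kept); dosages with in-sample variance
below $10^{-12}$ (monomorphic in sample) produce NA rows excluded from
multiple testing; p-values are floored at the smallest positive double
so they stay in $(0, 1]$. Affine maps of any covariate or of the
response leave all dosage p-values unchanged — the invariance that makes
"PEER factors versus scaled PCs" a distinction without a difference in
linear regression. Benjamini–Hochberg q-values are computed globally
over the emitted pairs by default (per-feature optionally); the power
metric thresholds on q ≤ FDR by default, with a nominal-p rule retained
as an alternative since reasonable benchmarks differ here.

## Synthetic data

The generator exists to create datasets where the truth is known
exactly, at the study conditions the benchmark is reported under.

**Genotypes.** Per-SNP minor-allele frequencies are uniform on
`mafRange` (default 0.05–0.5, common variants). Haplotypes follow a
first-order Markov copying chain: each allele copies its left neighbor
with probability `ldRho`, else is a fresh Bernoulli(maf) draw; dosage is
the sum of two haplotypes. This produces locally decaying LD with
adjacent-dosage correlation of roughly `ldRho` (default 0.3, moderate
local LD) — enough to make the ranking problem realistic, though far
simpler than real haplotype mosaics.

**Design 2 (cis-focused, the default).** Per gene: `numOfEffectSNPs`
causal SNPs drawn uniformly from the gene's 50-SNP cis block, standard
normal effect sizes and covariate loadings, covariate values shared
across genes, i.i.d. Gaussian noise. The three components are rescaled
so their realized sample-variance shares are *exactly*
`PVEGenotype : PVECovariates : remainder` — deterministic division by
realized standard deviations rather than expected-value calibration —
which makes `realizedPVE` a testable invariant and removes a nuisance
source of replicate noise. Defaults (n = 200, p = 500, q = 50, one
causal SNP per gene, three hidden covariates and no known ones,
PVEGenotype = 0.1, PVECovariates = 0.4) describe a moderately
confounded study in which hidden-covariate adjustment visibly matters;
they are the conditions under which the package's benchmark figures are
computed. Genes occupy disjoint cis blocks, so inter-gene correlation
arises only through shared covariates.

**Design 1 (trans-dominated).** Latent factors (default 10) drive dense
trans effects on all genes; the first `numTransHotspots` (default 5)
factors are made partially genetic by mixing in a hotspot SNP's
standardized dosage with weight `pveHotspot` (default 0.5). Genes get a
sparse cis effect, a covariate component, the trans component (aggregate
share `pveTrans`, default 0.6 — expression dominated by trans
regulation), and noise, rescaled exactly as in design 2. Truth records
cis pairs and every (gene, hotspot) pair as trans. With zero hotspots
and zero trans share the design degenerates to a cis-only dataset.

**What the generator does not emulate:** non-linear covariate effects,
heavy-tailed or count-valued phenotypes, population structure,
relatedness, realistic LD blocks, allele-frequency spectra, or sparse
per-gene covariate effects (loadings are dense). Passing benchmarks here
demonstrates correct behavior under linear-Gaussian confounding, not
performance on any particular real cohort.

All randomness flows from one master seed through labeled stream
splitting (`deriveSeed(seed, label)`), so each stage is independently
reproducible and every derived seed stays below $2^{31}$.

## Evaluation metrics

**AUPRC.** Pairs ranked by ascending p-value; tied p-values collapse
into single threshold steps; the area is the step-wise sum of precision
at achieved recall (no interpolation) — appropriate when negatives
outnumber positives a thousandfold, where AUROC saturates. A random
ranking concentrates near the prevalence.

**Concordance.** With $m$ true hidden covariates and $n_{\mathrm{inf}}$
inferred ones: regress each true covariate on the full inferred set ($m$
adjusted $R^2$'s, small-sample adjustment
$1 - (1 - R^2)(N-1)/(N-k-1)$), each inferred covariate on the full true
set ($n_{\mathrm{inf}}$ reverse adjusted $R^2$'s); the two means are the
adjusted-$R^2$ score and the reverse score, and the concordance score is
their average. It is invariant to per-column affine maps, permutations
and sign flips of either set, equals 1 exactly when the sets span the
same space, and is mean-zero for independent sets. The reverse direction
guards against "inferred covariates" that correlate with nothing real.

## Diagnostics

`countFactorClusters()` clusters factors by complete linkage on
$1 - |\mathrm{cor}|$ and cuts so that within every cluster all pairwise
$|\mathrm{cor}|$ exceed the threshold *strictly* (the cut height is
nudged by $10^{-9}$ so a pair at exactly the threshold separates).
The cluster count reads as the number of genuinely distinct factors —
methods without an orthogonality guarantee can return many near-copies,
and requesting 20 factors that form 3 clusters means 3 usable
dimensions. `matchFactorsToPCs()` pairs factors with PCs greedily on
$|\mathrm{cor}|$ (largest remaining correlation first); greedy matches
the exhaustive best bijection whenever the correlation matrix has a
dominant matching, and an `optimal` exhaustive mode (up to 9 factors) is
available for the constructed cases where greedy is suboptimal. The
reordered matrix is summarized by its diagonal and off-diagonal means
with standard errors; factors that truly are the PCs give exactly 1
and 0.

## Numerical choices, in one place

- OLS throughout is QR-based with pivoting; collinear columns drop with
  a warning (first of each dependent set kept).
- PCA sign: largest-|loading| positive. PVE over all $\min(n-1, p)$
  components sums to 1.
- Elbow ties: smallest index. BE quantile: type 1. BE stopping:
  sequential prefix.
- HCP convergence: relative objective change; non-finite loss is a hard
  error.
- Monomorphic-dosage threshold: in-sample variance $< 10^{-12}$.
- p-value floor: `.Machine$double.xmin`.
- Cluster cut: $h = (1 - \mathrm{threshold}) - 10^{-9}$ (strict
  threshold).
- Written numeric tables carry 17 significant digits and survive
  read/write round trips to $10^{-12}$.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the benchmark at the
default design-2 conditions (200 × 500 × 50, up to 10 replicates),
BE calibration on 100 × 200 matrices (50 null + 20 spiked runs), engine
oracle checks on dozens of small random instances, and a 1,000-pair
type-I simulation — sizes chosen to exercise every code path at
meaningful scale while keeping a full run in minutes on one core.

## Known limitations

- The QTL engine is OLS-only: no mixed models or kinship correction, no
  permutation-based feature-level calling, no interaction terms.
- PCA variants are plain SVD — no sparse, robust or probabilistic PCA.
- The benchmark accepts externally computed factor matrices
  (`external:<file>`) rather than re-implementing variational or
  iteratively reweighted competitors; comparisons with those methods use
  their own output files.
- VCF support is biallelic GT-based only (no DS dosages, no BCF/PLINK
  formats).
- Design defaults above are the package's chosen study conditions;
  conclusions at other points of the parameter space require running the
  grid there.
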