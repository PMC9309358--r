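---
title: "Tri-modal coupling of monocyte genes, cortex and cognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tri-modal coupling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trimodal)
```

## The scientific question

Circulating monocytes come in three subsets defined by CD14/CD16 surface
markers — classical (CD14++CD16−), intermediate (CD14++CD16+) and
nonclassical (CD14+CD16++) — each with its own transcriptomic signature.
This package implements a cohort-level analysis of how the blood expression
of subset-labeled monocyte signature genes *couples* with cortical thickness
(34 bilateral Desikan–Killiany regions) and cognitive performance (the seven
MCCB domain T-scores) in two groups: healthy controls (HC) and first-episode
schizophrenia patients (FES). The working hypothesis it operationalizes is
that monocyte gene expression relates *negatively* to cortical thickness and
cognition in health, and that this coupling is attenuated or even reversed
early in psychosis.

The unit of analysis is a *coupling profile*: the matrix of covariate-
adjusted partial correlations between two feature blocks, computed
separately per group, Fisher-transformed, and compared between groups as a
paired sample of matched entries.

## The statistical procedure

1. **Preprocessing.** Raw gene counts are filtered (mean count across
   subjects ≥ 4, then the lowest 15% of the raw-count variance distribution
   removed), normalized to log2 counts per million
   (`log2(count / library size × 10^6 + 1)`), and restricted to the 54
   annotated signature genes. Left/right thickness columns are averaged to
   34 bilateral regions.
2. **Group statistics.** Demographics use Pearson chi-square (no continuity
   correction), Student's t or the tie-corrected Mann–Whitney approximate Z
   (the t/Z dispatch is a Shapiro–Wilk normality check at α = 0.05 in both
   groups). Outcome comparisons are ANCOVA-style partial F tests for the
   group term in `y ~ group + covariates`. A per-gene log-linear model on
   log2-CPM with an ordinary t test supplies a simplified differential
   expression table; it is deliberately *not* a negative-binomial fit.
3. **Coupling.** For feature pair (x, y), both are residualized on
   [intercept | covariates] by least squares; r is the Pearson correlation
   of residuals, df = n − 2 − k, and `Z_r = atanh(r)`. Covariates are age
   and sex, plus education years whenever a cognition block is involved.
   Profiles are compared between groups by a paired two-sided t test across
   matched entries (strict upper triangle within a module; all entries
   between modules), with Benjamini–Hochberg adjustment across the scopes
   of one comparison family. Subset-stratified comparisons restrict gene
   rows to one monocyte subset. The gene-by-feature screen computes all
   pairwise partial correlations, reports nominal p < 0.01 hits, and
   adjusts over the full family (54 × 34 regions, 54 × 7 domains).
4. **Mediation.** The X → M → Y decomposition fits `M ~ X + covs`,
   `Y ~ X + M + covs` and `Y ~ X + covs` by least squares on z-scored
   variables, giving β-style paths a, b, c′, c and indirect effect
   ab = a·b (c = c′ + ab exactly). Whole subject rows are resampled with
   replacement 5000 times; the 2.5/97.5 percentiles of ab give the CI.
   Mediation is *full* if the CI excludes 0 and the direct path is not
   significant (p ≥ 0.05), *partial* if both are significant.

## The synthetic cohort generator

Because subject-level data of this kind cannot be redistributed, the
package ships a generator that reproduces the statistical *structure* the
analysis assumes, so every stage can be validated end to end.

Each subject s carries one latent factor `u_s ~ N(0,1)` shared by all three
modalities; coupling is induced by per-feature loadings and group
differences in coupling purely by group-specific loading scales:

* gene signal: `x_is = β_age·age + β_sex·sex + λ_i^(g)·u_s + ε`, ε ~ N(0,1);
  counts are negative binomial with mean
  `libsize/10^6 · 2^(base_i + FC_i·1[FES] + σ_x·x_is)` and dispersion 0.2;
* thickness: `t_js = T_j + Δ_j·1[FES] + γ_age·(age−mean) + s_T·(μ_j^(g)·u_s + ε)`,
  split into hemispheres as `t ± N(0, 0.02 mm)` so bilateral averaging is a
  real (and exactly invertible) operation;
* cognition: `c_ks = C_k + δ_k·1[FES] + γ_edu·(edu−mean) + s_Ck·(ν_k^(g)·u_s + ε)`;
* monocyte subset percentages: logistic-normal components calibrated by
  quadrature to the target means/SDs, with the group shift on the
  nonclassical component (7.61% HC vs 5.27% FES).

For unit-variance noise, the implied correlation between features with
loadings l and m is `l·m / √((l²+1)(m²+1))` — the package's closed-form
oracle (`impliedCoupling(..., layer = "latent")`). What the *pipeline*
estimates is additionally attenuated by counting noise on the log2-CPM
scale; the `"observed"` layer multiplies in the per-gene delta-method
factor `α_i = √(σ_x²(λ_i²+1) / (σ_x²(λ_i²+1) + v_i))` with
`v_i = (ψ′(1/φ) + 1/μ_i)/ln(2)²` (φ the NB dispersion, μ_i the expected
count). Covariate effects never enter either layer because partial
correlation removes them.

The count matrix also contains 446 *background* genes with zero loadings
and zero fold change, log-spread baselines scaled so expected totals are
about 10^6 CPM-equivalents. They matter twice: the variance/abundance
filters have realistic material to remove, and — more importantly — the
per-million normalization divides by a column total dominated by
factor-free genes. (In a 54-gene matrix the total itself would carry the
latent factor and normalization would cancel the very signal under study.)

### Presets and calibration

`defaultConfig("paper-like")` encodes the study conditions: 111 HC vs 128
FES; 54 genes split 4/9/20/21 across pan/classical/intermediate/
nonclassical; mean cortical thinning ≈ −0.05 mm (eight
parietal/temporal/occipital regions thinner, pericalcarine and lingual
thicker); MCCB composite deficit ≈ −13.8 T; nonclassical decrease.
Gene-loading scales are fixed (0.6 HC, 0.4 FES, encoding attenuated
within-gene coupling in patients); the region and cognition loading scales
are then solved by root-finding so the *observed-layer* block-mean Fisher
Z_r hits −0.116 (HC) vs −0.025 (FES) for gene–cortex and −0.088 vs +0.085
for gene–cognition. `"null"` zeroes all loadings and group effects;
`"strong-coupling"` uses scales of ±3 so every implied latent correlation
exceeds 0.3 in magnitude.

Optional `missingness` settings blank the thickness, MCCB or subset-
percentage blocks outside nested sub-cohorts (imaging 60/54, MCCB 58/52,
flow cytometry 29/27), emulating the partial-overlap design; missing
subjects are excluded pairwise per analysis, never listwise. The preset
default is complete data, which is what the parameter-recovery checks use.

### What the generator does *not* emulate

* **One factor cannot match every block mean.** With group-specific
  loadings on a single factor, the signs of the three between-module block
  means are linked: in the FES calibration (gene–cortex < 0,
  gene–cognition > 0) the implied cortex–cognition coupling is negative,
  whereas a real patient cohort shows a weakly positive one. The two
  calibrated targets are the gene–brain and gene–cognition profiles.
* **Within-module coupling is much weaker than real data.** Real gene–gene
  and region–region correlation means (Fisher Z ≈ 0.3–0.45) reflect broad
  co-expression and a global thickness factor that the one-factor model
  does not contain; here the within-module means are small and serve only
  directional checks (HC above FES).
* **No global thickness factor.** Regional noise is independent, so the
  whole-cortex average is much less variable than in real cohorts and
  group F statistics on it are correspondingly inflated.
* **No transcriptome.** Only the 54 signature genes plus generic background
  genes are simulated — no 9000-gene differential-expression inventory, no
  reads, no images.

Passing tests therefore demonstrate that the *pipeline* recovers the
structure it assumes at the study's sample sizes — not that real data obey
that structure.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `minMeanCount` | 4 | counts | abundance filter on per-gene mean raw count |
| `varPercentile` | 15 | % | share of remaining genes dropped as low-variance |
| `pseudocount` | 1 | CPM | keeps zero counts at exactly 0 on the log2 scale |
| covariates | age, sex (+ education) | — | education only when cognition enters |
| `alphaNominal` | 0.01 | — | per-pair screen level |
| `alphaFDR` | 0.05 | — | family FDR threshold |
| `nBoot` | 5000 | resamples | percentile CI of the indirect effect |
| NB dispersion | 0.2 | — | typical bulk RNA-seq overdispersion |
| library size | lognormal(ln 2×10^7, 0.25) | reads | typical whole-blood depth |
| `s_T` | 0.10 | mm | per-region thickness scale |
| hemispheric SD | 0.02 | mm | L/R split noise |

## Numerical and design choices

* "Counts < 4" is read as *mean* raw count across subjects < 4; a per-cell
  reading would empty realistic matrices. Filtering precedes normalization;
  per-million totals default to the pre-filter column sums.
* Variance-filter ties are broken by keeping the larger mean, then gene
  symbol order, so filtering is deterministic; the filter is idempotent at
  fixed thresholds.
* Correlations with |r| ≥ 1 − 10⁻¹² are clipped before `atanh` (with a
  warning); within-module paired comparisons use the strict upper triangle
  because diagonal Z_r is infinite.
* Between-module comparisons pool all gene × feature entries into one
  paired vector per scope (rather than averaging per gene first). Entries
  within a profile are statistically dependent; the paired t treats them as
  exchangeable pairs, so its type-I calibration is asserted for
  independent-entry simulations only.
* Zero-variance paired differences are reported as t = 0, p = 1 with a
  flag, never NaN.
* Sex is coded 0 = female, 1 = male in every model matrix. TSV is the
  default dialect; CSV is sniffed from the extension.
* The bootstrap CI is the plain percentile interval (no bias correction);
  resampling is of whole subject rows; degenerate resamples are redrawn
  (at most 100 times). Coefficients are β-style via upfront z-scoring; raw
  scale is available with `standardize = FALSE`. An exactly deterministic
  mediator is collinear with its cause and rejected rather than decomposed.
* The canonical Desikan–Killiany order is alphabetical by FreeSurfer label;
  region-name validation accepts exactly those 34 labels.
* `.Random.seed` is saved and restored around every seeded operation, so
  package calls never perturb user RNG state; a pipeline run is a pure
  function of (inputs, config, seed) and its outputs are byte-identical
  across repeats.

## Problem sizes used in the test suite

Generator fidelity is checked at 5000 subjects per group (block-pair mean
correlations within 3/√n of the closed form; individual pairs within 5/√n,
the wider band covering the maximum over ~1800 correlated entries plus the
delta-method approximation). Parameter recovery runs 50 seeds at the study
sizes (128/111), requiring the mean recovered gene–cortex block means
within ±0.03 of the implied values and the group difference flagged at
FDR < 0.05 in at least 95% of seeds. Type-I error of the paired comparison
uses 500 independent-entry null profile pairs; mediation CI coverage uses
300 datasets of n = 200 at 1000 resamples. These sizes were chosen to give
tight Monte-Carlo error on desktop hardware.

## Worked example

```{r example, eval = FALSE}
cfg <- defaultConfig("paper-like")
coh <- generateCohort(cfg, seed = 1)
cnt <- rawCounts(coh); ph <- phenotypes(coh)
expr <- log2RPM(filterCounts(cnt)$counts, libSizes = colSums(cnt))
sig <- selectSignatureGenes(expr, geneAnnotation(coh))
th <- averageHemispheres(thicknessTable(coh))
cog <- cognitionMatrix(ph)
hc <- buildCoupling(sig, th, cog, ph, "HC")
fes <- buildCoupling(sig, th, cog, ph, "FES")
compareCouplingSets(hc, fes)
```

Or, end to end with files on disk:

```{r pipeline, eval = FALSE}
runPipeline(pipelineConfig(synthetic = TRUE, seed = 1, outdir = "out"))
```
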