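---
title: "Methods: phantoms, texture features and survival models in petrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantoms, texture features and survival models in petrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

petrad implements an FDG-PET radiomics survival workflow — tumor
delineation, grey-level texture quantification, repeated-LASSO feature
selection, and Cox/concordance survival modelling — exercised entirely on
synthetic phantoms and synthetic cohorts, so that every stage is testable
without patient data. This vignette documents the models, the defaults and
the design choices that were genuinely open.

## The phantom generator

A phantom is a spherical lesion on a flat background, sampled on a grid with
voxel spacing `(2.73, 2.73, 3.27)` mm by default (a typical clinical PET
reconstruction grid). The uptake profile is

$$ I(d) = b + (p - b)\,\pi(d), \qquad
   \pi(d) = \begin{cases} 1 & d \le r \\
   \exp\!\left(-\frac{(d-r)^2}{2\sigma^2}\right) & d > r, \end{cases} $$

with background $b$ (default 1 SUV, soft-tissue-like), peak $p$ (default
12 SUV, a typical hot head-and-neck primary), plateau radius $r$ (default
12 mm) and border falloff $\sigma$ (`border_sigma_mm`). Additive Gaussian
noise (default SD 0.5) is truncated at zero. Two points matter:

* **The border falloff is the phenotype knob.** $\sigma \to 0$ yields a
  sharp binary plateau — the "spiculated-looking" uptake associated with
  recurrence — while large $\sigma$ yields a smooth, Gaussian-like lesion.
  A single parameter therefore controls the low-intensity long-run emphasis
  (LILRE) contrast between the two phenotypes: a wide dim shoulder inside
  the isocontour produces long runs of low grey levels.
* **Noise is additive truncated Gaussian, not reconstruction noise.** The
  downstream features only need a controllable heterogeneity scale; no
  scanner point-spread function, scatter or attenuation is simulated, so
  passing tests say nothing about robustness to real reconstruction
  artefacts, inter-scanner variation, or physiological uptake patterns.

A lesion that does not fit inside the grid is rejected at spec time. Voxel
centres sit at $(i - \tfrac12)\cdot\text{spacing}$; phantoms are
bit-reproducible given a seed.

## Segmentation and the volume filter

Delineation is the 40% SUVmax isocontour: all voxels at or **above**
`fraction * max(SUV)` (inclusive, which makes the constant image well
defined), restricted to the 26-connected component containing the
global-maximum voxel. Ties for the maximum anchor on the lowest linear
index, which is the lexicographically smallest (z, y, x) voxel; tied voxels
are all in-threshold regardless. The threshold is relative, so segmentation
is invariant under positive rescaling. Voxel thresholding is used rather
than a sub-voxel marching surface; no morphological post-processing is
applied, since the clinical analogue of that step is visual inspection.

Tumors below 2.6 ml are excluded before feature extraction: texture
statistics on a handful of voxels are unstable or undefined. 2.6 ml is the
volume of the third-smallest NEMA IEC quality-assurance sphere (17 mm inner
diameter; $\tfrac43\pi(0.85\,\text{cm})^3 \approx 2.57$ ml, 2.6 to one
decimal). The rule is strict: a 2.60 ml lesion is retained.

## Quantization and texture features

The VOI is digitized into `B = 64` bins between the minimum and maximum SUV
inside the mask: `level = min(B, floor((v - vmin)/(vmax - vmin) * B) + 1)`.
The `min()` assigns `vmax` to bin B in closed form with no empty top bin. A
degenerate VOI maps to level 1 everywhere. Because the reference range is
internal, all quantized-domain features are invariant under positive affine
rescaling of the SUVs.

The matrix definitions (all with explicit brute-force-verifiable forms):

* **GLRLM** — maximal collinear runs of equal level along each of the 13
  unique 3D directions, runs breaking at the mask boundary; matrices summed
  over directions before feature computation (an `aggregation = "average"`
  switch computes per-direction features and averages them instead, since
  either convention is found in texture toolkits; summing is stabler for
  small VOIs). Run percentage is `n_runs / (13 * n_voxels)`; LILRE is
  $(1/N_r)\sum_{ij} p(i,j)\, j^2/i^2$.
* **GLCM** — symmetric co-occurrence at displacement 1 over the 13
  directions, normalized; homogeneity $\sum P/(1+|i-j|)$ and contrast
  $\sum P (i-j)^2$.
* **NGTDM** — per level, the occurrence probability and the summed absolute
  deviation from the mean of the in-mask 26-neighbours; neighbourhoods are
  truncated at the mask boundary and voxels with no in-mask neighbour are
  skipped. Coarseness is $1/(\varepsilon + \sum_i p_i s_i)$ with
  $\varepsilon = 10^{-6}$, so a constant VOI caps at $10^6$ — note this cap
  means coarseness is *not* monotone in border smoothness down to
  $\sigma = 0$, where the noise-free VOI becomes a constant plateau.
* **GLSZM** — 26-connected zones of constant level; low-intensity
  large-zone emphasis is $(1/N_z)\sum z(i,s)\, s^2/i^2$.
* **Texture-spectrum codes** — each voxel is coded against its 26
  neighbours in a fixed order (0 lower / 1 equal / 2 higher on quantized
  levels; missing or out-of-mask neighbours code as "equal"), and code
  similarity is the probability that two random distinct voxels share an
  identical code (the Simpson index of the code distribution). No published
  closed definition of "code similarity" was available to mirror, so this
  explicit substitute is isolated behind one function.

First-order features (mean, max, moment skewness $m_3/m_2^{3/2}$, Pearson
kurtosis $m_4/m_2^2$) and SUV peak are computed on raw SUV — the
quantized-domain/raw-domain split is a deliberate choice where toolkit
conventions differ. SUV peak is the maximal mean over a 1 cm³ sphere of
voxel offsets centred at each mask voxel; SUL peak rescales it by lean body
mass over weight, with LBM from the sex-specific James formula.

Degenerate VOIs never crash extraction: undefined features (skewness of a
constant VOI) come back as `NA`.

## The synthetic cohort

Clinical covariates follow a fixed scheme modelled on a typical
head-and-neck chemoradiotherapy population: gender Bernoulli(0.75 male),
age uniform 40–80 y, stage Bernoulli(0.65 IV), site Bernoulli(0.55
oropharynx), concurrent chemotherapy Bernoulli(0.7 yes), plus sex-specific
weight and height for the SUL scaling. Event times are exponential with
hazard $h_0 \exp(\sum_f \beta_f z_f)$ over standardized features
($h_0 = 0.02$/month by default, a median of about 35 months). Censoring is
independent uniform on $(0, u)$ with $u$ solved by root finding so the
expected censored fraction matches the target rate given the drawn event
times. The log hazard ratios tying survival to image features are free
parameters of the generator (no natural-scale effect size was available to
calibrate them against); the pipeline default is $\beta_{\text{LILRE}} =
-1.5$ per SD, and the recovery tests use $-3$ for a decisively strong
signal.

## Stability selection

Each of `n_runs` repetitions draws a bootstrap resample of subjects
(`resample = "none"` reproduces a folds-only reading, where the only
randomness is the CV fold assignment), standardizes columns **within** the
resample, fits a penalized Cox path, and picks the penalty by 10-fold
cross-validated partial-likelihood deviance. Features active in strictly
more than half the runs are selected.

The per-run penalty rule was a genuinely open choice. The
deviance-minimizing `lambda.min` is a common default but demonstrably
overselects: in our recovery setting (n = 500, one causal feature, four
noise features, 100 bootstrap runs) it selects individual noise features in
well over half the runs, which would make the majority-vote threshold
meaningless. The default here is therefore the one-standard-error rule
`lambda.1se`, the parsimonious standard alternative, under which noise
frequencies stay near zero while a strong causal feature is selected in
every run; `lambda_rule = "min"` remains available. Degenerate resamples
(e.g. all-censored) are redrawn and counted.

The correlation screens are Spearman (flagging selected-feature pairs at
$|\rho| \ge 0.6$, redundancy) and Pearson (flagging feature–clinical pairs
at $|\rho| \ge 0.2$, non-independence).

## Survival statistics

Cox models use Efron tie handling. Monotone-likelihood pathologies are
flagged when a coefficient exceeds 15 in absolute value (hazard ratios on
such fits are astronomically unreliable). The Harrell c-index uses the
original comparable-pair definition: a pair is comparable iff the shorter
observed time ends in an event (ties in time are not comparable), tied risk
scores count one half. Ten-fold cross-validation pools the held-out linear
predictors and computes one c-index on the pooled vector; fold assignment
is seeded and falls back to event-stratified assignment if a training fold
would have fewer than two events.

No standard test for comparing two Harrell c-indexes on the same cohort is
canonical, so the package uses a paired bootstrap over subjects of
$\Delta c$: percentile CI and two-sided bootstrap p-value
($p = 2\min(\Pr(\Delta c^* \le 0), \Pr(\Delta c^* \ge 0))$). Comparing a
model with itself returns $\Delta c = 0$ and $p = 1$ exactly.

Kaplan–Meier estimation and the log-rank test are delegated to the survival
package; the median split assigns ties to the low group. The rank-sum test
is exact when both groups have at most 20 observations without ties,
otherwise normal-approximate with tie and continuity corrections. The
recurrence-pattern rule classifies the fraction of recurrence volume inside
the prescription 95% isodose surface as in-field (> 0.80), marginal
(0.20–0.80) or out-field (< 0.20).

## Pipeline and reproducibility

Stages communicate only via files (NIfTI, CSV, JSON); every CSV carries a
provenance header with the package version and a hash of the configuration
(excluding the output path). One global seed deterministically derives all
stage seeds, and identical configuration plus seed reproduces byte-identical
tables. In the final model, age and stage are force-included alongside the
selected imaging features; whether chemotherapy enters the pool is a config
flag (`include_cht`, default TRUE).

## Problem sizes used by the test suite

The suite verifies matrix builders against exhaustive enumeration on
4×4×4 masked volumes (100 seeded draws), c-index endpoints at n = 2000,
parameter recovery on a 300-subject cohort with 200 stability runs, and
phenotype separation on 30 + 30 phantoms on a 32×32×24 grid — sizes chosen
to make each property decisively testable on a single CPU while staying
well away from asymptotic regimes that would add nothing to the check.

## Known limitations

* Phantoms are spherical (optionally ellipsoidal) with radially symmetric
  borders; real lesions have irregular shapes, necrotic cores and
  physiological background gradients, none of which are emulated.
* The feature catalogue covers the families containing every named headline
  feature (first-order, GLCM homogeneity/contrast, GLRLM run
  percentage/LILRE, NGTDM coarseness, texture-spectrum code similarity,
  GLSZM low-intensity large-zone emphasis, SUV/SUL peak), not a full
  75-feature toolkit catalogue, and no IBSI certification is claimed.
* The exponential hazard and uniform censoring of the cohort generator are
  convenient, not clinically fitted; absolute hazard ratios from synthetic
  runs have no clinical meaning.
* Where a published definition was unavailable (texture-code similarity,
  NGTDM boundary handling, the stability-selection randomness source), the
  implemented choice is explicit, documented above and isolated behind one
  function or option.
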