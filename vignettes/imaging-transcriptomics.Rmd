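---
title: "Linking spatial gene expression to meta-analytic brain activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking spatial gene expression to meta-analytic brain activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imgtx)
```

## The question and the model

Imaging transcriptomics asks whether the spatial distribution of a gene's
expression across the brain resembles the spatial distribution of some
functional property — here, the likelihood that a brain location activates
in tasks tagged with a cognitive term. The two data sources are very
different in kind: postmortem microarray expression measured at a few
hundred sampling sites per donor (an Allen-Human-Brain-Atlas-style atlas,
six adult donors, roughly 500 sites each, probe-level normalized
expression), and a coordinate database of published fMRI studies, each
tagged with term labels and contributing a list of activation foci in MNI
millimeters (a Neurosynth-style resource).

The inference chain `imgtx` implements:

1. **Meta-analytic map.** For a term, collect its studies and build a
   voxelwise activation-likelihood map: a voxel's value is the fraction of
   the term's studies reporting a focus within a kernel radius of that
   voxel's center (`build_activation_map()`).
2. **Per-donor correlation.** For each donor, average the gene's probes at
   each sampling site, read the map value at each site (nearest voxel), and
   fit the least-squares line between the standardized expression and
   standardized map values; on standardized variables the slope equals the
   Pearson correlation (`donor_correlation()`).
3. **Random-effects aggregation.** Treat the six per-donor slopes as draws
   from a donor population and test their mean against zero with a
   one-sample t-test, `t = mean/(sd/sqrt(n))` on `n - 1` df
   (`random_effects_test()`). This is what licenses generalization beyond
   the sampled donors.
4. **Repeatability null.** The robustness statistic is the number of donors
   whose correlation is individually significant (uncorrected, two-tailed).
   Its null distribution is built by resampling: draw as many studies as
   the term set from the *non*-term studies, rebuild the map, recount, and
   repeat B times (`repeatability_test()`). The empirical p is the fraction
   of null counts at least as large as the observed count.
5. **Two-gene independence.** To ask whether the focal gene's association
   is explained by a second gene, each donor's map values are regressed on
   both genes' standardized expression and their product (the interaction)
   by bidirectional stepwise selection; unselected terms contribute beta =
   0, and each term's betas are aggregated across donors with the same
   random-effects t-test (`stepwise_gene_pair()`).
6. **Pathway screen and domain profile.** The same per-gene statistic runs
   over a gene list with Benjamini–Hochberg FDR across the set
   (`screen_genes()`), and over a grid of cognitive-domain terms for one
   gene (`domain_profile()`), with repetition counts classified as robust
   (all donors), marginal (all but one), or none.
7. **Behavioral stage.** A 16-item sense-of-direction questionnaire is sum
   scored with reverse keying, and its sex-adjusted partial correlation
   with a circadian-regularity rating is computed by residualizing both
   variables on sex and correlating the residuals
   (`partial_correlation()`).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| kernel radius | 10 mm | focus-to-voxel sphere; the platform convention at this scale. Masks are monotone in it. |
| grid spacing | 4 mm | isotropic voxel size over an MNI-like box (−90..90, −126..90, −72..108 mm); 2 mm available but 4 mm is the desk-scale working resolution. |
| map mode | likelihood | plain activation frequency across the term's studies, matching the "activation likelihood" reading; an association-test mode (two-proportion z against non-term studies) is available behind a flag and recorded in outputs, because platform association maps differ from raw frequencies. |
| per-donor alpha | 0.05 | uncorrected two-tailed level entering the repetition count. Two-tailed is used throughout; a same-sign option exists since an all-positive pattern is the usual finding of interest. |
| B | 1000 (null), 200 (bundled pipeline default) | resampling iterations; the plain proportion estimator is the default, the add-one estimator (never below 1/(B+1)) a flag. |
| p_enter / p_remove | 0.05 / 0.10 | stepwise thresholds. The literature this emulates says only "stepwise"; bidirectional with these defaults is this package's documented choice, not an assertion about any published procedure, and both are config keys. |
| FDR q | 0.05 | BH step-up across the screened gene set only; domain profiles stay uncorrected, reflecting their exploratory role. |
| reverse items | odd items | the synthetic instrument's reverse-keyed half; real data should pass the instrument's documented set. |

## What the synthetic generator emulates

`simulation_config()` fixes the study conditions; its defaults are the
scale of the real resources: 400 studies of which 61 carry the target term
with ~49 foci each (≈ 2,989 activations), term foci scattered (SD 8 mm)
around bilateral medial-temporal and retrosplenial hotspots, background
foci uniform over the box; 6 donors × 500 sites; the focal gene with its
three microarray probes and planted site-level correlation ρ = 0.3 with
the target map; and a behavioral sample of 292 (155 female) with a planted
sex-adjusted correlation of 0.15.

Generator mechanics and the choices behind them:

* **Foci counts** are Poisson(mean 49) truncated at 1 — variable per study,
  as real activation tables are, with no stronger assumption.
* **Sites** are drawn half from voxels with nonzero map support and half
  uniformly (`support_fraction = 0.5`), then jittered within their voxel so
  nearest-voxel lookup is exercised without changing the sampled value.
  Per-donor site counts accept a vector for asymmetric coverage (real
  atlases cover hemispheres unevenly); the default treats donors
  symmetrically.
* **Planted correlation.** The latent gene signal at a site is
  `ρ·z + sqrt(1−ρ²)·ε` with `z` the standardized map values at the donor's
  sites, so the planted site-level correlation is exactly ρ. Each probe
  adds i.i.d. Gaussian noise (SD 0.3 by default); averaging k probes
  attenuates the expected observed correlation to `ρ/sqrt(1 + σ²/k)` — a
  property the test suite verifies by Monte Carlo.
* **Study terms.** Every study carries the constituent words of two
  concepts sampled from the sub-domain vocabulary, so two-word conjunction
  queries resolve to non-trivial study sets. A consequence worth knowing:
  term studies also carry domain words, so synthetic domain maps share
  hotspot-concentrated studies with the target map and the focal gene
  correlates with many domains — which mirrors how overlapping
  meta-analytic study sets behave on the real platform.
* **Behavior.** Latent sense-of-direction and circadian scores are
  bivariate normal at the planted correlation; male participants get a
  +0.8 SD shift on both latents, a deliberately strong, visible confound so
  the sex adjustment has something real to remove (the marginal correlation
  runs near 0.25 when the adjusted one is 0.15). Items add Gaussian noise
  (SD 0.8, putting the 16-item sum's reliability around 0.95) and are
  mapped to their 1–5 and 1–9 scales by equal-width binning of the
  standardized score — simple, monotone, and bounded.

What passing tests on these data do **not** show about real data: the
generator has no cortical geometry, no spatial autocorrelation in
expression beyond the planted map-coupling, no gene–gene co-expression
structure, and donors are exchangeable. In particular the repeatability
null here is calibrated because background foci are genuinely uniform;
on real data, spatial autocorrelation can inflate apparent repeatability,
and autocorrelation-preserving nulls (spin tests, variogram-matched
surrogates) are deliberately out of scope.

## Numerical choices

* Standardization uses the sample (n−1) SD and refuses constant vectors
  ("zero variance") instead of returning zeros, since every downstream
  correlation is undefined there.
* Correlations are clamped to [−1, 1] before the t transform; |r| = 1 maps
  to p = 0 via an infinite t.
* The stepwise entry step stops once the selected model explains the
  response to numerical precision (RSS < 1e−12 × TSS): partial p-values
  computed on ~1e−16 residuals are uniform noise and would admit arbitrary
  terms. Entry ties break lexicographically by term name, making selection
  deterministic.
* Candidate pairs with |r| > 0.9999 are rejected by name rather than fit.
* The repeatability test's default engine precomputes a study-by-site
  activation indicator (a site's snapped voxel center within the kernel
  radius of any focus) and forms each resampled map's site values as a
  row mean — algebraically identical to rebuilding the full voxel map and
  sampling it, which the naive engine does; a test asserts the two agree
  exactly. This is what makes B = 1000 nulls and calibration studies cheap.
* Per-iteration seeds are drawn up front from the master seed, so null
  results are independent of iteration order; failed iterations (e.g., a
  constant map at one donor's sites) are recorded, and more than 1% of
  them aborts the run.
* The empirical p counts ties as extreme (≥), the conservative reading of
  "equal or higher repeatability".

## Problem sizes used in the bundled checks

The test suite runs the chain at the default conditions above; the
calibration study uses 100 generator seeds at 6 donors × 300 sites with
B = 200, the planted-recovery and stepwise-recovery checks use 6 × 500
sites, and the end-to-end determinism check runs the full pipeline twice
at B = 200. `scripts/acceptance.R` runs the full default study with
B = 1000. These sizes were chosen so the whole battery completes in a few
minutes on one core while keeping Monte-Carlo error well inside the
asserted tolerances.

## Known limitations

* Nearest-voxel (not trilinear) map sampling; interpolation would blur the
  likelihood values, which are step functions by construction.
* The per-donor correlation treats sites as independent observations; its
  p-values ignore spatial autocorrelation (see above).
* The likelihood map is a raw frequency, not a reverse-inference
  statistic; the association-test mode narrows but does not close that
  gap.
* Donor MRI coregistration is out of scope: all site coordinates are
  assumed to be in MNI mm already, and the real-data loaders expect
  precomputed coordinates.
* The discrete Likert mapping mildly attenuates the behavioral correlation
  (toward ~0.14 from a planted 0.15) and adds a little estimator variance
  over the continuous ideal — inherent to emulating coarse scales, and
  worth remembering when comparing recovered and planted values.

## Reproducing the full study

```{r, eval = FALSE}
library(imgtx)
config <- pipeline_config(seed = 1, B = 1000L)
report <- run_full_study(config, out_dir = "results")
```

The report lists every statistic with the settings and a config hash;
`report.md` is the human-readable account, `report.json` the
machine-readable one, and two runs with the same config are byte-identical.
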