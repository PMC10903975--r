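---
title: "Methods: actuarial classification and voxel-wise centrality for subtle cognitive decline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: actuarial classification and voxel-wise centrality for subtle cognitive decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What this package computes

`objscd` implements an analysis chain for studying resting-state
functional-connectivity centrality in objectively-defined subtle cognitive
decline (Obj-SCD), a preclinical stage between normal cognition (CN) and mild
cognitive impairment (MCI):

1. **Actuarial cognitive classification.** Participants are classified from
   nine neuropsychological measures — six total test scores spanning three
   domains (memory: AVLT 30-minute delayed recall, AVLT recognition;
   language: Boston Naming Test, Animal Fluency; attention/executive: Trail
   Making Test A and B) plus three AVLT process scores (learning slope
   `(Trial5 − Trial1)/5`, retroactive interference `Trial6/Trial5`, total
   extra-list intrusions).
2. **rs-fMRI cleaning.** Per-run: discard of the first 10 volumes, motion
   screening, joint detrending and nuisance regression (Friston-24 motion
   set, mean white-matter and CSF signals), and 0.01–0.1 Hz band-pass
   filtering at TR 3 s.
3. **Voxel-wise centrality.** Degree centrality (DC; the number of voxels
   correlated at r ≥ 0.25) and eigenvector centrality (EC; the principal
   eigenvector of the rescaled correlation matrix, computed implicitly) on a
   gray-matter mask (probability > 0.3), followed by within-mask
   standardization and 6 mm FWHM Gaussian smoothing.
4. **Group inference.** Demographic one-way ANOVA / chi-square from summary
   statistics, voxel-wise ANCOVA (group adjusted for age, sex, education,
   mean frame-wise displacement), permutation-based cluster-level
   correction, ROI extraction, Fisher-LSD post hoc contrasts, partial
   correlations, and a two-timepoint group-by-time interaction test.
5. **Synthetic cohort generation.** Phenotype tables and 4D BOLD phantoms
   with planted group structure and ground-truth labels, used to validate
   every stage end to end.

## The normative z-score model

For each test, an ordinary least-squares regression of the score on age,
education and sex is fitted in a *robust normative* sample of CN
participants. A participant's z-score is

$$ z = \frac{\text{observed} - \text{predicted}}{\text{SEE}}, $$

where SEE is the residual standard error with denominator $n - 4$ (four
estimated parameters). Scores where larger values mean worse performance
(TMT-A, TMT-B, intrusions) are sign-flipped after this formula so that
$z < -1$ uniformly denotes impairment; the threshold is strict
(`z = -1.000` exactly is unimpaired). Process-score models use the same
covariates as the totals.

Decision rules, applied sequentially (MCI first, Obj-SCD among the rest):

* **MCI**: (i) two impaired totals within one domain, or (ii) at least one
  impaired total in each of the three domains.
* **Obj-SCD**: (i) one impaired total in each of two different domains,
  (ii) two impaired AVLT process scores, or (iii) one impaired total plus
  one impaired process score.
* **CN** otherwise; a participant with no scorable totals is reported
  `unclassifiable`, and a missing single test simply cannot contribute an
  impairment flag.

Amyloid status is `A+` when CSF A\(\beta\)42 < 192 pg/mL (strict), `A−` at
or above, `unknown` when missing.

**Degenerate norms.** When norms are fitted on noise-free data the SEE is
0; `compute_z()` then uses the limit convention — z = 0 for an exactly
predicted score, signed infinity otherwise — which keeps the classifier
well-defined on deterministic cohorts.

## The synthetic cohort: what it emulates, and what it does not

`generate_phenotypes()` draws each score as *group mean + linear
age/education/sex effects (centred at the group's demographic means, so the
planted group mean is exact) + Gaussian noise*, with per-test, per-group means
and SDs defaulting to the cohort characteristics of the two study designs
(cross-sectional 42/29/55; longitudinal 30/22/48), and a separate robust
normative sample (default n = 239) drawn from the CN model. AVLT trials are
generated first (trial 5, slope, and interference ratio parameterize the
learning curve) and all derived scores are computed from them, so derived
and stored values agree exactly. Scores are kept continuous: rounding to
instrument integers would break the exact trial/process consistency and
bias the planted means, which matter more here than integer realism.

The **ground-truth label** of a simulated participant is defined as the
actuarial rule applied under the *generating* normative model (true
weights, SEE equal to the generating noise SD). With realistic score noise
the actuarial rules are probabilistic — a sampled "CN" participant has an
appreciable chance of a qualifying impairment pattern — so sampling-group
labels are not recoverable by *any* classifier, while the rule-based label
is exactly recoverable in the noise-free limit and recovered to ≈90% at
default noise (the residual disagreement measures norm-estimation error
from the finite robust sample).

`generate_bold_run()` produces 4D phantoms on a common grid (default
24×24×16 at 3.31 mm, 140 volumes, TR 3 s; spatial normalization is out of
scope, so runs are born co-registered). Two gray-matter hub blobs (an
"L-STG-like" and an "L-PCu-like" region, ~10–15% of gray matter) load on
band-limited (0.01–0.1 Hz) latent signals with group- and
timepoint-dependent strength; the two hub latents share a coupling of 0.85,
as coupled network hubs do — with independent latents the leading
eigenvector of the correlation matrix flips between blobs across subjects
and EC carries little group signal. Non-hub gray-matter blobs carry a
background loading of 0.3, placing their within-blob correlations just
below the DC threshold after band-pass filtering (which removes roughly
half the white-noise variance and therefore raises all correlations).
White-matter and CSF compartments have their own latents; every voxel gets
white noise and a linear drift; a random-walk motion trace is emitted, with
an optional fraction of participants exceeding the 3 mm exclusion limit.

Default hub strengths (baseline CN/Obj-SCD/MCI = 0.9/2.0/1.05; month-6
0.85/1.0/0.95) plant the qualitative published pattern — Obj-SCD highest at
baseline in both hubs and declining fastest over follow-up — at magnitudes
that give unambiguous effects at desk scale. Baseline and month-6 runs of
one participant share a participant-level random effect on hub strength
(SD 0.1); the within-subject correlation of repeated scans is not
characterized by the source study, so this shared-random-effect model is a
modeling choice of this package.

What the phantoms do **not** emulate: hemodynamic response shape,
physiological (cardiac/respiratory) noise, scanner drift artifacts beyond a
linear trend, spatial inhomogeneity, or registration error. Passing the
recovery tests therefore demonstrates the *statistical machinery* —
cleaning, centrality, permutation inference — not robustness to real
acquisition artifacts.

## Preprocessing choices

* **Order** (fixed, recorded in provenance): discard → motion screen →
  joint detrend + nuisance regression → band-pass.
* **FD** uses the backward-difference sum with rotations converted to arc
  length on a 50 mm sphere, the standard constant for this method; the
  first frame's FD is 0. Mean FD is computed after the volume discard and
  the QC report says so.
* **Exclusion** is strict "more than": 3 mm translation or 3° rotation on
  any axis. Decisions depend only on the motion trace.
* **Nuisance regression** is a single joint OLS (intercept, linear trend,
  Friston-24, WM, CSF means) rather than sequential steps — order-invariant
  and exactly orthogonal residuals. Collinear columns are dropped with a
  warning. WM/CSF means use probability > 0.9 masks eroded by one voxel
  (6-neighbourhood); thin compartments that erode to nothing fall back to
  the uneroded mask.
* **Band-pass** is an ideal rectangular mask in the discrete Fourier domain
  after demeaning (DC always removed); it is idempotent in the pass-band,
  which makes it exactly testable. A 4th-order forward-backward Butterworth
  is available behind `method = "butterworth"`.

## Centrality choices

* **Gray-matter mask**: strict `prob > 0.3` (the conventional statement of
  this threshold does not fix the direction at equality; strict is
  documented and configurable).
* **DC** counts the binarized positive tail only, `r >= 0.25` inclusive;
  negative correlations never contribute. Correlations are computed
  blockwise from standardized series (default 512-voxel blocks), so the
  V×V matrix is never materialized; an exact brute-force oracle covers the
  implementation. Constant in-mask series get degree 0 with a warning and
  contribute r = 0 edges.
* **EC** is the principal eigenvector of `A = (1 + R)/2`, nonnegative with
  unit Euclidean norm, by power iteration from the uniform vector with
  implicit products `A x = (1 (1ᵀx) + Zᵀ(Z x)/(T−1))/2` (O(V·T) per
  iteration); convergence is a successive-iterate max-abs difference below
  `1e-10`, and non-convergence is an error reporting the last residual.
* **Standardization**: "Fisher's Z transformation" applied to a count-valued
  DC map is not mathematically defined, so the default is within-mask
  z-standardization (the dominant toolbox convention for centrality maps);
  `atanh` is available for correlation-valued maps via
  `standardize_map(method = "fisher")`. Whether the original analysis used
  one or the other cannot be determined from its description; both are
  provided and the default is documented here.
* **Smoothing** follows standardization (the published order), with a
  separable Gaussian of 6 mm FWHM, σ = FWHM/(2√(2 ln 2)) per axis in voxel
  units; the map and the mask are convolved separately and their ratio
  re-masked, so out-of-mask voxels neither contribute nor dilute. FWHM
  below half a voxel is the identity.

## Inference choices

* **Summary-statistic ANOVA** reconstructs F from group means/SDs/ns
  (`SS_b = Σ nᵢ(mᵢ − m̄)²`, `SS_w = Σ (nᵢ−1)SDᵢ²`) and is algebraically
  identical to full-data one-way ANOVA; demographic comparisons are
  unadjusted one-way tests, while ANCOVA is reserved for the imaging
  measures, mirroring the split used in the source study design.
* **Voxel-wise ANCOVA** is a partial-F test of the group factor (full:
  group + age + sex + education + mean FD; reduced: covariates only),
  vectorized over voxels through QR projections.
* **Cluster-level correction** replaces analytical Gaussian-random-field
  correction with a permutation test: suprathreshold voxels (p < 0.005 on
  the F map) are grouped by 26-connectivity (configurable to 18/6) and each
  observed extent is compared with the permutation distribution of the
  *maximal* cluster extent under the Freedman–Lane scheme (permute reduced-
  model residuals, add back the reduced fit, recompute the partial-F map).
  GRF asymptotics are inappropriate on desk-scale lattices; permutation
  controls the same familywise error quantity, and clusters are formed from
  the omnibus F, which is inherently two-sided for three groups. Corrected
  p uses the add-one estimator `(1 + #{null ≥ obs})/(n_perm + 1)`.
* **LSD post hoc** tests are classical Fisher LSD: unadjusted pairwise
  contrasts from the covariate-adjusted three-group model with the pooled
  error term, interpreted only when the omnibus test is significant.
* **Two-timepoint interaction**: for two timepoints the mixed-design
  group-by-time F is algebraically the ANCOVA-on-change-scores F, which is
  how `rm_interaction()` computes it (verified against the mixed-model
  algebra in tests). Covariates are optional — the source description is
  ambiguous between repeated-measures ANOVA and ANCOVA, so both variants
  are exposed; the default is the unadjusted variant.

## Numerical and degenerate-input policy

Zero-variance voxels: z-scored to zeros (r = 0 edges, degree 0). Constant
maps: standardization errors out. Zero SEE: limit convention above. Ties at
thresholds: strict `<` for impairment and exclusion limits, inclusive
`>=` for the degree threshold, strict `>` for the gray-matter mask — each
matching the printed convention where one exists, documented here where
not. All randomized steps take explicit seeds, recorded in output
provenance; fixed seed implies bit-identical phenotypes, phantoms and
permutation p-values.

## Problem sizes used by the test-suite simulations

Simulation-based checks run at desk scale, chosen as the smallest sizes at
which the planted effects are unambiguous: voxel-level type-I calibration
at 60 subjects × 2 500 voxels; familywise-error calibration over 20
full-null repetitions of 40 subjects on a 16×16×8 grid with 250
permutations; interaction null calibration over 500 simulated two-group
designs; pattern-recovery replicates on an 18×18×12 grid with 140 volumes,
20/16/24 subjects per group cross-sectionally and 14/20 (Obj-SCD/MCI)
longitudinally, 199 permutations, 20 replicates. The acceptance script
(`scripts/acceptance.R`) re-runs the same computations from scratch under a
caller-supplied seed.

## Known limitations

* Phantoms are blob-world: no real anatomy, no registration step, and the
  imaging statistics of any real cohort (which depend on its acquired data)
  are not reproducible from them; recovery checks are qualitative
  (cluster location, group ordering, detection rates).
* The permutation null assumes exchangeable reduced-model residuals;
  heavy-tailed or heteroscedastic subject maps would need a studentized
  variant.
* Longitudinal modeling is limited to two timepoints by design; more visits
  need a mixed-effects extension.
* Education-stratified lookup-table norms, dementia adjudication and
  progression modeling are out of scope.
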