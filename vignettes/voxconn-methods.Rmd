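---
title: "Voxel-wise connectomics of symptom change: models, conventions and calibration"
author: "voxconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise connectomics of symptom change: models, conventions and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxconn)
```

## The analysis

voxconn implements a longitudinal, whole-brain resting-state
connectomics analysis of symptom change: which features of a patient's
functional network organization at baseline predict how their symptoms
evolve, and which longitudinal reorganizations accompany that change?
The population it was built around is functional neurological disorder
(FND), where clinical trajectories are highly heterogeneous, but every
stage is generic: any cohort with per-subject 4D resting-state scans at
one or two timepoints, a grey-matter mask, a seven-network cortical
parcellation, and two-timepoint symptom questionnaires can be run
through the same pipeline.

The chain is:

1. per-subject voxel-by-voxel Pearson connectivity matrices
   (`computeFCMatrix`), negatives removed;
2. three voxel-wise graph metrics (`weightedDegreeMap`,
   `integrationMap`, `segregationMap`) and their follow-up-minus-baseline
   change maps (`metricChangeMap`);
3. mass-univariate brain-behavior general linear models
   (`fitBrainBehaviorGLM`) with Monte-Carlo cluster-extent correction
   (`clusterNullDistribution`, `applyClusterCorrection`);
4. seed-based post-hoc characterization of significant integration
   voxels (`seedToVoxelZMap`, `groupSeedGLM`,
   `countBetweenNetworkConnections`);
5. cohort statistics and healthy-control contextualization
   (`pairedTest`, `mannWhitneyU`, `bhFDR`, `stratifyExtremes`,
   `hcContextualize`).

A synthetic-cohort generator (`simulateLongitudinalCohort`) with known,
configurable brain-behavior effects is a first-class component: it is
how the pipeline's type-I error and power are demonstrated, since
subject-level clinical imaging data cannot ship with a package.

## Graph metrics

For the weight matrix $\mathrm{adj}(i,j)$ of nonnegative Pearson
correlations between voxel time series (negatives set to zero -- not
absolute-valued, not shifted -- and a zero diagonal, since
self-correlation is not a connection):

* **weighted-degree** $WD_i = \sum_{j \ne i} \mathrm{adj}(i,j)$ over the
  whole grey-matter matrix: global centrality;
* **integration** $I_i = \sum_{j:\, \ell(j) \ne \ell(i)}
  \mathrm{adj}(i,j)$ over the isocortical-only matrix, where $\ell$ is
  the seven-network label: between-network connectivity;
* **segregation** $S_i = \sum_{j:\, \ell(j) = \ell(i), j \ne i}
  \mathrm{adj}(i,j)$: within-network connectivity.

Integration and segregation partition the isocortical row sum exactly;
that identity is enforced in the test suite at $10^{-9}$ relative
tolerance. For Pearson weights the isocortical-only matrix equals the
corresponding submatrix of the whole-grey matrix, so
`isocorticalSubmatrix` takes a view rather than recomputing. A
zero-variance voxel has undefined correlations; its row and column are
zeroed with a warning instead of being dropped, so map geometry never
changes mid-pipeline.

Subjects whose grey-matter-mean weighted-degree is extreme are screened
out before analysis (`flagOutlierSubjects`). The screen compares each
subject with the leave-one-out mean and SD of the others (default 3
SD): with cohorts of a few dozen subjects a single gross outlier
inflates the pooled SD enough to mask itself, which the jackknifed
version avoids.

## Brain-behavior GLMs

At every voxel the model is

$$\Delta \text{symptom} \sim \beta_0 + \beta_1\, \text{metric}_v +
  \text{age} + \text{sex} + \text{SSRI/SNRI} + \text{mean FD} +
  \text{interval} + \text{baseline score},$$

fit by least squares; the metric term's $t$ is converted to a $z$
statistic by tail-probability matching ($z = \Phi^{-1}(F_t(t))$,
computed on the log scale so large statistics do not saturate, capped
at $\pm 8.2$ with a flag for numerically perfect fits). The symptom
change score is the outcome and the voxel metric the predictor, but by
the Frisch-Waugh partialling identity the metric-term $t$ is invariant
under exchanging those roles with the same covariates -- the direction
is a labeling convention, and the identity is tested to $10^{-8}$.
Continuous covariates are mean-centered (this moves only the
intercept); binary indicators are left as coded (female = 1). Voxels
whose residualized metric has no cross-subject variance get $z = 0$
with a flag rather than an undefined statistic.

Implementation note: the fit residualizes the outcome and all voxel
metrics on the nuisance design once and computes every per-voxel slope
from the residualized pair, which is algebraically identical to
refitting the full model per voxel but vectorizes over ~$10^5$ voxels.
The per-voxel statistics are verified against an explicit
normal-equations oracle in the tests.

## Monte-Carlo cluster-extent correction

Voxel-wise thresholding at $|z| > 1.96$ (two-sided; positive and
negative excursions labeled separately) is followed by a cluster-extent
threshold derived from simulation: white Gaussian fields on the
bounding grid are smoothed to the estimated per-axis smoothness of the
GLM residual maps, re-standardized within the analysis mask (so the
voxel threshold keeps its nominal rate), thresholded identically, and
the maximum connected-component extent recorded per iteration
(default 10,000 iterations; the dominant volumetric convention of
26-connectivity is the default, configurable to 6 or 18).

Smoothness is estimated from the residual maps, not the raw data, so
the null matches the model's error structure. The estimator is the
classical gradient-variance formula per axis,
$\mathrm{FWHM} = \sqrt{-2\ln 2 / \ln(1 - \mathrm{var}(\partial e) /
(2\,\mathrm{var}(e)))}$, averaged over residual maps and floored at one
voxel (the intrinsic lattice smoothness of white noise); simulated
fields are smoothed with a kernel of the estimated FWHM directly, a
convention verified by self-consistency (noise smoothed at FWHM 3
estimates back in [2.4, 3.6]).

The extent threshold is the smallest integer $k$ whose empirical
exceedance probability among the sampled maxima is at most $\alpha$;
clusters of extent $\ge k$ survive. With discrete extents this realizes
a family-wise error rate at the largest attainable value not exceeding
$\alpha$; the test suite measures the realized rate on fresh null
fields and checks it against the binomial CI around 5%. When no simulated field ever crosses the voxel threshold the null
is degenerate and flagged: any nonempty observed cluster then survives
vacuously, which the caller should treat as a configuration warning,
not a finding.

Post-hoc covariate sensitivity (`posthocCovariateSensitivity`) refits
the full voxel-wise model with each extra covariate set (phenotype;
baseline affective scores; childhood-trauma scores; change scores for
the longitudinal models), re-runs the correction at the re-estimated
smoothness, and reports a primary cluster as "held" when at least one
surviving voxel overlaps it -- the weakest robustness reading,
deliberately; stricter overlap fractions are a parameter.

## Seed-based post-hoc characterization

Significant integration voxels are assigned to their networks;
for the top three networks by voxel count (ties broken toward the lower
network index) a seed is formed by averaging the member voxels' time
series. Seed-to-voxel Pearson correlations over the isocortex are
Fisher-transformed ($z = \mathrm{atanh}\, r$, with $r$ clipped to
$\pm(1 - 10^{-7})$ so seed-member voxels stay finite), entered into a
group GLM against zero (covariates: age, sex, SSRI/SNRI, mean FD;
centered, intercept tested), and cluster-corrected identically.
Between-network connection counts per target network exclude the seed's
own network -- within-network links are not integration. Longitudinal
comparisons use the same seed voxel set at both timepoints, so count
differences reflect connectivity change rather than seed change;
percentages use each target network's isocortical voxel count as the
denominator (an explicit convention -- nothing in the underlying
quantity fixes the denominator).

## Cohort statistics conventions

* Change scores are follow-up minus baseline; lower questionnaire
  totals are better, so negative change is improvement.
* CGI-I: "improved" aggregates much improved + improved, "worsened"
  aggregates worse + much worse. Improved and unchanged percentages are
  rounded half-up to one decimal; the worsened percentage is the
  complement to 100.0, the clinical-reporting convention under which
  19/32, 10/32, 3/32 print as 59.4 / 31.3 / 9.3.
* Wilcoxon signed-rank: zero differences dropped, midranks for ties,
  normal approximation without continuity correction -- so a signed $z$
  is reported. Paired $t$ for the (approximately) normal measures; exact
  McNemar (binomial on discordant pairs when below 25) for paired
  binary traits. Benjamini-Hochberg FDR is applied per symptom measure.
* Mann-Whitney U is reported for the first sample, with the exact
  two-sided p for untied samples below n = 50 per group and the
  tie-corrected normal approximation otherwise.
* Extreme-responder strata take $k = \max(1, \lfloor n \cdot
  \text{fraction}\rfloor)$ subjects per tail (floor, not rounding: a
  28-subject cohort at 20% gives 5); boundary ties break by subject
  order with a warning.
* Healthy-control contextualization extracts per-subject means over the
  voxels shared by the baseline-predictor and longitudinal-change
  significance masks and runs six Mann-Whitney tests: {full cohort, top
  stratum, bottom stratum} x {baseline, follow-up} against controls.

## The synthetic cohort generator

### Generative model

Each session is drawn from a latent-factor block covariance: voxel $v$
in network $k$ follows

$$x_{vt} = \sqrt{r_b}\, g_t + \sqrt{r_w - r_b}\, f_{kt}
  + c\, f_{k^\ast t}\,[v \in R] + \sqrt{1 - r_w}\, e_{vt}$$

with a shared global factor $g$, one factor per network, and
independent voxel noise, so expected voxel-pair correlations are $r_w$
within and $r_b$ between networks (defaults 0.5 / 0.1, positive
definiteness is automatic for $0 \le r_b \le r_w < 1$). The planted
effect loads the "insula-like" region $R$ (a contiguous ball inside the
salience-like network 3) onto the somatomotor-like target network's
factor with subject-specific strength $c$.

Two in-sample normalizations matter. The factor series are
orthonormalized per session, and the voxel noise is projected off the
factor subspace. Without them the realized factor covariance
fluctuates at $O(1/\sqrt{T})$, every subject carries a global
connectivity shift, and the group-level $z$ fields acquire long-range
correlation that local FWHM matching cannot represent, inflating the
null cluster rate several-fold. With them the generator emulates fully
nuisance-regressed (preprocessed) resting-state data, which is what the
analysis consumes in practice, and the end-to-end null calibration
experiment in the test suite verifies the ~5% rate. Phantoms and
analyses never see these internals; they only matter for what "null"
means.

### Cohort structure and symptom model

Defaults mirror the emulated study: 32 FND subjects (28 with a second
imaging session ~6.8 months later), 50 healthy controls with one
session each, 28F:4M, 13/32 on SSRI/SNRI, 10/32 with a seizure
phenotype. Binary traits are assigned deterministically from the
subject index at exactly those rates (a Kronecker sequence): Bernoulli
draws at 28/32 produce an all-female -- rank-deficient -- cohort in
about 1.4% of replicates, which is both unlike the emulated design and
fatal to repeated-cohort calibration experiments. Continuous
covariates and questionnaire totals are drawn at the magnitudes of the
emulated cohort (age 42 +/- 13; baseline SOMS:CD ~ gamma with mean 6.6,
SD 6.3; analogous choices for PHQ-15, BDI-II, STAI, PCL-5 and CTQ;
session mean FD ~ 0.07 +/- 0.04 mm). Every subject owns an RNG stream
derived from the master seed by fixed offsets, so enlarging a cohort
never perturbs existing subjects.

Core-symptom change is generated directly from the planted effects:

$$\Delta = b_0(-c_i) + b_1(-\Delta c_i) + \sigma \epsilon_i,$$

so higher baseline integration, and integration decreases over time,
map to more negative (improved) scores. Follow-up totals are the
baseline total plus the change, rounded but deliberately not floored at
zero: the change score is the scientific quantity, and a floor would
distort planted correlations for low-baseline subjects. Defaults
$b_0 = b_1 = 12$, boost SD 0.15, change SD 0.15, noise SD 2.4 give a
baseline-only boost-outcome correlation of
$1.8/\sqrt{1.8^2 + 2.4^2} = 0.6$; the realized voxel-level partial
correlation in the effect region is slightly attenuated by metric
estimation noise and is recomputed by `scripts/acceptance.R` on every
run (~0.6-0.7 at 100 timepoints on the bundled phantom). CGI-I categories derive
deterministically from the generated change score through fixed
cutpoints.

### What the generator does not emulate

No anatomy, no scanner artifacts, no physiological noise spectra, no
motion-corrupted frames, no item-level questionnaires, and no
treatment-exposure structure. Passing calibration and recovery tests
on this generator demonstrates that the statistical machinery is sound
under its stated assumptions -- not that those assumptions hold in any
particular clinical dataset; in particular, real resting-state data
retain global nuisance structure to the extent preprocessing leaves it,
and real effect regions have no reason to respect network boundaries.

## Validation experiments and problem sizes

The test suite runs three simulation experiments, sized to finish in a
few minutes on one core while keeping their Monte-Carlo error useful
(the sizes are choices, stated here so they can be scaled):

* **Extent-threshold calibration**: 2,000-iteration null on the
  12x12x10 phantom's 624-voxel isocortical mask, then 200 fresh null
  fields; the realized family-wise error must sit inside the 95%
  binomial CI around 5%.
* **Parameter recovery**: 25 replicate 32-subject cohorts with the
  planted baseline effect (100 timepoints, 500-iteration nulls); at
  least 80% of replicates must recover >= 50% of the effect region's
  voxels. A false flag is a surviving cluster that misses the planted
  effect's full footprint (region plus target network, dilated one
  voxel) entirely -- the coupling is reciprocal, so target-network
  voxels carry a genuine, weaker effect, and cluster-wise inference
  controls cluster-wise, not voxel-wise, error.
* **End-to-end null calibration**: 100 null cohorts (60 timepoints,
  250-iteration nulls) through metrics, GLM and correction; the
  fraction with any significant cluster must be consistent with 5%.

## Known limitations

* Cluster-extent inference assumes the residual fields are adequately
  described by a stationary local smoothness; data with strong global
  or network-structured residual correlation (e.g. without global
  nuisance regression) will be anticonservative, exactly as the
  generator demonstrated before its factors were orthonormalized.
* The smoothness estimator is gradient-based and isotropic per axis; it
  will not capture heavy-tailed or nonstationary smoothness.
* The Monte-Carlo null is voxel-threshold-specific: the `ClusterNull`
  object must be rebuilt for a different `zThresh`, mask or
  connectivity.
* Extent thresholds are integers; the realized family-wise error sits
  at the largest attainable value below alpha, which on very small
  masks can be well below it.
* `runPipeline` holds all session matrices in memory; at clinical
  resolutions (~10^5 grey voxels) the voxel-by-voxel matrix path needs
  the chunked-computation contract rather than the dense default.
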