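# voxconn

Voxel-wise resting-state connectomics for longitudinal brain–behavior
analyses: which features of a patient's functional network organization
at baseline predict symptom change, and which longitudinal network
reorganizations accompany it?

The package is aimed at clinical-neuroimaging analysts working with
cohorts of the functional-neurological-disorder type — a few dozen
patients scanned at two timepoints with questionnaire totals at each,
plus matched healthy controls — but every stage is population-agnostic.
It covers the full chain: voxel-by-voxel connectivity matrices, graph
metrics, mass-univariate covariate-adjusted GLMs, Monte-Carlo
cluster-extent correction, seed-based post-hoc network
characterization, clinical cohort statistics, healthy-control
contextualization, and a synthetic longitudinal cohort generator with
planted, recoverable effects used to demonstrate calibration and power.

## The model

From each subject's time series, pairwise Pearson correlations between
grey-matter voxels form a weight matrix `adj(i,j)` (negatives removed,
zero diagonal). Three per-voxel metrics summarize network organization:

- weighted-degree `WD_i = Σ_j adj(i,j)` — global centrality, whole
  grey matter;
- integration `I_i = Σ_{ℓ(j) ≠ ℓ(i)} adj(i,j)` — between-network
  connectivity over the isocortex, where `ℓ` assigns each voxel to one
  of seven functional networks;
- segregation `S_i = Σ_{ℓ(j) = ℓ(i)} adj(i,j)` — within-network
  connectivity (`I_i + S_i` equals the isocortical row sum exactly).

At each voxel a GLM relates the symptom change score (follow-up −
baseline; negative = improvement) to the metric — or, for the
longitudinal analyses, to the metric's change map — adjusting for age,
sex, SSRI/SNRI use, mean framewise displacement, inter-session interval
and the baseline score. The metric term's t is converted to z by
tail-probability matching, thresholded two-sidedly at |z| > 1.96, and
cluster-corrected against a Monte-Carlo null of maximum cluster extents
simulated at the smoothness of the model residuals (p < 0.05
family-wise). Post-hoc stages characterize which networks significant
integration voxels connect across, and contextualize overlap regions
against healthy controls with Mann-Whitney tests over
extreme-responder strata.

## Worked example

A complete baseline-predictor analysis on a synthetic cohort with a
planted effect (32 subjects, 100 timepoints, 12×12×10 phantom with 7
contiguous networks):

```r
library(voxconn)

space <- makePhantomSpace(c(12, 12, 10), nNetworks = 7, seed = 1)
cfg <- simulationConfig(space, nFND = 32, nFollowup = 0, nHC = 0,
                        nTimepoints = 100, longitudinalEffectSize = 0,
                        seed = 1)
cohort <- simulateLongitudinalCohort(space, cfg)
tab <- cohortCovariates(cohort)

## per-subject baseline integration maps
gv <- greyVoxels(space)
isoCols <- match(isoVoxels(space), gv)
maps <- lapply(tab$subject, function(id) {
  ts <- cohortScans(cohort)[[id]]$baseline
  fc <- computeFCMatrix(ts[, isoCols], voxels = isoVoxels(space),
                        scope = "isocortical", dims = spaceDims(space))
  integrationMap(fc, space, subject = id)
})

## symptom change ~ integration + covariates, cluster-corrected
change <- changeScore(tab$soms_cd_followup, tab$soms_cd_baseline)
covs <- data.frame(age = tab$age, sex = tab$sex,
                   ssri_snri = tab$ssri_snri,
                   mean_fd = tab$mean_fd_baseline,
                   interval = tab$interval_months,
                   baseline_score = tab$soms_cd_baseline)
fit <- fitBrainBehaviorGLM(maps, change, covs,
                           outcomeName = "delta_soms_cd",
                           term = "integration")
null <- clusterNullDistribution(isoMask(space),
                                fwhm = estimateMapSmoothness(fit),
                                zThresh = 1.96, nIter = 2000, seed = 7)
clusters <- applyClusterCorrection(fit, null)
clusters
```

which prints:

```
ClusterNull: |z| > 1.96 , 2000 iterations, fwhm 1/1/1 -> extent threshold 6 voxels
ClusterResult: 1 surviving cluster(s), 43 significant voxels
  id extent    peak_z peak_x peak_y peak_z_coord sign
1  1     43 -3.286544      5      9            1   -1
```

One negative-sign cluster survives: voxels where higher baseline
integration predicts a more negative (improved) symptom change. It
covers 14 of the 31 planted effect-region voxels plus the target
network the region was coupled into. The cluster-mean association is
what a scatterplot would show:

```r
cm <- clusterMeanValues(clusters, maps)
spearmanAssoc(change, rowMeans(cm))
#  Spearman rho = -0.47, p = 0.0065
```

`runPipeline(config)` drives the same chain end to end from a YAML
configuration (synthetic or file-based inputs), writing NIfTI maps,
TSV tables, a JSON report and a log; see the methods vignette
(`vignettes/voxconn-methods.Rmd`) for the statistical conventions and
every tunable parameter.

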