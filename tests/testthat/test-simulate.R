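test_that("simulated time series hit their correlation targets", {
  sp <- tinySpace()
  ts <- simulateSubjectTimeseries(sp, withinR = 0.5, betweenR = 0.1,
                                  nTimepoints = 5000, seed = 11)
  gv <- greyVoxels(sp)
  lab <- networkLabels(sp)[gv]
  iso <- lab > 0L
  r <- cor(ts[, iso])
  labI <- lab[iso]
  same <- outer(labI, labI, "==") & upper.tri(r)
  diff <- outer(labI, labI, "!=") & upper.tri(r)
  expect_gt(mean(r[same]), 0.45)
  expect_lt(mean(r[same]), 0.55)
  expect_gt(mean(r[diff]), 0.05)
  expect_lt(mean(r[diff]), 0.15)
})

test_that("invalid correlation targets are a parameterization error", {
  sp <- tinySpace()
  expect_error(simulateSubjectTimeseries(sp, 0.5, 0.6, nTimepoints = 50),
               "parameterization")
  expect_error(simulateSubjectTimeseries(sp, 1.0, 0.1, nTimepoints = 50),
               "parameterization")
  expect_error(simulateSubjectTimeseries(sp, 0.5, 0.1, nTimepoints = 10),
               ">= 20")
})

test_that("region integration is monotone in the planted boost", {
  sp <- tinySpace()
  reg <- defaultEffectRegion(sp, network = 3, radius = 1.5)
  gv <- greyVoxels(sp)
  isoIdx <- isoVoxels(sp)
  isoCols <- match(isoIdx, gv)
  meanRegionIntegration <- function(boost) {
    ts <- simulateSubjectTimeseries(sp, 0.5, 0.1, regionBoost = boost,
                                    effectRegion = reg,
                                    targetNetwork = 1L,
                                    nTimepoints = 600, seed = 21)
    fc <- computeFCMatrix(ts[, isoCols], voxels = isoIdx,
                          scope = "isocortical", dims = spaceDims(sp))
    im <- integrationMap(fc, sp)
    mean(mapValues(im)[match(reg, mapVoxels(im))])
  }
  vals <- vapply(c(0, 0.3, 0.6), meanRegionIntegration, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("with no boost the effect region matches its network peers", {
  sp <- tinySpace()
  reg <- defaultEffectRegion(sp, network = 3, radius = 1.5)
  gv <- greyVoxels(sp)
  isoIdx <- isoVoxels(sp)
  ts <- simulateSubjectTimeseries(sp, 0.5, 0.1, regionBoost = 0,
                                  effectRegion = reg,
                                  nTimepoints = 2000, seed = 31)
  fc <- computeFCMatrix(ts[, match(isoIdx, gv)], voxels = isoIdx,
                        scope = "isocortical", dims = spaceDims(sp))
  im <- integrationMap(fc, sp)
  peers <- setdiff(which(networkLabels(sp) == 3L), reg)
  vReg <- mapValues(im)[match(reg, mapVoxels(im))]
  vPeer <- mapValues(im)[match(peers, mapVoxels(im))]
  # same expected integration; allow generous Monte-Carlo slack
  expect_lt(abs(mean(vReg) - mean(vPeer)),
            3 * sd(vPeer) / sqrt(length(vPeer)) + 0.05 * mean(vPeer))
})

test_that("cohorts are deterministic and earlier subjects are stable", {
  sp <- tinySpace()
  cfgA <- simulationConfig(sp, nFND = 5L, nFollowup = 4L, nHC = 2L,
                           nTimepoints = 40L, seed = 3L)
  a1 <- simulateLongitudinalCohort(sp, cfgA)
  a2 <- simulateLongitudinalCohort(sp, cfgA)
  expect_identical(cohortScans(a1), cohortScans(a2))
  expect_identical(cohortCovariates(a1), cohortCovariates(a2))

  cfgB <- simulationConfig(sp, nFND = 6L, nFollowup = 4L, nHC = 2L,
                           nTimepoints = 40L, seed = 3L)
  b <- simulateLongitudinalCohort(sp, cfgB)
  expect_identical(cohortScans(a1)[["FND_03"]], cohortScans(b)[["FND_03"]])
  expect_identical(cohortScans(a1)[["HC_02"]], cohortScans(b)[["HC_02"]])
})

test_that("null configurations decouple boosts from symptom change", {
  sp <- tinySpace()
  cfg <- simulationConfig(sp, nFND = 32L, nFollowup = 28L, nHC = 0L,
                          nTimepoints = 20L, baselineEffectSize = 0,
                          longitudinalEffectSize = 0, seed = 9L)
  coh <- simulateLongitudinalCohort(sp, cfg)
  tab <- cohortCovariates(coh)
  change <- changeScore(tab$soms_cd_followup, tab$soms_cd_baseline)
  expect_lt(abs(cor(cohortTruth(coh)$boost, change)), 0.35)

  nullCoh <- simulateNullCohort(sp, cfg)
  expect_true(all(cohortTruth(nullCoh)$boost == 0))
  expect_true(all(cohortTruth(nullCoh)$delta == 0, na.rm = TRUE))
})

test_that("in the noiseless limit change scores track the boost ranks", {
  sp <- tinySpace()
  cfg <- simulationConfig(sp, nFND = 12L, nFollowup = 12L, nHC = 0L,
                          nTimepoints = 20L, baselineEffectSize = 60,
                          longitudinalEffectSize = 0, noiseSD = 0,
                          seed = 13L)
  coh <- simulateLongitudinalCohort(sp, cfg)
  tab <- cohortCovariates(coh)
  change <- changeScore(tab$soms_cd_followup, tab$soms_cd_baseline)
  expect_gt(cor(cohortTruth(coh)$boost, -change, method = "spearman"),
            0.99)
})

test_that("cohort structure matches the configured design", {
  sp <- tinySpace()
  cfg <- simulationConfig(sp, nFND = 6L, nFollowup = 4L, nHC = 3L,
                          nTimepoints = 25L, seed = 2L)
  coh <- simulateLongitudinalCohort(sp, cfg)
  tab <- cohortCovariates(coh)
  expect_equal(sum(tab$group == "FND"), 6L)
  expect_equal(sum(tab$group == "HC"), 3L)
  nses <- vapply(cohortScans(coh), length, 1L)
  expect_equal(unname(nses[tab$group == "HC"]), rep(1L, 3))
  expect_equal(sum(nses[tab$group == "FND"] == 2L), 4L)
  expect_true(all(is.na(tab$soms_cd_baseline[tab$group == "HC"])))
  expect_true(all(tab$cgi_i[tab$group == "FND"] %in%
    c("much improved", "improved", "unchanged", "worse", "much worse")))
})

test_that("simulation configs survive YAML serialization", {
  sp <- tinySpace()
  cfg <- simulationConfig(sp, nFND = 4L, nFollowup = 3L, nHC = 1L,
                          nTimepoints = 30L, seed = 5L)
  txt <- yaml::as.yaml(configAsList(cfg))
  back <- configFromList(yaml::yaml.load(txt))
  for (s in methods::slotNames(cfg))
    expect_equal(methods::slot(back, s), methods::slot(cfg, s),
                 label = paste("slot", s))
})
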