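test_that("significant voxels are histogrammed by network label", {
  sp <- midSpace()
  lab <- networkLabels(sp)
  pick <- c(which(lab == 5)[1:3], which(lab == 6)[1:2], which(lab == 7)[1])
  counts <- assignClusterVoxelsToNetworks(pick, sp)
  expect_equal(unname(counts[c("5", "6", "7")]), c(3L, 2L, 1L))
  expect_equal(sum(counts), length(pick))

  expect_equal(sum(assignClusterVoxelsToNetworks(integer(0), sp)), 0L)

  # voxels outside the isocortex are excluded with a warning
  outside <- setdiff(which(greyMask(sp)), which(isoMask(sp)))[1]
  expect_warning(c2 <- assignClusterVoxelsToNetworks(c(pick, outside), sp),
                 "outside")
  expect_equal(sum(c2), length(pick))

  # conservation on a random isocortical mask
  set.seed(6)
  rnd <- sample(which(isoMask(sp)), 40)
  expect_equal(sum(assignClusterVoxelsToNetworks(rnd, sp)), 40L)
})

test_that("top networks are selected by count with index tie-breaks", {
  counts <- c("1" = 10L, "2" = 0L, "3" = 0L, "4" = 7L, "5" = 7L,
              "6" = 0L, "7" = 1L)
  expect_equal(selectTopNetworks(counts, 3), c(1L, 4L, 5L))
  expect_warning(one <- selectTopNetworks(c("2" = 5L, "3" = 0L), 3),
                 "1 network")
  expect_equal(one, 2L)
  expect_warning(none <- selectTopNetworks(c("1" = 0L, "2" = 0L), 2),
                 "0 network")
  expect_length(none, 0L)
  expect_error(selectTopNetworks(counts, 0), "k")
})

test_that("seed maps apply the Fisher transform exactly", {
  sp <- tinySpace()
  gv <- greyVoxels(sp)
  isoIdx <- isoVoxels(sp)
  Tn <- 60
  set.seed(9)
  s <- scale(rnorm(Tn))[, 1]
  o <- rnorm(Tn)
  o <- scale(o - s * sum(o * s) / sum(s * s))[, 1]  # exactly orthogonal

  ts <- matrix(rnorm(Tn * length(gv)), Tn, length(gv))
  seedVox <- gv[1:2]
  ts[, 1:2] <- s                       # seed average = s
  probe <- isoIdx[10]
  for (r in c(-0.6, -0.2, 0.2, 0.5, 0.8)) {
    ts[, match(probe, gv)] <- r * s + sqrt(1 - r^2) * o
    zm <- seedToVoxelZMap(ts, seedVox, sp)
    got <- mapValues(zm)[match(probe, mapVoxels(zm))]
    expect_equal(got, 0.5 * log((1 + r) / (1 - r)), tolerance = 1e-10,
                 label = paste("fisher z at r =", r))
  }
  # oddness and zero at r = 0 follow from the closed form checked above;
  # a voxel equal to the seed average is clipped to a large finite value
  ts[, match(probe, gv)] <- s
  zm <- seedToVoxelZMap(ts, seedVox, sp)
  got <- mapValues(zm)[match(probe, mapVoxels(zm))]
  expect_true(is.finite(got))
  expect_gt(got, 8)

  # zero-variance seed -> flagged undefined map
  ts[, 1:2] <- 1
  expect_warning(zm0 <- seedToVoxelZMap(ts, seedVox, sp),
                 "zero-variance")
  expect_true(all(is.na(mapValues(zm0))))

  expect_error(seedToVoxelZMap(ts, max(gv) + 50L, sp), "seed voxels")
})

test_that("group seed GLM handles null, saturated and planted means", {
  sp <- tinySpace()
  isoIdx <- isoVoxels(sp)
  nSub <- 16
  covs <- data.frame(age = rnorm(nSub, 40, 10),
                     sex = rbinom(nSub, 1, 0.8),
                     ssri_snri = rbinom(nSub, 1, 0.4),
                     mean_fd = rgamma(nSub, 3, 40))
  mkMaps <- function(M) lapply(seq_len(nSub), function(i)
    methods::new("MetricMap", metric = "seed_fisher_z", values = M[i, ],
                 voxels = as.integer(isoIdx), dims = spaceDims(sp),
                 subject = paste0("s", i), timepoint = "baseline"))

  # identically zero maps -> empty significance mask
  res0 <- groupSeedGLM(mkMaps(matrix(0, nSub, length(isoIdx))), covs,
                       isoMask(sp), nIter = 150, seed = 3)
  expect_equal(sum(significanceMask(res0$clusters)), 0L)

  # constant 0.8 maps -> saturated capped intercept, whole mask flagged
  resC <- groupSeedGLM(mkMaps(matrix(0.8, nSub, length(isoIdx))), covs,
                       isoMask(sp), nIter = 150, seed = 3)
  expect_true(all(zMap(resC$glm) == 8.2))
  expect_equal(sum(significanceMask(resC$clusters)), length(isoIdx))

  # planted positive-mean region on noise is recovered
  set.seed(12)
  reg <- defaultEffectRegion(sp, network = 2, radius = 1.8)
  M <- matrix(rnorm(nSub * length(isoIdx), 0, 0.1), nSub,
              length(isoIdx))
  M[, match(reg, isoIdx)] <- M[, match(reg, isoIdx)] + 0.5
  resP <- groupSeedGLM(mkMaps(M), covs, isoMask(sp), nIter = 300,
                       seed = 3)
  sig <- significanceMask(resP$clusters)
  expect_gte(sum(sig[reg]), 0.8 * length(reg))
})

test_that("between-network counting excludes the seed network", {
  sp <- midSpace()
  lab <- networkLabels(sp)
  mask <- c(which(lab == 1)[1:2], which(lab == 2)[1], which(lab == 3)[1:3])
  cnt <- countBetweenNetworkConnections(mask, sp, seedNetwork = 1)
  expect_false(1 %in% cnt$network)
  expect_equal(cnt$count[cnt$network == 2], 1L)
  expect_equal(cnt$count[cnt$network == 3], 3L)
  expect_equal(sum(cnt$count), length(mask) - 2L)

  onlySeed <- countBetweenNetworkConnections(which(lab == 4)[1:5], sp, 4)
  expect_true(all(onlySeed$count == 0L))
})

test_that("timepoint comparisons report percentages and decreases", {
  sp <- midSpace()
  lab <- networkLabels(sp)
  sizes <- table(lab[lab > 0])
  base <- countBetweenNetworkConnections(which(lab == 2)[1:10], sp, 1,
                                         timepoint = "baseline")
  fol <- countBetweenNetworkConnections(which(lab == 2)[1:4], sp, 1,
                                        timepoint = "followup")
  cmp <- compareTimepointConnectionCounts(base, fol, sp)
  r2 <- cmp[cmp$network == 2, ]
  expect_equal(r2$baseline_pct, 100 * 10 / sizes[["2"]])
  expect_equal(r2$followup_pct, 100 * 4 / sizes[["2"]])
  expect_equal(r2$delta_pct, r2$followup_pct - r2$baseline_pct)
  expect_true(r2$decreased)
  expect_true(all(cmp$delta_pct[cmp$network != 2] == 0))
  expect_false(any(cmp$decreased[cmp$network != 2]))

  same <- compareTimepointConnectionCounts(base, base, sp)
  expect_true(all(same$delta_pct == 0))

  other <- countBetweenNetworkConnections(which(lab == 2)[1:4], sp, 3)
  expect_error(compareTimepointConnectionCounts(base, other, sp),
               "mismatched seed")
})

test_that("the planted target network attracts the largest seed counts", {
  # planted cross-network coupling with no global background: the seed
  # (effect region, network 3) should connect predominantly into the
  # target network (network 1), across replicates
  sp <- tinySpace()
  reg <- defaultEffectRegion(sp, network = 3, radius = 1.8)
  gv <- greyVoxels(sp)
  nSub <- 10
  wins <- 0L
  for (rep in 1:10) {
    zmaps <- lapply(seq_len(nSub), function(i) {
      ts <- simulateSubjectTimeseries(sp, withinR = 0.5, betweenR = 0,
                                      regionBoost = 0.6,
                                      effectRegion = reg,
                                      targetNetwork = 1L,
                                      nTimepoints = 80,
                                      seed = 1000 * rep + i)
      seedToVoxelZMap(ts, reg, sp, subject = paste0("s", i))
    })
    covs <- data.frame(age = c(31, 45, 28, 52, 40, 37, 61, 29, 48, 35),
                       sex = rep(c(0, 1), length.out = nSub),
                       ssri_snri = rep(c(1, 0, 0), length.out = nSub),
                       mean_fd = c(0.05, 0.08, 0.04, 0.07, 0.06, 0.09,
                                   0.05, 0.10, 0.06, 0.07))
    grp <- groupSeedGLM(zmaps, covs, isoMask(sp), nIter = 150,
                        seed = rep)
    cnt <- countBetweenNetworkConnections(
      which(significanceMask(grp$clusters)), sp, seedNetwork = 3)
    if (sum(cnt$count) > 0 &&
        cnt$network[which.max(cnt$count)] == 1L) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})
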