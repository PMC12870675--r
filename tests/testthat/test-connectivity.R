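test_that("connectivity matrices apply the negative-removal rule", {
  # identical series -> r = 1 kept off-diagonal
  ts <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  w <- connWeights(computeFCMatrix(ts))
  expect_equal(w, matrix(c(0, 1, 1, 0), 2))

  # anti-correlated series -> r = -1 removed
  ts <- cbind(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(connWeights(computeFCMatrix(ts)), matrix(0, 2, 2))

  # mixed signs: r(A,B)=1 kept, r(A,C)=r(B,C)=-1 removed
  ts <- cbind(A = c(0, 1, 0, 1), B = c(0, 1, 0, 1), C = c(1, 0, 1, 0))
  w <- connWeights(computeFCMatrix(ts))
  expect_equal(w[1, 2], 1)
  expect_equal(w[1, 3], 0)
  expect_equal(w[2, 3], 0)
})

test_that("zero-variance voxels are zeroed with a warning", {
  ts <- cbind(c(1, 2, 3, 4), c(2, 2, 2, 2), c(2, 4, 5, 9))
  expect_warning(fc <- computeFCMatrix(ts), "zero-variance")
  w <- connWeights(fc)
  expect_equal(w[2, ], c(0, 0, 0))
  expect_equal(w[, 2], c(0, 0, 0))
  expect_gt(w[1, 3], 0)  # remaining positively correlated pair kept
})

test_that("matrix preconditions are enforced", {
  expect_error(computeFCMatrix(matrix(1:4, 2, 2)), "3 timepoints")
  ts <- matrix(rnorm(12), 4, 3)
  expect_error(computeFCMatrix(ts, voxels = integer(0)), "nonempty")
})

test_that("weighted-degree matches its definition and scope contract", {
  # complete graph of 5 voxels with unit weights -> degree 4 everywhere
  w <- matrix(1, 5, 5); diag(w) <- 0
  wd <- weightedDegreeMap(fcFromWeights(w, scope = "grey"))
  expect_equal(mapValues(wd), rep(4, 5))

  # isolated voxel -> degree 0
  w2 <- matrix(0, 3, 3); w2[1, 2] <- w2[2, 1] <- 0.5
  wd2 <- weightedDegreeMap(fcFromWeights(w2, scope = "grey"))
  expect_equal(mapValues(wd2), c(0.5, 0.5, 0))

  expect_error(weightedDegreeMap(fcFromWeights(w, scope = "isocortical")),
               "grey")
})

test_that("all three metrics match naive double-loop oracles", {
  for (seed in c(1, 2, 3)) {
    v <- sample(8:20, 1)
    w <- randomWeights(v, seed)
    set.seed(seed + 100)
    lab <- sample(1:3, v, replace = TRUE)
    lab[1:3] <- 1:3  # every network populated

    expect_equal(mapValues(weightedDegreeMap(fcFromWeights(w, "grey"))),
                 oracleWeightedDegree(w), tolerance = 1e-12)
    fc <- fcFromWeights(w, "isocortical")
    expect_equal(mapValues(integrationMap(fc, lab)),
                 oracleIntegration(w, lab), tolerance = 1e-12)
    expect_equal(mapValues(segregationMap(fc, lab)),
                 oracleSegregation(w, lab), tolerance = 1e-12)
  }
})

test_that("integration and segregation cover their analytic examples", {
  w <- matrix(1, 4, 4); diag(w) <- 0
  fc <- fcFromWeights(w)
  lab <- c(1, 1, 2, 2)
  expect_equal(mapValues(integrationMap(fc, lab)), rep(2, 4))
  expect_equal(mapValues(segregationMap(fc, lab)), rep(1, 4))
  # one shared label -> integration zero; all distinct -> segregation zero
  expect_equal(mapValues(integrationMap(fc, rep(1, 4))), rep(0, 4))
  expect_equal(mapValues(segregationMap(fc, 1:4)), rep(0, 4))
  expect_error(integrationMap(fc, c(1, 1, 0, 2)), "label")
})

test_that("integration + segregation partitions the row sum", {
  for (seed in 1:5) {
    v <- 10 + seed
    w <- randomWeights(v, seed)
    set.seed(seed)
    lab <- sample(1:4, v, replace = TRUE)
    fc <- fcFromWeights(w)
    tot <- mapValues(integrationMap(fc, lab)) +
      mapValues(segregationMap(fc, lab))
    expect_equal(tot, rowSums(w), tolerance = 1e-12)
  }
})

test_that("metric maps are equivariant under voxel permutation", {
  v <- 12
  w <- randomWeights(v, 4)
  set.seed(4); lab <- sample(1:3, v, replace = TRUE)
  perm <- sample(v)
  fc <- fcFromWeights(w)
  fcP <- fcFromWeights(w[perm, perm])
  expect_equal(mapValues(integrationMap(fcP, lab[perm])),
               mapValues(integrationMap(fc, lab))[perm])
  expect_equal(mapValues(segregationMap(fcP, lab[perm])),
               mapValues(segregationMap(fc, lab))[perm])
  expect_equal(
    mapValues(weightedDegreeMap(fcFromWeights(w[perm, perm], "grey"))),
    mapValues(weightedDegreeMap(fcFromWeights(w, "grey")))[perm])
})

test_that("the isocortical submatrix equals a recomputation on iso voxels", {
  sp <- tinySpace()
  ts <- simulateSubjectTimeseries(sp, 0.4, 0.1, nTimepoints = 60,
                                  seed = 5)
  gv <- greyVoxels(sp)
  full <- computeFCMatrix(ts, voxels = gv, scope = "grey",
                          dims = spaceDims(sp))
  sub <- isocorticalSubmatrix(full, sp)
  direct <- computeFCMatrix(ts[, match(isoVoxels(sp), gv)],
                            voxels = isoVoxels(sp),
                            scope = "isocortical", dims = spaceDims(sp))
  expect_equal(connWeights(sub), connWeights(direct), tolerance = 1e-12)
  expect_identical(mapVoxels(sub), mapVoxels(direct))
})

test_that("change maps subtract baseline from follow-up", {
  mk <- function(vals, tp, subj = "s1")
    methods::new("MetricMap", metric = "integration", values = vals,
                 voxels = 1:3, dims = c(3L, 1L, 1L), subject = subj,
                 timepoint = tp)
  base <- mk(c(2, 2, 2), "baseline")
  fu <- mk(c(5, 5, 5), "followup")
  ch <- metricChangeMap(fu, base)
  expect_equal(mapValues(ch), c(3, 3, 3))
  expect_identical(mapTimepoint(ch), "change")
  expect_equal(mapValues(metricChangeMap(base, base)), c(0, 0, 0))

  other <- methods::new("MetricMap", metric = "integration",
                        values = 1:2 / 2, voxels = 1:2,
                        dims = c(2L, 1L, 1L), subject = "s1",
                        timepoint = "baseline")
  expect_error(metricChangeMap(fu, other), "mask mismatch")
  wd <- methods::new("MetricMap", metric = "weighted_degree",
                     values = c(1, 1, 1), voxels = 1:3,
                     dims = c(3L, 1L, 1L), subject = "s1",
                     timepoint = "baseline")
  expect_error(metricChangeMap(fu, wd), "metric mismatch")
})

test_that("the weighted-degree outlier screen flags gross deviants only", {
  x <- c(a = 10, b = 11, c = 10.5, d = 10.2, e = 60)
  expect_identical(flagOutlierSubjects(x, kSD = 3), "e")
  expect_identical(flagOutlierSubjects(rep(5, 6)), character(0))
  expect_error(flagOutlierSubjects(c(1, 2)), "3 subjects")
  # no false flags on a tight cohort
  set.seed(1)
  expect_identical(flagOutlierSubjects(rnorm(30, 100, 5)), character(0))
})
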