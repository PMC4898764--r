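test_that("generation is fully deterministic under the config seed", {
  cfg <- smallConfig(seed = 101)
  L1 <- generateLandscape(cfg)
  L2 <- generateLandscape(smallConfig(seed = 101))
  expect_identical(patchData(L1$patches), patchData(L2$patches))
  expect_identical(gridValues(L1$fields$twi), gridValues(L2$fields$twi))
  expect_identical(L1$cubes$t_max@values, L2$cubes$t_max@values)
  # byte-identical patch tables on disk
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writePatchTable(L1$patches, f1); writePatchTable(L2$patches, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # a different seed moves the patches
  L3 <- generateLandscape(smallConfig(seed = 102))
  expect_false(identical(patchData(L1$patches)$x, patchData(L3$patches)$x))
})

test_that("generated patch sets satisfy all record invariants", {
  for (s in 1:3) {
    ps <- generateLandscape(smallConfig(seed = 200 + s))$patches
    expect_true(validObject(ps))
    p <- patchData(ps)
    expect_true(all(p$area >= 0.3 * 1e4))          # minimum mapping unit
    expect_true(all(p$perimeter >= 2 * sqrt(pi * p$area) * (1 - 1e-9)))
    expect_false(anyDuplicated(p$id) > 0)
  }
})

test_that("zero field amplitude gives constant fields; defaults are autocorrelated", {
  cfg0 <- smallConfig(seed = 110, fieldAmplitude = 0)
  f0 <- generateStaticFields(cfg0)
  for (nm in names(f0))
    expect_equal(stats::sd(gridValues(f0[[nm]])), 0)

  # lag-1 Moran statistic (east-west neighbours) is clearly positive
  moran1 <- function(m) {
    a <- m[, -ncol(m)] - mean(m); b <- m[, -1] - mean(m)
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  f <- generateStaticFields(smallConfig(seed = 111))
  for (nm in names(f))
    expect_gt(moran1(gridValues(f[[nm]])), 0.5)
})

test_that("climate cubes honour their anomaly construction", {
  # noise 0: the FEB ANOMALY extent equals the imposed February anomaly field
  cfg <- smallConfig(seed = 120, climateNoiseSd = c(t_max = 0),
                     droughtAnomaly = c(t_max = 2),
                     anomalyMonths = list(t_max = 7:12))
  cube <- generateClimateCube(cfg, "t_max")
  fr <- featureRasters(cube, "FEB", "ANOMALY", 2011)
  expect_equal(gridValues(fr$anomaly), cube@metadata$anomalyMonthly[[12]],
               tolerance = 1e-9)

  # noise 0, -45% precipitation: PERCENT = 100 * (1 + anomaly) for the
  # water-year sum, exactly, at every cell (all months share the weight
  # only when the monthly anomaly patterns are collapsed; test via FEB)
  cfgP <- smallConfig(seed = 121, climateNoiseSd = c(precipitation = 0),
                      droughtAnomaly = c(precipitation = -0.45),
                      anomalyMonths = list(precipitation = 1:12))
  cubeP <- generateClimateCube(cfgP, "precipitation")
  pctF <- gridValues(featureRasters(cubeP, "FEB", "PERCENT", 2011)$percent)
  wFeb <- cubeP@metadata$anomalyMonthly[[12]] / -0.45  # weight in [0,1]
  expect_equal(pctF, 100 * (1 - 0.45 * wFeb), tolerance = 1e-9)
  # at the strongest-anomaly cell the deficit approaches the configured 45%
  expect_equal(min(pctF), 100 * (1 - 0.45 * max(wFeb)), tolerance = 1e-9)
  expect_lt(min(pctF), 80)

  # zero anomaly: the current-year aggregate is unbiased for the historic
  # mean (averaged over replicate cubes, within Monte-Carlo error)
  devs <- vapply(1:8, function(s) {
    cfg0 <- smallConfig(seed = 130 + s, droughtAnomaly = c(t_max = 0))
    cb <- generateClimateCube(cfg0, "t_max")
    fr <- featureRasters(cb, "DJF", "ANOMALY", 2011)
    mean(gridValues(fr$anomaly))
  }, numeric(1))
  noiseSd <- smallConfig()$climateNoiseSd[["t_max"]]
  mcSE <- noiseSd / sqrt(3) / sqrt(8)  # DJF averages 3 months, 8 replicates
  expect_lt(abs(mean(devs)), 3 * mcSE)
})

test_that("alpha is recovered when size effects are off", {
  cfg <- syntheticConfig(seed = 140, nParents = 500, meanOffspring = 20,
                         sizeEffects = numeric(0),
                         densityEffects = numeric(0))
  ps <- generatePatches(cfg, generateStaticFields(cfg), list())
  expect_gt(nPatches(ps), 5000)
  fit <- fitPowerLaw(patchAreas(ps, "ha"), xmin = 0.3)
  expect_lt(abs(exponent(fit) - 2.7), 0.05)
})

test_that("shape indices collapse to circles in the degenerate limit", {
  cfg <- smallConfig(seed = 150, sizeEffects = numeric(0),
                     densityEffects = numeric(0),
                     shapeLognormal = c(mu = -30, sigma = 1e-6))
  ps <- generatePatches(cfg, generateStaticFields(cfg), list())
  p <- patchData(ps)
  expect_equal(shapeIndex(p$area, p$perimeter),
               rep(1, nPatches(ps)), tolerance = 1e-9)
})

test_that("a positive density effect raises density in the top covariate quartile", {
  # effect is on stand height with positive sign here: clusters should sit
  # preferentially at tall-stand cells, so density rises with the covariate
  diffs <- vapply(1:20, function(s) {
    cfg <- smallConfig(seed = 300 + s, nParents = 40, meanOffspring = 4,
                       densityEffects = c(stand_height = 0.3),
                       sizeEffects = numeric(0))
    fields <- generateStaticFields(cfg)
    ps <- generatePatches(cfg, fields, list())
    ps <- attributeDensity(ps, kernelDensity(ps, 2000, 60))
    sh <- sampleAtCentroids(fields$stand_height, ps)
    kd <- patchAttr(ps, "kernel_density")
    q <- stats::quantile(sh, c(0.25, 0.75))
    mean(kd[sh >= q[2]]) - mean(kd[sh <= q[1]])
  }, numeric(1))
  expect_gt(mean(diffs) / (stats::sd(diffs) / sqrt(length(diffs))), 1.64)
})

test_that("degenerate configs error out", {
  expect_error(syntheticConfig(alphaTrue = 0.9))
  expect_error(syntheticConfig(clusterSd = 0))
  cfg <- smallConfig(seed = 160, nParents = 1, meanOffspring = 1,
                     sizeEffects = numeric(0), densityEffects = numeric(0))
  # tiny processes can yield zero offspring -> explicit error, not silence
  got <- tryCatch(generatePatches(cfg, generateStaticFields(cfg), list()),
                  error = conditionMessage)
  expect_true(is(got, "PatchSet") || grepl("zero patches", got))
})
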