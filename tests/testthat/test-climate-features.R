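# small hand-built cube: 2 x 3 grid, 1975-2011 monthly
makeCube <- function(variable = "precipitation", fill = NULL, seed = 1) {
  nm <- 12 * 37
  if (is.null(fill)) {
    set.seed(seed)
    vals <- array(runif(2 * 3 * nm, 10, 100), dim = c(2, 3, nm))
  } else {
    vals <- array(fill, dim = c(2, 3, nm))
  }
  climateCube(variable, vals, xll = 0, yll = 0, cellSize = 5000,
              startYear = 1975L)
}

test_that("grain aggregation sums fluxes, averages states, FEB is identity", {
  cube <- makeCube("precipitation", seed = 2)
  feb <- aggregateGrain(cube, "FEB", 2011)
  idx <- (2011 - 1975) * 12 + 2
  expect_equal(gridValues(feb), cube@values[, , idx])

  cst <- makeCube("t_max", fill = 7)
  expect_equal(unique(as.vector(gridValues(
    aggregateGrain(cst, "DJF", 2000)))), 7)   # state: mean
  cstP <- makeCube("precipitation", fill = 7)
  expect_equal(unique(as.vector(gridValues(
    aggregateGrain(cstP, "DJF", 2000)))), 21) # flux: sum of 3 months

  # brute-force oracle for SONDJF: re-sum the six listed months directly
  mons <- rbind(cbind(2009, 9:12), cbind(2010, 1:2))
  oracle <- Reduce(`+`, lapply(seq_len(nrow(mons)), function(i)
    cube@values[, , (mons[i, 1] - 1975) * 12 + mons[i, 2]]))
  expect_equal(gridValues(aggregateGrain(cube, "SONDJF", 2010)), oracle,
               tolerance = 1e-12)

  # missing months named
  expect_error(aggregateGrain(cube, "WATER_YEAR", 1975), "missing month")
})

test_that("extent composition has its algebraic identities", {
  cube <- makeCube("precipitation", seed = 3)
  cur <- aggregateGrain(cube, "DJF", 2011)
  hist <- lapply(setdiff(availableWaterYears(cube, "DJF"), 2011),
                 function(y) aggregateGrain(cube, "DJF", y))

  # current == historic mean everywhere -> ANOMALY 0, PERCENT 100
  hmean <- Reduce(`+`, lapply(hist, gridValues)) / length(hist)
  curEq <- rasterGrid(hmean, 0, 0, 5000)
  expect_equal(unique(round(as.vector(gridValues(
    composeExtent(curEq, hist, "ANOMALY")$anomaly)), 9)), 0)
  expect_equal(unique(round(as.vector(gridValues(
    composeExtent(curEq, hist, "PERCENT")$percent)), 9)), 100)

  # PERCENT * historic / 100 recovers current to 1e-9
  pct <- gridValues(composeExtent(cur, hist, "PERCENT")$percent)
  expect_equal(pct * hmean / 100, gridValues(cur), tolerance = 1e-9)

  # ANOMALY = historic * (PERCENT/100 - 1) exactly
  anom <- gridValues(composeExtent(cur, hist, "ANOMALY")$anomaly)
  expect_equal(anom, hmean * (pct / 100 - 1), tolerance = 1e-9)

  # COVARIATE yields the two columns, HISTORIC the mean
  cov <- composeExtent(cur, hist, "COVARIATE")
  expect_named(cov, c("current", "historic"))
  expect_equal(gridValues(cov$historic), hmean)
  expect_equal(gridValues(composeExtent(cur, hist, "HISTORIC")$historic),
               hmean)

  # zero historic mean flags PERCENT as undefined
  z <- lapply(hist, function(g) rasterGrid(gridValues(g) * 0, 0, 0, 5000))
  expect_warning(p0 <- composeExtent(cur, z, "PERCENT"), "undefined")
  expect_true(all(is.na(gridValues(p0$percent))))
})

test_that("HISTORIC is invariant to permuting the year order and flux scaling is linear", {
  cube <- makeCube("aet", seed = 4)
  hist <- lapply(1990:2005, function(y) aggregateGrain(cube, "DJF", y))
  cur <- aggregateGrain(cube, "DJF", 2011)
  h1 <- gridValues(composeExtent(cur, hist, "HISTORIC")$historic)
  set.seed(1)
  h2 <- gridValues(composeExtent(cur, sample(hist), "HISTORIC")$historic)
  expect_equal(h1, h2, tolerance = 1e-12)

  k <- 3.7
  cube2 <- climateCube("aet", cube@values * k, xll = 0, yll = 0,
                       cellSize = 5000, startYear = 1975L)
  expect_equal(gridValues(aggregateGrain(cube2, "SONDJF", 2000)),
               k * gridValues(aggregateGrain(cube, "SONDJF", 2000)),
               tolerance = 1e-9)
})

test_that("the factorial enumeration is complete and ordered", {
  e <- enumerateParameterizations()
  expect_equal(nrow(e), 20)
  expect_equal(e$grain[1], "FEB")
  expect_equal(e$extent[1], "HISTORIC")
  expect_equal(sum(e$nColumns == 2), 4)   # one COVARIATE per grain
  got <- paste(e$grain, e$extent)
  want <- as.vector(t(outer(temporalGrains(), temporalExtents(), paste)))
  expect_identical(got, want)
})

test_that("centroid sampling matches direct index arithmetic", {
  set.seed(6)
  m <- matrix(rnorm(20 * 30), 20, 30)
  g <- rasterGrid(m, xll = 1000, yll = 2000, cellSize = 25)
  x <- runif(100, 1000, 1000 + 30 * 25)
  y <- runif(100, 2000, 2000 + 20 * 25)
  ps <- patchSet(data.frame(id = as.character(1:100), x = x, y = y,
                            area = 1e4, perimeter = 2 * sqrt(pi * 1e4)))
  got <- sampleAtCentroids(g, ps)
  # oracle: row/col arithmetic done from scratch
  col <- pmin(30, floor((x - 1000) / 25) + 1)
  row <- 20 - pmin(20, floor((y - 2000) / 25) + 1) + 1
  expect_equal(got, m[cbind(row, col)])

  # constant raster -> the constant; outside -> error with patch ids
  expect_equal(sampleAtCentroids(rasterGrid(matrix(5, 20, 30), 1000, 2000,
                                            25), ps), rep(5, 100))
  out <- patchSet(data.frame(id = "far", x = 1e6, y = 2000, area = 1e4,
                             perimeter = 2 * sqrt(pi * 1e4)))
  expect_error(sampleAtCentroids(g, out), "far")
})

test_that("climate features carry variable/grain/extent names and warn on temperature percents", {
  cfg <- smallConfig(seed = 5)
  cube <- generateClimateCube(cfg, "t_max")
  ps <- generatePatches(cfg, generateStaticFields(cfg),
                        list(t_max = cube))
  f <- climateFeature(cube, "DJF", "ANOMALY", ps)
  expect_identical(names(f), "t_max_djf_anomaly")
  expect_equal(nrow(f), nPatches(ps))
  expect_warning(climateFeature(cube, "FEB", "PERCENT", ps), "temperature")
  cv <- suppressWarnings(climateFeature(cube, "FEB", "COVARIATE", ps))
  expect_identical(names(cv),
                   c("t_max_feb_covariate_current",
                     "t_max_feb_covariate_historic"))
})
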