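test_that("log transform is the natural log on positive values", {
  expect_equal(logTransformResponse(1), 0)
  expect_equal(logTransformResponse(exp(1)), 1)
  x <- runif(50, 0.01, 100)
  expect_equal(exp(logTransformResponse(x)), x, tolerance = 1e-12)
  expect_error(logTransformResponse(c(1, 0)), "positive")
})

test_that("fitGlm matches the normal-equations solve to 1e-8", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 50
    X <- data.frame(a = rnorm(n), b = runif(n), c = rnorm(n, 5, 2))
    y <- 2 + 1.5 * X$a - 0.7 * X$b + 0.2 * X$c + rnorm(n, 0, 0.5)
    fit <- fitGlm(y, X)
    Xm <- cbind(1, as.matrix(X))
    beta <- solve(t(Xm) %*% Xm, t(Xm) %*% y)
    expect_equal(coefTable(fit)$coefficient, as.vector(beta),
                 tolerance = 1e-8)
    # SE oracle from the same normal equations
    res <- y - Xm %*% beta
    s2 <- sum(res^2) / (n - ncol(Xm))
    se <- sqrt(diag(s2 * solve(t(Xm) %*% Xm)))
    expect_equal(coefTable(fit)$SE, unname(se), tolerance = 1e-8)
  }
})

test_that("fitGlm handles exact fits, pure noise and rank deficiency", {
  x <- seq_len(30)
  fit <- suppressWarnings(fitGlm(3 + 2 * x, data.frame(x = x)))
  expect_equal(rSquared(fit), 1, tolerance = 1e-12)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-9)

  set.seed(32)
  f0 <- fitGlm(rnorm(40), NULL)
  expect_equal(rSquared(f0), 0)
  expect_equal(nrow(coefTable(f0)), 1)
  expect_equal(coefTable(f0)$term, "intercept")

  X <- data.frame(a = rnorm(30), b = rnorm(30))
  X$dup <- X$a * 2
  expect_error(fitGlm(rnorm(30), X), "dup")
  expect_error(fitGlm(rnorm(3), data.frame(a = rnorm(3), b = rnorm(3))),
               "n > p")
})

test_that("fitGlm is affine-equivariant in the predictors", {
  set.seed(33)
  n <- 60
  X <- data.frame(a = rnorm(n), b = runif(n))
  y <- 1 + X$a - 2 * X$b + rnorm(n, 0, 0.3)
  f1 <- fitGlm(y, X)
  k <- 40
  X2 <- X; X2$a <- X$a * k
  f2 <- fitGlm(y, X2)
  t1 <- coefTable(f1); t2 <- coefTable(f2)
  expect_equal(t2$coefficient[t2$term == "a"],
               t1$coefficient[t1$term == "a"] / k, tolerance = 1e-8)
  expect_equal(modelAIC(f2), modelAIC(f1), tolerance = 1e-8)
  expect_equal(rSquared(f2), rSquared(f1), tolerance = 1e-8)
  expect_equal(t2$t, t1$t, tolerance = 1e-8)
})

test_that("AIC selection recovers a planted parameterization and breaks ties by order", {
  cfg <- smallConfig(seed = 41, climateNoiseSd = c(t_max = 0.3),
                     droughtAnomaly = c(t_max = 2),
                     anomalyMonths = list(t_max = 10:12))
  cube <- generateClimateCube(cfg, "t_max")
  ps <- generatePatches(cfg, generateStaticFields(cfg), list(t_max = cube))
  f <- climateFeature(cube, "DJF", "ANOMALY", ps)[[1]]
  set.seed(41)
  y <- 2 - 1.5 * f + rnorm(length(f), 0, 0.1)   # strong, low-noise signal
  sel <- suppressWarnings(selectParameterization(y, cube, ps))
  expect_equal(sel$grain, "DJF")
  expect_equal(sel$extent, "ANOMALY")
  # winner's AIC is the minimum of all computed candidates
  expect_equal(min(sel$table$aic, na.rm = TRUE), modelAIC(sel$fit))

  # a time-constant cube with exactly representable integer values: every
  # grain/extent view of a state variable is the same spatial field (ANOMALY
  # is exactly 0, PERCENT exactly 100, COVARIATE aliased, so those are
  # skipped) -> 8 candidates tie bitwise and the declared enumeration order
  # picks (FEB, HISTORIC)
  V <- outer(1:2, 10 * (1:3), `+`)
  vals <- array(rep(V, 12 * 37), dim = c(2, 3, 12 * 37))
  cube0 <- climateCube("t_max", vals, xll = 0, yll = 0, cellSize = 5000,
                       startYear = 1975L)
  set.seed(42)
  ps0 <- patchSet(data.frame(id = as.character(1:40),
                             x = runif(40, 500, 14500),
                             y = runif(40, 500, 9500),
                             area = 1e4, perimeter = 2 * sqrt(pi * 1e4)))
  y0 <- rnorm(40)
  sel0 <- suppressWarnings(selectParameterization(y0, cube0, ps0))
  computed <- !is.na(sel0$table$aic)
  expect_equal(sum(computed), 8)   # HISTORIC + CURRENT per grain
  expect_lt(diff(range(sel0$table$aic[computed])), 1e-9)
  expect_equal(sel0$grain, "FEB")
  expect_equal(sel0$extent, "HISTORIC")
})

test_that("stepwise entry obeys the delta-AIC threshold exactly", {
  set.seed(51)
  n <- 80
  x <- rnorm(n)
  y <- 0.3 * x + rnorm(n)
  a0 <- modelAIC(fitGlm(y, NULL))
  a1 <- modelAIC(fitGlm(y, data.frame(x = x)))
  red <- a0 - a1
  expect_gt(red, 0.2)  # construction sanity
  over <- stepwiseSelect(y, list(x = x), deltaAic = red + 0.1)
  expect_equal(nrow(coefTable(over$fit)), 1)      # intercept-only
  expect_match(over$stopReason, "no candidate")
  under <- stepwiseSelect(y, list(x = x), deltaAic = red - 0.1)
  expect_true("x" %in% coefTable(under$fit)$term)
})

test_that("stepwise recovers planted effects and rejects decoys", {
  set.seed(52)
  n <- 226
  x1 <- rnorm(n); x2 <- rnorm(n)
  decoys <- as.data.frame(matrix(rnorm(n * 5), n,
                                 dimnames = list(NULL, paste0("d", 1:5))))
  y <- 3 * x1 - 2 * x2 + rnorm(n, 0, 0.8)
  cands <- c(list(x1 = x1, x2 = x2), as.list(decoys))
  res <- stepwiseSelect(y, cands, deltaAic = 2)
  terms <- coefTable(res$fit)
  expect_true(all(c("x1", "x2") %in% terms$term))
  expect_false(any(paste0("d", 1:5) %in% terms$term))
  expect_lt(abs(terms$coefficient[terms$term == "x1"] - 3),
            3 * terms$SE[terms$term == "x1"])
  expect_lt(abs(terms$coefficient[terms$term == "x2"] + 2),
            3 * terms$SE[terms$term == "x2"])

  # trace invariants: monotone decreasing AIC, every entry reduction > 2
  tr <- res$trace
  aicPath <- c(modelAIC(fitGlm(y, NULL)),
               tr$aic_if_added[tr$entered])
  expect_true(all(diff(aicPath) < -2))
  expect_lte(modelAIC(res$fit), aicPath[1])
})

test_that("COVARIATE bundles enter and leave stepwise as one block", {
  set.seed(53)
  n <- 150
  cur <- rnorm(n); hist <- rnorm(n)
  y <- 1.2 * cur - 0.8 * hist + rnorm(n, 0, 0.5)
  cands <- list(t_bundle = data.frame(t_cur = cur, t_hist = hist),
                decoy = rnorm(n))
  res <- stepwiseSelect(y, cands, deltaAic = 2)
  terms <- coefTable(res$fit)$term
  expect_true(all(c("t_cur", "t_hist") %in% terms))
  expect_false("decoy" %in% terms)
})

test_that("collinearity screen flags duplicates and matches the direct formula", {
  set.seed(61)
  n <- 100
  X <- data.frame(a = rnorm(n))
  X$b <- X$a                           # duplicate
  X$c <- rnorm(n)
  expect_warning(scr <- collinearityScreen(X, threshold = 0.7),
                 "intercorrelated")
  ab <- scr$correlations[scr$correlations$var1 == "a" &
                           scr$correlations$var2 == "b", ]
  expect_equal(ab$r, 1)
  expect_true(ab$flagged)

  # direct-formula oracle for a random pair
  ac <- scr$correlations[scr$correlations$var1 == "a" &
                           scr$correlations$var2 == "c", ]
  rOracle <- sum((X$a - mean(X$a)) * (X$c - mean(X$c))) /
    sqrt(sum((X$a - mean(X$a))^2) * sum((X$c - mean(X$c))^2))
  expect_equal(ac$r, rOracle, tolerance = 1e-12)

  # orthogonalized pair has r = 0
  e <- residuals(lm(X$c ~ X$a))
  expect_lt(abs(suppressWarnings(
    collinearityScreen(data.frame(a = X$a, e = e))
  )$correlations$r[1]), 1e-12)

  Xz <- data.frame(a = rnorm(10), z = rep(2, 10))
  expect_warning(s2 <- collinearityScreen(Xz), "zero-variance")
  expect_equal(s2$zeroVariance, "z")
  expect_error(collinearityScreen(data.frame(a = 1:5)), "2 columns")
})

test_that("Mantel p at n = 5 equals exhaustive enumeration", {
  set.seed(71)
  xy <- matrix(runif(10), 5, 2)
  r <- rnorm(5)
  d1 <- as.matrix(dist(xy))
  d2 <- abs(outer(r, r, `-`))
  got <- mantelTest(d1, d2, nPerm = 999, seed = 1)
  expect_true(got$exact)
  expect_equal(got$nPerm, 120)

  # oracle: enumerate all 120 permutations independently
  perms <- expand.grid(a = 1:5, b = 1:5, c = 1:5, d = 1:5, e = 1:5)
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  lt <- lower.tri(d1)
  rStat <- function(p) {
    dp <- d2[unlist(p), unlist(p)]
    cor(d1[lt], dp[lt])
  }
  rAll <- apply(perms, 1, function(p) rStat(as.integer(p)))
  rObs <- cor(d1[lt], d2[lt])
  expect_equal(got$r, rObs, tolerance = 1e-12)
  expect_equal(got$p, mean(rAll >= rObs - 1e-12), tolerance = 1e-12)
})

test_that("Mantel Monte-Carlo path agrees with vegan on the statistic", {
  skip_if_not_installed("vegan")
  set.seed(72)
  n <- 25
  xy <- matrix(runif(2 * n, 0, 1000), n, 2)
  r <- rnorm(n) + 0.002 * xy[, 1]      # mild spatial signal
  d1 <- as.matrix(dist(xy))
  d2 <- abs(outer(r, r, `-`))
  ours <- mantelTest(d1, d2, nPerm = 999, seed = 5)
  expect_false(ours$exact)
  vg <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 999)
  expect_equal(ours$r, unname(vg$statistic), tolerance = 1e-10)
  expect_lt(abs(ours$p - vg$signif), 0.08)   # both are MC estimates
  expect_error(mantelTest(d1, d2, nPerm = 50, seed = 1), ">= 99")
  expect_error(mantelTest(d1, d2, nPerm = 999), "seed")
})

test_that("residual diagnostics catch coordinate-aligned residuals", {
  set.seed(73)
  ps <- makePatches(40, seed = 73)
  p <- patchData(ps)
  # residuals equal to centroid x: coordinate correlation is exactly 1
  y <- p$x - mean(p$x)
  fit <- fitGlm(y, NULL)
  d <- residualSpatialCheck(fit, ps, nPerm = 199, seed = 3)
  expect_equal(d$xCor, 1, tolerance = 1e-9)
  expect_lt(d$xP, 1e-10)
  expect_lt(d$mantelP, 0.05)
})
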