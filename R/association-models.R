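#' Log-transform a patch characteristic
#'
#' Natural log; all patch characteristics are log transformed before
#' modelling to achieve homoscedasticity and approximate residual normality.
#'
#' @param values positive numeric vector.
#' @return log-transformed vector.
#' @export
logTransformResponse <- function(values) {
  if (any(values <= 0))
    stop("log transform requires positive values", call. = FALSE)
  log(values)
}

#' Fit a Gaussian identity-link GLM
#'
#' Ordinary least-squares (Gaussian likelihood) fit of a response on
#' predictor columns, with coefficient table (estimate, SE, t, two-sided p),
#' AIC under the full Gaussian log-likelihood convention (`stats::AIC`: k
#' counts the intercept, slopes and the error variance) and `R^2 = 1 -
#' RSS/TSS`.
#'
#' @param y numeric response.
#' @param X data frame / matrix of predictor columns, or NULL for the
#'   intercept-only model.
#' @param response label stored with the fit.
#' @return a [GlmFit-class].
#' @export
fitGlm <- function(y, X = NULL, response = "y") {
  if (is.null(X) || NCOL(X) == 0L) {
    df <- data.frame(y = y)
    form <- y ~ 1
  } else {
    X <- as.data.frame(X)
    if (anyNA(X) || anyNA(y)) stop("missing values in y or X", call. = FALSE)
    if (length(y) <= ncol(X) + 1L)
      stop("need n > p + 1 observations", call. = FALSE)
    df <- data.frame(y = y, X, check.names = FALSE)
    form <- stats::as.formula(paste(
      "y ~", paste(sprintf("`%s`", names(X)), collapse = " + ")))
  }
  m <- stats::lm(form, data = df)
  cf <- stats::coef(m)
  if (anyNA(cf))
    stop("rank-deficient design; aliased column(s): ",
         paste(gsub("`", "", names(cf)[is.na(cf)]), collapse = ", "),
         call. = FALSE)
  sm <- summary(m)$coefficients
  terms <- data.frame(term = gsub("`", "", rownames(sm)),
                      coefficient = sm[, 1L], SE = sm[, 2L],
                      t = sm[, 3L], p = sm[, 4L],
                      stringsAsFactors = FALSE, row.names = NULL)
  terms$term[terms$term == "(Intercept)"] <- "intercept"
  rss <- sum(stats::residuals(m)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  new("GlmFit", response = response, terms = terms,
      aic = stats::AIC(m), rSquared = max(0, min(1, r2)),
      residuals = unname(stats::residuals(m)), n = length(y))
}

#' Select a climate variable's temporal parameterization by AIC
#'
#' Fits all 20 grain x extent parameterizations of one climate variable in
#' univariate models of the response (bivariate for the COVARIATE extent)
#' and returns the minimum-AIC parameterization. Parameterizations that are
#' undefined at any centroid (PERCENT over a zero historic mean) are skipped
#' with a warning. Ties are broken toward fewer predictor columns, then
#' enumeration order.
#'
#' @param y per-patch response (already log transformed).
#' @param cube a [ClimateCube-class].
#' @param patches a [PatchSet-class].
#' @param currentYear drought water-year label.
#' @return list with `grain`, `extent`, `fit` (the winning [GlmFit-class]),
#'   `features` (its predictor columns) and `table` (all 20 candidates with
#'   AIC, NA where skipped).
#' @export
selectParameterization <- function(y, cube, patches, currentYear = 2011L) {
  cands <- enumerateParameterizations()
  cands$aic <- NA_real_
  fits <- vector("list", nrow(cands))
  feats <- vector("list", nrow(cands))
  for (i in seq_len(nrow(cands))) {
    Xi <- tryCatch(
      suppressWarnings(climateFeature(cube, cands$grain[i], cands$extent[i],
                                      patches, currentYear)),
      error = function(e) NULL)
    if (is.null(Xi) || anyNA(Xi)) {
      warning("skipping ", cands$grain[i], "/", cands$extent[i],
              " for ", cube@variable, ": undefined at some centroids",
              call. = FALSE)
      next
    }
    fi <- tryCatch(fitGlm(y, Xi, response = cube@variable),
                   error = function(e) NULL)
    if (is.null(fi)) next
    cands$aic[i] <- modelAIC(fi)
    fits[[i]] <- fi
    feats[[i]] <- Xi
  }
  if (all(is.na(cands$aic)))
    stop("no parameterization of ", cube@variable, " could be fit",
         call. = FALSE)
  ord <- order(cands$aic, cands$nColumns, seq_len(nrow(cands)),
               na.last = TRUE)
  best <- ord[1L]
  list(grain = cands$grain[best], extent = cands$extent[best],
       fit = fits[[best]], features = feats[[best]], table = cands)
}

#' Forward stepwise selection with a delta-AIC stopping rule
#'
#' Starts from the intercept-only model and at each step enters the
#' candidate giving the largest AIC reduction, provided that reduction
#' exceeds `deltaAic` (default 2.0) -- a single variable can reduce AIC
#' slightly without a real gain in likelihood, so entry demands more than
#' the minimum. Candidates may be single columns or bundled multi-column
#' blocks (a COVARIATE current+historic pair enters and leaves together).
#' No removal phase: entry-only, with the full evaluation trace recorded.
#'
#' @param y numeric response.
#' @param candidates named list; each element a numeric vector or a data
#'   frame of columns forming one candidate block.
#' @param deltaAic required AIC reduction for entry.
#' @param response label for the final fit.
#' @return list with `fit` (final [GlmFit-class]), `trace` (data frame of
#'   every candidate evaluation: step, candidate, aic_if_added, entered) and
#'   `stopReason`.
#' @export
stepwiseSelect <- function(y, candidates, deltaAic = 2.0, response = "y") {
  stopifnot(length(candidates) >= 1L, !is.null(names(candidates)))
  blocks <- lapply(candidates, function(b) {
    b <- as.data.frame(b)
    b
  })
  for (nm in names(blocks))
    if (ncol(blocks[[nm]]) == 1L) names(blocks[[nm]]) <- nm
  inModel <- character()
  remaining <- names(blocks)
  current <- fitGlm(y, NULL, response = response)
  trace <- list()
  step <- 0L
  stopReason <- NA_character_
  repeat {
    step <- step + 1L
    if (!length(remaining)) { stopReason <- "all candidates entered"; break }
    aics <- vapply(remaining, function(nm) {
      X <- do.call(cbind, c(lapply(inModel, function(m) blocks[[m]]),
                            list(blocks[[nm]])))
      tryCatch(modelAIC(fitGlm(y, X, response = response)),
               error = function(e) NA_real_)
    }, numeric(1))
    best <- which.min(aics)
    entered <- length(best) == 1L && !is.na(aics[best]) &&
      (modelAIC(current) - aics[best]) > deltaAic
    trace[[step]] <- data.frame(step = step, candidate = remaining,
                                aic_if_added = unname(aics),
                                entered = seq_along(remaining) ==
                                  best & entered,
                                stringsAsFactors = FALSE)
    if (!entered) {
      stopReason <- sprintf(
        "no candidate reduces AIC by more than %.1f", deltaAic)
      break
    }
    inModel <- c(inModel, remaining[best])
    remaining <- remaining[-best]
    current <- fitGlm(y, do.call(cbind, lapply(inModel,
                                               function(m) blocks[[m]])),
                      response = response)
  }
  list(fit = current, trace = do.call(rbind, trace), stopReason = stopReason)
}

#' Pairwise collinearity screen
#'
#' All pairwise Pearson correlations among predictor columns; pairs with
#' `|r|` at or above the threshold are flagged (warn-only: final models are
#' screened so that entered variables are not highly intercorrelated, but
#' removal is left to the analyst by default). Zero-variance columns are
#' flagged and excluded from the correlations.
#'
#' @param X data frame / matrix of >= 2 predictor columns.
#' @param threshold flag level for `|r|` (default 0.7).
#' @return list with `correlations` (data frame var1, var2, r, flagged) and
#'   `zeroVariance` (column names).
#' @export
collinearityScreen <- function(X, threshold = 0.7) {
  X <- as.data.frame(X)
  if (ncol(X) < 2L) stop("need at least 2 columns", call. = FALSE)
  sds <- vapply(X, stats::sd, numeric(1))
  zv <- names(X)[sds == 0]
  keep <- names(X)[sds > 0]
  out <- NULL
  if (length(keep) >= 2L) {
    cm <- stats::cor(X[keep])
    idx <- which(upper.tri(cm), arr.ind = TRUE)
    out <- data.frame(var1 = keep[idx[, 1L]], var2 = keep[idx[, 2L]],
                      r = cm[idx], stringsAsFactors = FALSE)
    out$flagged <- abs(out$r) >= threshold
    if (any(out$flagged))
      warning("highly intercorrelated predictors: ",
              paste(sprintf("%s~%s (r=%.2f)", out$var1[out$flagged],
                            out$var2[out$flagged], out$r[out$flagged]),
                    collapse = ", "), call. = FALSE)
  }
  if (length(zv))
    warning("zero-variance column(s): ", paste(zv, collapse = ", "),
            call. = FALSE)
  list(correlations = out, zeroVariance = zv)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation between the lower triangles, with a one-sided
#' permutation p (proportion of row/column permutations whose statistic is
#' at or above the observed). When `factorial(n) <= nPerm` all permutations
#' are enumerated and the p-value is exact; otherwise `nPerm` random
#' permutations are drawn under the seed and
#' `p = (1 + #\{r_perm >= r_obs\}) / (nPerm + 1)`.
#'
#' @param d1,d2 symmetric distance matrices (or `dist` objects) of the same
#'   size.
#' @param nPerm number of permutations (>= 99).
#' @param seed integer RNG seed.
#' @return list with `r`, `p`, `nPerm`, `exact`.
#' @export
mantelTest <- function(d1, d2, nPerm = 999, seed) {
  if (nPerm < 99) stop("nPerm must be >= 99", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  n <- nrow(d1)
  stopifnot(ncol(d1) == n, all(dim(d2) == n))
  lt <- lower.tri(d1)
  rObs <- stats::cor(d1[lt], d2[lt])
  statFor <- function(perm) {
    dp <- d2[perm, perm]
    stats::cor(d1[lt], dp[lt])
  }
  exact <- factorial(n) <= nPerm
  if (exact) {
    perms <- allPermutations(n)
    rs <- vapply(perms, statFor, numeric(1))
    p <- mean(rs >= rObs - 1e-12)
  } else {
    set.seed(as.integer(seed))
    rs <- vapply(seq_len(nPerm), function(i) statFor(sample.int(n)),
                 numeric(1))
    p <- (1 + sum(rs >= rObs - 1e-12)) / (nPerm + 1)
  }
  list(r = rObs, p = p, nPerm = if (exact) length(rs) else nPerm,
       exact = exact)
}

allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- allPermutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub)
    for (pos in 0:(n - 1L)) {       # insert n into every slot of each perm
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos)
    }
  out
}

#' Residual spatial diagnostics
#'
#' Confirms the absence of residual spatial structure: Pearson correlations
#' (with p) of the model residuals against centroid x and y, plus a Mantel
#' test between the Euclidean geographic distance matrix of the centroids
#' and the absolute-difference dissimilarity matrix of the residuals.
#'
#' @param fit a [GlmFit-class] whose residuals align with patch order.
#' @param patches the [PatchSet-class] the model was fit on.
#' @param nPerm Mantel permutations (>= 99).
#' @param seed integer RNG seed.
#' @return list with `xCor`, `xP`, `yCor`, `yP`, `mantelR`, `mantelP`.
#' @export
residualSpatialCheck <- function(fit, patches, nPerm = 999, seed) {
  r <- residuals(fit)
  p <- patchData(patches)
  stopifnot(length(r) == nrow(p))
  cx <- stats::cor.test(r, p$x)
  cy <- stats::cor.test(r, p$y)
  dg <- as.matrix(stats::dist(cbind(p$x, p$y)))
  dr <- abs(outer(r, r, `-`))
  mt <- mantelTest(dg, dr, nPerm = nPerm, seed = seed)
  list(xCor = unname(cx$estimate), xP = cx$p.value,
       yCor = unname(cy$estimate), yP = cy$p.value,
       mantelR = mt$r, mantelP = mt$p, mantelExact = mt$exact)
}
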