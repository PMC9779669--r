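## regression_pipeline: z-score standardization, feature selection by
## penalized regression (lasso / ridge) refined by stepwise AIC, and the
## repeated 80/20 train/test protocol reporting the fraction of variation
## explained (training R^2) and the predicted R^2
## (1 - SSE/SST on the held-out split), each as mean +/- sd over repeats.

#' Z-score standardization with a reusable transform
#'
#' Columns are centred and scaled to unit sample sd.  Constant columns are
#' dropped with a warning.  The returned object stores the training
#' statistics so the identical transform can be re-applied to test splits
#' via \code{\link{applyStandardization}}.
#'
#' @param X numeric matrix (genes x features).
#' @return list of class \code{StandardizedFeatures} with elements
#'   \code{X}, \code{center}, \code{scale}, \code{dropped}.
#' @export
standardizeFeatures <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X, na.rm = TRUE)
  scl <- apply(X, 2L, sd, na.rm = TRUE)
  constant <- !is.finite(scl) | scl == 0
  if (any(constant))
    warning("dropping constant column(s): ",
            paste(colnames(X)[constant], collapse = ", "))
  keep <- !constant
  out <- sweep(sweep(X[, keep, drop = FALSE], 2L, ctr[keep]), 2L,
               scl[keep], `/`)
  structure(list(X = out, center = ctr[keep], scale = scl[keep],
                 dropped = colnames(X)[constant]),
            class = "StandardizedFeatures")
}

#' @rdname standardizeFeatures
#' @param transform a \code{StandardizedFeatures} object.
#' @param newX matrix with (a subset of) the same columns.
#' @export
applyStandardization <- function(transform, newX) {
  cols <- intersect(colnames(newX), names(transform$center))
  sweep(sweep(as.matrix(newX)[, cols, drop = FALSE], 2L,
              transform$center[cols]), 2L, transform$scale[cols], `/`)
}

predictedR2 <- function(yTest, yHat) {
  sst <- sum((yTest - mean(yTest))^2)
  1 - sum((yTest - yHat)^2) / sst
}

repeatedSplitFit <- function(X, y, features, nRepeats, split, engine, seed) {
  df <- data.frame(y = y, X[, features, drop = FALSE], check.names = FALSE)
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n < length(features) + 2L)
    stop("fewer complete cases than model parameters")
  if (n < 20L) stop("need at least 20 complete cases")
  fml <- as.formula(paste("y ~",
                          paste(sprintf("`%s`", features), collapse = " + ")))
  seeds <- deriveSeeds(seed, nRepeats)
  frac <- numeric(nRepeats); pr2 <- numeric(nRepeats)
  coefSum <- NULL
  for (r in seq_len(nRepeats)) {
    idx <- withSeed(seeds[r], sample.int(n, floor(split * n)))
    tr <- df[idx, , drop = FALSE]; te <- df[-idx, , drop = FALSE]
    if (engine == "linear") {
      fit <- lm(fml, data = tr)
      frac[r] <- summary(fit)$r.squared
      yHat <- predict(fit, newdata = te)
      cf <- coef(fit)
      coefSum <- if (is.null(coefSum)) cf else coefSum + cf
    } else {
      if (!requireNamespace("randomForest", quietly = TRUE))
        stop("engine 'randomForest' requires the randomForest package")
      fit <- withSeed(seeds[r],
                      randomForest::randomForest(fml, data = tr))
      frac[r] <- predictedR2(tr$y, predict(fit, newdata = tr))
      yHat <- predict(fit, newdata = te)
    }
    pr2[r] <- predictedR2(te$y, yHat)
  }
  list(features = features,
       fractionExplained = mean(frac), fractionExplainedSD = sd(frac),
       predictedR2 = mean(pr2), predictedR2SD = sd(pr2),
       nRepeats = nRepeats, split = split, engine = engine,
       coefficients = if (!is.null(coefSum)) coefSum / nRepeats else NULL)
}

#' Predictive power of a single feature over repeated train/test splits
#'
#' Per repeat: a random 80/20 split, a least-squares fit of noise on the
#' feature on the training part (fraction of variation explained =
#' training R^2), and the predicted R^2 = 1 - SSE/SST on the held-out part
#' (SST about the test mean).  The protocol is repeated \code{nRepeats}
#' times (1000 in the full-scale analysis) to obtain mean and sd.
#'
#' @param X genes x features matrix.
#' @param y response (noise) vector.
#' @param feature feature (column) name.
#' @param nRepeats number of random splits (default 1000).
#' @param split training fraction (default 0.8).
#' @param seed master seed; per-repeat seeds are derived from it.
#' @return list of class \code{ModelReport}.
#' @export
singleFeatureModel <- function(X, y, feature, nRepeats = 1000L,
                               split = 0.8, seed = 1L) {
  out <- repeatedSplitFit(as.matrix(X), y, feature, nRepeats, split,
                          "linear", seed)
  class(out) <- "ModelReport"
  out
}

#' Predictive power of a feature set
#'
#' As \code{\link{singleFeatureModel}} with several predictors; the
#' \code{"randomForest"} engine reports the same two statistics from a
#' random forest fit.
#'
#' @inheritParams singleFeatureModel
#' @param features character vector of feature names.
#' @param engine "linear" (default) or "randomForest".
#' @export
multiFeatureModel <- function(X, y, features, nRepeats = 1000L,
                              split = 0.8,
                              engine = c("linear", "randomForest"),
                              seed = 1L) {
  engine <- match.arg(engine)
  out <- repeatedSplitFit(as.matrix(X), y, features, nRepeats, split,
                          engine, seed)
  class(out) <- "ModelReport"
  out
}

#' @export
print.ModelReport <- function(x, ...) {
  cat(sprintf("ModelReport (%s, %d features, %d repeats of %.0f/%.0f splits)\n",
              x$engine, length(x$features), x$nRepeats, 100 * x$split,
              100 * (1 - x$split)))
  cat(sprintf("  fraction of variation explained: %.3f +/- %.3f\n",
              x$fractionExplained, x$fractionExplainedSD))
  cat(sprintf("  predicted R^2:                   %.3f +/- %.3f\n",
              x$predictedR2, x$predictedR2SD))
  invisible(x)
}

#' Feature selection by penalized regression
#'
#' Lasso (default): \code{glmnet} with the penalty chosen by 10-fold
#' cross-validation; features with nonzero coefficients at that penalty are
#' returned.  The canonical penalty is the CV-error minimiser
#' (\code{lambdaRule = "min"}), which reliably contains the true support
#' but is known to carry false positives; \code{lambdaRule = "1se"} applies
#' the one-standard-error rule and is far sparser.  Ridge: the ridge fit at
#' the CV-selected penalty with approximate coefficient t-tests on the
#' fit's effective degrees of freedom; features significant at
#' \code{alpha} are returned.
#'
#' @param X genes x features matrix (standardize first).
#' @param y response vector.
#' @param method "lasso" (default) or "ridge".
#' @param lambdaRule "min" (default) or "1se" (lasso only).
#' @param alpha significance level for the ridge coefficient tests.
#' @param nFolds CV folds (default 10).
#' @param seed seed for the CV fold assignment.
#' @return character vector of selected feature names.
#' @export
selectFeatures <- function(X, y, method = c("lasso", "ridge"),
                           lambdaRule = c("min", "1se"),
                           alpha = 0.05, nFolds = 10L, seed = 1L) {
  method <- match.arg(method)
  lambdaRule <- match.arg(lambdaRule)
  X <- as.matrix(X)
  cc <- complete.cases(X) & is.finite(y)
  X <- X[cc, , drop = FALSE]; y <- y[cc]
  n <- nrow(X)
  withSeed(seed, {
    if (method == "lasso") {
      cvfit <- glmnet::cv.glmnet(X, y, alpha = 1, nfolds = nFolds)
      cf <- coef(cvfit, s = paste0("lambda.", lambdaRule))
      sel <- rownames(cf)[as.numeric(cf) != 0]
      setdiff(sel, "(Intercept)")
    } else {
      cvfit <- glmnet::cv.glmnet(X, y, alpha = 0, nfolds = nFolds)
      ## ridge solve at the CV-selected penalty on centred/scaled data;
      ## glmnet's objective 1/(2n)||y-Xb||^2 + lambda/2 ||b||^2 gives
      ## b = (X'X + n lambda I)^{-1} X'y
      Xs <- scale(X); ys <- y - mean(y)
      A <- solve(crossprod(Xs) + diag(cvfit$lambda.min * n, ncol(Xs)))
      b <- A %*% crossprod(Xs, ys)
      H <- Xs %*% A %*% t(Xs)
      edf <- sum(diag(H))
      res <- ys - Xs %*% b
      sigma2 <- sum(res^2) / (n - edf)
      covB <- sigma2 * A %*% crossprod(Xs) %*% A
      tstat <- b / sqrt(diag(covB))
      p <- 2 * stats::pt(-abs(tstat), df = n - edf)
      colnames(X)[p < alpha]
    }
  })
}

#' Bidirectional stepwise refinement by AIC
#'
#' Starting from the intercept-only model, features are added and removed
#' until no single move lowers the AIC (\code{stats::step}, both
#' directions).  Candidates are processed in alphabetical order so the
#' search is deterministic; the AIC of the returned model never exceeds
#' that of the full candidate model.
#'
#' @param X genes x features matrix.
#' @param y response vector.
#' @param candidates candidate feature names (default: all columns).
#' @return character vector: the feature set of the AIC-minimal model
#'   found, with the final model's AIC as attribute \code{"AIC"}.
#' @export
stepwiseAIC <- function(X, y, candidates = colnames(X)) {
  candidates <- sort(candidates)
  df <- data.frame(y = y, as.matrix(X)[, candidates, drop = FALSE],
                   check.names = FALSE)
  df <- df[complete.cases(df), , drop = FALSE]
  upper <- as.formula(paste("~", paste(sprintf("`%s`", candidates),
                                       collapse = " + ")))
  fit0 <- lm(y ~ 1, data = df)
  fit <- step(fit0, scope = list(lower = ~1, upper = upper),
              direction = "both", trace = 0)
  sel <- setdiff(attr(stats::terms(fit), "term.labels"), character(0))
  sel <- gsub("^`|`$", "", sel)
  structure(sel, AIC = AIC(fit))
}

#' Filter features by correlation with noise or by individual impact
#'
#' Correlation mode keeps features whose Pearson correlation with the
#' response is significant (p < \code{alpha}); impact mode keeps features
#' whose single-feature model explains at least \code{minFraction} of the
#' variation OR has predicted R^2 of at least \code{minPredictedR2}
#' (defaults 0.05 and 0.05).
#'
#' @param X genes x features matrix.
#' @param y response vector.
#' @param mode "correlation" or "impact".
#' @param alpha significance level for correlation mode.
#' @param minFraction,minPredictedR2 impact-mode thresholds.
#' @param nRepeats splits per single-feature model in impact mode.
#' @param seed master seed for impact mode.
#' @return character vector of retained feature names.
#' @export
filterFeatures <- function(X, y, mode = c("correlation", "impact"),
                           alpha = 0.05, minFraction = 0.05,
                           minPredictedR2 = 0.05, nRepeats = 100L,
                           seed = 1L) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (mode == "correlation") {
    keep <- vapply(colnames(X), function(f) {
      ok <- is.finite(X[, f]) & is.finite(y)
      suppressWarnings(cor.test(X[ok, f], y[ok])$p.value) < alpha
    }, logical(1))
  } else {
    keep <- vapply(colnames(X), function(f) {
      rep <- singleFeatureModel(X, y, f, nRepeats = nRepeats, seed = seed)
      rep$fractionExplained >= minFraction ||
        rep$predictedR2 >= minPredictedR2
    }, logical(1))
  }
  colnames(X)[keep]
}

#' Rank features by explanatory and predictive power
#'
#' Every feature is scored by \code{\link{singleFeatureModel}} against each
#' supplied response; features are ranked by fraction of variation
#' explained and by predicted R^2, and the rankings obtained on the two
#' responses are compared by Spearman correlation.
#'
#' @param X genes x features matrix.
#' @param y1,y2 two response vectors (e.g. mRNA-level and protein-level
#'   noise).
#' @param nRepeats splits per single-feature model (default 100).
#' @param seed master seed.
#' @return list with \code{scores} (per feature x response), \code{ranks},
#'   and \code{rankCorrelation} (Spearman, one value per metric).
#' @export
rankFeatures <- function(X, y1, y2, nRepeats = 100L, seed = 1L) {
  X <- as.matrix(X)
  score <- function(y) {
    t(vapply(colnames(X), function(f) {
      rep <- singleFeatureModel(X, y, f, nRepeats = nRepeats, seed = seed)
      c(fractionExplained = rep$fractionExplained,
        predictedR2 = rep$predictedR2)
    }, numeric(2)))
  }
  s1 <- score(y1); s2 <- score(y2)
  rk <- function(v) rank(-v, ties.method = "average")
  ranks <- list(
    fractionExplained = cbind(y1 = rk(s1[, 1]), y2 = rk(s2[, 1])),
    predictedR2 = cbind(y1 = rk(s1[, 2]), y2 = rk(s2[, 2])))
  rc <- c(
    fractionExplained = suppressWarnings(
      cor(ranks$fractionExplained[, 1], ranks$fractionExplained[, 2],
          method = "spearman")),
    predictedR2 = suppressWarnings(
      cor(ranks$predictedR2[, 1], ranks$predictedR2[, 2],
          method = "spearman")))
  list(scores = list(y1 = s1, y2 = s2), ranks = ranks,
       rankCorrelation = rc)
}
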