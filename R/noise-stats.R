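## noise_stats: per-gene expression noise (CV), the mean-adjusted noise
## statistic obtained by polynomial detrending of CV against log mean, and
## the 20-bin noise stratification used to contrast low- and high-noise
## genes.

#' Per-gene mean, standard deviation and coefficient of variation
#'
#' @param x a genes x cells matrix, or a \code{SummarizedExperiment} whose
#'   first assay is one.
#' @return data.frame with columns \code{gene}, \code{mean}, \code{sd},
#'   \code{cv} (sample sd / mean, n-1 denominator; NA for zero-mean genes)
#'   and \code{zeroMean} (flag: excluded from trend fitting).
#' @examples
#' m <- rbind(a = c(2, 4), b = c(3, 3))
#' computeCV(m)   # gene a: mean 3, sd sqrt(2), cv 0.4714
#' @export
computeCV <- function(x) {
  if (is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, 1L)
  x <- as.matrix(x)
  if (ncol(x) < 2L)
    stop("degenerate input: need at least 2 cells per gene to compute a CV")
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, sd)
  cv <- ifelse(mu > 0, sdv / mu, NA_real_)
  data.frame(gene = rownames(x) %||% sprintf("gene%04d", seq_len(nrow(x))),
             mean = mu, sd = sdv, cv = cv, zeroMean = mu == 0,
             row.names = NULL)
}

#' Fit the polynomial trend of CV on log mean expression
#'
#' Least-squares polynomials of CV on natural-log mean are fitted for each
#' candidate order and scored by 10-fold cross-validated mean squared
#' error.  The default selection applies the one-standard-error parsimony
#' rule (smallest order whose CV score is within one standard error of the
#' minimum); \code{selection = "min"} takes the arg-min instead.  Orders
#' with fewer than \code{order + 2} points are refused.
#'
#' @param records data.frame from \code{\link{computeCV}} (columns
#'   \code{mean}, \code{cv}); zero-mean / NA-cv genes are dropped.
#' @param orders candidate polynomial orders (default 1:7).
#' @param nFolds cross-validation folds (default 10).
#' @param selection "1se" (default) or "min".
#' @param logCV fit log(CV) instead of CV (off by default; the canonical
#'   statistic detrends untransformed CV).
#' @param seed seed for the fold assignment.
#' @return a \linkS4class{TrendFit}.
#' @export
fitNoiseTrend <- function(records, orders = 1:7, nFolds = 10L,
                          selection = c("1se", "min"), logCV = FALSE,
                          seed = 1L) {
  selection <- match.arg(selection)
  d <- records[is.finite(records$cv) & records$mean > 0, , drop = FALSE]
  d <- data.frame(logMean = log(d$mean),
                  y = if (logCV) log(d$cv) else d$cv)
  n <- nrow(d)
  orders <- orders[orders >= 1L]
  ok <- n >= orders + 2L
  if (!any(ok)) stop("too few genes with defined CV for any candidate order")
  if (!all(ok)) {
    warning("refusing orders with fewer points than parameters: ",
            paste(orders[!ok], collapse = ", "))
    orders <- orders[ok]
  }
  folds <- withSeed(seed, sample(rep_len(seq_len(nFolds), n)))
  scores <- se <- setNames(numeric(length(orders)), orders)
  for (i in seq_along(orders)) {
    o <- orders[i]
    foldMSE <- vapply(seq_len(nFolds), function(f) {
      tr <- d[folds != f, , drop = FALSE]
      te <- d[folds == f, , drop = FALSE]
      fit <- lm(y ~ poly(logMean, degree = o, raw = TRUE), data = tr)
      mean((te$y - predict(fit, newdata = te))^2)
    }, numeric(1))
    scores[i] <- mean(foldMSE)
    se[i] <- sd(foldMSE) / sqrt(nFolds)
  }
  best <- which.min(scores)
  ## epsilon guards the degenerate noiseless case where every adequate
  ## order has numerically-zero CV error
  eps <- 1e-10 * stats::var(d$y)
  pick <- if (selection == "min") best
  else min(which(scores <= scores[best] + se[best] + eps))
  o <- orders[pick]
  fit <- lm(y ~ poly(logMean, degree = o, raw = TRUE), data = d)
  new("TrendFit", order = as.integer(o),
      coefficients = unname(coef(fit)),
      cvScores = scores, cvScoreSE = se, selection = selection, fit = fit)
}

#' Evaluate a fitted trend (optionally with its 95 percent confidence band)
#'
#' @param trend a \linkS4class{TrendFit}.
#' @param logMean natural-log mean expression values at which to evaluate.
#' @param interval if TRUE, return a data.frame with \code{fit},
#'   \code{lwr}, \code{upr} (95 percent confidence band); otherwise the
#'   fitted values.
#' @export
predictTrend <- function(trend, logMean, interval = FALSE) {
  nd <- data.frame(logMean = logMean)
  if (interval)
    as.data.frame(predict(trend@fit, newdata = nd, interval = "confidence",
                          level = 0.95))
  else unname(predict(trend@fit, newdata = nd))
}

#' Mean-adjusted noise: vertical distance of CV from the fitted trend
#'
#' @param records data.frame from \code{\link{computeCV}}.
#' @param trend a \linkS4class{TrendFit}.
#' @return \code{records} with an \code{adjustedNoise} column
#'   (\code{cv - trend(log mean)}; NA where cv is undefined).
#' @export
adjustedNoise <- function(records, trend) {
  adj <- rep(NA_real_, nrow(records))
  okr <- is.finite(records$cv) & records$mean > 0
  adj[okr] <- records$cv[okr] - predictTrend(trend, log(records$mean[okr]))
  records$adjustedNoise <- adj
  records
}

#' Classify genes into equally spaced noise bins
#'
#' Interior bin edges are equally spaced across a central range of the noise
#' values (by default the 2.5th to 97.5th percentiles, which avoids
#' near-empty interior bins); the first and last bins are open-ended below
#' and above so every gene is assigned.
#'
#' @param values numeric noise values (NAs stay NA).
#' @param nBins number of bins (>= 3; default 20).
#' @param probs numeric(2): quantile probabilities bounding the interior
#'   edges.
#' @return integer bin per gene in 1..nBins.
#' @export
binByNoise <- function(values, nBins = 20L, probs = c(0.025, 0.975)) {
  stopifnot(nBins >= 3L)
  v <- values[is.finite(values)]
  q <- quantile(v, probs, names = FALSE)
  if (q[1] == q[2]) {
    warning("all noise values identical: single-bin degenerate result")
    return(ifelse(is.finite(values), 1L, NA_integer_))
  }
  edges <- seq(q[1], q[2], length.out = nBins - 1L)
  out <- findInterval(values, edges, left.open = TRUE) + 1L
  out[!is.finite(values)] <- NA_integer_
  as.integer(out)
}

#' Distance-to-median noise (running-median detrending)
#'
#' Convenience implementation of a DM-style statistic: the vertical distance
#' of each gene's CV from a running median of CV along the mean-expression
#' order, with a window of \code{windowFrac} of the genes.  This is NOT the
#' canonical DM of the protein-noise literature (which this package treats
#' as an externally supplied noise column); it is provided for exploratory
#' use only.
#'
#' @param mean,cv per-gene mean expression and CV.
#' @param windowFrac window size as a fraction of the number of genes.
#' @return numeric DM values aligned with the input order.
#' @export
distanceToMedian <- function(mean, cv, windowFrac = 0.1) {
  ok <- is.finite(cv) & is.finite(mean)
  ord <- order(mean[ok])
  k <- max(3L, floor(sum(ok) * windowFrac))
  if (k %% 2L == 0L) k <- k + 1L
  run <- stats::runmed(cv[ok][ord], k, endrule = "median")
  out <- rep(NA_real_, length(cv))
  idx <- which(ok)[ord]
  out[idx] <- cv[idx] - run
  out
}
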