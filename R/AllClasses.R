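#' SimParams: rate constants and scenario for the telegraph simulator
#'
#' Container for the two-state (telegraph) promoter model.  The promoter
#' switches between an inactive (off) and an active (on) state; off durations
#' are exponential with rate \code{lambdaOn} (mean off time \code{1/lambdaOn})
#' and on durations exponential with rate \code{lambdaOff}.  While active,
#' mRNA is produced at rate \code{betaM} (the burst size per unit time),
#' translated at rate \code{betaP} per mRNA, and both species are removed at
#' first-order rates \code{alphaM} and \code{alphaP}.
#'
#' Four binding scenarios are supported:
#' \describe{
#'   \item{single}{one TF, one telegraph process.}
#'   \item{independent}{\code{kTfs} TFs each with their own telegraph process;
#'     the gene is active when at least one TF is bound and the transcription
#'     rate is the sum of the bound TFs' rates
#'     (\code{multipliers[i] * betaM} each).}
#'   \item{cooperative}{\code{kTfs} TFs; transcription is all-or-none and
#'     occurs at rate \code{betaM} only while every TF is bound.}
#'   \item{competitive}{one shared binding site; at every off-to-on
#'     transition one of \code{kTfs} TFs is chosen uniformly at random and
#'     transcription proceeds at \code{multipliers[chosen] * betaM}.}
#' }
#'
#' @slot lambdaOn,lambdaOff switching rates (1/time).
#' @slot betaM transcription rate while active (mRNA/time).
#' @slot betaP translation rate (protein per mRNA per time).
#' @slot alphaM,alphaP removal rates (1/time).
#' @slot dt integration time step.
#' @slot totalTime simulated horizon per cell.
#' @slot burnIn initial time discarded before pooling statistics.
#' @slot nCells number of simulated cells.
#' @slot scenario one of "single", "independent", "cooperative",
#'   "competitive".
#' @slot kTfs number of TFs (forced to 1 for "single").
#' @slot multipliers per-TF transcription-rate multipliers; they average to 1
#'   for matched-mean comparisons (default c(1.3, 0.7) for competitive k = 2).
#' @slot hillCoefficient cooperative Hill coefficient; transcription is
#'   all-or-none regardless of its value, it is carried for bookkeeping only.
#' @slot initialOn logical; start every TF bound (used for deterministic
#'   always-on limits).
#' @slot swapConvention logical; if TRUE the rate-to-duration convention is
#'   swapped (on durations ~ Exp(lambdaOn)).
#' @slot seed integer seed or NA.
#' @exportClass SimParams
setClass("SimParams", representation(
  lambdaOn = "numeric", lambdaOff = "numeric",
  betaM = "numeric", betaP = "numeric",
  alphaM = "numeric", alphaP = "numeric",
  dt = "numeric", totalTime = "numeric", burnIn = "numeric",
  nCells = "integer", scenario = "character", kTfs = "integer",
  multipliers = "numeric", hillCoefficient = "numeric",
  initialOn = "logical", swapConvention = "logical", seed = "integer"))

setValidity("SimParams", function(object) {
  msg <- character()
  rates <- c(object@lambdaOn, object@lambdaOff, object@betaM, object@betaP,
             object@alphaM, object@alphaP)
  if (any(!is.finite(rates)) || any(rates < 0))
    msg <- c(msg, "all rates must be finite and >= 0")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  amax <- max(object@alphaM, object@alphaP)
  if (amax > 0 && object@dt * amax > 1)
    msg <- c(msg, "unstable time step: dt * max(alphaM, alphaP) > 1")
  if (object@totalTime <= object@burnIn)
    msg <- c(msg, "totalTime must exceed burnIn")
  if (!object@scenario %in% c("single", "independent", "cooperative",
                              "competitive"))
    msg <- c(msg, "unknown scenario")
  if (object@scenario == "single" && object@kTfs != 1L)
    msg <- c(msg, "scenario 'single' requires kTfs = 1")
  if (object@scenario != "single" && object@kTfs < 2L)
    msg <- c(msg, "multi-TF scenarios require kTfs >= 2")
  if (length(object@multipliers) != object@kTfs)
    msg <- c(msg, "multipliers must have length kTfs")
  if (length(msg)) msg else TRUE
})

#' SimResult: population summaries from the telegraph simulator
#'
#' Protein and mRNA levels are pooled across cells and across all retained
#' time points (after burn-in); noise is the coefficient of variation
#' CV = sd/mean of that pool.  Burst frequency is the fraction of retained
#' time the gene spends in the active state, averaged over cells.
#'
#' @slot meanProtein,proteinCV,meanMrna,mrnaCV pooled summaries.
#' @slot burstFrequency fraction in [0, 1].
#' @slot nCells number of cells simulated.
#' @slot perCell per-cell summary data.frame (meanProtein, meanMrna,
#'   activeFraction).
#' @slot params the SimParams used.
#' @exportClass SimResult
setClass("SimResult", representation(
  meanProtein = "numeric", proteinCV = "numeric",
  meanMrna = "numeric", mrnaCV = "numeric",
  burstFrequency = "numeric", nCells = "integer",
  perCell = "data.frame", params = "SimParams"))

#' TrendFit: polynomial trend of CV on log mean expression
#'
#' @slot order selected polynomial order.
#' @slot coefficients coefficients of the selected least-squares polynomial
#'   (intercept first, powers of natural-log mean).
#' @slot cvScores named numeric: 10-fold cross-validated MSE per candidate
#'   order (audit trail for the order selection).
#' @slot cvScoreSE standard errors of the CV scores across folds.
#' @slot selection "1se" or "min" - the selection rule applied.
#' @slot fit the underlying lm fit (used for the 95 percent confidence band).
#' @exportClass TrendFit
setClass("TrendFit", representation(
  order = "integer", coefficients = "numeric",
  cvScores = "numeric", cvScoreSE = "numeric",
  selection = "character", fit = "ANY"))

#' MCMCRun: one greedy parameter-space chain
#'
#' @slot trajectory data.frame with one row per evaluated move: iteration,
#'   parameter, direction, proposal value, achieved mean, accepted flag,
#'   distance to the target midpoint.
#' @slot params terminal SimParams.
#' @slot terminalMean,terminalCV terminal population mean protein and CV.
#' @slot burstFrequency terminal burst frequency.
#' @slot converged logical: terminal mean inside the target window.
#' @slot feasible logical: burst frequency inside the admissible window.
#' @slot iterations number of iterations used.
#' @exportClass MCMCRun
setClass("MCMCRun", representation(
  trajectory = "data.frame", params = "SimParams",
  terminalMean = "numeric", terminalCV = "numeric",
  burstFrequency = "numeric", converged = "logical",
  feasible = "logical", iterations = "integer"))

#' Motif: a TF binding motif as a set of same-length consensus variants
#'
#' A motif is stored as the explicit set of ACGT strings it can match:
#' an IUPAC consensus or a position weight matrix is expanded into all
#' allowed base combinations (see \code{\link{motif}}).
#'
#' @slot tfId transcription factor identifier.
#' @slot variants character vector of equal-length ACGT strings.
#' @exportClass Motif
setClass("Motif", representation(tfId = "character", variants = "character"))

setValidity("Motif", function(object) {
  if (!length(object@variants)) return("motif needs at least one variant")
  w <- unique(nchar(object@variants))
  if (length(w) != 1L) return("all variants must have the same length")
  if (any(grepl("[^ACGT]", object@variants)))
    return("variants must be over {A,C,G,T}")
  TRUE
})

#' @describeIn Motif-class motif length in bp
#' @param x a Motif
#' @export
motifLength <- function(x) nchar(x@variants[1L])

#' @describeIn Motif-class the expanded variant set
#' @export
motifVariants <- function(x) x@variants

setMethod("show", "Motif", function(object) {
  cat("Motif for", object@tfId, "-", length(object@variants),
      "variant(s) of length", motifLength(object), "\n")
  cat("  e.g.", paste(head(object@variants, 3L), collapse = ", "), "\n")
})

setMethod("show", "SimParams", function(object) {
  cat("SimParams:", object@scenario,
      sprintf("(k = %d)\n", object@kTfs))
  cat(sprintf("  lambdaOn %.4g  lambdaOff %.4g  betaM %.4g  betaP %.4g\n",
              object@lambdaOn, object@lambdaOff, object@betaM, object@betaP))
  cat(sprintf("  alphaM %.4g  alphaP %.4g  dt %.4g  totalTime %.4g (burn-in %.4g)\n",
              object@alphaM, object@alphaP, object@dt, object@totalTime,
              object@burnIn))
  cat(sprintf("  cells %d  multipliers %s\n", object@nCells,
              paste(signif(object@multipliers, 3), collapse = "/")))
})

setMethod("show", "SimResult", function(object) {
  cat("SimResult over", object@nCells, "cells\n")
  cat(sprintf("  protein: mean %.4g, CV %.4g\n",
              object@meanProtein, object@proteinCV))
  cat(sprintf("  mRNA:    mean %.4g, CV %.4g\n",
              object@meanMrna, object@mrnaCV))
  cat(sprintf("  burst frequency %.3f\n", object@burstFrequency))
})

setMethod("show", "TrendFit", function(object) {
  cat("TrendFit: polynomial order", object@order,
      sprintf("(selected by %s rule)\n", object@selection))
  cat("  CV MSE per order:",
      paste(sprintf("%s=%.4g", names(object@cvScores), object@cvScores),
            collapse = "  "), "\n")
})

setMethod("show", "MCMCRun", function(object) {
  cat("MCMCRun:", object@iterations, "iterations;",
      if (object@converged) "converged" else "not converged",
      if (object@feasible) "(feasible)" else "(infeasible)", "\n")
  cat(sprintf("  terminal mean %.4g, CV %.4g, burst frequency %.3f\n",
              object@terminalMean, object@terminalCV, object@burstFrequency))
})

## --- accessors -------------------------------------------------------------

#' @rdname SimResult-class
#' @param object a SimResult
#' @export
meanProtein <- function(object) object@meanProtein

#' @rdname SimResult-class
#' @export
proteinCV <- function(object) object@proteinCV

#' @rdname SimResult-class
#' @export
meanMrna <- function(object) object@meanMrna

#' @rdname SimResult-class
#' @export
mrnaCV <- function(object) object@mrnaCV

#' @rdname SimResult-class
#' @export
burstFrequency <- function(object) object@burstFrequency

#' @rdname SimResult-class
#' @export
perCellSummary <- function(object) object@perCell

#' @rdname TrendFit-class
#' @param object a TrendFit
#' @export
trendOrder <- function(object) object@order

#' @rdname TrendFit-class
#' @export
trendCoefficients <- function(object) object@coefficients

#' @rdname TrendFit-class
#' @export
trendCVScores <- function(object) object@cvScores

#' @rdname MCMCRun-class
#' @param object an MCMCRun
#' @export
chainTrajectory <- function(object) object@trajectory

#' @rdname MCMCRun-class
#' @export
isConverged <- function(object) object@converged

#' @rdname MCMCRun-class
#' @export
isFeasible <- function(object) object@feasible
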