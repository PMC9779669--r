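## mcmc_sampler: greedy Monte-Carlo exploration of the telegraph model's
## parameter space toward a target mean protein expression window, used to
## compare noise across binding scenarios at matched means.  The acceptance
## rule is a strict descent on |mean - target midpoint| (the procedure keeps
## the field's "MCMC" name although it does not target a likelihood).

mcmcParNames <- c("lambdaOn", "lambdaOff", "betaM", "betaP",
                  "alphaM", "alphaP")

#' Configuration for the parameter-space sampler
#'
#' @param targetWindow numeric(2): target mean protein window in molecules
#'   (default \code{c(1.0e6, 1.1e6)}).
#' @param bounds named list of numeric(2) lower/upper bounds per parameter
#'   (lambdaOn, lambdaOff, betaM, betaP, alphaM, alphaP).
#' @param stepFactor multiplicative step per move (default 1.1, a 10 percent
#'   change of the perturbed rate).
#' @param initFactor admissible initialisation band: the starting mean must
#'   lie within this factor of the target midpoint (default 5).
#' @param escapeFactor a rejected move whose mean falls outside
#'   \code{[low/escapeFactor, escapeFactor*high]} additionally triggers a
#'   resampling of which parameter to perturb (default 2).
#' @param maxIterations chain cap (default 50).
#' @param cellsPerEval cells per mean/noise evaluation (default 1000).
#' @param burstWindow admissible terminal burst-frequency window
#'   (default \code{c(0.2, 0.8)}).
#' @param kTfs,multiplierSpread multi-TF settings for the competitive /
#'   cooperative scenarios.
#' @param maxInitDraws cap on initialisation rejection draws.
#' @param seed master seed.
#' @return an object of class \code{MCMCConfig}.
#' @export
mcmcConfig <- function(targetWindow = c(1.0e6, 1.1e6),
                       bounds = list(lambdaOn = c(0.1, 10),
                                     lambdaOff = c(0.1, 10),
                                     betaM = c(10, 1000),
                                     betaP = c(5, 500),
                                     alphaM = c(0.5, 8),
                                     alphaP = c(0.05, 2)),
                       stepFactor = 1.1, initFactor = 5, escapeFactor = 2,
                       maxIterations = 50L, cellsPerEval = 1000L,
                       burstWindow = c(0.2, 0.8), kTfs = 2L,
                       multiplierSpread = 0.3, maxInitDraws = 5000L,
                       seed = 1L) {
  stopifnot(length(targetWindow) == 2L, targetWindow[1] < targetWindow[2],
            stepFactor > 1, initFactor > 1, escapeFactor > 1,
            maxIterations >= 1L,
            all(mcmcParNames %in% names(bounds)))
  for (p in mcmcParNames)
    stopifnot(bounds[[p]][1] > 0, bounds[[p]][1] < bounds[[p]][2])
  structure(list(targetWindow = targetWindow, bounds = bounds,
                 stepFactor = stepFactor, initFactor = initFactor,
                 escapeFactor = escapeFactor,
                 maxIterations = as.integer(maxIterations),
                 cellsPerEval = as.integer(cellsPerEval),
                 burstWindow = burstWindow, kTfs = as.integer(kTfs),
                 multiplierSpread = multiplierSpread,
                 maxInitDraws = as.integer(maxInitDraws),
                 seed = as.integer(seed)),
            class = "MCMCConfig")
}

#' @export
print.MCMCConfig <- function(x, ...) {
  cat(sprintf("MCMCConfig: target mean in [%.3g, %.3g], <=%d iterations, %d cells/eval\n",
              x$targetWindow[1], x$targetWindow[2], x$maxIterations,
              x$cellsPerEval))
  invisible(x)
}

## Stationary-state expected mean protein, used only to pre-screen random
## initialisations before confirming with a stochastic simulation.
analyticMeanProtein <- function(theta, scenario, k, multipliers) {
  f <- theta["lambdaOn"] / (theta["lambdaOn"] + theta["lambdaOff"])
  eRate <- switch(scenario,
    single = f * theta["betaM"],
    independent = f * theta["betaM"] * sum(multipliers),
    cooperative = f^k * theta["betaM"],
    competitive = f * theta["betaM"] * mean(multipliers))
  unname(eRate * theta["betaP"] / (theta["alphaM"] * theta["alphaP"]))
}

thetaToParams <- function(theta, scenario, config, nCells, seed) {
  simParams(scenario,
            lambdaOn = theta[["lambdaOn"]], lambdaOff = theta[["lambdaOff"]],
            betaM = theta[["betaM"]], betaP = theta[["betaP"]],
            alphaM = theta[["alphaM"]], alphaP = theta[["alphaP"]],
            kTfs = if (scenario == "single") 1L else config$kTfs,
            multiplierSpread = config$multiplierSpread,
            nCells = nCells, seed = seed)
}

evalTheta <- function(theta, scenario, config, seed) {
  res <- runPopulation(thetaToParams(theta, scenario, config,
                                     config$cellsPerEval, seed))
  list(mean = meanProtein(res), cv = proteinCV(res),
       burst = burstFrequency(res), result = res)
}

#' Initialise a chain inside the admissible band
#'
#' Rejection-samples log-uniform parameter vectors within the configured
#' bounds until the population mean (confirmed on \code{cellsPerEval} cells)
#' lies within \code{initFactor} times the target window, i.e. in
#' \code{[low/initFactor, high*initFactor]}.  A cheap stationary-state
#' formula pre-screens candidates before any simulation is spent on them.
#'
#' @param config an \code{\link{mcmcConfig}}.
#' @param scenario binding scenario.
#' @param seed seed for the draw stream.
#' @return list with \code{theta} (named parameter vector), \code{mean}
#'   (achieved mean), \code{evalSeed}.
#' @export
mcmcInit <- function(config, scenario, seed = config$seed) {
  admLow <- config$targetWindow[1] / config$initFactor
  admHigh <- config$targetWindow[2] * config$initFactor
  mult <- if (scenario == "competitive")
    seq(1 + config$multiplierSpread, 1 - config$multiplierSpread,
        length.out = config$kTfs) else rep(1, config$kTfs)
  k <- if (scenario == "single") 1L else config$kTfs
  seeds <- deriveSeeds(seed, 2L)
  evalSeed <- seeds[2L]
  withSeed(seeds[1L], {
    for (i in seq_len(config$maxInitDraws)) {
      theta <- vapply(mcmcParNames, function(p) {
        b <- config$bounds[[p]]
        exp(runif(1L, log(b[1]), log(b[2])))
      }, numeric(1))
      aMean <- analyticMeanProtein(theta, scenario, k, mult)
      if (aMean > admHigh || aMean < admLow) next
      ev <- evalTheta(theta, scenario, config, evalSeed)
      if (ev$mean <= admHigh && ev$mean >= admLow)
        return(list(theta = theta, mean = ev$mean, evalSeed = evalSeed))
    }
    stop(sprintf(paste0("no admissible initialisation within %d draws: the ",
                        "bounds cannot reach within %gx of the target ",
                        "window [%.3g, %.3g]"),
                 config$maxInitDraws, config$initFactor,
                 config$targetWindow[1], config$targetWindow[2]))
  })
}

#' Run one greedy parameter-space chain
#'
#' At each iteration one parameter is perturbed by the multiplicative step
#' in the current direction.  A move that brings the population mean closer
#' to the target midpoint is accepted and the same parameter/direction is
#' kept for the next move; a rejected move is reverted (and the direction
#' resampled), and if its mean fell outside
#' \code{[low/escapeFactor, escapeFactor*high]} the parameter to perturb is
#' resampled as well.  A move into a bound counts as a rejection without a
#' simulation.  The chain stops when the mean enters the target window or
#' after \code{maxIterations} evaluations.  All mean evaluations within a
#' chain share one RNG stream seed (common random numbers), so the descent
#' criterion compares like with like.
#'
#' @param config an \code{\link{mcmcConfig}}.
#' @param scenario binding scenario.
#' @param seed chain seed (default \code{config$seed}).
#' @return an \linkS4class{MCMCRun}.
#' @export
mcmcRun <- function(config, scenario = c("single", "independent",
                                         "cooperative", "competitive"),
                    seed = config$seed) {
  scenario <- match.arg(scenario)
  lowW <- config$targetWindow[1]; highW <- config$targetWindow[2]
  mid <- mean(config$targetWindow)
  init <- mcmcInit(config, scenario, seed = seed)
  theta <- init$theta
  curMean <- init$mean
  evalSeed <- init$evalSeed
  rngSeed <- deriveSeeds(seed + 1L, 1L)

  rows <- list()
  converged <- curMean >= lowW && curMean <= highW
  it <- 0L
  withSeed(rngSeed, {
    par <- sample(mcmcParNames, 1L)
    dir <- sample(c(-1, 1), 1L)
    while (!converged && it < config$maxIterations) {
      it <- it + 1L
      b <- config$bounds[[par]]
      prop <- theta[[par]] * config$stepFactor^dir
      if (prop < b[1] || prop > b[2]) {
        ## move into a bound: reject without evaluating
        rows[[length(rows) + 1L]] <- data.frame(
          iteration = it, parameter = par, direction = dir,
          value = prop, mean = NA_real_, accepted = FALSE,
          distance = abs(curMean - mid))
        dir <- sample(c(-1, 1), 1L)
        par <- sample(mcmcParNames, 1L)
        next
      }
      cand <- theta
      cand[[par]] <- prop
      ev <- evalTheta(cand, scenario, config, evalSeed)
      accepted <- abs(ev$mean - mid) < abs(curMean - mid)
      rows[[length(rows) + 1L]] <- data.frame(
        iteration = it, parameter = par, direction = dir,
        value = prop, mean = ev$mean, accepted = accepted,
        distance = abs(ev$mean - mid))
      if (accepted) {
        theta <- cand
        curMean <- ev$mean
        converged <- curMean >= lowW && curMean <= highW
        ## keep the same parameter and direction
      } else {
        escape <- ev$mean > highW * config$escapeFactor ||
          ev$mean < lowW / config$escapeFactor
        dir <- sample(c(-1, 1), 1L)
        if (escape) par <- sample(mcmcParNames, 1L)
      }
    }
  })
  terminal <- evalTheta(theta, scenario, config, evalSeed)
  feas <- terminal$burst > config$burstWindow[1] &&
    terminal$burst < config$burstWindow[2]
  traj <- if (length(rows)) do.call(rbind, rows) else
    data.frame(iteration = integer(), parameter = character(),
               direction = numeric(), value = numeric(), mean = numeric(),
               accepted = logical(), distance = numeric())
  new("MCMCRun", trajectory = traj,
      params = thetaToParams(theta, scenario, config, config$cellsPerEval,
                             evalSeed),
      terminalMean = terminal$mean, terminalCV = terminal$cv,
      burstFrequency = terminal$burst, converged = converged,
      feasible = feas, iterations = it)
}

#' Compare terminal noise across scenarios from replicate chains
#'
#' In the default paired mode, each replicate runs one chain on the
#' reference scenario (the first of \code{scenarios}); the other scenarios
#' are then evaluated at that chain's terminal parameter set - the
#' mathematically controlled comparison, with only the binding process
#' differing.  Competitive binding shares the reference mean by
#' construction (its multipliers average 1); cooperative binding has its
#' \code{lambdaOff} reduced by \code{\link{matchMean}} to restore the
#' reference mean, as in the rest of the model.  With
#' \code{paired = FALSE}, fully independent chains are run per scenario
#' instead.  Converged, burst-feasible terminal CVs are compared between
#' each scenario and the reference with a two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test.
#'
#' @param config an \code{\link{mcmcConfig}}; its \code{targetWindow} is
#'   replaced by each entry of \code{windows} in turn.
#' @param scenarios scenarios to compare; the first is the reference.
#' @param nReplicates chains per scenario per window (default 200; the
#'   full-scale analysis uses 10000).
#' @param windows list of numeric(2) target windows (default: the single
#'   window in \code{config}).
#' @param paired evaluate all scenarios on each sampled parameter set
#'   (default TRUE).
#' @return list with \code{replicates} (data.frame over all chains),
#'   \code{medians} (per window x scenario median terminal CV of usable
#'   chains), and \code{tests} (pairwise Mann-Whitney results vs the
#'   reference scenario).
#' @export
mcmcCompareNoise <- function(config,
                             scenarios = c("single", "competitive",
                                           "cooperative"),
                             nReplicates = 200L, windows = NULL,
                             paired = TRUE) {
  if (is.null(windows)) windows <- list(config$targetWindow)
  reps <- if (paired)
    mcmcComparePaired(config, scenarios, nReplicates, windows)
  else mcmcCompareIndependent(config, scenarios, nReplicates, windows)
  usable <- reps[reps$converged & reps$feasible & !is.na(reps$cv), ,
                 drop = FALSE]
  medians <- stats::aggregate(cv ~ window + scenario, data = usable, median)
  tests <- list(); pairedTests <- list()
  refSc <- scenarios[1L]
  for (w in seq_along(windows)) for (sc in scenarios[-1L]) {
    a <- usable$cv[usable$window == w & usable$scenario == sc]
    b <- usable$cv[usable$window == w & usable$scenario == refSc]
    key <- sprintf("w%d:%s_vs_%s", w, sc, refSc)
    tests[[key]] <- if (length(a) >= 2L && length(b) >= 2L)
      suppressWarnings(wilcox.test(a, b))$p.value else NA_real_
    if (paired) {
      ## within-replicate contrast at the shared parameter set
      wr <- reps[reps$window == w, , drop = FALSE]
      d <- merge(wr[wr$scenario == sc, c("replicate", "cv")],
                 wr[wr$scenario == refSc, c("replicate", "cv")],
                 by = "replicate")
      d <- d[stats::complete.cases(d), , drop = FALSE]
      pairedTests[[key]] <- if (nrow(d) >= 2L)
        suppressWarnings(wilcox.test(d$cv.x, d$cv.y,
                                     paired = TRUE))$p.value else NA_real_
    }
  }
  list(replicates = reps, medians = medians, tests = unlist(tests),
       pairedTests = if (paired) unlist(pairedTests) else NULL)
}

## One chain per scenario per replicate (independent sampling).
mcmcCompareIndependent <- function(config, scenarios, nReplicates,
                                   windows) {
  seeds <- deriveSeeds(config$seed,
                       length(windows) * length(scenarios) * nReplicates)
  si <- 0L
  reps <- list()
  for (w in seq_along(windows)) {
    cfg <- config
    cfg$targetWindow <- windows[[w]]
    for (sc in scenarios) for (r in seq_len(nReplicates)) {
      si <- si + 1L
      run <- tryCatch(mcmcRun(cfg, sc, seed = seeds[si]),
                      error = function(e) NULL)
      reps[[length(reps) + 1L]] <- data.frame(
        window = w, scenario = sc, replicate = r,
        converged = if (is.null(run)) FALSE else isConverged(run),
        feasible = if (is.null(run)) FALSE else isFeasible(run),
        mean = if (is.null(run)) NA_real_ else run@terminalMean,
        cv = if (is.null(run)) NA_real_ else run@terminalCV,
        burstFrequency = if (is.null(run)) NA_real_ else run@burstFrequency)
    }
  }
  do.call(rbind, reps)
}

## One reference chain per replicate; every scenario evaluated at the
## sampled terminal parameter set (cooperative lambdaOff recalibrated to
## keep the mean matched).
mcmcComparePaired <- function(config, scenarios, nReplicates, windows) {
  refSc <- scenarios[1L]
  seeds <- deriveSeeds(config$seed, length(windows) * nReplicates)
  si <- 0L
  reps <- list()
  addRow <- function(w, sc, r, conv, feas, mean, cv, bf) {
    reps[[length(reps) + 1L]] <<- data.frame(
      window = w, scenario = sc, replicate = r, converged = conv,
      feasible = feas, mean = mean, cv = cv, burstFrequency = bf)
  }
  for (w in seq_along(windows)) {
    cfg <- config
    cfg$targetWindow <- windows[[w]]
    for (r in seq_len(nReplicates)) {
      si <- si + 1L
      run <- tryCatch(mcmcRun(cfg, refSc, seed = seeds[si]),
                      error = function(e) NULL)
      if (is.null(run) || !isConverged(run)) {
        for (sc in scenarios)
          addRow(w, sc, r, FALSE, FALSE, NA_real_, NA_real_, NA_real_)
        next
      }
      inWin <- function(bf) bf > cfg$burstWindow[1] & bf < cfg$burstWindow[2]
      addRow(w, refSc, r, TRUE, inWin(run@burstFrequency),
             run@terminalMean, run@terminalCV, run@burstFrequency)
      th <- run@params
      for (sc in scenarios[-1L]) {
        p <- simParams(sc, lambdaOn = th@lambdaOn,
                       lambdaOff = th@lambdaOff, betaM = th@betaM,
                       betaP = th@betaP, alphaM = th@alphaM,
                       alphaP = th@alphaP,
                       kTfs = if (sc == "single") 1L else cfg$kTfs,
                       multiplierSpread = cfg$multiplierSpread,
                       nCells = cfg$cellsPerEval, seed = th@seed)
        if (sc == "cooperative") {
          cal <- tryCatch(matchMean(p, run@terminalMean, tol = 0.05),
                          error = function(e) NULL)
          if (is.null(cal)) {
            addRow(w, sc, r, FALSE, FALSE, NA_real_, NA_real_, NA_real_)
            next
          }
          p <- cal$params
        }
        res <- runPopulation(p)
        addRow(w, sc, r, TRUE, inWin(burstFrequency(res)),
               meanProtein(res), proteinCV(res), burstFrequency(res))
      }
    }
  }
  do.call(rbind, reps)
}
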