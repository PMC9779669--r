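## tf_binding_simulator: stochastic two-state (telegraph) model of
## transcription under single / independent / cooperative / competitive TF
## binding.  Switching events are realised at their exact exponential times;
## mRNA and protein follow the forward updates
##   [mRNA]_{t+dt} = [mRNA]_t + (betaM - alphaM*[mRNA]_t) * dt   (while active)
##   [P]_{t+dt}    = [P]_t + (betaP*[mRNA]_t - alphaP*[P]_t) * dt
## with the betaM term time-weighted by the exact fraction of each dt step
## spent transcribing.

#' Construct simulation parameters for the telegraph model
#'
#' See \linkS4class{SimParams} for the meaning of every rate and scenario.
#' Off durations are drawn Exp(\code{lambdaOn}) and on durations
#' Exp(\code{lambdaOff}), giving a stationary active fraction
#' \code{lambdaOn/(lambdaOn+lambdaOff)} for a single TF;
#' \code{swapConvention = TRUE} swaps the two roles.
#'
#' @param scenario binding scenario.
#' @param lambdaOn,lambdaOff,betaM,betaP,alphaM,alphaP model rates (1/time;
#'   betaM in mRNA/time, betaP in protein per mRNA per time).
#' @param kTfs number of TFs (>= 2 for multi-TF scenarios).
#' @param multipliers per-TF transcription-rate multipliers.  Default: all 1,
#'   except competitive binding where they are evenly spaced around 1 with
#'   spread \code{multiplierSpread} (k = 2 gives c(1.3, 0.7)).
#' @param multiplierSpread half-range of the competitive multipliers.
#' @param hillCoefficient cooperative Hill coefficient (bookkeeping only:
#'   transcription is all-or-none regardless of its value).
#' @param nCells population size (default 10000).
#' @param dt integration step; default \code{min(0.05, 0.1/max(alphaM,
#'   alphaP))}.
#' @param burnIn initial transient discarded before pooling; default
#'   \code{max(5/alphaM, 5/alphaP)}.
#' @param totalTime simulation horizon; default \code{burnIn + 25}.
#' @param initialOn start with all TFs bound (deterministic always-on limit
#'   when \code{lambdaOff = 0}).
#' @param swapConvention swap the rate-to-duration convention.
#' @param seed integer seed (NA: use the current RNG state).
#' @return a validated \linkS4class{SimParams}.
#' @examples
#' p <- simParams("single", nCells = 100, seed = 1)
#' runPopulation(p)
#' @export
simParams <- function(scenario = c("single", "independent", "cooperative",
                                   "competitive"),
                      lambdaOn = 1, lambdaOff = 1, betaM = 100, betaP = 50,
                      alphaM = 2, alphaP = 0.1,
                      kTfs = NULL, multipliers = NULL, multiplierSpread = 0.3,
                      hillCoefficient = 2, nCells = 10000,
                      dt = NULL, burnIn = NULL, totalTime = NULL,
                      initialOn = FALSE, swapConvention = FALSE, seed = NA) {
  scenario <- match.arg(scenario)
  if (is.null(kTfs)) kTfs <- if (scenario == "single") 1L else 2L
  kTfs <- as.integer(kTfs)
  if (scenario == "single" && kTfs != 1L)
    stop("scenario 'single' requires kTfs = 1")
  if (is.null(multipliers)) {
    multipliers <- if (scenario == "competitive")
      seq(1 + multiplierSpread, 1 - multiplierSpread, length.out = kTfs)
    else rep(1, kTfs)
  }
  amax <- max(alphaM, alphaP)
  if (is.null(dt)) dt <- if (amax > 0) min(0.05, 0.1 / amax) else 0.05
  if (is.null(burnIn))
    burnIn <- max(if (alphaM > 0) 5 / alphaM else 0,
                  if (alphaP > 0) 5 / alphaP else 0)
  if (is.null(totalTime)) totalTime <- burnIn + 25
  if (lambdaOn == 0 && lambdaOff == 0)
    warning("lambdaOn = lambdaOff = 0: the promoter never switches state")
  new("SimParams", lambdaOn = lambdaOn, lambdaOff = lambdaOff,
      betaM = betaM, betaP = betaP, alphaM = alphaM, alphaP = alphaP,
      dt = dt, totalTime = totalTime, burnIn = burnIn,
      nCells = as.integer(nCells), scenario = scenario, kTfs = kTfs,
      multipliers = as.numeric(multipliers),
      hillCoefficient = hillCoefficient, initialOn = initialOn,
      swapConvention = swapConvention,
      seed = if (is.na(seed)) NA_integer_ else as.integer(seed))
}

scenarioCode <- function(s) match(s, c("single", "independent",
                                       "cooperative", "competitive")) - 1L

#' Simulate the promoter state trajectory of one cell
#'
#' Generates the exact switching-event segments of the telegraph process(es)
#' for a single cell over \code{[0, totalTime]}.  In the independent scenario
#' the gene is active whenever at least one TF is bound and the transcription
#' rate is the sum over bound TFs; cooperative requires all TFs bound;
#' competitive picks one TF uniformly at each off-to-on transition and
#' transcribes at that TF's multiplier times \code{betaM}.
#'
#' @param params a \linkS4class{SimParams} (its \code{nCells} is ignored).
#' @param seed optional seed overriding \code{params@seed}.
#' @return data.frame of constant-state segments with columns \code{start},
#'   \code{end}, \code{nBound}, \code{active}, \code{rate}, \code{boundTf}
#'   (competitive: index of the TF bound during the segment, NA otherwise).
#' @export
simulateStateTrajectory <- function(params, seed = params@seed) {
  stopifnot(is(params, "SimParams"))
  withSeed(if (is.na(seed)) NULL else seed, {
    sc <- params@scenario
    nProc <- if (sc %in% c("independent", "cooperative")) params@kTfs else 1L
    rOff <- if (params@swapConvention) params@lambdaOff else params@lambdaOn
    rOn  <- if (params@swapConvention) params@lambdaOn  else params@lambdaOff
    drawExp <- function(rate) if (rate <= 0) Inf else rexp(1L, rate)
    ## TF choice at on transitions mirrors the C++ engine draw-for-draw
    drawChoice <- function() floor(runif(1L) * params@kTfs) + 1L
    bound <- rep(params@initialOn, nProc)
    nextT <- vapply(seq_len(nProc),
                    function(i) drawExp(if (bound[i]) rOn else rOff),
                    numeric(1))
    choice <- if (sc == "competitive" && params@initialOn)
      drawChoice() else NA_integer_

    segs <- list(); t <- 0; Tend <- params@totalTime
    stateRow <- function(t0, t1) {
      nb <- sum(bound)
      active <- switch(sc,
        single = bound[1L], independent = nb > 0L,
        cooperative = nb == nProc, competitive = bound[1L])
      rate <- switch(sc,
        single = if (active) params@betaM else 0,
        independent = params@betaM * sum(params@multipliers[bound]),
        cooperative = if (active) params@betaM else 0,
        competitive = if (active)
          params@betaM * params@multipliers[choice] else 0)
      data.frame(start = t0, end = t1, nBound = nb, active = active,
                 rate = rate,
                 boundTf = if (sc == "competitive" && active)
                   choice else NA_integer_)
    }
    repeat {
      i <- which.min(nextT)
      tNext <- min(nextT[i], Tend)
      segs[[length(segs) + 1L]] <- stateRow(t, tNext)
      t <- tNext
      if (t >= Tend) break
      if (bound[i]) {
        bound[i] <- FALSE
        nextT[i] <- t + drawExp(rOff)
      } else {
        bound[i] <- TRUE
        nextT[i] <- t + drawExp(rOn)
        if (sc == "competitive") choice <- drawChoice()
      }
    }
    out <- do.call(rbind, segs)
    out[out$end > out$start, , drop = FALSE]
  })
}

#' Integrate mRNA and protein over a state trajectory
#'
#' Applies the forward updates
#' \code{M <- M + (rbar - alphaM*M)*dt} and
#' \code{P <- P + (betaP*M - alphaP*P)*dt}
#' on the dt grid, where \code{rbar} is the transcription rate time-weighted
#' over each step using the exact segment boundaries of \code{trajectory}.
#'
#' @param trajectory a data.frame as returned by
#'   \code{\link{simulateStateTrajectory}}, or any data.frame with columns
#'   \code{start}, \code{end}, \code{rate} (a custom activity schedule).
#' @param params a \linkS4class{SimParams} supplying rates and \code{dt}.
#' @param mrna0,protein0 initial conditions.
#' @return data.frame with columns \code{time}, \code{mrna}, \code{protein}.
#' @export
integrateExpression <- function(trajectory, params, mrna0 = 0, protein0 = 0) {
  dt <- params@dt
  if (dt * max(params@alphaM, params@alphaP) > 1)
    stop("unstable time step: dt * max(alphaM, alphaP) > 1")
  Tend <- max(trajectory$end)
  n <- ceiling(Tend / dt)
  grid <- seq(0, by = dt, length.out = n + 1L)
  ## piecewise-linear cumulative integral of the rate over time
  knots <- c(trajectory$start[1L], trajectory$end)
  cumRate <- c(0, cumsum(trajectory$rate *
                         (trajectory$end - trajectory$start)))
  Rg <- approx(knots, cumRate, xout = pmin(grid, Tend), rule = 2)$y
  rbar <- diff(Rg) / dt
  M <- numeric(n + 1L); P <- numeric(n + 1L)
  M[1L] <- mrna0; P[1L] <- protein0
  for (j in seq_len(n)) {
    P[j + 1L] <- P[j] + (params@betaP * M[j] - params@alphaP * P[j]) * dt
    M[j + 1L] <- M[j] + (rbar[j] - params@alphaM * M[j]) * dt
  }
  data.frame(time = grid, mrna = M, protein = P)
}

#' Run a population simulation
#'
#' Simulates \code{nCells} independent cells and pools protein (and mRNA)
#' values across cells and across all retained time points (those after the
#' burn-in).  Noise is reported as CV = sd/mean of the pooled values; burst
#' frequency is the fraction of retained time spent in the active state,
#' averaged over cells.
#'
#' @param params a \linkS4class{SimParams}.
#' @param engine "cpp" (default) or "R" (pure-R reference implementation of
#'   the same semantics; much slower, intended for cross-checks).
#' @return a \linkS4class{SimResult}.
#' @export
runPopulation <- function(params, engine = c("cpp", "R")) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  engine <- match.arg(engine)
  raw <- withSeed(if (is.na(params@seed)) NULL else params@seed, {
    if (engine == "cpp") {
      cppRunPopulation(params@nCells, scenarioCode(params@scenario),
                       params@kTfs, params@lambdaOn, params@lambdaOff,
                       params@betaM, params@betaP, params@alphaM,
                       params@alphaP, params@multipliers, params@dt,
                       params@totalTime, params@burnIn, params@initialOn,
                       params@swapConvention)
    } else {
      runPopulationRawR(params)
    }
  })
  nObs <- raw$nObs[1L]
  if (nObs < 1L) stop("no retained time points: totalTime <= burnIn")
  N <- sum(raw$nObs)
  meanP <- sum(raw$sumP) / N
  varP <- sum(raw$sumP2) / N - meanP^2
  meanM <- sum(raw$sumM) / N
  varM <- sum(raw$sumM2) / N - meanM^2
  cvP <- if (meanP > 0) sqrt(max(varP, 0)) / meanP else {
    warning("mean protein level is 0; CV undefined"); NA_real_
  }
  cvM <- if (meanM > 0) sqrt(max(varM, 0)) / meanM else NA_real_
  retained <- nObs * params@dt
  perCell <- data.frame(
    meanProtein = raw$sumP / raw$nObs,
    meanMrna = raw$sumM / raw$nObs,
    activeFraction = raw$activeTime / retained,
    sumP = raw$sumP, sumP2 = raw$sumP2, nObs = raw$nObs)
  new("SimResult", meanProtein = meanP, proteinCV = cvP,
      meanMrna = meanM, mrnaCV = cvM,
      burstFrequency = mean(perCell$activeFraction),
      nCells = params@nCells, perCell = perCell, params = params)
}

## Pure-R reference engine: one cell at a time through the exported
## trajectory + integrator path, accumulating the same sufficient statistics
## as the C++ engine.
runPopulationRawR <- function(params) {
  nObs <- integer(params@nCells)
  sumP <- sumP2 <- sumM <- sumM2 <- activeTime <- numeric(params@nCells)
  for (c in seq_len(params@nCells)) {
    traj <- simulateStateTrajectory(params, seed = NA)
    ts <- integrateExpression(traj, params)
    keep <- ts$time > params@burnIn + 1e-12
    keep[1L] <- FALSE      # t = 0 is an initial condition, not an update
    P <- ts$protein[keep]; M <- ts$mrna[keep]
    nObs[c] <- length(P)
    sumP[c] <- sum(P); sumP2[c] <- sum(P^2)
    sumM[c] <- sum(M); sumM2[c] <- sum(M^2)
    act <- traj[traj$active, , drop = FALSE]
    if (nrow(act)) {
      s <- pmax(act$start, params@burnIn)
      activeTime[c] <- sum(pmax(act$end - s, 0))
    }
  }
  list(sumP = sumP, sumP2 = sumP2, sumM = sumM, sumM2 = sumM2,
       activeTime = activeTime, nObs = nObs)
}

#' Monte-Carlo standard error of the pooled protein CV
#'
#' Cells are split (in order) into \code{nGroups} batches; the pooled CV is
#' recomputed per batch and the batch-to-batch spread gives the standard
#' error of the full-population CV.
#'
#' @param result a \linkS4class{SimResult}.
#' @param nGroups number of batches (default 20).
#' @return the estimated standard error (numeric).
#' @export
proteinCVSE <- function(result, nGroups = 20L) {
  pc <- result@perCell
  g <- cut(seq_len(nrow(pc)), breaks = nGroups, labels = FALSE)
  cvs <- vapply(split(pc, g), function(d) {
    N <- sum(d$nObs); m <- sum(d$sumP) / N
    v <- sum(d$sumP2) / N - m^2
    if (m > 0) sqrt(max(v, 0)) / m else NA_real_
  }, numeric(1))
  stats::sd(cvs, na.rm = TRUE) / sqrt(sum(!is.na(cvs)))
}

#' Calibrate lambdaOff to match a reference mean protein level
#'
#' Reducing \code{lambdaOff} prolongs the on state and raises the mean;
#' this performs a monotone bisection on \code{lambdaOff} in
#' \code{[0, params@lambdaOff]} until the population mean protein is within
#' \code{tol} (relative) of \code{referenceMean}.  Used to hold the mean
#' fixed when comparing cooperative binding (whose burst frequency drops
#' with the number of TFs) against single-TF regulation.
#'
#' @param params scenario parameters to calibrate.
#' @param referenceMean target mean protein level.
#' @param tol relative tolerance (default 0.02).
#' @param maxIter bisection iterations (default 30).
#' @param nCells cells per evaluation (default \code{params@nCells}).
#' @return list with \code{params} (calibrated), \code{achievedMean},
#'   \code{lambdaOff}.
#' @export
matchMean <- function(params, referenceMean, tol = 0.02, maxIter = 30L,
                      nCells = params@nCells) {
  evalMean <- function(lo) {
    p <- params
    p@lambdaOff <- lo
    p@nCells <- as.integer(nCells)
    meanProtein(runPopulation(p))
  }
  hi <- params@lambdaOff              # largest lambdaOff considered
  mAtZero <- evalMean(0)
  if (mAtZero < referenceMean * (1 - tol))
    stop(sprintf(paste0("target mean %.4g unreachable: even lambdaOff = 0 ",
                        "gives mean %.4g"), referenceMean, mAtZero))
  loB <- 0; hiB <- hi
  m <- evalMean(hiB)
  if (m >= referenceMean * (1 - tol) && m <= referenceMean * (1 + tol)) {
    params@lambdaOff <- hiB
    return(list(params = params, achievedMean = m, lambdaOff = hiB))
  }
  best <- c(lo = hiB, mean = m)
  for (i in seq_len(maxIter)) {
    mid <- (loB + hiB) / 2
    m <- evalMean(mid)
    if (abs(m - referenceMean) < abs(best["mean"] - referenceMean))
      best <- c(lo = mid, mean = m)
    if (m >= referenceMean * (1 - tol) && m <= referenceMean * (1 + tol))
      break
    if (m > referenceMean) loB <- mid else hiB <- mid
  }
  params@lambdaOff <- unname(best["lo"])
  list(params = params, achievedMean = unname(best["mean"]),
       lambdaOff = unname(best["lo"]))
}

#' Compare expression noise across TF-binding scenarios
#'
#' Runs the population simulator under shared base rates for each requested
#' scenario, following the concentration conventions of the model: every
#' scenario keeps the single-TF \code{lambdaOn} (each cooperative TF has the
#' single-TF concentration; the competitive TFs' concentrations sum to it),
#' and \code{betaP, alphaM, alphaP} are identical throughout.  With
#' \code{matched = TRUE} the cooperative \code{lambdaOff} is calibrated by
#' \code{\link{matchMean}} so all comparisons are made at a similar mean
#' protein level.
#'
#' @param base a \linkS4class{SimParams} describing the single-TF reference.
#' @param scenarios character vector of scenarios to compare.
#' @param kTfs number of TFs for the multi-TF scenarios (default 2).
#' @param matched calibrate cooperative lambdaOff to the single-TF mean.
#' @param multiplierSpread competitive multiplier spread (default 0.3).
#' @param seed master seed; per-scenario seeds are derived from it.
#' @return data.frame with one row per scenario: \code{scenario},
#'   \code{meanProtein}, \code{proteinCV}, \code{cvSE},
#'   \code{burstFrequency}.
#' @export
compareScenarios <- function(base,
                             scenarios = c("single", "independent",
                                           "cooperative", "competitive"),
                             kTfs = 2L, matched = TRUE,
                             multiplierSpread = 0.3, seed = base@seed) {
  seeds <- deriveSeeds(if (is.na(seed)) 1L else seed,
                       length(scenarios) + 1L)
  mkParams <- function(sc, i) {
    simParams(sc, lambdaOn = base@lambdaOn, lambdaOff = base@lambdaOff,
              betaM = base@betaM, betaP = base@betaP, alphaM = base@alphaM,
              alphaP = base@alphaP,
              kTfs = if (sc == "single") 1L else as.integer(kTfs),
              multiplierSpread = multiplierSpread,
              nCells = base@nCells, dt = base@dt, burnIn = base@burnIn,
              totalTime = base@totalTime, seed = seeds[i])
  }
  ref <- if (matched && "cooperative" %in% scenarios)
    meanProtein(runPopulation(mkParams("single", length(scenarios) + 1L)))
  else NULL
  rows <- lapply(seq_along(scenarios), function(i) {
    sc <- scenarios[i]
    p <- mkParams(sc, i)
    if (sc == "cooperative" && !is.null(ref))
      p <- matchMean(p, ref, tol = 0.02)$params
    res <- runPopulation(p)
    data.frame(scenario = sc, meanProtein = meanProtein(res),
               proteinCV = proteinCV(res), cvSE = proteinCVSE(res),
               burstFrequency = burstFrequency(res))
  })
  do.call(rbind, rows)
}
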