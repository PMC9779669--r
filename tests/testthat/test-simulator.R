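fastParams <- function(...) simParams(..., nCells = 200, seed = 17)

test_that("parameter validation catches unstable and inconsistent settings", {
  expect_error(simParams("single", lambdaOn = -1), "finite")
  expect_error(simParams("single", alphaM = 10, dt = 0.5), "unstable")
  expect_error(simParams("single", kTfs = 2), "kTfs = 1")
  expect_error(simParams("cooperative", kTfs = 1), "kTfs >= 2")
  expect_warning(simParams("single", lambdaOn = 0, lambdaOff = 0),
                 "never switches")
})

test_that("active fraction matches the renewal closed form", {
  for (rates in list(c(1, 1), c(0.5, 2), c(3, 0.7))) {
    p <- simParams("single", lambdaOn = rates[1], lambdaOff = rates[2],
                   nCells = 400, seed = 23)
    r <- runPopulation(p)
    f <- rates[1] / sum(rates)
    se <- sd(perCellSummary(r)$activeFraction) / sqrt(400)
    expect_lt(abs(burstFrequency(r) - f), 4 * se + 1e-6)
  }
})

test_that("swapping the rate convention mirrors the active fraction", {
  p <- simParams("single", lambdaOn = 3, lambdaOff = 1, nCells = 300,
                 swapConvention = TRUE, seed = 29)
  r <- runPopulation(p)
  expect_lt(abs(burstFrequency(r) - 0.25), 0.02)
})

test_that("the always-on limit reaches the deterministic steady state", {
  p <- suppressWarnings(
    simParams("single", lambdaOn = 0, lambdaOff = 0, alphaM = 2,
              alphaP = 0.5, dt = 0.005, nCells = 1, initialOn = TRUE,
              totalTime = 50, burnIn = 30, seed = 1))
  r <- suppressWarnings(runPopulation(p))
  expect_equal(meanMrna(r), p@betaM / p@alphaM, tolerance = 0.01)
  expect_equal(meanProtein(r),
               p@betaM * p@betaP / (p@alphaM * p@alphaP), tolerance = 0.01)
  ## never-active: everything decays to zero
  p0 <- suppressWarnings(
    simParams("single", lambdaOn = 0, lambdaOff = 0, nCells = 1,
              totalTime = 60, burnIn = 50, seed = 1))
  r0 <- suppressWarnings(runPopulation(p0))
  expect_identical(meanMrna(r0), 0)
  expect_true(is.na(proteinCV(r0)))
})

test_that("a single transcription pulse reproduces the linear-system peak", {
  p <- simParams("single", betaM = 100, alphaM = 2, dt = 0.001,
                 totalTime = 10, burnIn = 0, nCells = 1)
  tau <- 1.5
  traj <- data.frame(start = c(0, tau), end = c(tau, 10),
                     rate = c(p@betaM, 0))
  ts <- integrateExpression(traj, p)
  peak <- max(ts$mrna)
  closed <- (p@betaM / p@alphaM) * (1 - exp(-p@alphaM * tau))
  expect_equal(peak, closed, tolerance = 0.005)
})

test_that("the R reference engine reproduces the C++ engine exactly", {
  for (sc in c("single", "independent", "cooperative", "competitive")) {
    p <- simParams(sc, kTfs = if (sc == "single") 1L else 3L,
                   nCells = 25, totalTime = 55, seed = 41)
    rc <- runPopulation(p, engine = "cpp")
    rr <- runPopulation(p, engine = "R")
    expect_equal(meanProtein(rc), meanProtein(rr), tolerance = 1e-10)
    expect_equal(proteinCV(rc), proteinCV(rr), tolerance = 1e-10)
    expect_equal(burstFrequency(rc), burstFrequency(rr), tolerance = 1e-6)
  }
})

test_that("populations are seed-deterministic with distinct cell streams", {
  p <- fastParams("single")
  a <- runPopulation(p); b <- runPopulation(p)
  expect_identical(perCellSummary(a), perCellSummary(b))
  expect_gt(sd(perCellSummary(a)$meanProtein), 0)
  p2 <- simParams("single", nCells = 200, seed = 18)
  expect_false(identical(perCellSummary(runPopulation(p2)),
                         perCellSummary(a)))
})

test_that("faster switching at a fixed on/off ratio lowers the noise", {
  slow <- simParams("single", lambdaOn = 0.2, lambdaOff = 0.2,
                    nCells = 500, seed = 3)
  fast <- simParams("single", lambdaOn = 2, lambdaOff = 2,
                    nCells = 500, seed = 4)
  expect_gt(proteinCV(runPopulation(slow)),
            proteinCV(runPopulation(fast)) + 0.02)
})

test_that("competitive binding picks each TF uniformly at on transitions", {
  p <- simParams("competitive", kTfs = 2, totalTime = 3000, nCells = 1,
                 seed = 47)
  traj <- simulateStateTrajectory(p)
  picks <- traj$boundTf[traj$active]
  frac <- mean(picks == 1)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / length(picks)) + 0.02)
})

test_that("cooperative mean drops with TF number and lambdaOff rescues it", {
  ref <- meanProtein(runPopulation(simParams("single", nCells = 500,
                                             seed = 51)))
  means <- vapply(2:4, function(k)
    meanProtein(runPopulation(simParams("cooperative", kTfs = k,
                                        nCells = 500, seed = 50 + k))),
    numeric(1))
  expect_true(all(diff(means) < 0))
  expect_true(all(means < ref))
  cal <- matchMean(simParams("cooperative", kTfs = 2, nCells = 500,
                             seed = 60), ref, tol = 0.03)
  expect_lt(cal$lambdaOff, 1)                      # compensates downward
  expect_lt(abs(cal$achievedMean - ref) / ref, 0.05)
  ## larger k needs a smaller lambdaOff
  cal3 <- matchMean(simParams("cooperative", kTfs = 3, nCells = 500,
                              seed = 61), ref, tol = 0.03)
  expect_lt(cal3$lambdaOff, cal$lambdaOff)
})

test_that("unreachable calibration targets fail with an informative error", {
  p <- simParams("cooperative", kTfs = 2, nCells = 100, seed = 5)
  expect_error(matchMean(p, 1e9), "unreachable")
})

test_that("wider competitive multiplier spread increases noise", {
  narrow <- simParams("competitive", kTfs = 2, multipliers = c(1, 1),
                      nCells = 800, seed = 71)
  wide <- simParams("competitive", kTfs = 2, multipliers = c(1.6, 0.4),
                    nCells = 800, seed = 72)
  rn <- runPopulation(narrow); rw <- runPopulation(wide)
  expect_equal(meanProtein(rn), meanProtein(rw), tolerance = 0.1)
  expect_gt(proteinCV(rw),
            proteinCV(rn) + 2 * sqrt(proteinCVSE(rn)^2 + proteinCVSE(rw)^2))
})

test_that("scenario noise orderings hold across one-at-a-time rate sweeps", {
  ## S1-Text-style robustness: vary each rate over 3 values, keep the rest
  ## at baseline, and check competitive > single and independent < single
  grid <- list(lambdaOn = c(0.5, 1, 2), betaM = c(50, 100, 200),
               alphaP = c(0.05, 0.1, 0.2))
  for (par in names(grid)) for (v in grid[[par]]) {
    args <- list(scenario = "single", nCells = 300, seed = 81)
    args[[par]] <- v
    base <- do.call(simParams, args)
    tab <- compareScenarios(base, scenarios = c("single", "independent",
                                                "competitive"),
                            matched = FALSE, seed = 81)
    cvs <- setNames(tab$proteinCV, tab$scenario)
    expect_gt(cvs["competitive"], cvs["single"] - 0.01)
    expect_lt(cvs["independent"], cvs["single"])
  }
})
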