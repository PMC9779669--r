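test_that("expression generator is a pure function of its seed", {
  a <- simExpressionMatrix(nGenes = 40, nCells = 30, seed = 11)
  b <- simExpressionMatrix(nGenes = 40, nCells = 30, seed = 11)
  d <- simExpressionMatrix(nGenes = 40, nCells = 30, seed = 12)
  expect_identical(SummarizedExperiment::assay(a),
                   SummarizedExperiment::assay(b))
  expect_false(identical(SummarizedExperiment::assay(a),
                         SummarizedExperiment::assay(d)))
})

test_that("planted excess noise appears as a CV difference at large n", {
  ## two genes with identical means, excess (0, +0.3): realized CVs differ
  ## by ~0.3 once sampling error is negligible
  tc <- c(0.6, 0, 0, 0, 0, 0)     # flat baseline CV 0.6
  se <- simExpressionMatrix(nGenes = 2, nCells = 50000,
                            trendCoefficients = tc,
                            excessNoise = c(0, 0.3),
                            meanRange = c(49.99, 50.01), seed = 5)
  cvs <- computeCV(se)$cv
  expect_equal(cvs[2] - cvs[1], 0.3, tolerance = 0.05)
  expect_equal(cvs[1], 0.6, tolerance = 0.02)
})

test_that("invalid expression specs are rejected", {
  expect_error(simExpressionMatrix(nGenes = 0), "positive")
  expect_error(simExpressionMatrix(nGenes = 10, nCells = -1), "positive")
  ## target CV below the Poisson floor
  expect_error(simExpressionMatrix(nGenes = 5, nCells = 10,
                                   trendCoefficients = c(0.05, 0, 0, 0, 0, 0),
                                   excessNoise = rep(0, 5),
                                   meanRange = c(5, 10), seed = 1),
               "Poisson floor")
})

test_that("promoter generator plants recoverable sites and is reproducible", {
  m <- motif("REB1", "TTACCCGG")
  plant <- data.frame(promoter = 1, motif = "REB1", start = 200,
                      strand = "+", nMismatches = 0)
  ps <- simPromoters(nPromoters = 2, motifs = list(m), plantedSites = plant,
                     seed = 3)
  hits <- scanMotif(ps$promoters[[1]], m, maxMismatch = 0)
  expect_true(any(GenomicRanges::start(hits) == 201 &
                  GenomicRanges::end(hits) == 208))
  ## byte-identical FASTA on rerun with the same seed
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(ps$promoters, f1, width = 60)
  ps2 <- simPromoters(nPromoters = 2, motifs = list(m), plantedSites = plant,
                      seed = 3)
  Biostrings::writeXStringSet(ps2$promoters, f2, width = 60)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("overlapping planted sites are allowed and yield a known overlap", {
  m1 <- motif("TFA", "AAAAAA"); m2 <- motif("TFB", "CCCCCC")
  plant <- data.frame(promoter = 1, motif = c("TFA", "TFB"),
                      start = c(10, 13), strand = "+", nMismatches = 0)
  ps <- simPromoters(nPromoters = 1, motifs = list(m1, m2),
                     plantedSites = plant, seed = 1)
  st <- siteOverlapStats(ps$sites)
  expect_identical(st$nOverlappingPairs, 1L)
  expect_equal(st$meanOverlapLength, 3)
})

test_that("promoter background composition follows the requested GC", {
  ps <- simPromoters(nPromoters = 30, promoterLength = 1000,
                     backgroundGC = 0.38, seed = 9)
  freq <- Biostrings::alphabetFrequency(ps$promoters, as.prob = TRUE)
  gc <- mean(rowSums(freq[, c("C", "G")]))
  expect_equal(gc, 0.38, tolerance = 0.01)
})

test_that("feature-table generator controls the population R2", {
  ft <- simFeatureTable(nGenes = 3000, nFeatures = 20, populationR2 = 0.4,
                        seed = 2)
  expect_equal(ft$populationR2, 0.4, tolerance = 1e-12)
  realized <- summary(lm(ft$response ~ ft$X))$r.squared
  expect_lt(abs(realized - 0.4), 0.04)
  ## noiseless limit
  ft0 <- simFeatureTable(nGenes = 100, nFeatures = 5, noiseSd = 0, seed = 2)
  r2perfect <- suppressWarnings(summary(lm(ft0$response ~ ft0$X))$r.squared)
  expect_equal(r2perfect, 1)
  ## correlated features keep the implied R2 formula consistent
  ftc <- simFeatureTable(nGenes = 5000, nFeatures = 10,
                         featureCorrelation = 0.5, populationR2 = 0.3,
                         seed = 4)
  expect_lt(abs(summary(lm(ftc$response ~ ftc$X))$r.squared - 0.3), 0.04)
})

test_that("coexpression panel plants exact slopes in the noiseless limit", {
  pan <- simCoexpressionPanel(40, c(ACT1 = 1), residSd = 0, seed = 1)
  est <- geneTfRegulation(pan, "gene", "ACT1")
  expect_identical(est$role, "activator")
  expect_equal(est$slope, 1, tolerance = 1e-10)
})

test_that("ground-truth tables round-trip through the TSV writer/reader", {
  df <- data.frame(gene = c("g1", "g2"), mean = c(3.141592653589793, 2e-8),
                   bin = c(1L, 20L))
  f <- tempfile(fileext = ".tsv")
  writeTSV(df, f)
  back <- readTSV(f)
  expect_equal(back$mean, df$mean, tolerance = 1e-15)
  expect_identical(back$gene, df$gene)
  expect_equal(back$bin, df$bin)
})
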