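## synthetic_data: generators for every input the analysis modules consume,
## with known ground truth.  They emulate the statistical structure of the
## study's external datasets (a mean-CV trend with gene-specific excess
## noise, promoters with planted motif instances, TF-target co-expression
## with planted slopes, feature tables with a sparse linear effect) without
## claiming to reproduce any real genome or read-level artefacts.

#' Default CV-vs-log-mean trend polynomial
#'
#' A genuinely order-5 polynomial over \code{log(meanRange)}: a smooth
#' decreasing quadratic baseline (CV falls with expression, as in single-cell
#' data) plus a degree-5 Chebyshev wiggle of amplitude \code{wiggle} whose
#' best order-4 approximation error is exactly \code{wiggle} - so order
#' selection on data generated from it has a well-defined answer.
#'
#' @param meanRange numeric(2) range of true mean expression.
#' @param wiggle amplitude of the degree-5 component (default 0.04 CV units).
#' @return numeric(6): coefficients of the polynomial in natural-log mean
#'   (intercept first).
#' @export
defaultNoiseTrend <- function(meanRange = c(5, 150), wiggle = 0.04) {
  a <- log(meanRange[1]); b <- log(meanRange[2])
  f <- function(x) {
    u <- (2 * x - a - b) / (b - a)
    0.62 - 0.25 * u + 0.08 * u^2 + wiggle * (16 * u^5 - 20 * u^3 + 5 * u)
  }
  ## recover power-basis coefficients exactly from 6 evaluation points
  xs <- seq(a, b, length.out = 6L)
  V <- outer(xs, 0:5, `^`)
  as.numeric(solve(V, f(xs)))
}

polyEval <- function(coefs, x) {
  drop(outer(x, seq_along(coefs) - 1L, `^`) %*% coefs)
}

#' Generate a synthetic single-cell expression matrix with planted noise
#'
#' Gene counts are negative binomial with gene-specific dispersion chosen so
#' that the true CV of gene g equals \code{trend(log mean_g) + excess_g}:
#' for the NB, CV^2 = 1/mu + dispersion, so dispersion = targetCV^2 - 1/mu
#' (a target CV below the Poisson floor \code{1/sqrt(mu)} is an error).
#' True means are log-uniform over \code{meanRange}.
#'
#' @param nGenes,nCells matrix dimensions (the study's single-cell dataset
#'   had 127 cells, the default here).
#' @param trendCoefficients polynomial (in natural-log mean) giving the
#'   baseline CV; default \code{\link{defaultNoiseTrend}(meanRange)}.
#' @param excessNoise per-gene planted mean-adjusted noise (CV units);
#'   default: 0 for 80 percent of genes, Uniform(0.1, 0.4) for the rest.
#' @param meanRange range of true mean expression (counts).
#' @param seed integer seed.
#' @return a \code{SummarizedExperiment} with assay \code{counts} and
#'   rowData columns \code{trueMean}, \code{trendCV}, \code{trueExcess},
#'   \code{trueCV}.
#' @examples
#' se <- simExpressionMatrix(nGenes = 50, nCells = 60, seed = 1)
#' head(SummarizedExperiment::rowData(se))
#' @export
simExpressionMatrix <- function(nGenes = 5000, nCells = 127,
                                trendCoefficients = NULL,
                                excessNoise = NULL,
                                meanRange = c(5, 150), seed = 1L) {
  if (nGenes < 1 || nCells < 1)
    stop("invalid spec: nGenes and nCells must be positive")
  if (meanRange[1] <= 0 || meanRange[1] >= meanRange[2])
    stop("invalid spec: meanRange must be a positive increasing interval")
  if (is.null(trendCoefficients))
    trendCoefficients <- defaultNoiseTrend(meanRange)
  grid <- seq(log(meanRange[1]), log(meanRange[2]), length.out = 101L)
  if (any(polyEval(trendCoefficients, grid) <= 0))
    stop("invalid spec: baseline CV trend must be positive over meanRange")
  withSeed(seed, {
    mu <- exp(runif(nGenes, log(meanRange[1]), log(meanRange[2])))
    if (is.null(excessNoise)) {
      excessNoise <- numeric(nGenes)
      hi <- runif(nGenes) < 0.2
      excessNoise[hi] <- runif(sum(hi), 0.1, 0.4)
    }
    if (length(excessNoise) != nGenes || any(!is.finite(excessNoise)))
      stop("invalid spec: excessNoise must be a finite vector of length nGenes")
    trendCV <- polyEval(trendCoefficients, log(mu))
    targetCV <- trendCV + excessNoise
    disp <- targetCV^2 - 1 / mu
    if (any(disp < -1e-12))
      stop("invalid spec: target CV below the Poisson floor 1/sqrt(mean)")
    disp <- pmax(disp, 0)
    counts <- matrix(0L, nGenes, nCells,
                     dimnames = list(sprintf("gene%04d", seq_len(nGenes)),
                                     sprintf("cell%03d", seq_len(nCells))))
    for (g in seq_len(nGenes)) {
      counts[g, ] <- if (disp[g] > 0)
        rnbinom(nCells, mu = mu[g], size = 1 / disp[g])
      else rpois(nCells, mu[g])
    }
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      rowData = S4Vectors::DataFrame(trueMean = mu, trendCV = trendCV,
                                     trueExcess = excessNoise,
                                     trueCV = targetCV))
  })
}

#' Generate synthetic promoters with planted motif sites
#'
#' Background sequence is i.i.d. with the stated GC content.  Planted sites
#' take the motif's first consensus variant, mutate \code{nMismatches}
#' random positions, reverse-complement it for minus-strand sites, and write
#' it at the requested offset.  Overlapping planted sites are allowed (they
#' are needed to exercise the overlap counters); when they conflict, later
#' rows of \code{plantedSites} overwrite earlier ones.
#'
#' Coordinates in \code{plantedSites$start} and in the returned ground truth
#' are 0-based half-open offsets on the forward strand of the promoter,
#' where offset 0 is position -1000 relative to the start codon and offset
#' 1000 is +1 (the first base of ATG); see \code{\link{toPaperCoord}}.
#'
#' @param nPromoters number of promoters.
#' @param promoterLength promoter length in bp (default 1010 = -1000..+10).
#' @param motifs list of \linkS4class{Motif} objects (or a named character
#'   vector of IUPAC consensus strings, expanded via \code{\link{motif}}).
#' @param plantedSites data.frame with columns \code{promoter} (index),
#'   \code{motif} (name or index), \code{start} (0-based offset),
#'   \code{strand} ("+"/"-"), \code{nMismatches}; NULL for none.
#' @param backgroundGC background GC fraction (default 0.38, budding-yeast
#'   like).
#' @param seed integer seed.
#' @return list with \code{promoters} (a named \code{DNAStringSet}) and
#'   \code{sites} (a \code{GRanges} of planted sites, 1-based closed as
#'   usual for GRanges, with mcols \code{tf}, \code{nMismatches},
#'   \code{planted} sequence).
#' @export
simPromoters <- function(nPromoters = 100, promoterLength = 1010,
                         motifs = list(), plantedSites = NULL,
                         backgroundGC = 0.38, seed = 1L) {
  if (nPromoters < 1 || promoterLength < 1)
    stop("invalid spec: dimensions must be positive")
  if (backgroundGC < 0 || backgroundGC > 1)
    stop("invalid spec: backgroundGC must be in [0, 1]")
  if (is.character(motifs))
    motifs <- lapply(seq_along(motifs),
                     function(i) motif(names(motifs)[i] %||%
                                         paste0("TF", i), motifs[i]))
  motifNames <- vapply(motifs, function(m) m@tfId, character(1))
  withSeed(seed, {
    p <- c(A = (1 - backgroundGC) / 2, C = backgroundGC / 2,
           G = backgroundGC / 2, T = (1 - backgroundGC) / 2)
    seqs <- vapply(seq_len(nPromoters), function(i)
      paste(sample(names(p), promoterLength, replace = TRUE, prob = p),
            collapse = ""), character(1))
    gr <- GenomicRanges::GRanges()
    if (!is.null(plantedSites) && nrow(plantedSites)) {
      rows <- list()
      chars <- strsplit(seqs, "")
      for (r in seq_len(nrow(plantedSites))) {
        ps <- plantedSites[r, ]
        mi <- if (is.character(ps$motif) || is.factor(ps$motif))
          match(as.character(ps$motif), motifNames) else as.integer(ps$motif)
        m <- motifs[[mi]]
        L <- motifLength(m)
        if (ps$start < 0 || ps$start + L > promoterLength)
          stop("invalid spec: planted site outside promoter bounds")
        if (ps$nMismatches > L)
          stop("invalid spec: nMismatches exceeds motif length")
        v <- strsplit(m@variants[1L], "")[[1L]]
        if (ps$nMismatches > 0) {
          pos <- sample.int(L, ps$nMismatches)
          for (q in pos)
            v[q] <- sample(setdiff(c("A", "C", "G", "T"), v[q]), 1L)
        }
        placed <- paste(v, collapse = "")
        if (ps$strand == "-")
          placed <- as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(placed)))
        idx <- (ps$start + 1L):(ps$start + L)
        chars[[ps$promoter]][idx] <- strsplit(placed, "")[[1L]]
        rows[[r]] <- data.frame(
          promoter = sprintf("promoter%03d", ps$promoter),
          start = ps$start + 1L, end = ps$start + L,
          strand = ps$strand, tf = m@tfId,
          nMismatches = ps$nMismatches, planted = placed)
      }
      seqs <- vapply(chars, paste, character(1), collapse = "")
      st <- do.call(rbind, rows)
      gr <- GenomicRanges::GRanges(
        seqnames = st$promoter,
        ranges = IRanges::IRanges(start = st$start, end = st$end),
        strand = st$strand, tf = st$tf, nMismatches = st$nMismatches,
        planted = st$planted)
    }
    proms <- Biostrings::DNAStringSet(seqs)
    names(proms) <- sprintf("promoter%03d", seq_len(nPromoters))
    list(promoters = proms, sites = gr)
  })
}

#' Generate a feature table with a planted sparse linear effect on noise
#'
#' Features are standard normal with optional equicorrelation
#' \code{featureCorrelation} (a single-factor structure); the response is
#' \code{X beta + Normal(0, noiseSd^2)}.  If \code{noiseSd} is NULL it is
#' derived from \code{populationR2}:
#' R2 = var(X beta) / (var(X beta) + noiseSd^2).
#'
#' @param nGenes,nFeatures table dimensions.
#' @param trueCoefficients sparse coefficient vector (default: the first 5
#'   features have coefficient 1, the rest 0).
#' @param noiseSd residual standard deviation, or NULL to derive it.
#' @param populationR2 implied population R-squared in (0, 1) used when
#'   \code{noiseSd} is NULL (default 0.4).
#' @param featureCorrelation equicorrelation among features in [0, 1).
#' @param seed integer seed.
#' @return list with \code{X} (matrix with named columns), \code{response},
#'   \code{trueCoefficients}, \code{noiseSd}, \code{populationR2}.
#' @export
simFeatureTable <- function(nGenes = 2000, nFeatures = 100,
                            trueCoefficients = NULL, noiseSd = NULL,
                            populationR2 = 0.4, featureCorrelation = 0,
                            seed = 1L) {
  if (nGenes < 1 || nFeatures < 1)
    stop("invalid spec: dimensions must be positive")
  if (featureCorrelation < 0 || featureCorrelation >= 1)
    stop("invalid spec: featureCorrelation must be in [0, 1)")
  if (is.null(trueCoefficients)) {
    trueCoefficients <- numeric(nFeatures)
    trueCoefficients[seq_len(min(5L, nFeatures))] <- 1
  }
  stopifnot(length(trueCoefficients) == nFeatures)
  rho <- featureCorrelation
  b <- trueCoefficients
  varXb <- (1 - rho) * sum(b^2) + rho * sum(b)^2
  if (is.null(noiseSd)) {
    if (populationR2 <= 0 || populationR2 >= 1)
      stop("invalid spec: populationR2 must be in (0, 1)")
    noiseSd <- sqrt(varXb * (1 - populationR2) / populationR2)
  }
  impliedR2 <- varXb / (varXb + noiseSd^2)
  withSeed(seed, {
    z <- rnorm(nGenes)
    E <- matrix(rnorm(nGenes * nFeatures), nGenes, nFeatures)
    X <- sqrt(rho) * z + sqrt(1 - rho) * E
    colnames(X) <- sprintf("feat%03d", seq_len(nFeatures))
    rownames(X) <- sprintf("gene%04d", seq_len(nGenes))
    y <- drop(X %*% b) + rnorm(nGenes, sd = noiseSd)
    list(X = X, response = y, trueCoefficients = b, noiseSd = noiseSd,
         populationR2 = impliedR2)
  })
}

#' Generate a co-expression panel for one gene and its TFs
#'
#' TF expression profiles are standard normal over samples; TFs listed in a
#' block share a latent factor giving pairwise correlation \code{r} within
#' the block.  The target gene is
#' \code{sum(slopes * TF) + Normal(0, residSd^2)}.
#'
#' @param nSamples number of conditions/samples (default 50).
#' @param tfTargetSlopes named numeric: planted regulation slope per TF
#'   (positive = activator, negative = repressor, 0 = no regulation).
#' @param tfTfBlocks list of blocks, each a list with elements \code{tfs}
#'   (character) and \code{r} (pairwise correlation in [0, 1)).
#' @param residSd residual sd of the target gene (0 gives exact linearity).
#' @param seed integer seed.
#' @return numeric matrix of samples x (gene, TFs) with column names
#'   \code{c("gene", names(tfTargetSlopes))}.
#' @export
simCoexpressionPanel <- function(nSamples = 50, tfTargetSlopes,
                                 tfTfBlocks = list(), residSd = 1,
                                 seed = 1L) {
  stopifnot(nSamples >= 3, !is.null(names(tfTargetSlopes)))
  tfs <- names(tfTargetSlopes)
  withSeed(seed, {
    TF <- matrix(rnorm(nSamples * length(tfs)), nSamples,
                 dimnames = list(NULL, tfs))
    for (blk in tfTfBlocks) {
      stopifnot(all(blk$tfs %in% tfs), blk$r >= 0, blk$r < 1)
      z <- rnorm(nSamples)
      for (tf in blk$tfs)
        TF[, tf] <- sqrt(blk$r) * z + sqrt(1 - blk$r) * rnorm(nSamples)
    }
    gene <- drop(TF %*% tfTargetSlopes) +
      if (residSd > 0) rnorm(nSamples, sd = residSd) else 0
    cbind(gene = gene, TF)
  })
}

#' Write / read a tab-separated table (lossless round trip)
#'
#' Thin wrappers around \code{write.table}/\code{read.delim} with full
#' double precision, used for ground-truth and feature tables.
#'
#' @param x a data.frame.
#' @param path file path.
#' @export
writeTSV <- function(x, path) {
  utils::write.table(format(x, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeTSV
#' @export
readTSV <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Export motif sites as BED (0-based half-open)
#'
#' @param sites a GRanges of sites (mcols \code{tf}, \code{nMismatches}).
#' @param path output path.
#' @export
exportSitesBed <- function(sites, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(sites)),
    start = GenomicRanges::start(sites) - 1L,
    end = GenomicRanges::end(sites),
    name = S4Vectors::mcols(sites)$tf,
    score = S4Vectors::mcols(sites)$nMismatches,
    strand = as.character(GenomicRanges::strand(sites)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
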