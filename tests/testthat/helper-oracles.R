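## Independent brute-force oracles used to validate the fast implementations.
## These deliberately use naive per-window / per-pair loops and share no code
## with the package internals.

oracleRevComp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

## per-window minimal Hamming distance scan, both strands, with the same
## palindromic-dedup convention as the package (one "+" record carrying the
## smaller distance)
oracleScan <- function(seq, variants, maxMismatch, bothStrands = TRUE) {
  sc <- strsplit(seq, "")[[1]]
  L <- nchar(variants[1])
  rcv <- vapply(variants, oracleRevComp, character(1))
  rows <- list()
  for (i in seq_len(length(sc) - L + 1)) {
    win <- sc[i:(i + L - 1)]
    dist1 <- function(v) sum(win != strsplit(v, "")[[1]])
    dP <- min(vapply(variants, dist1, numeric(1)))
    dM <- if (bothStrands) min(vapply(rcv, dist1, numeric(1))) else L + 1
    if (dP <= maxMismatch && dM <= maxMismatch)
      rows[[length(rows) + 1]] <- data.frame(start = i, strand = "+",
                                             nmm = min(dP, dM))
    else if (dP <= maxMismatch)
      rows[[length(rows) + 1]] <- data.frame(start = i, strand = "+",
                                             nmm = dP)
    else if (dM <= maxMismatch)
      rows[[length(rows) + 1]] <- data.frame(start = i, strand = "-",
                                             nmm = dM)
  }
  if (!length(rows))
    return(data.frame(start = integer(0), strand = character(0),
                      nmm = integer(0)))
  do.call(rbind, rows)
}

## O(n^2) interval-overlap pair count and lengths (1-based closed intervals)
oracleOverlapPairs <- function(starts, ends) {
  n <- length(starts)
  pairs <- 0L; lens <- numeric(0)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    lo <- max(starts[i], starts[j]); hi <- min(ends[i], ends[j])
    if (hi >= lo) { pairs <- pairs + 1L; lens <- c(lens, hi - lo + 1) }
  }
  list(nPairs = pairs, lengths = lens)
}

## exhaustive best-subset search minimising AIC
oracleBestSubsetAIC <- function(X, y) {
  p <- ncol(X)
  best <- character(0)
  bestAIC <- AIC(lm(y ~ 1))
  for (k in seq_len(p)) {
    for (cmb in asplit(combn(p, k), 2)) {
      d <- data.frame(y = y, X[, cmb, drop = FALSE])
      a <- AIC(lm(y ~ ., data = d))
      if (a < bestAIC) { bestAIC <- a; best <- colnames(X)[cmb] }
    }
  }
  sort(best)
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

cliScript <- function() system.file("scripts", "tfnoise.R",
                                    package = "tfnoise")

runCli <- function(args) {
  rscript <- file.path(R.home("bin"), "Rscript")
  system2(rscript, c(cliScript(), args), stdout = TRUE, stderr = TRUE)
}
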