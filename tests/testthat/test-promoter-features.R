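test_that("motif expansion enumerates IUPAC and weight-matrix combinations", {
  m <- motif("TBP", "TATAWA")
  expect_setequal(motifVariants(m), c("TATAAA", "TATATA"))
  expect_identical(motifLength(m), 6L)
  pwm <- matrix(c(0.9, 0.1, 0, 0,
                  0, 0, 1, 0,
                  0.5, 0, 0, 0.5), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  m2 <- motif("X", pwm = pwm)       # threshold 0: any nonzero weight
  expect_setequal(motifVariants(m2), c("AGA", "AGT", "CGA", "CGT"))
  m3 <- motif("X", pwm = pwm, threshold = 0.5)
  expect_setequal(motifVariants(m3), c("AGA", "AGT"))
  big <- matrix(1, 4, 12, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(motif("Y", pwm = big, maxVariants = 1e6), "cap")
})

test_that("exact consensus matches are located precisely", {
  hits <- scanMotif("GCGTATAAAGC", motif("TBP", "TATAAA"), maxMismatch = 0)
  expect_identical(length(hits), 1L)
  expect_identical(GenomicRanges::start(hits), 4L)   # 0-based [3, 9)
  expect_identical(GenomicRanges::end(hits), 9L)
  expect_identical(as.character(GenomicRanges::strand(hits)), "+")
})

test_that("scanner agrees with the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:30) {
    seq <- randomSeq(200)
    mot <- motif(paste0("TF", i), randomSeq(6))
    mm <- sample(0:2, 1)
    hits <- scanMotif(seq, mot, maxMismatch = mm)
    oracle <- oracleScan(seq, motifVariants(mot), mm)
    expect_identical(length(hits), nrow(oracle))
    if (length(hits)) {
      expect_identical(GenomicRanges::start(hits), oracle$start)
      expect_identical(as.character(GenomicRanges::strand(hits)),
                       oracle$strand)
      expect_identical(S4Vectors::mcols(hits)$nMismatches,
                       as.integer(oracle$nmm))
    }
  }
})

test_that("non-ACGT characters warn and mismatch everything", {
  expect_warning(h <- scanMotif("ANNNNNA", motif("Z", "AAAAAAA"),
                                maxMismatch = 2), "non-ACGT")
  expect_identical(length(h), 0L)
})

test_that("overlap statistics match hand counts and the quadratic oracle", {
  gr <- function(starts, ends, tf = "T")
    GenomicRanges::GRanges("p", IRanges::IRanges(starts, ends), "+",
                           tf = tf, nMismatches = 0L)
  ## [0,6) and [3,9): one pair of length 3
  st <- siteOverlapStats(gr(c(1, 4), c(6, 9)))
  expect_identical(st$nOverlappingPairs, 1L)
  expect_equal(st$meanOverlapLength, 3)
  ## k identical sites: k(k-1)/2 pairs
  k <- 5
  st2 <- siteOverlapStats(gr(rep(10, k), rep(17, k)))
  expect_identical(st2$nOverlappingPairs, as.integer(k * (k - 1) / 2))
  ## 50 random sites vs O(n^2) oracle; invariant to reordering
  set.seed(8)
  s <- sample(1:950, 50); e <- s + sample(5:12, 50, replace = TRUE)
  st3 <- siteOverlapStats(gr(s, e))
  orc <- oracleOverlapPairs(s, e)
  expect_identical(st3$nOverlappingPairs, orc$nPairs)
  expect_equal(st3$meanOverlapLength, mean(orc$lengths))
  perm <- sample(50)
  st4 <- siteOverlapStats(gr(s[perm], e[perm]))
  expect_identical(st4$nOverlappingPairs, st3$nOverlappingPairs)
  ## adding a site never decreases the pair count
  st5 <- siteOverlapStats(gr(c(s, 500), c(e, 520)))
  expect_gte(st5$nOverlappingPairs, st3$nOverlappingPairs)
  ## empty input: all-zero stats
  st0 <- siteOverlapStats(gr(1, 6)[0])
  expect_identical(st0$nOverlappingPairs, 0L)
})

test_that("role fractions and same-TF exclusion are honoured", {
  gr <- GenomicRanges::GRanges("p", IRanges::IRanges(c(1, 4, 4), c(6, 9, 9)),
                               "+", tf = c("A1", "A1", "R1"),
                               nMismatches = 0L)
  roles <- c(A1 = "activator", R1 = "repressor")
  st <- siteOverlapStats(gr, roles = roles)
  expect_identical(st$nOverlappingPairs, 3L)
  expect_equal(unname(st$roleFractions["actAct"]), 1 / 3)
  expect_equal(unname(st$roleFractions["actRep"]), 2 / 3)
  stx <- siteOverlapStats(gr, roles = roles, excludeSameTf = TRUE)
  expect_identical(stx$nOverlappingPairs, 2L)
  expect_equal(unname(stx$roleFractions["actRep"]), 1)
})

test_that("positional site counts partition the sites by upstream window", {
  ## a site starting at paper position -150 belongs to the 100-200bp window
  off <- which(toPaperCoord(0:1009) == -150) - 1L
  gr <- GenomicRanges::GRanges("p", IRanges::IRanges(off + 1L, off + 8L),
                               "+", tf = "T", nMismatches = 0L)
  counts <- positionalSiteCounts(gr)
  expect_identical(unname(counts["100-200bp"]), 1L)
  expect_identical(sum(counts), 1L)
  ## random sites vs brute-force histogram; counts always sum to n
  set.seed(5)
  s0 <- sample(0:1000, 80, replace = TRUE)
  gr2 <- GenomicRanges::GRanges("p", IRanges::IRanges(s0 + 1L, s0 + 6L),
                                "+", tf = "T", nMismatches = 0L)
  counts2 <- positionalSiteCounts(gr2)
  pp <- toPaperCoord(s0)
  oracle <- vapply(1:10, function(k)
    sum(pp >= -100 * k & pp <= -100 * (k - 1) - 1), integer(1))
  expect_identical(unname(counts2[1:10]), oracle)
  expect_identical(sum(counts2), 80L)
})

test_that("occupancy windows follow the 12-window promoter layout", {
  occ <- rep(2.5, 1010)
  w <- occupancyWindows(occ)
  expect_identical(length(w), 12L)
  expect_true(all(w == 2.5))
  expect_identical(names(w)[1], "-1000..-900")
  expect_identical(names(w)[12], "-50..10")
  ## step track: 0 upstream of -500, 1 downstream of it
  step <- c(rep(0, 500), rep(1, 510))
  ws <- occupancyWindows(step)
  expect_identical(unname(ws["-600..-500"]), 0)
  expect_identical(unname(ws["-500..-400"]), 1)
  ## occupied-site threshold drops sub-threshold positions
  mix <- c(rep(0.1, 505), rep(3, 505))
  wt <- occupancyWindows(mix, threshold = 1)
  expect_identical(unname(wt["-1000..-900"]), NA_real_)
  expect_identical(unname(wt["-50..10"]), 3)
  expect_warning(occupancyWindows(replace(occ, 1:50, NA)), "excluded")
})

test_that("occupancy accepts a GRanges track over a located promoter", {
  prom <- GenomicRanges::GRanges("chrI", IRanges::IRanges(5001, 6010))
  track <- GenomicRanges::GRanges("chrI",
                                  IRanges::IRanges(c(5001, 5506), c(5505, 6200)),
                                  score = c(1, 4))
  w <- occupancyWindows(track, promoterRange = prom)
  expect_identical(unname(w["-1000..-900"]), 1)
  expect_identical(unname(w["-50..10"]), 4)
})

test_that("tAI is the geometric mean of codon weights over prefixes", {
  wts <- c(ATG = 0.25, GCT = 1)
  expect_equal(unname(taiProfile("ATGGCT", wts)["full"]), 0.5)
  ## all weights one
  w1 <- setNames(rep(1, 3), c("ATG", "GCT", "GGT"))
  expect_true(all(taiProfile("ATGGCTGGT", w1) == 1))
  ## random gene vs brute-force product^(1/n)
  set.seed(3)
  codons <- apply(expand.grid(BASES <- c("A", "C", "G", "T"), BASES, BASES),
                  1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  wts2 <- setNames(runif(length(codons), 0.05, 1), codons)
  gene <- paste(sample(codons, 60, replace = TRUE), collapse = "")
  prof <- taiProfile(gene, wts2)
  cods <- substring(gene, seq(1, nchar(gene), 3), seq(3, nchar(gene), 3))
  expect_equal(unname(prof["20"]), prod(wts2[cods[1:20]])^(1 / 20))
  expect_equal(unname(prof["full"]), prod(wts2[cods])^(1 / 60))
  ## monotone in any single weight
  wts3 <- wts2; wts3[cods[1]] <- min(1, wts3[cods[1]] * 1.2)
  expect_gt(taiProfile(gene, wts3)["full"], prof["full"])
  ## stop codons excluded with a warning; short genes flagged
  expect_warning(pstop <- taiProfile("ATGTAAGCT", c(ATG = 0.5, GCT = 0.5)),
                 "stop codon")
  expect_equal(unname(pstop["full"]), 0.5)
  expect_true(all(attr(taiProfile("ATGGCT", wts), "truncated")))
  expect_error(taiProfile("ATGG", wts), "divisible")
})

test_that("overlap degeneracy contrasts mismatch load by overlap status", {
  gr <- GenomicRanges::GRanges("p",
                               IRanges::IRanges(c(1, 4, 100), c(6, 9, 105)),
                               "+", tf = "T", nMismatches = c(2L, 1L, 0L))
  d <- overlapDegeneracy(gr)
  expect_equal(d$meanOverlapping, 1.5)
  expect_equal(d$meanNonOverlapping, 0)
  expect_equal(d$difference, 1.5)
  ## no overlaps: overlapping category undefined
  gr2 <- GenomicRanges::GRanges("p", IRanges::IRanges(c(1, 50), c(6, 55)),
                                "+", tf = "T", nMismatches = 0L)
  expect_true(overlapDegeneracy(gr2)$undefinedCategory)
})
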