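## promoter_features: motif scanning with mismatch tolerance on both
## strands, binding-site overlap statistics, positional site counts,
## nucleosome-occupancy window averages and tRNA-adaptation-index profiles.
##
## Coordinates are 0-based half-open promoter-local offsets internally
## (GRanges outputs are the usual 1-based closed); the promoter spans
## -1000..+10 around the start codon, offset 0 = -1000, offset 1000 = +1
## (first base of ATG).  toPaperCoord() converts.

BASES <- c("A", "C", "G", "T")

#' Convert a 0-based promoter offset to the signed biologist coordinate
#'
#' @param offset0 0-based offsets within the promoter.
#' @param upstream number of bases upstream of the start codon (default
#'   1000).
#' @return signed positions relative to the start codon (-1000..-1, +1..).
#' @export
toPaperCoord <- function(offset0, upstream = 1000L) {
  ifelse(offset0 < upstream, offset0 - upstream, offset0 - upstream + 1L)
}

#' Build a motif from an IUPAC consensus or a position weight matrix
#'
#' The motif is expanded to the explicit set of ACGT strings it matches:
#' each IUPAC code contributes its allowed bases, and each weight-matrix
#' column contributes the bases whose weight exceeds \code{threshold} times
#' the column maximum (the default 0 admits every base with nonzero
#' weight, i.e. all possible combinations of bases).
#'
#' @param tfId transcription factor identifier.
#' @param consensus IUPAC consensus string (used if \code{pwm} is NULL).
#' @param pwm 4 x L numeric matrix with rownames A, C, G, T.
#' @param threshold fraction of the column maximum a base's weight must
#'   exceed to be admitted (PWM expansion only).
#' @param maxVariants guard against combinatorial explosion (default 1e6);
#'   exceeding it is an error suggesting a higher threshold.
#' @return a \linkS4class{Motif}.
#' @examples
#' motif("TBP", "TATAWA")
#' @export
motif <- function(tfId, consensus = NULL, pwm = NULL, threshold = 0,
                  maxVariants = 1e6) {
  sets <- if (!is.null(pwm)) {
    stopifnot(nrow(pwm) == 4L, all(BASES %in% rownames(pwm)))
    lapply(seq_len(ncol(pwm)), function(j) {
      col <- pwm[BASES, j]
      BASES[col > threshold * max(col)]
    })
  } else {
    stopifnot(is.character(consensus), length(consensus) == 1L)
    map <- Biostrings::IUPAC_CODE_MAP
    lapply(strsplit(toupper(consensus), "")[[1L]], function(ch) {
      if (!ch %in% names(map)) stop("unknown IUPAC code: ", ch)
      strsplit(map[[ch]], "")[[1L]]
    })
  }
  nVar <- prod(vapply(sets, length, numeric(1)))
  if (nVar > maxVariants)
    stop(sprintf(paste0("motif expands to %.3g variants (cap %g); raise ",
                        "'threshold' to restrict the per-position base sets"),
                 nVar, maxVariants))
  grid <- do.call(expand.grid,
                  c(rev(sets), list(stringsAsFactors = FALSE)))
  variants <- apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L,
                    paste, collapse = "")
  new("Motif", tfId = tfId, variants = unique(variants))
}

revComp <- function(x)
  vapply(x, function(v)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(v))),
    character(1), USE.NAMES = FALSE)

## minimal Hamming distance of every length-L window of seqChars to any of
## the variant strings; returns list(mm = integer vector, var = index)
minMismatchScan <- function(seqChars, variants) {
  L <- nchar(variants[1L])
  nwin <- length(seqChars) - L + 1L
  if (nwin < 1L) return(list(mm = integer(0), var = integer(0)))
  idx <- outer(seq_len(L) - 1L, seq_len(nwin), `+`)
  win <- matrix(seqChars[idx], nrow = L)
  mm <- rep.int(L + 1L, nwin)
  vi <- rep.int(NA_integer_, nwin)
  for (v in seq_along(variants)) {
    vc <- strsplit(variants[v], "")[[1L]]
    d <- colSums(win != vc)
    better <- d < mm
    mm[better] <- d[better]
    vi[better] <- v
  }
  list(mm = as.integer(mm), var = vi)
}

#' Scan a promoter for motif occurrences with mismatch tolerance
#'
#' Every window (on both strands by default) whose Hamming distance to any
#' motif variant is at most \code{maxMismatch} is reported with its minimal
#' distance.  The default tolerance is two mismatches.  A window matching
#' on both strands at the same interval (a palindromic double hit) yields a
#' single site on the "+" strand carrying the smaller of the two distances.
#' Non-ACGT characters mismatch every base and trigger a warning.
#'
#' @param promoter a character string, \code{DNAString}, or a length-1
#'   \code{DNAStringSet}.
#' @param motifObj a \linkS4class{Motif}.
#' @param maxMismatch maximum Hamming distance (default 2).
#' @param bothStrands scan the reverse complement too (default TRUE).
#' @param promoterId seqname used in the returned GRanges.
#' @return a \code{GRanges} (1-based closed coordinates, sorted by start)
#'   with mcols \code{tf}, \code{nMismatches}, \code{variant}.
#' @export
scanMotif <- function(promoter, motifObj, maxMismatch = 2L,
                      bothStrands = TRUE, promoterId = "promoter") {
  if (is(promoter, "DNAStringSet")) {
    if (!is.null(names(promoter)) && promoterId == "promoter")
      promoterId <- names(promoter)[1L]
    promoter <- promoter[[1L]]
  }
  s <- toupper(as.character(promoter))
  if (nchar(s) < motifLength(motifObj))
    stop("promoter shorter than the motif")
  seqChars <- strsplit(s, "")[[1L]]
  if (any(!seqChars %in% BASES))
    warning("non-ACGT characters in promoter are treated as mismatching ",
            "every base")
  fwd <- minMismatchScan(seqChars, motifObj@variants)
  rev <- if (bothStrands)
    minMismatchScan(seqChars, revComp(motifObj@variants))
  else list(mm = rep.int(motifLength(motifObj) + 1L, length(fwd$mm)),
            var = fwd$var)
  L <- motifLength(motifObj)
  hitF <- fwd$mm <= maxMismatch
  hitR <- rev$mm <= maxMismatch
  w <- which(hitF | hitR)
  if (!length(w)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      tf = character(0), nMismatches = integer(0), variant = character(0))
    return(gr)
  }
  strand <- ifelse(hitF[w], "+", "-")
  nmm <- ifelse(hitF[w] & hitR[w], pmin(fwd$mm[w], rev$mm[w]),
                ifelse(hitF[w], fwd$mm[w], rev$mm[w]))
  vidx <- ifelse(hitF[w] & hitR[w] & rev$mm[w] < fwd$mm[w], rev$var[w],
                 ifelse(hitF[w], fwd$var[w], rev$var[w]))
  GenomicRanges::GRanges(
    seqnames = promoterId,
    ranges = IRanges::IRanges(start = w, width = L),
    strand = strand, tf = motifObj@tfId,
    nMismatches = as.integer(nmm),
    variant = motifObj@variants[vidx])
}

#' Scan several promoters for several motifs
#'
#' @param promoters a named \code{DNAStringSet}.
#' @param motifs list of \linkS4class{Motif} objects.
#' @inheritParams scanMotif
#' @return a combined \code{GRanges} of sites.
#' @export
scanPromoters <- function(promoters, motifs, maxMismatch = 2L,
                          bothStrands = TRUE) {
  out <- list()
  for (i in seq_along(promoters)) for (m in motifs)
    out[[length(out) + 1L]] <-
      scanMotif(promoters[[i]], m, maxMismatch, bothStrands,
                promoterId = names(promoters)[i] %||% paste0("promoter", i))
  suppressWarnings(do.call(c, out))
}

positionalWindowLabels <- function(upstream = 1000L, windowSize = 100L) {
  k <- upstream %/% windowSize
  c(sprintf("%d-%dbp", windowSize * (seq_len(k) - 1L), windowSize * seq_len(k)),
    "downstream")
}

## window index (1..k upstream windows, k+1 = downstream tail) for 0-based
## promoter offsets, by distance upstream of the start codon
positionalWindowIndex <- function(offset0, upstream = 1000L,
                                  windowSize = 100L) {
  k <- upstream %/% windowSize
  paperPos <- toPaperCoord(offset0, upstream)
  ifelse(paperPos >= 0L, k + 1L, (-paperPos - 1L) %/% windowSize + 1L)
}

#' Count binding sites per upstream distance window
#'
#' Sites are attributed by their start coordinate to ten 100-bp windows
#' covering 0-100bp, 100-200bp, ... 900-1000bp upstream of the start codon,
#' plus a downstream tail (+1..+10); counts sum to the number of sites.
#'
#' @param sites a \code{GRanges} of sites on one promoter.
#' @param upstream bases upstream of the start codon (default 1000).
#' @param windowSize window width (default 100).
#' @return named integer vector of counts.
#' @export
positionalSiteCounts <- function(sites, upstream = 1000L,
                                 windowSize = 100L) {
  labels <- positionalWindowLabels(upstream, windowSize)
  counts <- setNames(integer(length(labels)), labels)
  if (!length(sites)) return(counts)
  idx <- positionalWindowIndex(GenomicRanges::start(sites) - 1L,
                               upstream, windowSize)
  tab <- table(factor(idx, levels = seq_along(labels)))
  counts[] <- as.integer(tab)
  counts
}

#' Pairwise overlap statistics for binding sites on one promoter
#'
#' Two sites overlap iff their intervals share at least 1 bp, regardless of
#' strand.  Reports the number of overlapping pairs, pairs per site, the
#' fraction of sites participating in any overlap, the mean overlap length,
#' the per-window pair counts (a pair is attributed to the positional
#' window containing the midpoint of its overlap), and - given a TF role
#' map - the fractions of pairs shared by two activators, two repressors,
#' or an activator and a repressor.
#'
#' @param sites a \code{GRanges} of sites on one promoter (mcols \code{tf},
#'   \code{nMismatches}).
#' @param roles optional named character vector mapping tf id to
#'   "activator" or "repressor".
#' @param excludeSameTf drop pairs of sites of the same TF (default FALSE:
#'   same-TF overlaps are counted).
#' @param upstream,windowSize positional window layout.
#' @return list of class \code{OverlapStats}.
#' @export
siteOverlapStats <- function(sites, roles = NULL, excludeSameTf = FALSE,
                             upstream = 1000L, windowSize = 100L) {
  labels <- positionalWindowLabels(upstream, windowSize)
  empty <- list(nSites = length(sites), nOverlappingPairs = 0L,
                overlapsPerSite = if (length(sites)) 0 else NA_real_,
                fracSitesOverlapping = if (length(sites)) 0 else NA_real_,
                meanOverlapLength = NA_real_,
                perWindowPairs = setNames(integer(length(labels)), labels),
                roleFractions = c(actAct = NA_real_, repRep = NA_real_,
                                  actRep = NA_real_))
  class(empty) <- "OverlapStats"
  if (length(sites) < 2L) return(empty)
  hits <- GenomicRanges::findOverlaps(sites, drop.self = TRUE,
                                      drop.redundant = TRUE,
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  if (excludeSameTf && length(q)) {
    tf <- S4Vectors::mcols(sites)$tf
    keep <- tf[q] != tf[s]
    q <- q[keep]; s <- s[keep]
  }
  if (!length(q)) return(empty)
  ovStart <- pmax(GenomicRanges::start(sites)[q],
                  GenomicRanges::start(sites)[s])
  ovEnd <- pmin(GenomicRanges::end(sites)[q], GenomicRanges::end(sites)[s])
  ovLen <- ovEnd - ovStart + 1L
  mid0 <- floor((ovStart + ovEnd) / 2) - 1L   # 0-based midpoint offset
  widx <- positionalWindowIndex(mid0, upstream, windowSize)
  perWin <- setNames(as.integer(table(factor(widx,
                                             levels = seq_along(labels)))),
                     labels)
  roleFrac <- c(actAct = NA_real_, repRep = NA_real_, actRep = NA_real_)
  if (!is.null(roles)) {
    tf <- S4Vectors::mcols(sites)$tf
    r1 <- roles[tf[q]]; r2 <- roles[tf[s]]
    known <- !is.na(r1) & !is.na(r2)
    if (any(known)) {
      aa <- r1 == "activator" & r2 == "activator"
      rr <- r1 == "repressor" & r2 == "repressor"
      roleFrac <- c(actAct = mean(aa[known]), repRep = mean(rr[known]),
                    actRep = mean((!aa & !rr)[known]))
    }
  }
  out <- list(nSites = length(sites), nOverlappingPairs = length(q),
              overlapsPerSite = length(q) / length(sites),
              fracSitesOverlapping =
                length(unique(c(q, s))) / length(sites),
              meanOverlapLength = mean(ovLen),
              perWindowPairs = perWin, roleFractions = roleFrac)
  class(out) <- "OverlapStats"
  out
}

#' @export
print.OverlapStats <- function(x, ...) {
  cat(sprintf("OverlapStats: %d sites, %d overlapping pairs (%.2f per site)\n",
              x$nSites, x$nOverlappingPairs, x$overlapsPerSite))
  if (x$nOverlappingPairs > 0)
    cat(sprintf("  mean overlap length %.2f bp\n", x$meanOverlapLength))
  invisible(x)
}

#' Binding-site degeneracy in overlapping vs non-overlapping sites
#'
#' @param sites a \code{GRanges} with mcols \code{nMismatches}.
#' @return list with \code{meanOverlapping}, \code{meanNonOverlapping},
#'   \code{difference} (overlapping minus non-overlapping; NA with a flag
#'   when either category is empty) and the category sizes.
#' @export
overlapDegeneracy <- function(sites) {
  nmm <- S4Vectors::mcols(sites)$nMismatches
  hits <- GenomicRanges::findOverlaps(sites, drop.self = TRUE,
                                      drop.redundant = TRUE,
                                      ignore.strand = TRUE)
  inOv <- seq_along(sites) %in%
    c(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  mo <- if (any(inOv)) mean(nmm[inOv]) else NA_real_
  mn <- if (any(!inOv)) mean(nmm[!inOv]) else NA_real_
  list(meanOverlapping = mo, meanNonOverlapping = mn,
       difference = mo - mn, nOverlapping = sum(inOv),
       nNonOverlapping = sum(!inOv),
       undefinedCategory = !any(inOv) || !any(!inOv))
}

occupancyWindowDefs <- function(upstream = 1000L, downstream = 10L) {
  starts <- c(seq(-upstream, -300L, by = 100L), -200L, -150L, -100L, -50L)
  ends <- c(starts[-1L], downstream)
  labels <- sprintf("%d..%d", starts, ends)
  list(starts = starts, ends = ends, labels = labels)
}

#' Mean nucleosome occupancy over the promoter windows
#'
#' Averages an occupancy track over the twelve promoter windows used for
#' nucleosome features: 100-bp windows from -1000 to -200, then 50-bp
#' windows -200..-150, -150..-100, -100..-50, and -50..+10.  Positions not
#' covered by the track (NA) are excluded from the average with a warning.
#' With \code{threshold > 0} only positions whose occupancy exceeds the
#' threshold ("occupied sites") enter the average; the default 0 takes the
#' plain mean.
#'
#' @param occupancy numeric vector of per-base occupancy along the promoter
#'   (length \code{upstream + downstream}, offsets -1000..+10), or a
#'   \code{GRanges} with a \code{score} column together with
#'   \code{promoterRange}.
#' @param promoterRange a \code{GRanges} of length 1 locating the promoter,
#'   required when \code{occupancy} is a \code{GRanges} track.
#' @param upstream,downstream promoter extent (defaults 1000 and 10).
#' @param threshold occupied-site threshold (default 0: plain mean).
#' @return named numeric vector of 12 window means.
#' @export
occupancyWindows <- function(occupancy, promoterRange = NULL,
                             upstream = 1000L, downstream = 10L,
                             threshold = 0) {
  len <- upstream + downstream
  if (is(occupancy, "GRanges")) {
    stopifnot(!is.null(promoterRange), length(promoterRange) == 1L)
    v <- rep(NA_real_, len)
    hits <- GenomicRanges::findOverlaps(occupancy, promoterRange)
    for (h in S4Vectors::queryHits(hits)) {
      from <- max(GenomicRanges::start(occupancy)[h],
                  GenomicRanges::start(promoterRange))
      to <- min(GenomicRanges::end(occupancy)[h],
                GenomicRanges::end(promoterRange))
      v[(from:to) - GenomicRanges::start(promoterRange) + 1L] <-
        S4Vectors::mcols(occupancy)$score[h]
    }
    occupancy <- v
  }
  stopifnot(length(occupancy) == len)
  if (anyNA(occupancy))
    warning("positions without track coverage are excluded from the ",
            "window averages")
  defs <- occupancyWindowDefs(upstream, downstream)
  out <- setNames(numeric(length(defs$labels)), defs$labels)
  for (i in seq_along(defs$starts)) {
    offs <- (defs$starts[i] + upstream):(defs$ends[i] + upstream - 1L) + 1L
    vals <- occupancy[offs]
    vals <- vals[!is.na(vals)]
    if (threshold > 0) vals <- vals[vals > threshold]
    out[i] <- if (length(vals)) mean(vals) else NA_real_
  }
  out
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' tRNA adaptation index over codon prefixes
#'
#' tAI is the geometric mean of per-codon adaptiveness weights.  It is
#' computed for the first 5, 10, 15, 20, 25, 30, 40 and 50 codons and for
#' the whole gene; prefixes longer than the gene fall back to the full-gene
#' value and are flagged in the \code{"truncated"} attribute.  Stop codons
#' are excluded from the mean with a warning.
#'
#' @param cds coding sequence (character or \code{DNAString}); length must
#'   be a multiple of 3.
#' @param weights named numeric vector of codon weights in (0, 1].
#' @param prefixLengths codon prefix lengths (default
#'   \code{c(5, 10, 15, 20, 25, 30, 40, 50)}).
#' @return named numeric vector over the prefixes plus \code{"full"}.
#' @export
taiProfile <- function(cds, weights,
                       prefixLengths = c(5, 10, 15, 20, 25, 30, 40, 50)) {
  s <- toupper(as.character(cds))
  if (nchar(s) %% 3L != 0L)
    stop("coding sequence length must be divisible by 3")
  if (any(weights <= 0) || any(weights > 1))
    stop("codon weights must lie in (0, 1]")
  codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  isStop <- codons %in% STOP_CODONS
  if (any(isStop))
    warning("stop codon(s) excluded from the tAI average")
  known <- codons %in% names(weights)
  if (any(!known & !isStop))
    stop("codon(s) missing from the weight table: ",
         paste(unique(codons[!known & !isStop]), collapse = ", "))
  prefixTai <- function(k) {
    idx <- seq_len(min(k, length(codons)))
    use <- idx[!isStop[idx]]
    if (!length(use)) return(NA_real_)
    geometricMean(weights[codons[use]])
  }
  full <- prefixTai(length(codons))
  out <- c(vapply(prefixLengths, prefixTai, numeric(1)), full)
  names(out) <- c(as.character(prefixLengths), "full")
  attr(out, "truncated") <- prefixLengths > length(codons)
  out
}
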