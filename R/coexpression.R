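## coexpression: classify regulatory TFs as activators/repressors from
## gene-TF expression correlation across conditions, estimate regulation
## strength as the OLS slope, and flag co-expressing TFs by the
## at-least-three-significant-partners rule.

#' Classify a gene's regulatory TFs as activators or repressors
#'
#' Pearson correlation between the gene and each TF across samples, with a
#' two-sided test at level \code{alpha} (raw p-values by default, matching
#' the canonical protocol; \code{adjust = "BH"} is available).  A TF with a
#' significant positive correlation is an activator, significant negative a
#' repressor; the OLS slope of gene on TF is the strength of regulation and
#' is reported only for significant TFs.
#'
#' @param panel samples x genes numeric matrix (column names include
#'   \code{gene} and \code{tfs}).
#' @param gene target gene column name.
#' @param tfs character vector of TF column names.
#' @param alpha significance level (default 0.05).
#' @param adjust p-value adjustment method (default "none").
#' @param logScale correlate/slope on log-transformed expression
#'   (off by default).
#' @return data.frame with columns \code{gene}, \code{tf}, \code{r},
#'   \code{p}, \code{slope}, \code{role} ("activator", "repressor" or
#'   "none") and \code{zeroVariance} flag.
#' @export
geneTfRegulation <- function(panel, gene, tfs, alpha = 0.05,
                             adjust = "none", logScale = FALSE) {
  stopifnot(nrow(panel) >= 3L, gene %in% colnames(panel),
            all(tfs %in% colnames(panel)))
  y <- panel[, gene]
  if (logScale) y <- log(y)
  rows <- lapply(tfs, function(tf) {
    x <- panel[, tf]
    if (logScale) x <- log(x)
    if (sd(x) == 0 || sd(y) == 0)
      return(data.frame(gene = gene, tf = tf, r = NA_real_, p = NA_real_,
                        slope = NA_real_, role = "none",
                        zeroVariance = TRUE))
    ct <- suppressWarnings(cor.test(y, x, method = "pearson"))
    data.frame(gene = gene, tf = tf, r = unname(ct$estimate),
               p = ct$p.value, slope = NA_real_, role = "none",
               zeroVariance = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p <- stats::p.adjust(out$p, method = adjust)
  sig <- !is.na(out$p) & out$p < alpha
  out$role[sig & out$r > 0] <- "activator"
  out$role[sig & out$r < 0] <- "repressor"
  for (i in which(out$role != "none")) {
    x <- panel[, out$tf[i]]
    if (logScale) x <- log(x)
    out$slope[i] <- unname(coef(lm(y ~ x))[2L])
  }
  out
}

#' Pairwise TF-TF co-expression and the >= 3-partner rule
#'
#' All pairwise Pearson correlations among a gene's TFs are tested at level
#' \code{alpha}; a TF with at least \code{minPartners} significant positive
#' partners is flagged positively co-expressing (same for negative).
#'
#' @param panel samples x genes numeric matrix.
#' @param tfs TF column names.
#' @param alpha significance level (default 0.05).
#' @param minPartners partner threshold (default 3).
#' @param adjust p-value adjustment method (default "none").
#' @return list with \code{perTF} (data.frame: tf, nPositive, nNegative,
#'   positivelyCoexpressing, negativelyCoexpressing), \code{correlation}
#'   (symmetric matrix), \code{pValues}, and summary counts/percentages.
#' @export
tfTfCoexpression <- function(panel, tfs, alpha = 0.05, minPartners = 3L,
                             adjust = "none") {
  stopifnot(length(tfs) >= 2L, all(tfs %in% colnames(panel)))
  k <- length(tfs)
  R <- matrix(NA_real_, k, k, dimnames = list(tfs, tfs))
  P <- R
  diag(R) <- 1
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    x <- panel[, tfs[i]]; y <- panel[, tfs[j]]
    if (sd(x) == 0 || sd(y) == 0) next
    ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
    R[i, j] <- R[j, i] <- unname(ct$estimate)
    P[i, j] <- P[j, i] <- ct$p.value
  }
  Padj <- P
  ut <- upper.tri(P)
  Padj[ut] <- stats::p.adjust(P[ut], method = adjust)
  Padj[lower.tri(Padj)] <- t(Padj)[lower.tri(Padj)]
  sig <- !is.na(Padj) & Padj < alpha
  nPos <- rowSums(sig & R > 0, na.rm = TRUE)
  nNeg <- rowSums(sig & R < 0, na.rm = TRUE)
  perTF <- data.frame(tf = tfs, nPositive = nPos, nNegative = nNeg,
                      positivelyCoexpressing = nPos >= minPartners,
                      negativelyCoexpressing = nNeg >= minPartners,
                      row.names = NULL)
  list(perTF = perTF, correlation = R, pValues = Padj,
       nCoexpressing = sum(perTF$positivelyCoexpressing |
                             perTF$negativelyCoexpressing),
       pctCoexpressing = 100 * mean(perTF$positivelyCoexpressing |
                                      perTF$negativelyCoexpressing))
}
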