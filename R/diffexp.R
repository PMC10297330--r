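# Two-group negative-binomial differential expression with BH correction.
# Deliberately simple relative to a full DESeq-style analysis: no
# mean-dispersion trend, no independent filtering, no LFC moderation.
# Dispersion is a gene-wise method-of-moments estimate moderated toward
# the across-gene median, which keeps the Wald test both calibrated and
# powered at triplicate sample sizes.

#' Median-of-ratios size factors
#'
#' For genes with nonzero counts in every sample, each sample's factor is
#' the median ratio of its counts to the gene-wise geometric mean; factors
#' are rescaled to geometric mean 1.
#'
#' @param counts count matrix (genes x samples) or [count_matrix()] object.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok))
    pc_stop("degenerate input: no gene has nonzero counts in all samples")
  lg <- log(counts[ok, , drop = FALSE])
  geo <- exp(rowMeans(lg))
  f <- apply(counts[ok, , drop = FALSE] / geo, 2, median)
  f / exp(mean(log(f)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment; output order matches
#' input order, values capped at 1.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    pc_stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Negative-binomial Wald test for one two-group contrast
#'
#' Counts are normalized by [size_factors()] computed on the contrast's
#' samples. Per gene: group means of normalized counts;
#' `log2fc = log2((mu_A + 0.5) / (mu_B + 0.5))` (pseudocount 0.5
#' normalized counts). The NB dispersion `alpha` (variance
#' `mu + alpha * mu^2`) is estimated per gene by method of moments,
#' `alpha_g = ((v_A - mu_A) + (v_B - mu_B)) / (mu_A^2 + mu_B^2)`, then
#' moderated toward the across-gene median `alpha_0` with prior weight
#' `prior_df`:
#' `alpha* = (prior_df * alpha_0 + d_g * alpha_g) / (prior_df + d_g)`,
#' `d_g = n_A + n_B - 2`, floored at 1e-8. With only a handful of
#' replicates, the raw gene-wise estimate carries so much noise that a
#' Wald test built on it is either anti-conservative (normal reference)
#' or severely under-powered (t with `d_g` df); sharing information
#' across genes, as empirical-Bayes DE methods do, resolves both. The
#' Wald statistic divides log2fc by a delta-method standard error from
#' the moderated NB variance of each group mean; two-sided p-values use a
#' t reference with `d_g + prior_df` degrees of freedom. BH adjustment
#' runs over tested genes only; genes with all-zero counts in the
#' contrast are excluded beforehand and reported in the `excluded`
#' attribute.
#'
#' @param cm [count_matrix()] object.
#' @param contrast character(2): group labels `(A, B)`; log2fc is A over B.
#' @param ann optional [gene_annotation()] used to attach symbols.
#' @param lfc_cut,alpha thresholds recorded for the `call` column.
#' @param prior_df weight of the across-gene dispersion median in the
#'   moderated estimate (0 disables moderation).
#' @return [contrast_result()] data frame.
#' @export
nb_wald_test <- function(cm, contrast, ann = NULL, lfc_cut = 1,
                         alpha = 0.05, prior_df = 10) {
  stopifnot(length(contrast) == 2)
  sA <- group_columns(cm$samples, contrast[1])
  sB <- group_columns(cm$samples, contrast[2])
  if (length(sA) < 2 || length(sB) < 2)
    pc_stop("each group needs >= 2 replicates (got %d and %d)",
            length(sA), length(sB))
  sub <- cm$counts[, c(sA, sB), drop = FALSE]
  sf <- size_factors(sub)
  norm <- sweep(sub, 2, sf, "/")
  tested <- rowSums(sub) > 0
  excluded <- rownames(sub)[!tested]
  norm <- norm[tested, , drop = FALSE]
  iA <- seq_along(sA)
  iB <- length(sA) + seq_along(sB)
  nA <- length(iA); nB <- length(iB)
  dg <- nA + nB - 2
  muA <- rowMeans(norm[, iA, drop = FALSE])
  muB <- rowMeans(norm[, iB, drop = FALSE])
  vA <- apply(norm[, iA, drop = FALSE], 1, var)
  vB <- apply(norm[, iB, drop = FALSE], 1, var)
  raw <- ((vA - muA) + (vB - muB)) /
    pmax(muA^2 + muB^2, .Machine$double.xmin)
  base_mean <- rowMeans(norm)
  informative <- base_mean >= 1
  alpha0 <- if (any(informative)) median(raw[informative]) else 0
  disp <- pmax((prior_df * alpha0 + dg * raw) / (prior_df + dg), 1e-8)
  pc <- 0.5
  log2fc <- log2((muA + pc) / (muB + pc))
  var_muA <- (muA + disp * muA^2) / nA
  var_muB <- (muB + disp * muB^2) / nB
  se2 <- var_muA / ((muA + pc)^2 * log(2)^2) +
    var_muB / ((muB + pc)^2 * log(2)^2)
  wald <- log2fc / sqrt(se2)
  pval <- 2 * pt(-abs(wald), df = dg + prior_df)
  padj <- bh_adjust(pval)
  ids <- rownames(norm)
  sym <- if (is.null(ann)) ids else {
    i <- match(ids, ann$gene_id)
    ifelse(is.na(i), ids, ann$symbol[i])
  }
  cellA <- unique(cm$samples$cell_type[sA])
  cellB <- unique(cm$samples$cell_type[sB])
  cultA <- unique(cm$samples$culture[sA])
  cultB <- unique(cm$samples$culture[sB])
  contrast_result(ids, sym, base_mean = base_mean, log2fc = log2fc,
                  pvalue = pval, padj = padj, contrast = contrast,
                  cells = c(cellA, cellB), cultures = c(cultA, cultB),
                  lfc_cut = lfc_cut, alpha = alpha, excluded = excluded)
}

#' Call differentially expressed genes
#'
#' Thresholds follow the convention `|log2FC| >= lfc_cut` (inclusive) and
#' `padj < alpha` (strict).
#'
#' @param result [contrast_result()] data frame.
#' @param lfc_cut,alpha thresholds.
#' @return list with character vectors `up` and `down` (gene ids).
#' @export
call_degs <- function(result, lfc_cut = 1, alpha = 0.05) {
  up <- result$gene_id[result$log2fc >= lfc_cut & result$padj < alpha]
  down <- result$gene_id[result$log2fc <= -lfc_cut & result$padj < alpha]
  list(up = up, down = down)
}

# DEG symbols on one side of a contrast, with per-symbol fold change.
# Duplicated symbols keep the entry with the largest |log2fc|.
deg_symbols <- function(result, side = c("up", "down"), lfc_cut = 1,
                        alpha = 0.05) {
  side <- match.arg(side)
  sel <- if (side == "up") result$log2fc >= lfc_cut & result$padj < alpha
         else result$log2fc <= -lfc_cut & result$padj < alpha
  d <- result[sel, c("symbol", "log2fc")]
  d <- d[order(-abs(d$log2fc)), ]
  d <- d[!duplicated(d$symbol), ]
  setNames(d$log2fc, d$symbol)
}
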