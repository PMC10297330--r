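# Expression quantification (FPKM), expression filtering, sample-level QC
# and the 2^-ddCt qPCR utility.

#' Compute FPKM from read counts
#'
#' FPKM for gene g in sample s is
#' `counts[g,s] * 1e9 / (length_bp[g] * total_counts[s])`, where
#' `total_counts[s]` is the column sum of the count matrix. FPKM is
#' invariant to scaling a sample's sequencing depth.
#'
#' @param cm [count_matrix()] object.
#' @param ann [gene_annotation()] covering every gene in `cm`.
#' @return object of class `expression_matrix`: list with `fpkm` (matrix),
#'   `samples` (metadata) and `symbol` (per-gene symbol lookup).
#' @export
compute_fpkm <- function(cm, ann) {
  idx <- match(rownames(cm$counts), ann$gene_id)
  if (anyNA(idx))
    pc_stop("no annotation (gene length) for gene(s): %s",
            paste(head(rownames(cm$counts)[is.na(idx)], 5), collapse = ", "))
  len <- ann$length_bp[idx]
  totals <- colSums(cm$counts)
  if (any(totals == 0))
    pc_stop("sample(s) with zero total counts: %s",
            paste(colnames(cm$counts)[totals == 0], collapse = ", "))
  fpkm <- sweep(cm$counts / len, 2, totals, "/") * 1e9
  structure(list(fpkm = fpkm, samples = cm$samples,
                 symbol = setNames(ann$symbol[idx], rownames(cm$counts))),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (FPKM)\n",
              nrow(x$fpkm), ncol(x$fpkm)))
  invisible(x)
}

group_columns <- function(samples, group) {
  cols <- which(samples$group == group)
  if (!length(cols)) pc_stop("unknown group label: %s", group)
  cols
}

group_mean_fpkm <- function(expr, groups = NULL) {
  if (is.null(groups)) groups <- unique(expr$samples$group)
  vapply(groups, function(g) {
    rowMeans(expr$fpkm[, group_columns(expr$samples, g), drop = FALSE])
  }, numeric(nrow(expr$fpkm)))
}

#' Genes expressed per group
#'
#' A gene counts as expressed in a group when its mean FPKM over that
#' group's replicates reaches the threshold (default FPKM >= 1).
#'
#' @param expr [compute_fpkm()] output.
#' @param groups group labels to evaluate (default: all groups present).
#' @param threshold mean-FPKM cutoff, >= 0.
#' @return named list of gene-id character vectors, one per group.
#' @export
expressed_genes <- function(expr, groups = NULL, threshold = 1) {
  if (threshold < 0) pc_stop("threshold must be >= 0")
  if (is.null(groups)) groups <- unique(expr$samples$group)
  gm <- group_mean_fpkm(expr, groups)
  out <- lapply(seq_along(groups),
                function(j) rownames(expr$fpkm)[gm[, j] >= threshold])
  setNames(out, groups)
}

#' Sample-level quality control report
#'
#' PCA (samples as observations, genes as features), Pearson correlation
#' and average-linkage hierarchical clustering on distance `1 - r`, all on
#' `log2(FPKM + 1)`. Each principal component is oriented so that its
#' largest-magnitude gene loading is positive, making signs deterministic.
#'
#' @param expr [compute_fpkm()] output with at least 2 samples.
#' @param k number of principal components to keep.
#' @return object of class `qc_report`: `pc_coords` (samples x k),
#'   `pc_variance_fraction`, `corr` (samples x samples), `hclust` and
#'   `samples`.
#' @export
qc_report <- function(expr, k = 2) {
  if (ncol(expr$fpkm) < 2) pc_stop("QC needs at least 2 samples")
  lx <- log2(expr$fpkm + 1)
  if (all(apply(lx, 1, var) == 0))
    pc_stop("degenerate input: expression matrix is constant across samples")
  pca <- prcomp(t(lx), center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pca$x))
  for (j in seq_len(k)) {
    top <- which.max(abs(pca$rotation[, j]))
    if (pca$rotation[top, j] < 0) {
      pca$rotation[, j] <- -pca$rotation[, j]
      pca$x[, j] <- -pca$x[, j]
    }
  }
  varfrac <- pca$sdev^2 / sum(pca$sdev^2)
  corr <- cor(lx, method = "pearson")
  hc <- hclust(as.dist(1 - corr), method = "average")
  structure(list(pc_coords = pca$x[, seq_len(k), drop = FALSE],
                 pc_variance_fraction = varfrac[seq_len(k)],
                 corr = corr, hclust = hc, samples = expr$samples),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d samples, %d PCs (%.1f%% variance)\n",
              nrow(x$pc_coords), ncol(x$pc_coords),
              100 * sum(x$pc_variance_fraction)))
  cat(sprintf("  correlation range: %.3f .. %.3f\n",
              min(x$corr[lower.tri(x$corr)]),
              max(x$corr[lower.tri(x$corr)])))
  invisible(x)
}

#' @export
plot.qc_report <- function(x, which = c("pca", "dendrogram"), ...) {
  which <- match.arg(which)
  if (which == "pca") {
    grp <- factor(x$samples$group)
    graphics::plot(x$pc_coords[, 1], x$pc_coords[, 2],
                   col = as.integer(grp), pch = 19,
                   xlab = sprintf("PC1 (%.1f%%)",
                                  100 * x$pc_variance_fraction[1]),
                   ylab = sprintf("PC2 (%.1f%%)",
                                  100 * x$pc_variance_fraction[2]), ...)
    graphics::legend("topright", legend = levels(grp), col =
                       seq_along(levels(grp)), pch = 19, cex = 0.8)
  } else {
    graphics::plot(x$hclust, xlab = "", sub = "", ...)
  }
  invisible(x)
}

#' Group-mean expression profile for a gene panel
#'
#' Resolves panel symbols to gene ids, keeps panel genes expressed (per
#' [expressed_genes()]) in at least one group, and returns their group-mean
#' FPKM. Unresolved symbols and fully filtered genes are reported in
#' attributes, not errors.
#'
#' @param expr [compute_fpkm()] output.
#' @param panel character vector of gene symbols.
#' @param threshold mean-FPKM expression cutoff.
#' @return data frame (symbol x group means) with attributes `unresolved`
#'   and `filtered`.
#' @export
panel_profile <- function(expr, panel, threshold = 1) {
  if (!length(panel)) pc_stop("empty panel")
  panel <- canon_symbol(panel)
  idx <- match(panel, expr$symbol)
  unresolved <- panel[is.na(idx)]
  panel <- panel[!is.na(idx)]
  ids <- names(expr$symbol)[idx[!is.na(idx)]]
  groups <- unique(expr$samples$group)
  gm <- group_mean_fpkm(expr)
  keep <- rowSums(gm[ids, , drop = FALSE] >= threshold) > 0
  out <- data.frame(symbol = panel[keep], gm[ids[keep], , drop = FALSE],
                    check.names = FALSE, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, unresolved = unresolved, filtered = panel[!keep],
            class = c("panel_profile", "data.frame"))
}

#' Relative qPCR quantification (2^-ddCt)
#'
#' `ddCt = (Ct_target,treated - Ct_reference,treated) -
#' (Ct_target,control - Ct_reference,control)`; the relative fold change
#' is `2^-ddCt`.
#'
#' @param ct_target_treated,ct_reference_treated Ct of the gene of interest
#'   and the reference gene (e.g. GAPDH) in the treated condition.
#' @param ct_target_control,ct_reference_control same in the control.
#' @return relative fold change (positive real), vectorized.
#' @export
ddct_fold_change <- function(ct_target_treated, ct_reference_treated,
                             ct_target_control, ct_reference_control) {
  args <- list(ct_target_treated, ct_reference_treated,
               ct_target_control, ct_reference_control)
  if (!all(vapply(args, function(a) all(is.finite(a)), TRUE)))
    pc_stop("Ct values must be finite")
  ddct <- (ct_target_treated - ct_reference_treated) -
    (ct_target_control - ct_reference_control)
  2^(-ddct)
}
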