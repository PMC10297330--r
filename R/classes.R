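#' @importFrom stats cor hclust as.dist prcomp median var p.adjust pnorm pt
#'   phyper rnbinom rlnorm runif setNames cutree
#' @importFrom utils read.delim write.table head
NULL

# Canonical group labels: monoculture groups are named after the cell type
# ("DPC", "HMC"); coculture groups carry the "sCO" suffix ("DPCsCO", "HMCsCO").
group_label <- function(cell_type, culture) {
  ifelse(culture == "co", paste0(cell_type, "sCO"), cell_type)
}

canon_symbol <- function(x) toupper(trimws(x))

pc_stop <- function(...) stop(sprintf(...), call. = FALSE)

#' Construct a validated count matrix
#'
#' Bundles an integer gene-by-sample read-count matrix with its sample
#' metadata (cell type, culture condition, replicate). All downstream stages
#' consume this container.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @param samples data frame with columns `sample_id`, `cell_type`
#'   (`"DPC"`/`"HMC"`), `culture` (`"mono"`/`"co"`), `replicate`.
#' @return An object of class `count_matrix` with elements `counts` and
#'   `samples`; `samples$group` holds the derived group label.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) pc_stop("counts must have gene ids as rownames")
  if (anyDuplicated(rownames(counts)))
    pc_stop("duplicate gene ids in count matrix")
  if (any(is.na(counts)) || any(counts < 0))
    pc_stop("counts must be non-negative and complete")
  if (any(counts != round(counts)))
    pc_stop("counts must be integers")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_type", "culture", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) pc_stop("sample metadata missing column(s): %s",
                            paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) pc_stop("duplicate sample_id")
  if (!all(samples$cell_type %in% c("DPC", "HMC")))
    pc_stop("cell_type must be 'DPC' or 'HMC'")
  if (!all(samples$culture %in% c("mono", "co")))
    pc_stop("culture must be 'mono' or 'co'")
  samples$replicate <- as.integer(samples$replicate)
  if (any(samples$replicate < 1)) pc_stop("replicate must be a positive integer")
  key <- paste(samples$cell_type, samples$culture, samples$replicate)
  if (anyDuplicated(key))
    pc_stop("(cell_type, culture, replicate) must be unique")
  if (ncol(counts) != nrow(samples))
    pc_stop("counts has %d columns but metadata has %d samples",
            ncol(counts), nrow(samples))
  colnames(counts) <- samples$sample_id
  samples$group <- group_label(samples$cell_type, samples$culture)
  storage.mode(counts) <- "double"
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$samples$group)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Construct a gene annotation table
#'
#' @param gene_id,symbol,length_bp parallel vectors; `length_bp` is the
#'   transcript length in base pairs used for FPKM.
#' @return data frame of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, symbol, length_bp) {
  gene_id <- as.character(gene_id)
  symbol <- canon_symbol(symbol)
  length_bp <- as.numeric(length_bp)
  if (anyDuplicated(gene_id)) pc_stop("duplicate gene_id in annotation")
  if (any(!nzchar(symbol)) || any(is.na(symbol)))
    pc_stop("annotation symbol must be non-empty")
  if (any(is.na(length_bp)) || any(length_bp < 1))
    pc_stop("length_bp must be >= 1")
  structure(data.frame(gene_id = gene_id, symbol = symbol,
                       length_bp = length_bp, stringsAsFactors = FALSE),
            class = c("gene_annotation", "data.frame"))
}

#' Construct a ligand-receptor database
#'
#' Directed ligand-to-receptor symbol pairs, deduplicated and uppercased.
#' The same symbol may act as ligand in one pair and receptor in another.
#'
#' @param ligand,receptor character vectors of equal length.
#' @param source_rows number of raw records the pairs were parsed from.
#' @return object of class `lr_database` with elements `pairs` (data frame
#'   `ligand`, `receptor`) and `source_rows`.
#' @export
lr_database <- function(ligand, receptor, source_rows = length(ligand)) {
  ligand <- canon_symbol(ligand)
  receptor <- canon_symbol(receptor)
  keep <- nzchar(ligand) & nzchar(receptor) & !is.na(ligand) & !is.na(receptor)
  if (!all(keep)) pc_stop("empty ligand or receptor symbol in pair list")
  pairs <- unique(data.frame(ligand = ligand, receptor = receptor,
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$ligand, pairs$receptor), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, source_rows = as.integer(source_rows)),
            class = "lr_database")
}

#' @export
print.lr_database <- function(x, ...) {
  cat(sprintf("lr_database: %d unique ligand->receptor pairs (%d source rows)\n",
              nrow(x$pairs), x$source_rows))
  invisible(x)
}

#' Construct a transcription-factor catalog
#'
#' @param symbols character vector; case-folded to upper case, deduplicated,
#'   empty entries dropped.
#' @return character vector of class `tf_catalog`.
#' @export
tf_catalog <- function(symbols) {
  s <- canon_symbol(symbols)
  s <- sort(unique(s[nzchar(s) & !is.na(s)]))
  structure(s, class = "tf_catalog")
}

#' @export
print.tf_catalog <- function(x, ...) {
  cat(sprintf("tf_catalog: %d transcription factors\n", length(x)))
  if (length(x)) cat(" ", paste(head(unclass(x), 8), collapse = ", "),
                     if (length(x) > 8) "...", "\n")
  invisible(x)
}

NODE_ROLES <- c("ligand", "receptor", "signaling_protein", "TF")

#' Construct a directed signaling network
#'
#' Nodes are gene symbols tagged with one or more roles (ligand, receptor,
#' signaling_protein, TF); edges are directed symbol-to-symbol links. Every
#' edge endpoint must be a declared node.
#'
#' @param nodes data frame with columns `symbol` and `roles`
#'   (comma-separated role tags).
#' @param edges data frame with columns `source`, `target`.
#' @param allow_self_loops keep self loops if `TRUE` (default drops none but
#'   errors on them).
#' @return object of class `signaling_network`.
#' @export
signaling_network <- function(nodes, edges, allow_self_loops = FALSE) {
  nodes <- data.frame(symbol = canon_symbol(nodes$symbol),
                      roles = as.character(nodes$roles),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$symbol)) pc_stop("duplicate node symbol in network")
  role_list <- strsplit(nodes$roles, "[,|]")
  bad <- !vapply(role_list, function(r) all(trimws(r) %in% NODE_ROLES), TRUE)
  if (any(bad))
    pc_stop("unknown node role for %s (allowed: %s)",
            paste(nodes$symbol[bad], collapse = ", "),
            paste(NODE_ROLES, collapse = ", "))
  nodes$roles <- vapply(role_list, function(r) paste(trimws(r), collapse = ","), "")
  edges <- data.frame(source = canon_symbol(edges$source),
                      target = canon_symbol(edges$target),
                      stringsAsFactors = FALSE)
  undeclared <- setdiff(unique(c(edges$source, edges$target)), nodes$symbol)
  if (length(undeclared))
    pc_stop("network edge references undeclared node(s): %s",
            paste(undeclared, collapse = ", "))
  loops <- edges$source == edges$target
  if (any(loops) && !allow_self_loops)
    pc_stop("self loop on %s (set allow_self_loops = TRUE to keep)",
            paste(unique(edges$source[loops]), collapse = ", "))
  edges <- unique(edges)
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "signaling_network")
}

#' @export
print.signaling_network <- function(x, ...) {
  cat(sprintf("signaling_network: %d nodes, %d directed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

node_roles <- function(network, symbol) {
  i <- match(symbol, network$nodes$symbol)
  if (is.na(i)) return(character(0))
  strsplit(network$nodes$roles[i], ",")[[1]]
}

network_to_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                vertices = network$nodes)
}

#' Construct a differential-expression contrast result
#'
#' Per-gene statistics for one two-group comparison (A over B). `call` is
#' `"up"` when `log2fc >= lfc_cut` and `padj < alpha`, `"down"` for the
#' mirrored condition, else `"ns"`.
#'
#' @param gene_id,symbol,base_mean,log2fc,pvalue,padj parallel vectors.
#' @param contrast character(2): group labels (A, B).
#' @param cells,cultures character(2): cell type and culture of A and B.
#' @param lfc_cut,alpha thresholds used for the `call` column.
#' @param excluded gene ids dropped before testing (all-zero counts).
#' @return data frame of class `contrast_result`.
#' @export
contrast_result <- function(gene_id, symbol, base_mean, log2fc, pvalue, padj,
                            contrast, cells = c(NA, NA),
                            cultures = c(NA, NA),
                            lfc_cut = 1, alpha = 0.05,
                            excluded = character(0)) {
  if (any(pvalue < 0 | pvalue > 1, na.rm = TRUE))
    pc_stop("pvalue outside [0, 1]")
  if (any(padj < 0 | padj > 1, na.rm = TRUE))
    pc_stop("padj outside [0, 1]")
  if (any(base_mean < 0, na.rm = TRUE)) pc_stop("base_mean must be >= 0")
  call <- rep("ns", length(gene_id))
  call[log2fc >= lfc_cut & padj < alpha] <- "up"
  call[log2fc <= -lfc_cut & padj < alpha] <- "down"
  out <- data.frame(gene_id = as.character(gene_id),
                    symbol = canon_symbol(symbol),
                    base_mean = base_mean, log2fc = log2fc,
                    pvalue = pvalue, padj = padj, call = call,
                    stringsAsFactors = FALSE)
  structure(out, contrast = as.character(contrast), cells = cells,
            cultures = cultures, lfc_cut = lfc_cut, alpha = alpha,
            excluded = excluded,
            class = c("contrast_result", "data.frame"))
}

#' @export
print.contrast_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("contrast_result: %s vs %s (%d genes tested, %d excluded)\n",
              ct[1], ct[2], nrow(x), length(attr(x, "excluded"))))
  cat(sprintf("  up: %d  down: %d  ns: %d  (|log2FC| >= %g, padj < %g)\n",
              sum(x$call == "up"), sum(x$call == "down"),
              sum(x$call == "ns"), attr(x, "lfc_cut"), attr(x, "alpha")))
  invisible(x)
}

#' @export
summary.contrast_result <- function(object, ...) {
  print(object)
  top <- object[order(object$padj, -abs(object$log2fc)), ]
  cat("top genes by padj:\n")
  print.data.frame(head(top, 10), row.names = FALSE, digits = 3)
  invisible(object)
}
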