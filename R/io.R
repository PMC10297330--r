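# Readers and writers for every external table the pipeline touches.
# Dialect: UTF-8 TSV, '#' comment lines ignored, no quoting.

read_tsv_strict <- function(path, what = "table") {
  if (!file.exists(path)) pc_stop("%s file not found: %s", what, path)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE, quote = "")
}

write_tsv_strict <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
}

require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    pc_stop("%s: missing required column(s): %s", path,
            paste(miss, collapse = ", "))
}

#' Read a count matrix and its sample metadata
#'
#' The count file is a TSV whose first column is `gene_id` and whose
#' remaining columns are samples; the metadata file maps `sample_id` to
#' `cell_type`, `culture` and `replicate`. Sample order follows the
#' metadata file.
#'
#' @param path count TSV.
#' @param meta_path sample metadata TSV.
#' @return [count_matrix()] object.
#' @export
read_count_matrix <- function(path, meta_path) {
  tab <- read_tsv_strict(path, "count")
  require_columns(tab, "gene_id", path)
  meta <- read_tsv_strict(meta_path, "sample metadata")
  require_columns(meta, c("sample_id", "cell_type", "culture", "replicate"),
                  meta_path)
  cnt_cols <- setdiff(names(tab), "gene_id")
  missing_meta <- setdiff(cnt_cols, meta$sample_id)
  if (length(missing_meta))
    pc_stop("sample(s) in counts missing from metadata: %s",
            paste(missing_meta, collapse = ", "))
  missing_counts <- setdiff(meta$sample_id, cnt_cols)
  if (length(missing_counts))
    pc_stop("sample(s) in metadata missing from counts: %s",
            paste(missing_counts, collapse = ", "))
  m <- as.matrix(tab[, meta$sample_id, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(tab[meta$sample_id], is.numeric, TRUE))[1]
    pc_stop("%s: non-numeric counts in column '%s'", path,
            meta$sample_id[bad])
  }
  frac <- which(m != round(m) | m < 0, arr.ind = TRUE)
  if (nrow(frac))
    pc_stop("%s: invalid count %s at gene '%s', sample '%s'", path,
            format(m[frac[1, 1], frac[1, 2]]), tab$gene_id[frac[1, 1]],
            meta$sample_id[frac[1, 2]])
  rownames(m) <- tab$gene_id
  count_matrix(m, meta[, c("sample_id", "cell_type", "culture", "replicate")])
}

#' Write a count matrix and its sample metadata
#'
#' @param cm [count_matrix()] object.
#' @param path,meta_path output TSV paths for counts and metadata.
#' @export
write_count_matrix <- function(cm, path, meta_path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
  write_tsv_strict(cm$samples[, c("sample_id", "cell_type", "culture",
                                  "replicate")], meta_path)
  invisible(c(path, meta_path))
}

#' Read a gene annotation table
#'
#' TSV with columns `gene_id`, `symbol`, `length_bp`.
#' @param path input TSV.
#' @return [gene_annotation()] data frame.
#' @export
read_gene_annotation <- function(path) {
  tab <- read_tsv_strict(path, "annotation")
  require_columns(tab, c("gene_id", "symbol", "length_bp"), path)
  gene_annotation(tab$gene_id, tab$symbol, tab$length_bp)
}

#' @rdname read_gene_annotation
#' @param ann annotation to write.
#' @export
write_gene_annotation <- function(ann, path) {
  write_tsv_strict(as.data.frame(ann), path)
  invisible(path)
}

#' Read a ligand-receptor interaction table (CellTalkDB dialect)
#'
#' Requires columns `lr_pair`, `ligand_gene_symbol`,
#' `receptor_gene_symbol`; extra columns are ignored. Rows whose `lr_pair`
#' string disagrees with the symbol columns are kept with a warning (the
#' symbol columns win); rows with an empty symbol are skipped with a
#' warning.
#'
#' @param path input TSV.
#' @return [lr_database()] object; `source_rows` counts raw records.
#' @export
read_lr_database <- function(path) {
  tab <- read_tsv_strict(path, "ligand-receptor database")
  require_columns(tab, c("lr_pair", "ligand_gene_symbol",
                         "receptor_gene_symbol"), path)
  lig <- canon_symbol(tab$ligand_gene_symbol)
  rec <- canon_symbol(tab$receptor_gene_symbol)
  lig[is.na(lig)] <- ""
  rec[is.na(rec)] <- ""
  keep <- nzchar(lig) & nzchar(rec)
  if (any(!keep))
    warning(sprintf("%d row(s) with empty ligand/receptor symbol skipped",
                    sum(!keep)), call. = FALSE)
  mismatch <- keep & canon_symbol(tab$lr_pair) != paste0(lig, "_", rec)
  if (any(mismatch))
    warning(sprintf(
      "%d row(s) where lr_pair disagrees with symbol columns; symbols win",
      sum(mismatch)), call. = FALSE)
  lr_database(lig[keep], rec[keep], source_rows = nrow(tab))
}

#' @rdname read_lr_database
#' @param db database to write (CellTalkDB-dialect columns).
#' @export
write_lr_database <- function(db, path) {
  df <- data.frame(lr_pair = paste0(db$pairs$ligand, "_", db$pairs$receptor),
                   ligand_gene_symbol = db$pairs$ligand,
                   receptor_gene_symbol = db$pairs$receptor,
                   stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
  invisible(path)
}

#' Read a transcription-factor catalog
#'
#' Plain text, one symbol per line; case-insensitive, deduplicated.
#' @param path input file.
#' @return [tf_catalog()] object.
#' @export
read_tf_catalog <- function(path) {
  if (!file.exists(path)) pc_stop("TF catalog file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  tf_catalog(lines)
}

#' @rdname read_tf_catalog
#' @param tfs catalog to write.
#' @export
write_tf_catalog <- function(tfs, path) {
  writeLines(unclass(tfs), path)
  invisible(path)
}

#' Read a directed signaling network
#'
#' Edges are a TSV with columns `source`, `target`; node roles come from a
#' sidecar TSV with columns `symbol`, `roles` (comma-separated tags among
#' ligand, receptor, signaling_protein, TF). An edge endpoint absent from
#' the node table is a consistency error.
#'
#' @param edges_path,nodes_path input TSV paths.
#' @return [signaling_network()] object.
#' @export
read_network <- function(edges_path, nodes_path) {
  edges <- read_tsv_strict(edges_path, "network edge")
  require_columns(edges, c("source", "target"), edges_path)
  nodes <- read_tsv_strict(nodes_path, "network node")
  require_columns(nodes, c("symbol", "roles"), nodes_path)
  signaling_network(nodes, edges)
}

#' @rdname read_network
#' @param network network to write.
#' @export
write_network <- function(network, edges_path, nodes_path) {
  write_tsv_strict(network$edges, edges_path)
  write_tsv_strict(network$nodes, nodes_path)
  invisible(c(edges_path, nodes_path))
}

#' Read or write a differential-expression contrast table
#'
#' TSV with columns `gene_id`, `symbol`, `base_mean`, `log2fc`, `pvalue`,
#' `padj`, `call`; the contrast's group labels are stored in a header
#' comment line and restored on read. Externally produced tables (e.g.
#' DESeq2 exports reshaped to these columns) can enter the pipeline here.
#'
#' @param path input TSV.
#' @return [contrast_result()] object.
#' @export
read_contrast_table <- function(path) {
  if (!file.exists(path)) pc_stop("contrast file not found: %s", path)
  first <- readLines(path, n = 1L)
  ct <- c(NA, NA); cells <- c(NA, NA); cultures <- c(NA, NA)
  if (grepl("^# contrast:", first)) {
    fields <- strsplit(sub("^# contrast:\\s*", "", first), "\t")[[1]]
    ct <- strsplit(fields[1], " vs ")[[1]]
    if (length(fields) >= 2) cells <- strsplit(fields[2], ",")[[1]]
    if (length(fields) >= 3) cultures <- strsplit(fields[3], ",")[[1]]
  }
  tab <- read_tsv_strict(path, "contrast")
  require_columns(tab, c("gene_id", "log2fc", "pvalue", "padj"), path)
  if (any(tab$padj < 0 | tab$padj > 1, na.rm = TRUE))
    pc_stop("%s: padj outside [0, 1]", path)
  if (any(tab$pvalue < 0 | tab$pvalue > 1, na.rm = TRUE))
    pc_stop("%s: pvalue outside [0, 1]", path)
  if (is.null(tab$symbol)) tab$symbol <- tab$gene_id
  if (is.null(tab$base_mean)) tab$base_mean <- NA_real_
  contrast_result(tab$gene_id, tab$symbol, tab$base_mean, tab$log2fc,
                  tab$pvalue, tab$padj, contrast = ct, cells = cells,
                  cultures = cultures)
}

#' @rdname read_contrast_table
#' @param res contrast result to write.
#' @export
write_contrast_table <- function(res, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ct <- attr(res, "contrast")
  writeLines(sprintf("# contrast: %s vs %s\t%s\t%s", ct[1], ct[2],
                     paste(attr(res, "cells"), collapse = ","),
                     paste(attr(res, "cultures"), collapse = ",")), con)
  write.table(as.data.frame(res), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write scored ligand-receptor pairs
#'
#' TSV with columns `ligand`, `receptor`, `sender`, `receiver`, `mode`,
#' `strategy`, `fc_ligand`, `fc_receptor`, `cs`, sorted by communication
#' score descending (ties by ligand then receptor).
#'
#' @param pairs `crosstalk_pairs` data frame (see [pairs_strategy1()]).
#' @param path output TSV.
#' @export
write_pairs <- function(pairs, path) {
  cols <- c("ligand", "receptor", "sender", "receiver", "mode", "strategy",
            "fc_ligand", "fc_receptor", "cs")
  pairs <- rank_pairs(pairs)
  write_tsv_strict(as.data.frame(pairs)[, cols, drop = FALSE], path)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  tab <- read_tsv_strict(path, "pairs")
  require_columns(tab, c("ligand", "receptor", "sender", "receiver", "mode",
                         "strategy", "fc_ligand", "fc_receptor", "cs"), path)
  as_crosstalk_pairs(tab)
}

#' Export signaling axes
#'
#' `write_axes_table` writes one axis per row with the path as dash-joined
#' symbols; `write_axes` additionally encodes the axes as GraphML, nodes
#' carrying their role and axis-membership attributes.
#'
#' @param axes `signaling_axes` data frame (see [infer_axes()]).
#' @param network the [signaling_network()] supplying node roles.
#' @param path output path (`.graphml` or `.tsv`).
#' @export
write_axes <- function(axes, network, path) {
  if (nrow(axes) == 0) {
    g <- igraph::make_empty_graph(directed = TRUE)
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  steps <- strsplit(axes$path, "-", fixed = TRUE)
  el <- do.call(rbind, lapply(seq_along(steps), function(i) {
    s <- steps[[i]]
    cbind(from = s[-length(s)], to = s[-1], axis = i)
  }))
  verts <- unique(unlist(steps))
  roles <- vapply(verts, function(v) {
    r <- node_roles(network, v)
    if (length(r)) paste(r, collapse = ",") else "ligand"
  }, "")
  membership <- vapply(verts, function(v) {
    paste(which(vapply(steps, function(s) v %in% s, TRUE)), collapse = ",")
  }, "")
  vdf <- data.frame(name = verts, role = roles, axes = membership,
                    stringsAsFactors = FALSE)
  edf <- unique(data.frame(from = el[, 1], to = el[, 2],
                           stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_axes
#' @export
write_axes_table <- function(axes, path) {
  cols <- c("ligand", "receptor", "intermediates", "tf", "sender",
            "receiver", "path", "n_intermediates", "cs")
  write_tsv_strict(as.data.frame(axes)[, cols, drop = FALSE], path)
  invisible(path)
}
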