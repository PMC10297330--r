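# Role screening: classify DEG symbols as ligands, receptors and/or TFs,
# derive cell-type signature genes, and intersect coculture-induced DEGs
# with signatures to obtain core communication molecules.

#' Classify gene symbols into ligand / receptor / TF roles
#'
#' A symbol is a ligand if it appears on the ligand side of at least one
#' database pair, a receptor if it appears on the receptor side, and a TF
#' if it is in the catalog. Roles are not exclusive (e.g. a nuclear
#' hormone receptor such as ESR1 can be both receptor and TF). Symbols
#' with no role are dropped; their count is kept in the `dropped`
#' attribute.
#'
#' @param symbols character vector of gene symbols.
#' @param db [lr_database()] object.
#' @param tfs [tf_catalog()] object.
#' @return data frame of class `role_tags` with logical columns `ligand`,
#'   `receptor`, `tf` and a comma-joined `roles` column.
#' @export
classify_roles <- function(symbols, db, tfs) {
  symbols <- unique(canon_symbol(symbols))
  is_l <- symbols %in% db$pairs$ligand
  is_r <- symbols %in% db$pairs$receptor
  is_t <- symbols %in% unclass(tfs)
  any_role <- is_l | is_r | is_t
  out <- data.frame(symbol = symbols[any_role],
                    ligand = is_l[any_role], receptor = is_r[any_role],
                    tf = is_t[any_role], stringsAsFactors = FALSE)
  out <- out[order(out$symbol), , drop = FALSE]
  out$roles <- apply(out[, c("ligand", "receptor", "tf")], 1, function(r)
    paste(c("ligand", "receptor", "TF")[r], collapse = ","))
  rownames(out) <- NULL
  structure(out, dropped = sum(!any_role),
            class = c("role_tags", "data.frame"))
}

#' Cell-type signature genes from the cocultured between-cell contrast
#'
#' Given the contrast of the two cocultured cell types (A over B), genes
#' called up belong to A's signature and genes called down to B's
#' signature. Optionally requires the gene to be expressed (mean FPKM >=
#' `fpkm_cut`) in the owning cell type's cocultured group.
#'
#' @param between_contrast [contrast_result()] for cocultured A vs
#'   cocultured B (both cultures must be `"co"` when declared).
#' @param expr optional [compute_fpkm()] output enabling the expression
#'   floor.
#' @param fpkm_cut expression floor applied when `expr` is given.
#' @param lfc_cut,alpha DEG thresholds.
#' @return named list of two gene-symbol vectors, one per cell type
#'   (names are the contrast's cell labels).
#' @export
signature_genes <- function(between_contrast, expr = NULL, fpkm_cut = 1,
                            lfc_cut = 1, alpha = 0.05) {
  cells <- attr(between_contrast, "cells")
  cultures <- attr(between_contrast, "cultures")
  if (!anyNA(cultures) && !all(cultures == "co"))
    pc_stop("signature contrast must compare two cocultured groups")
  if (!anyNA(cells) && cells[1] == cells[2])
    pc_stop("signature contrast must compare two different cell types")
  upA <- names(deg_symbols(between_contrast, "up", lfc_cut, alpha))
  upB <- names(deg_symbols(between_contrast, "down", lfc_cut, alpha))
  if (!is.null(expr)) {
    groups <- attr(between_contrast, "contrast")
    ex <- expressed_genes(expr, groups, threshold = fpkm_cut)
    sym_of <- function(ids) unname(expr$symbol[ids])
    upA <- intersect(upA, sym_of(ex[[groups[1]]]))
    upB <- intersect(upB, sym_of(ex[[groups[2]]]))
  }
  out <- list(upA, upB)
  names(out) <- if (!anyNA(cells)) cells else attr(between_contrast, "contrast")
  out
}

#' Core communication molecules for one cell type
#'
#' Intersects the genes upregulated by coculture in a cell type with that
#' cell type's signature genes, then partitions the intersection into core
#' ligands, receptors and TFs via [classify_roles()]. A gene may appear in
#' several partitions.
#'
#' @param up_in_coculture symbols up in the cell's coculture-vs-monoculture
#'   contrast.
#' @param cell_signature the same cell's signature symbols.
#' @param db [lr_database()] object.
#' @param tfs [tf_catalog()] object.
#' @return list with `intersection`, `ligands`, `receptors`, `tfs`
#'   (character vectors) and the `role_tags` data frame.
#' @export
core_molecules <- function(up_in_coculture, cell_signature, db, tfs) {
  common <- intersect(canon_symbol(up_in_coculture),
                      canon_symbol(cell_signature))
  tags <- classify_roles(common, db, tfs)
  list(intersection = sort(common),
       ligands = tags$symbol[tags$ligand],
       receptors = tags$symbol[tags$receptor],
       tfs = tags$symbol[tags$tf],
       role_tags = tags)
}

#' Generic n-way set intersection
#'
#' Utility for Venn-style analyses over arbitrary collections of DEG sets.
#'
#' @param ... two or more character vectors (or a single list of them).
#' @return character vector of elements present in every set.
#' @export
intersect_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]])) sets <- sets[[1]]
  if (length(sets) < 2) pc_stop("need at least two sets")
  Reduce(intersect, lapply(sets, canon_symbol))
}
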