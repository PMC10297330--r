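# Construction and scoring of autocrine/paracrine ligand-receptor pairs.
# The communication score (CS) of a pair is the product of the ligand's
# and the receptor's linear fold changes.

#' Communication score of a ligand-receptor pair
#'
#' @param fc_ligand,fc_receptor linear (not log) fold changes, > 0.
#' @return `fc_ligand * fc_receptor`, vectorized.
#' @export
communication_score <- function(fc_ligand, fc_receptor) {
  if (any(fc_ligand <= 0) || any(fc_receptor <= 0))
    pc_stop("fold changes must be positive (linear scale)")
  fc_ligand * fc_receptor
}

as_crosstalk_pairs <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("crosstalk_pairs", "data.frame")
  df
}

empty_pairs <- function() {
  as_crosstalk_pairs(data.frame(
    ligand = character(0), receptor = character(0), sender = character(0),
    receiver = character(0), mode = character(0), strategy = integer(0),
    fc_ligand = numeric(0), fc_receptor = numeric(0), cs = numeric(0),
    stringsAsFactors = FALSE))
}

#' @export
print.crosstalk_pairs <- function(x, ...) {
  cat(sprintf("crosstalk_pairs: %d scored ligand->receptor pairs\n", nrow(x)))
  if (nrow(x)) {
    cat(sprintf("  modes: %s\n",
                paste(sprintf("%s (%d)", names(table(x$mode)),
                              table(x$mode)), collapse = ", ")))
    print.data.frame(head(as.data.frame(x), 5), row.names = FALSE,
                     digits = 4)
  }
  invisible(x)
}

build_pairs <- function(lig_fc, rec_fc, db, sender, receiver, strategy,
                        cs_scale) {
  hit <- db$pairs$ligand %in% names(lig_fc) &
    db$pairs$receptor %in% names(rec_fc)
  if (!any(hit)) return(empty_pairs())
  d <- db$pairs[hit, , drop = FALSE]
  fcl <- 2^unname(lig_fc[d$ligand])
  fcr <- 2^unname(rec_fc[d$receptor])
  cs <- if (cs_scale == "log2") unname(lig_fc[d$ligand] + rec_fc[d$receptor])
        else communication_score(fcl, fcr)
  rank_pairs(as_crosstalk_pairs(data.frame(
    ligand = d$ligand, receptor = d$receptor, sender = sender,
    receiver = receiver,
    mode = if (sender == receiver) "autocrine" else "paracrine",
    strategy = strategy, fc_ligand = fcl, fc_receptor = fcr, cs = cs,
    stringsAsFactors = FALSE)))
}

check_co_vs_mono <- function(contrast, what) {
  cultures <- attr(contrast, "cultures")
  cells <- attr(contrast, "cells")
  if (!anyNA(cultures) && !identical(unname(cultures), c("co", "mono")))
    pc_stop("%s contrast must be oriented cocultured over monocultured", what)
  if (!anyNA(cells) && cells[1] != cells[2])
    pc_stop("%s contrast must compare one cell type with itself", what)
  if (!anyNA(cells)) cells[1] else attr(contrast, "contrast")[1]
}

#' Ligand-receptor pairs, strategy 1 (coculture vs monoculture)
#'
#' For every database pair whose ligand is upregulated in the sender
#' cell's coculture-vs-monoculture contrast and whose receptor is
#' upregulated in the receiver cell's contrast, emits a scored pair. Both
#' contrasts must be oriented cocultured over monocultured. Passing the
#' same contrast as sender and receiver yields that cell's autocrine
#' pairs. Fold changes are linear (`2^log2fc`) from the respective
#' contrasts.
#'
#' @param sender_contrast,receiver_contrast [contrast_result()] objects.
#' @param db [lr_database()] object.
#' @param lfc_cut,alpha DEG thresholds for "upregulated".
#' @param cs_scale `"linear"` (CS = product of fold changes) or `"log2"`
#'   (CS = sum of log2 fold changes, for sensitivity analyses).
#' @return `crosstalk_pairs` data frame sorted by CS descending, ties by
#'   (ligand, receptor).
#' @export
pairs_strategy1 <- function(sender_contrast, receiver_contrast, db,
                            lfc_cut = 1, alpha = 0.05,
                            cs_scale = c("linear", "log2")) {
  cs_scale <- match.arg(cs_scale)
  sender <- check_co_vs_mono(sender_contrast, "sender")
  receiver <- check_co_vs_mono(receiver_contrast, "receiver")
  lig <- deg_symbols(sender_contrast, "up", lfc_cut, alpha)
  rec <- deg_symbols(receiver_contrast, "up", lfc_cut, alpha)
  build_pairs(lig, rec, db, sender, receiver, strategy = 1L,
              cs_scale = cs_scale)
}

#' Ligand-receptor pairs, strategy 2 (between cocultured cell types)
#'
#' Uses the single contrast of the two cocultured cell types. Genes up in
#' the contrast belong to the first cell's side, genes down to the second
#' cell's side. Autocrine pairs for cell X take both ligand and receptor
#' from X's side; paracrine sender-to-receiver pairs take the ligand from
#' the sender's side and the receptor from the receiver's side. Fold
#' changes are magnitudes `2^|log2fc|` from this contrast.
#'
#' @param between_contrast [contrast_result()] of cocultured sender-side
#'   cell vs cocultured receiver-side cell.
#' @param db [lr_database()] object.
#' @param sender,receiver cell labels; must match the contrast's declared
#'   cells.
#' @param lfc_cut,alpha DEG thresholds.
#' @param cs_scale see [pairs_strategy1()].
#' @return `crosstalk_pairs` data frame.
#' @export
pairs_strategy2 <- function(between_contrast, db, sender, receiver,
                            lfc_cut = 1, alpha = 0.05,
                            cs_scale = c("linear", "log2")) {
  cs_scale <- match.arg(cs_scale)
  cells <- attr(between_contrast, "cells")
  cultures <- attr(between_contrast, "cultures")
  if (!anyNA(cultures) && !all(cultures == "co"))
    pc_stop("strategy-2 contrast must compare two cocultured groups")
  if (anyNA(cells)) cells <- attr(between_contrast, "contrast")
  if (cells[1] == cells[2])
    pc_stop("strategy-2 contrast must compare two different cell types")
  if (!all(c(sender, receiver) %in% cells))
    pc_stop("sender/receiver must be among the contrast's cell types (%s)",
            paste(cells, collapse = ", "))
  side <- list(deg_symbols(between_contrast, "up", lfc_cut, alpha),
               deg_symbols(between_contrast, "down", lfc_cut, alpha))
  names(side) <- cells
  lig <- abs(side[[sender]])
  rec <- abs(side[[receiver]])
  build_pairs(lig, rec, db, sender, receiver, strategy = 2L,
              cs_scale = cs_scale)
}

#' Rank scored pairs
#'
#' Descending communication score; ties broken lexicographically by
#' (ligand, receptor).
#'
#' @param pairs `crosstalk_pairs` data frame.
#' @return the same rows, reordered.
#' @export
rank_pairs <- function(pairs) {
  if (nrow(pairs) == 0) return(as_crosstalk_pairs(pairs))
  as_crosstalk_pairs(pairs[order(-pairs$cs, pairs$ligand, pairs$receptor), ,
                           drop = FALSE])
}
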