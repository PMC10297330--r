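# TF hub ranking, ligand->receptor->signaling-protein->TF axis inference
# over a directed signaling network, and a plain hypergeometric enrichment
# utility.

#' Degree ranking of transcription factors in a network
#'
#' Restricts the network to the induced subgraph on the given TF set and
#' ranks each TF by total degree (in + out) within that subgraph,
#' descending, ties broken lexicographically.
#'
#' @param network [signaling_network()] object (or any object with
#'   `nodes$symbol` and `edges`).
#' @param tfs character vector of TF symbols; members absent from the
#'   network are reported in the `missing` attribute.
#' @return data frame of class `hub_ranking` with columns `symbol`,
#'   `degree`.
#' @export
tf_degree_rank <- function(network, tfs) {
  tfs <- unique(canon_symbol(unclass(tfs)))
  if (!length(tfs)) pc_stop("empty TF set")
  present <- intersect(tfs, network$nodes$symbol)
  missing <- setdiff(tfs, present)
  g <- network_to_igraph(network)
  sub <- igraph::induced_subgraph(g, present)
  deg <- igraph::degree(sub, mode = "all")
  out <- data.frame(symbol = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, missing = missing,
            class = c("hub_ranking", "data.frame"))
}

empty_axes <- function() {
  structure(data.frame(
    ligand = character(0), receptor = character(0),
    intermediates = character(0), tf = character(0), sender = character(0),
    receiver = character(0), path = character(0),
    n_intermediates = integer(0), cs = numeric(0),
    stringsAsFactors = FALSE),
    class = c("signaling_axes", "data.frame"))
}

#' @export
print.signaling_axes <- function(x, ...) {
  cat(sprintf("signaling_axes: %d ligand->receptor->...->TF paths\n",
              nrow(x)))
  if (nrow(x))
    print.data.frame(head(as.data.frame(x)[, c("path", "sender", "receiver",
                                               "cs")], 8),
                     row.names = FALSE, digits = 4)
  invisible(x)
}

#' Infer ligand-receptor-signaling-protein-TF axes
#'
#' For each scored pair, performs a depth-bounded search over the directed
#' signaling network from the pair's receptor to any transcription factor
#' in `receiver_up_tfs`, visiting only nodes expressed in the receiver
#' cell and never revisiting a node. Every distinct simple path with at
#' most `max_intermediates` intermediate signaling proteins becomes one
#' axis. Pairs whose receptor is missing from the network (or not
#' expressed in the receiver) are skipped and reported in the
#' `skipped_receptors` attribute.
#'
#' @param pairs `crosstalk_pairs` data frame (see [pairs_strategy1()]).
#' @param network [signaling_network()] with role-tagged nodes; it
#'   supplies receptor-and-downstream edges only — ligand-to-receptor
#'   links come from the pair list.
#' @param receiver_expressed symbols expressed in the receiver cell; the
#'   receptor, all intermediates and the TF must be members.
#' @param receiver_up_tfs TF symbols upregulated in the receiver; axis
#'   endpoints are restricted to TF-role network nodes in this set.
#' @param max_intermediates maximum number of intermediate nodes (>= 0).
#' @return data frame of class `signaling_axes`, sorted by pair CS
#'   descending, then path length ascending, then path lexicographically.
#' @export
infer_axes <- function(pairs, network, receiver_expressed, receiver_up_tfs,
                       max_intermediates = 3) {
  if (max_intermediates < 0) pc_stop("max_intermediates must be >= 0")
  receiver_expressed <- canon_symbol(receiver_expressed)
  receiver_up_tfs <- canon_symbol(unclass(receiver_up_tfs))
  if (nrow(pairs) == 0) return(empty_axes())
  has_tf_role <- vapply(network$nodes$symbol,
                        function(s) "TF" %in% node_roles(network, s), TRUE)
  targets <- intersect(intersect(network$nodes$symbol[has_tf_role],
                                 receiver_up_tfs), receiver_expressed)
  keep_nodes <- intersect(network$nodes$symbol, receiver_expressed)
  g <- igraph::induced_subgraph(network_to_igraph(network), keep_nodes)
  skipped <- character(0)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    rec <- pairs$receptor[i]
    if (!(rec %in% keep_nodes)) {
      skipped <- c(skipped, rec)
      next
    }
    to <- setdiff(targets, rec)
    if (!length(to)) next
    paths <- igraph::all_simple_paths(g, from = rec,
                                      to = intersect(to, keep_nodes),
                                      mode = "out",
                                      cutoff = max_intermediates + 1)
    for (p in paths) {
      nm <- igraph::V(g)$name[as.integer(p)]
      if (!(nm[length(nm)] %in% targets)) next
      inter <- nm[-c(1, length(nm))]
      rows[[length(rows) + 1L]] <- data.frame(
        ligand = pairs$ligand[i], receptor = rec,
        intermediates = paste(inter, collapse = "-"),
        tf = nm[length(nm)], sender = pairs$sender[i],
        receiver = pairs$receiver[i],
        path = paste(c(pairs$ligand[i], nm), collapse = "-"),
        n_intermediates = length(inter), cs = pairs$cs[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- empty_axes()
    attr(out, "skipped_receptors") <- unique(skipped)
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- unique(out)
  out <- out[order(-out$cs, out$n_intermediates, out$path), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, skipped_receptors = unique(skipped),
            class = c("signaling_axes", "data.frame"))
}

#' Hypergeometric gene-set enrichment
#'
#' For each named gene set, tests over-representation of the query in the
#' set with the hypergeometric upper tail `P(X >= overlap)`; BH adjustment
#' across terms.
#'
#' @param query gene set of interest; must be a subset of `universe`.
#' @param universe background gene set (non-empty).
#' @param gene_sets named list of character vectors; each is intersected
#'   with the universe before testing.
#' @return data frame with columns `term`, `set_size`, `overlap`, `p`,
#'   `padj`, sorted by p ascending.
#' @export
hypergeom_enrich <- function(query, universe, gene_sets) {
  universe <- unique(canon_symbol(universe))
  if (!length(universe)) pc_stop("empty universe")
  query <- unique(canon_symbol(query))
  if (length(setdiff(query, universe)))
    pc_stop("query must be a subset of the universe")
  N <- length(universe)
  n <- length(query)
  res <- lapply(names(gene_sets), function(term) {
    set <- intersect(unique(canon_symbol(gene_sets[[term]])), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, set_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
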