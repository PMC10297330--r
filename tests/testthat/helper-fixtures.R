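# Shared builders and independent brute-force oracles.

# count_matrix for two 3-replicate groups (DPC mono vs HMC mono by default)
make_cm <- function(counts, cells = c("DPC", "HMC"),
                    cultures = c("mono", "mono"), reps = ncol(counts) / 2) {
  n <- ncol(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    cell_type = rep(cells, each = reps),
    culture = rep(cultures, each = reps),
    replicate = rep(seq_len(reps), times = 2),
    stringsAsFactors = FALSE)
  count_matrix(counts, samples)
}

# full 4-group design
make_cm4 <- function(counts, reps = 3) {
  groups <- data.frame(
    cell_type = rep(c("DPC", "DPC", "HMC", "HMC"), each = reps),
    culture = rep(c("mono", "co", "mono", "co"), each = reps))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(nrow(groups))),
    cell_type = groups$cell_type, culture = groups$culture,
    replicate = rep(seq_len(reps), times = 4), stringsAsFactors = FALSE)
  count_matrix(counts, samples)
}

# synthetic contrast_result with chosen up/down symbols and fold changes
make_contrast <- function(up = character(0), down = character(0),
                          ns = character(0), lfc_up = 2, lfc_down = -2,
                          contrast = c("DPCsCO", "DPC"),
                          cells = c("DPC", "DPC"),
                          cultures = c("co", "mono")) {
  sym <- c(up, down, ns)
  lfc <- c(rep_len(lfc_up, length(up)), rep_len(lfc_down, length(down)),
           rep(0, length(ns)))
  padj <- c(rep(0.01, length(up) + length(down)), rep(0.9, length(ns)))
  contrast_result(sym, sym, base_mean = rep(10, length(sym)), log2fc = lfc,
                  pvalue = padj, padj = padj, contrast = contrast,
                  cells = cells, cultures = cultures)
}

# --- independent oracles -------------------------------------------------

# step-up BH from the definition padj_i = min_{j >= rank(i)} p_(j) * m / j
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(ps[i:m] * m / (i:m))), 0)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# hypergeometric upper tail by direct summation of the pmf
hyper_tail_brute <- function(k, K, N, n) {
  j <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# double loop over the database: pairs whose ligand/receptor fall in the
# given up-symbol sets
pairs_brute <- function(lig_up, rec_up, db) {
  hits <- list()
  for (i in seq_len(nrow(db$pairs))) {
    l <- db$pairs$ligand[i]; r <- db$pairs$receptor[i]
    if (l %in% names(lig_up) && r %in% names(rec_up))
      hits[[length(hits) + 1L]] <- data.frame(
        ligand = l, receptor = r,
        cs = 2^unname(lig_up[l]) * 2^unname(rec_up[r]),
        stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(data.frame(ligand = character(0),
                                       receptor = character(0),
                                       cs = numeric(0)))
  do.call(rbind, hits)
}

# exhaustive simple-path enumeration with expression filter (recursive DFS,
# no igraph)
paths_brute <- function(edges, from, targets, allowed, max_intermediates) {
  adj <- split(edges$target, edges$source)
  found <- character(0)
  walk <- function(path) {
    last <- path[length(path)]
    if (length(path) > 1 && last %in% targets)
      found <<- c(found, paste(path, collapse = "-"))
    if (length(path) - 2L >= max_intermediates) return()
    nxt <- setdiff(intersect(adj[[last]], allowed), path)
    for (v in nxt) walk(c(path, v))
  }
  if (from %in% allowed) walk(from)
  sort(unique(found))
}

# degree within the induced subgraph by direct counting over the edge list
degree_brute <- function(edges, members) {
  keep <- edges$source %in% members & edges$target %in% members
  tab <- table(factor(c(edges$source[keep], edges$target[keep]),
                      levels = sort(members)))
  out <- data.frame(symbol = names(tab), degree = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$degree, out$symbol), ]
}

# random directed acyclic-ish graph on n nodes (self loops excluded)
random_edges <- function(n_nodes, n_edges) {
  syms <- sprintf("N%02d", seq_len(n_nodes))
  src <- sample(syms, n_edges, replace = TRUE)
  tgt <- sample(syms, n_edges, replace = TRUE)
  keep <- src != tgt
  unique(data.frame(source = src[keep], target = tgt[keep],
                    stringsAsFactors = FALSE))
}
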