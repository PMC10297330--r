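# Synthetic coculture experiment generator. Emulates the study design the
# pipeline targets: 2 cell types (DPC, HMC) x 2 culture conditions (mono,
# co) x replicates, negative-binomial counts with sample-specific depths,
# planted cell-type signature genes and coculture-induced regulation on
# chosen ligand, receptor and TF symbols. Ground-truth crosstalk pairs and
# signaling axes are derived analytically from the planted effects, so
# every pipeline stage can be scored against known truth.

GROUPS <- c("DPC", "DPCsCO", "HMC", "HMCsCO")

#' Built-in ligand-receptor database fixture
#'
#' Twenty curated human ligand-receptor pairs mixing hair-growth-relevant
#' interactions (leptin, interleukin, FGF, activin, R-spondin signaling)
#' with decoys whose members are expressed but not perturbed in the
#' default simulation.
#'
#' @return [lr_database()] object.
#' @export
default_lr_fixture <- function() {
  lig <- c("LEP", "IL6", "THBS1", "RSPO1", "FGF7", "INHBA", "INHBA",
           "IL1A", "ADM", "PDGFD", "EREG", "BMP4", "WNT5A", "DSC3",
           "NTF3", "ANGPT2", "RSPO2", "FGF10", "CDH1", "LAMB3")
  rec <- c("LEPR", "EGFR", "TNFRSF11B", "LRP6", "FGFR2", "ACVR2A",
           "ACVR2B", "IL1R1", "CALCRL", "PDGFRA", "EGFR", "BMPR1A",
           "FZD1", "DSG2", "NTRK2", "TEK", "LGR4", "FGFR2", "PTPRM",
           "ITGB4")
  lr_database(lig, rec)
}

#' Built-in transcription-factor catalog fixture
#'
#' @return [tf_catalog()] object.
#' @export
default_tf_fixture <- function() {
  tf_catalog(c("SMAD3", "RELA", "NFKB1", "FOS", "JUN", "ESR1", "STAT3",
               "CREB1", "HIF1A", "CLOCK", "RORA", "EGR1", "GLI2", "SP1",
               "RBPJ", "NFIL3"))
}

#' Built-in directed signaling-network fixture
#'
#' Receptor-and-downstream edges only (ligand-receptor links live in the
#' database fixture). Carries the activin cascade
#' ACVR2A/ACVR2B -> ACVR1/ACVR1B -> SMAD3, the interleukin-1 branch
#' IL1R1 -> IL1RAP -> FOS, and decoy branches ending in TFs that the
#' default simulation leaves unregulated.
#'
#' @return [signaling_network()] object.
#' @export
default_network_fixture <- function() {
  nodes <- data.frame(
    symbol = c("ACVR2A", "ACVR2B", "ACVR1", "ACVR1B", "SMAD3", "EGFR",
               "STAT3", "IL1R1", "IL1RAP", "FOS", "LEPR", "JAK2",
               "FGFR2", "IRS1", "RELA"),
    roles = c("receptor", "receptor", "receptor,signaling_protein",
              "receptor,signaling_protein", "TF", "receptor", "TF",
              "receptor", "signaling_protein", "TF", "receptor",
              "signaling_protein", "receptor", "signaling_protein", "TF"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    source = c("ACVR2A", "ACVR2A", "ACVR2B", "ACVR2B", "ACVR1", "ACVR1B",
               "EGFR", "IL1R1", "IL1RAP", "LEPR", "JAK2", "FGFR2",
               "IRS1"),
    target = c("ACVR1", "ACVR1B", "ACVR1", "ACVR1B", "SMAD3", "SMAD3",
               "STAT3", "IL1RAP", "FOS", "JAK2", "STAT3", "IRS1",
               "RELA"),
    stringsAsFactors = FALSE)
  signaling_network(nodes, edges)
}

#' Default planted effects
#'
#' Long-format table of per-group log2 offsets relative to a gene's
#' baseline mean. Cell-type signature genes (including the keratin marker
#' block of the hair-matrix lineage) carry +4 in both groups of their own
#' cell type; coculture-induced crosstalk molecules carry +3 in one
#' cocultured group, mirroring autocrine leptin signaling in dermal
#' papilla cells, paracrine interleukin-1 signaling toward them, and the
#' activin axis toward hair matrix cells.
#'
#' @param n_signature signature genes per cell type.
#' @param effect_signature,effect_crosstalk log2 effect sizes.
#' @return data frame with columns `symbol`, `group`, `log2fc`.
#' @export
default_planted_effects <- function(n_signature = 60, effect_signature = 4,
                                    effect_crosstalk = 3) {
  dpc_sig <- c("VCAN", "ALPL", "WIF1",
               sprintf("DPCSIG%03d", seq_len(max(0, n_signature - 3))))
  hmc_sig <- c("KRT14", "KRT5", "KRT17", "KRT8",
               sprintf("HMCSIG%03d", seq_len(max(0, n_signature - 4))))
  sig <- rbind(
    expand.grid(symbol = dpc_sig, group = c("DPC", "DPCsCO"),
                stringsAsFactors = FALSE),
    expand.grid(symbol = hmc_sig, group = c("HMC", "HMCsCO"),
                stringsAsFactors = FALSE))
  sig$log2fc <- effect_signature
  up_dpcsco <- c("LEP", "LEPR", "IL6", "EGFR", "THBS1", "TNFRSF11B",
                 "FGF7", "INHBA", "IL1R1", "CALCRL", "ESR1", "FOS")
  up_hmcsco <- c("RSPO1", "LRP6", "FGFR2", "ACVR2A", "ACVR2B", "IL1A",
                 "ADM", "SMAD3")
  cross <- rbind(
    data.frame(symbol = up_dpcsco, group = "DPCsCO",
               stringsAsFactors = FALSE),
    data.frame(symbol = up_hmcsco, group = "HMCsCO",
               stringsAsFactors = FALSE))
  cross$log2fc <- effect_crosstalk
  rbind(sig, cross)
}

#' Simulation configuration
#'
#' Defines the synthetic experiment: a 4-group (DPC, DPCsCO, HMC, HMCsCO)
#' design with `reps` replicates per group, gene baseline means drawn
#' log-normal, negative-binomial counts with the given dispersion, sample
#' depths log-normal around `depth_mean`, and planted log2 effects per
#' (symbol, group). Every symbol appearing in the planted table, the
#' ligand-receptor database, the TF catalog or the signaling network is
#' assigned to a gene with a fixed baseline of `named_baseline` mean
#' normalized counts so that fixture molecules are reliably expressed.
#'
#' @param n_genes total genes simulated.
#' @param reps replicates per group (>= 2).
#' @param depth_mean expected reads per sample.
#' @param depth_sdlog log-sd of sample depths.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of gene
#'   baseline means.
#' @param named_baseline baseline mean for fixture-named genes.
#' @param dispersion NB dispersion (variance `mu + dispersion * mu^2`).
#' @param planted data frame (`symbol`, `group`, `log2fc`).
#' @param lr_db,tfs,network fixture objects.
#' @param lfc_cut DEG threshold used when deriving analytic truth.
#' @param max_intermediates depth bound used for analytic axis truth.
#' @param seed integer seed; all draws flow from one generator stream.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000, reps = 3, depth_mean = 1.5e6,
                       depth_sdlog = 0.1, baseline_meanlog = log(100),
                       baseline_sdlog = 1.5, named_baseline = 200,
                       dispersion = 0.05,
                       planted = default_planted_effects(),
                       lr_db = default_lr_fixture(),
                       tfs = default_tf_fixture(),
                       network = default_network_fixture(),
                       lfc_cut = 1, max_intermediates = 3, seed = 42) {
  if (reps < 2) pc_stop("replicate count must be >= 2")
  if (dispersion <= 0) pc_stop("dispersion must be > 0")
  planted$symbol <- canon_symbol(planted$symbol)
  if (!all(planted$group %in% GROUPS))
    pc_stop("planted group labels must be among %s",
            paste(GROUPS, collapse = ", "))
  named <- sort(unique(c(planted$symbol, lr_db$pairs$ligand,
                         lr_db$pairs$receptor, unclass(tfs),
                         network$nodes$symbol)))
  if (n_genes < length(named))
    pc_stop("n_genes (%d) smaller than the %d fixture-named symbols",
            n_genes, length(named))
  structure(list(n_genes = n_genes, reps = reps, depth_mean = depth_mean,
                 depth_sdlog = depth_sdlog,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 named_baseline = named_baseline, dispersion = dispersion,
                 planted = planted, lr_db = lr_db, tfs = tfs,
                 network = network, named_symbols = named,
                 lfc_cut = lfc_cut, max_intermediates = max_intermediates,
                 seed = seed),
            class = "sim_config")
}

# log2 effect of `symbol` in `group` under the planted table (0 if absent)
planted_effect_matrix <- function(config) {
  sym <- config$named_symbols
  eff <- matrix(0, length(sym), length(GROUPS),
                dimnames = list(sym, GROUPS))
  p <- config$planted
  for (i in seq_len(nrow(p)))
    eff[p$symbol[i], p$group[i]] <- eff[p$symbol[i], p$group[i]] + p$log2fc[i]
  eff
}

# Exhaustive simple-path enumeration by recursive depth-first search,
# independent of the igraph-backed production path search. Used to derive
# analytic axis truth.
enumerate_paths <- function(edges, from, targets, max_intermediates) {
  adj <- split(edges$target, edges$source)
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (length(path) > 1 && last %in% targets)
      out[[length(out) + 1L]] <<- path
    if (length(path) - 2L >= max_intermediates) return()
    for (nxt in setdiff(adj[[last]], path)) walk(c(path, nxt))
  }
  walk(from)
  out
}

# Analytic ground truth from the planted effects: expected DEG direction
# per contrast, expected pairs per (mode, strategy) under the strategy
# definitions, and expected axes by brute-force path enumeration.
sim_truth <- function(config) {
  eff <- planted_effect_matrix(config)
  cut <- config$lfc_cut
  contrasts <- list(DPC = c("DPCsCO", "DPC"), HMC = c("HMCsCO", "HMC"),
                    between = c("HMCsCO", "DPCsCO"))
  true_lfc <- vapply(contrasts, function(ct) eff[, ct[1]] - eff[, ct[2]],
                     numeric(nrow(eff)))
  db <- config$lr_db$pairs
  up1 <- list(DPC = rownames(true_lfc)[true_lfc[, "DPC"] >= cut],
              HMC = rownames(true_lfc)[true_lfc[, "HMC"] >= cut])
  side2 <- list(HMC = rownames(true_lfc)[true_lfc[, "between"] >= cut],
                DPC = rownames(true_lfc)[true_lfc[, "between"] <= -cut])
  combos <- expand.grid(sender = c("DPC", "HMC"),
                        receiver = c("DPC", "HMC"),
                        stringsAsFactors = FALSE)
  mk <- function(strategy, sets) {
    do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      s <- combos$sender[i]; r <- combos$receiver[i]
      hit <- db$ligand %in% sets[[s]] & db$receptor %in% sets[[r]]
      if (!any(hit)) return(NULL)
      data.frame(ligand = db$ligand[hit], receptor = db$receptor[hit],
                 sender = s, receiver = r,
                 mode = if (s == r) "autocrine" else "paracrine",
                 strategy = strategy, stringsAsFactors = FALSE)
    }))
  }
  expected_pairs <- rbind(mk(1L, up1), mk(2L, side2))
  if (is.null(expected_pairs))
    expected_pairs <- data.frame(
      ligand = character(0), receptor = character(0),
      sender = character(0), receiver = character(0),
      mode = character(0), strategy = integer(0),
      stringsAsFactors = FALSE)
  rownames(expected_pairs) <- NULL
  # Axis truth follows the strategy-1 pairs: for each expected pair, paths
  # from its receptor to TFs truly upregulated in the receiver's coculture
  # contrast, through network nodes (all fixture-named, hence expressed).
  net <- config$network
  tf_nodes <- net$nodes$symbol[vapply(net$nodes$symbol, function(s)
    "TF" %in% node_roles(net, s), TRUE)]
  s1 <- expected_pairs[expected_pairs$strategy == 1L, , drop = FALSE]
  axes <- list()
  for (i in seq_len(nrow(s1))) {
    rec <- s1$receptor[i]
    if (!(rec %in% net$nodes$symbol)) next
    up_tfs <- intersect(intersect(tf_nodes, unclass(config$tfs)),
                        up1[[s1$receiver[i]]])
    paths <- enumerate_paths(net$edges, rec, setdiff(up_tfs, rec),
                             config$max_intermediates)
    for (p in paths)
      axes[[length(axes) + 1L]] <- data.frame(
        ligand = s1$ligand[i], receptor = rec,
        tf = p[length(p)], sender = s1$sender[i],
        receiver = s1$receiver[i],
        path = paste(c(s1$ligand[i], p), collapse = "-"),
        stringsAsFactors = FALSE)
  }
  expected_axes <- if (length(axes)) unique(do.call(rbind, axes)) else
    data.frame(ligand = character(0), receptor = character(0),
               tf = character(0), sender = character(0),
               receiver = character(0), path = character(0),
               stringsAsFactors = FALSE)
  rownames(expected_axes) <- NULL
  structure(list(true_lfc = true_lfc, expected_pairs = expected_pairs,
                 expected_axes = expected_axes, planted = config$planted),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d expected pairs, %d expected axes\n",
              nrow(x$expected_pairs), nrow(x$expected_axes)))
  invisible(x)
}

#' Simulate a coculture crosstalk experiment
#'
#' Draws negative-binomial counts for the 4-group design defined by the
#' configuration. Gene baseline means are log-normal (fixture-named genes
#' use a fixed baseline), group means multiply the baseline by
#' `2^(planted effect)`, sample depths are log-normal around
#' `depth_mean`, and gene lengths are uniform on 500-5000 bp. The result
#' is bit-reproducible given the seed.
#'
#' @param config [sim_config()] object.
#' @return list with elements `counts` ([count_matrix()]), `annotation`
#'   ([gene_annotation()]) and `truth` (`sim_truth`: true log2 effects per
#'   contrast, expected pairs per mode/strategy, expected axes).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  named <- config$named_symbols
  gene_id <- sprintf("G%05d", seq_len(n))
  symbol <- gene_id
  symbol[seq_along(named)] <- named
  length_bp <- round(runif(n, 500, 5000))
  baseline <- rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  baseline[seq_along(named)] <- config$named_baseline
  baseline <- baseline * config$depth_mean / sum(baseline)
  eff <- matrix(0, n, length(GROUPS), dimnames = list(NULL, GROUPS))
  eff[seq_along(named), ] <- planted_effect_matrix(config)
  samples <- data.frame(
    sample_id = unlist(lapply(GROUPS, function(g)
      sprintf("%s_%d", g, seq_len(config$reps)))),
    cell_type = rep(c("DPC", "DPC", "HMC", "HMC"), each = config$reps),
    culture = rep(c("mono", "co", "mono", "co"), each = config$reps),
    replicate = rep(seq_len(config$reps), times = 4),
    stringsAsFactors = FALSE)
  depths <- rlnorm(nrow(samples), log(config$depth_mean),
                   config$depth_sdlog)
  grp <- group_label(samples$cell_type, samples$culture)
  mu <- vapply(seq_len(nrow(samples)), function(s)
    baseline * 2^eff[, grp[s]] * depths[s] / config$depth_mean,
    numeric(n))
  counts <- matrix(rnbinom(length(mu), mu = mu,
                           size = 1 / config$dispersion),
                   nrow = n, dimnames = list(gene_id, samples$sample_id))
  list(counts = count_matrix(counts, samples),
       annotation = gene_annotation(gene_id, symbol, length_bp),
       truth = sim_truth(config))
}

pair_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  paste(df$ligand, df$receptor, df$sender, df$receiver, sep = ":")
}

#' Precision/recall of recovered pairs and axes against simulation truth
#'
#' @param truth `sim_truth` object from [simulate_experiment()].
#' @param called_pairs `crosstalk_pairs` data frame (any mix of modes and
#'   strategies; rows are matched on ligand, receptor, sender, receiver,
#'   mode, strategy).
#' @param called_axes optional `signaling_axes` data frame, matched on
#'   the dash-joined path plus sender and receiver.
#' @return object of class `recovery_report`: data frame with one row per
#'   (strategy, mode) plus an `axes` row when axes are supplied; columns
#'   `n_expected`, `n_called`, `n_hit`, `precision`, `recall`. Exact set
#'   differences are kept in the `missed` and `extra` attributes.
#'   Undefined ratios (empty denominator) are reported as `NA`.
#' @export
recovery_report <- function(truth, called_pairs, called_axes = NULL) {
  exp_p <- truth$expected_pairs
  strata <- unique(rbind(exp_p[, c("strategy", "mode")],
                         as.data.frame(called_pairs)[, c("strategy", "mode")]))
  strata <- strata[order(strata$strategy, strata$mode), , drop = FALSE]
  missed <- list(); extra <- list()
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    st <- strata$strategy[i]; md <- strata$mode[i]
    e <- pair_key(exp_p[exp_p$strategy == st & exp_p$mode == md, ])
    c_ <- pair_key(called_pairs[called_pairs$strategy == st &
                                  called_pairs$mode == md, ])
    hit <- length(intersect(e, c_))
    missed[[paste(st, md)]] <<- setdiff(e, c_)
    extra[[paste(st, md)]] <<- setdiff(c_, e)
    data.frame(strategy = as.character(st), mode = md,
               n_expected = length(e), n_called = length(c_),
               n_hit = hit,
               precision = if (length(c_)) hit / length(c_) else NA_real_,
               recall = if (length(e)) hit / length(e) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(strategy = character(0), mode = character(0),
                      n_expected = integer(0), n_called = integer(0),
                      n_hit = integer(0), precision = numeric(0),
                      recall = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(called_axes)) {
    akey <- function(df) if (nrow(df) == 0) character(0) else
      paste(df$path, df$sender, df$receiver, sep = ":")
    e <- akey(truth$expected_axes)
    c_ <- akey(as.data.frame(called_axes))
    hit <- length(intersect(e, c_))
    missed[["axes"]] <- setdiff(e, c_)
    extra[["axes"]] <- setdiff(c_, e)
    out <- rbind(out, data.frame(
      strategy = "1", mode = "axes", n_expected = length(e),
      n_called = length(c_), n_hit = hit,
      precision = if (length(c_)) hit / length(c_) else NA_real_,
      recall = if (length(e)) hit / length(e) else NA_real_,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  structure(out, missed = missed, extra = extra,
            class = c("recovery_report", "data.frame"))
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery_report:\n")
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}
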