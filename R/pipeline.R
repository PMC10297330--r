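# End-to-end orchestration: simulate (or load) -> FPKM -> QC -> DE (three
# contrasts) -> roles/signatures -> pairs (both strategies, all four
# modes) -> axes -> recovery, with a JSON manifest of parameters, seed and
# output checksums.

#' Assemble a pipeline configuration
#'
#' Exactly one data source must be active: either `simulate` (a
#' [sim_config()], or `TRUE` for the default one re-seeded with `seed`)
#' or the set of input `paths` (named list with `counts`, `meta`,
#' `annotation`, `lr_db`, `tf_list`, `network_edges`, `network_nodes`).
#'
#' @param simulate [sim_config()] object, `TRUE`, or `NULL`.
#' @param paths named list of input files, or `NULL`.
#' @param lfc_cut,alpha DEG thresholds.
#' @param fpkm_cut expression floor (mean FPKM).
#' @param max_intermediates axis search depth bound.
#' @param cs_scale `"linear"` or `"log2"` communication-score scale.
#' @param seed integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL, lfc_cut = 1,
                            alpha = 0.05, fpkm_cut = 1,
                            max_intermediates = 3,
                            cs_scale = c("linear", "log2"), seed = 42) {
  cs_scale <- match.arg(cs_scale)
  if (isFALSE(simulate)) simulate <- NULL
  if (!is.null(paths) && !is.null(simulate))
    pc_stop("config error: give either input paths or a simulate block, not both")
  if (is.null(paths) && is.null(simulate))
    pc_stop("config error: no data source (need paths or simulate)")
  if (lfc_cut <= 0 || alpha <= 0 || fpkm_cut < 0 || max_intermediates < 0)
    pc_stop("thresholds must be positive")
  if (isTRUE(simulate)) simulate <- sim_config(seed = seed)
  if (!is.null(paths)) {
    need <- c("counts", "meta", "annotation", "lr_db", "tf_list",
              "network_edges", "network_nodes")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      pc_stop("paths missing entries: %s", paste(miss, collapse = ", "))
  }
  structure(list(simulate = if (is.null(paths)) simulate else NULL,
                 paths = paths, lfc_cut = lfc_cut, alpha = alpha,
                 fpkm_cut = fpkm_cut, max_intermediates = max_intermediates,
                 cs_scale = cs_scale, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulate:` mapping may override [sim_config()] scalars (`n_genes`,
#' `reps`, `depth_mean`, `dispersion`, ...).
#'
#' @param path YAML file.
#' @return `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 42
  sim <- if (!is.null(y$simulate)) {
    if (isTRUE(y$simulate)) sim_config(seed = seed)
    else do.call(sim_config, c(y$simulate, list(seed = seed)))
  } else NULL
  pipeline_config(simulate = sim, paths = y$paths,
                  lfc_cut = y$lfc_cut %||% 1, alpha = y$alpha %||% 0.05,
                  fpkm_cut = y$fpkm_cut %||% 1,
                  max_intermediates = y$max_intermediates %||% 3,
                  cs_scale = y$cs_scale %||% "linear", seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    pc_stop("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full crosstalk pipeline
#'
#' Executes every stage and writes all outputs under `out_dir`: input
#' fixtures (when simulating), `fpkm.tsv`, QC tables, three contrast
#' tables (DPCsCO vs DPC, HMCsCO vs HMC, HMCsCO vs DPCsCO), role tables,
#' eight pair tables (2 strategies x 4 sender/receiver modes), axis TSV
#' and GraphML files, a recovery report when simulation truth is
#' available, and `manifest.json` recording parameters, seed, per-stage
#' counts and MD5 checksums of every output file. Two runs with the same
#' configuration and seed produce byte-identical outputs.
#'
#' @param config [pipeline_config()] object (or YAML path).
#' @param out_dir output directory (created if needed).
#' @param verbose print per-stage counts.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  p <- function(f) file.path(out_dir, f)
  truth <- NULL

  if (!is.null(config$simulate)) {
    sim <- stage("simulate", simulate_experiment(config$simulate))
    cm <- sim$counts; ann <- sim$annotation; truth <- sim$truth
    db <- config$simulate$lr_db
    tfs <- config$simulate$tfs
    network <- config$simulate$network
    stage("simulate", {
      write_count_matrix(cm, p("counts.tsv"), p("samples.tsv"))
      write_gene_annotation(ann, p("annotation.tsv"))
      write_lr_database(db, p("lr_database.tsv"))
      write_tf_catalog(tfs, p("tf_catalog.txt"))
      write_network(network, p("network_edges.tsv"), p("network_nodes.tsv"))
    })
    # re-read from disk so the run exercises the same readers real data uses
    cm <- stage("read", read_count_matrix(p("counts.tsv"), p("samples.tsv")))
    ann <- stage("read", read_gene_annotation(p("annotation.tsv")))
    say("simulate: %d genes x %d samples", nrow(cm$counts), ncol(cm$counts))
  } else {
    cm <- stage("read", read_count_matrix(config$paths$counts,
                                          config$paths$meta))
    ann <- stage("read", read_gene_annotation(config$paths$annotation))
    db <- stage("read", read_lr_database(config$paths$lr_db))
    tfs <- stage("read", read_tf_catalog(config$paths$tf_list))
    network <- stage("read", read_network(config$paths$network_edges,
                                          config$paths$network_nodes))
  }

  expr <- stage("fpkm", compute_fpkm(cm, ann))
  stage("fpkm", write_tsv_strict(
    data.frame(gene_id = rownames(expr$fpkm), expr$fpkm,
               check.names = FALSE), p("fpkm.tsv")))

  qc <- stage("qc", qc_report(expr))
  stage("qc", {
    write_tsv_strict(data.frame(sample_id = rownames(qc$pc_coords),
                                qc$pc_coords, check.names = FALSE),
                     p("qc_pca.tsv"))
    write_tsv_strict(data.frame(sample_id = rownames(qc$corr), qc$corr,
                                check.names = FALSE), p("qc_correlation.tsv"))
    writeLines(paste(qc$hclust$labels[qc$hclust$order], collapse = "\t"),
               p("qc_dendrogram_order.txt"))
  })
  say("qc: %d PCs, correlation range %.3f..%.3f",
      ncol(qc$pc_coords), min(qc$corr), max(qc$corr[lower.tri(qc$corr)]))

  contrasts <- list(dpc = c("DPCsCO", "DPC"), hmc = c("HMCsCO", "HMC"),
                    between = c("HMCsCO", "DPCsCO"))
  de <- lapply(contrasts, function(ct)
    stage("de", nb_wald_test(cm, ct, ann, config$lfc_cut, config$alpha)))
  for (nm in names(de))
    write_contrast_table(de[[nm]], p(sprintf("contrast_%s.tsv", nm)))
  for (nm in names(de))
    say("de %s: %d up, %d down", paste(attr(de[[nm]], "contrast"),
                                       collapse = " vs "),
        sum(de[[nm]]$call == "up"), sum(de[[nm]]$call == "down"))

  sig <- stage("roles", signature_genes(de$between, expr,
                                        fpkm_cut = config$fpkm_cut,
                                        lfc_cut = config$lfc_cut,
                                        alpha = config$alpha))
  core <- stage("roles", {
    up_sym <- list(
      DPC = names(deg_symbols(de$dpc, "up", config$lfc_cut, config$alpha)),
      HMC = names(deg_symbols(de$hmc, "up", config$lfc_cut, config$alpha)))
    lapply(c(DPC = "DPC", HMC = "HMC"), function(cell)
      core_molecules(up_sym[[cell]], sig[[cell]], db, tfs))
  })
  for (cell in names(core))
    write_tsv_strict(as.data.frame(core[[cell]]$role_tags),
                     p(sprintf("core_roles_%s.tsv", cell)))
  say("roles: DPC core %d, HMC core %d",
      length(core$DPC$intersection), length(core$HMC$intersection))

  combos <- expand.grid(sender = c("DPC", "HMC"),
                        receiver = c("DPC", "HMC"),
                        stringsAsFactors = FALSE)
  all_pairs <- list()
  for (i in seq_len(nrow(combos))) {
    s <- combos$sender[i]; r <- combos$receiver[i]
    tag <- if (s == r) sprintf("autocrine_%s", s) else
      sprintf("paracrine_%s_to_%s", s, r)
    de_of <- function(cell) if (cell == "DPC") de$dpc else de$hmc
    p1 <- stage("pairs", pairs_strategy1(de_of(s), de_of(r), db,
                                         config$lfc_cut, config$alpha,
                                         config$cs_scale))
    p2 <- stage("pairs", pairs_strategy2(de$between, db, s, r,
                                         config$lfc_cut, config$alpha,
                                         config$cs_scale))
    write_pairs(p1, p(sprintf("pairs_strategy1_%s.tsv", tag)))
    write_pairs(p2, p(sprintf("pairs_strategy2_%s.tsv", tag)))
    all_pairs[[length(all_pairs) + 1L]] <- p1
    all_pairs[[length(all_pairs) + 1L]] <- p2
    say("pairs %s: strategy1 %d, strategy2 %d", tag, nrow(p1), nrow(p2))
  }
  pairs_all <- as_crosstalk_pairs(do.call(rbind, lapply(all_pairs,
                                                        as.data.frame)))

  ex <- stage("axes", expressed_genes(expr, threshold = config$fpkm_cut))
  axes_all <- list()
  for (i in seq_len(nrow(combos))) {
    s <- combos$sender[i]; r <- combos$receiver[i]
    sel <- pairs_all$strategy == 1 & pairs_all$sender == s &
      pairs_all$receiver == r
    if (!any(sel)) next
    de_r <- if (r == "DPC") de$dpc else de$hmc
    rec_expr <- unname(expr$symbol[ex[[paste0(r, "sCO")]]])
    up_tfs <- intersect(names(deg_symbols(de_r, "up", config$lfc_cut,
                                          config$alpha)), unclass(tfs))
    ax <- stage("axes", infer_axes(pairs_all[sel, ], network, rec_expr,
                                   up_tfs, config$max_intermediates))
    axes_all[[length(axes_all) + 1L]] <- ax
  }
  axes <- if (length(axes_all))
    do.call(rbind, lapply(axes_all, as.data.frame)) else
      as.data.frame(empty_axes())
  axes <- structure(axes, class = c("signaling_axes", "data.frame"))
  write_axes_table(axes, p("axes.tsv"))
  write_axes(axes, network, p("axes.graphml"))
  say("axes: %d", nrow(axes))

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- stage("recover", recovery_report(truth, pairs_all, axes))
    write_tsv_strict(as.data.frame(recovery), p("recovery.tsv"))
  }

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "paircomm",
    seed = config$seed,
    parameters = list(lfc_cut = config$lfc_cut, alpha = config$alpha,
                      fpkm_cut = config$fpkm_cut,
                      max_intermediates = config$max_intermediates,
                      cs_scale = config$cs_scale,
                      simulated = !is.null(config$simulate),
                      contrast_orientation = "cocultured over monocultured; between contrast HMCsCO over DPCsCO"),
    counts = list(
      genes = nrow(cm$counts), samples = ncol(cm$counts),
      degs = lapply(de, function(d)
        list(up = sum(d$call == "up"), down = sum(d$call == "down"))),
      pairs = nrow(pairs_all), axes = nrow(axes)),
    checksums = as.list(setNames(unname(tools::md5sum(file.path(out_dir,
                                                                files))),
                                 files)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
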