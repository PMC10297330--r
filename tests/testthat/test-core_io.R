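test_that("count matrix round-trips through TSV and validates cells", {
  m <- matrix(c(1, 2, 0, 5, 10, 10), nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), NULL))
  samples <- data.frame(sample_id = c("s1", "s2"),
                        cell_type = c("DPC", "HMC"),
                        culture = c("mono", "mono"), replicate = c(1, 1))
  cm <- count_matrix(m, samples)
  expect_equal(dim(cm), c(3L, 2L))
  expect_equal(unname(cm$counts["gB", ]), c(0, 5))

  cpath <- withr::local_tempfile(fileext = ".tsv")
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(cm, cpath, mpath)
  back <- read_count_matrix(cpath, mpath)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$samples, cm$samples)

  # fractional count is a format error naming the offending cell
  writeLines(c("gene_id\ts1\ts2", "gA\t2.5\t1", "gB\t0\t5"), cpath)
  expect_error(read_count_matrix(cpath, mpath), "2.5.*gA.*s1")

  # sample present in counts but absent from metadata
  writeLines(c("gene_id\ts1\tsX", "gA\t1\t1"), cpath)
  expect_error(read_count_matrix(cpath, mpath), "missing from metadata")
})

test_that("simulated experiment survives a disk round-trip exactly", {
  cfg <- sim_config(n_genes = 400, seed = 7)
  sim <- simulate_experiment(cfg)
  cpath <- withr::local_tempfile(fileext = ".tsv")
  mpath <- withr::local_tempfile(fileext = ".tsv")
  apath <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(sim$counts, cpath, mpath)
  write_gene_annotation(sim$annotation, apath)
  expect_equal(read_count_matrix(cpath, mpath), sim$counts)
  expect_equal(read_gene_annotation(apath), sim$annotation,
               ignore_attr = TRUE)
})

test_that("ligand-receptor table parsing dedupes, case-folds and warns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("lr_pair\tligand_gene_symbol\treceptor_gene_symbol\textra",
               "LEP_LEPR\tLEP\tLEPR\tx",
               "IL6_EGFR\til6\tEGFR\tx",
               "IL6_EGFR\tIL6\tEGFR\tx"), path)
  db <- read_lr_database(path)
  expect_equal(db$source_rows, 3L)
  expect_equal(nrow(db$pairs), 2L)
  expect_true(all(c("IL6", "LEP") %in% db$pairs$ligand))

  writeLines(c("lr_pair\tligand_gene_symbol\treceptor_gene_symbol",
               "LEP_LEPR\tLEP\tLEPR", "IL6_\tIL6\t"), path)
  expect_warning(db2 <- read_lr_database(path), "empty")
  expect_equal(nrow(db2$pairs), 1L)
  expect_equal(db2$source_rows, 2L)

  writeLines(c("lr_pair\tligand_gene_symbol\treceptor_gene_symbol",
               "WRONG_NAME\tLEP\tLEPR"), path)
  expect_warning(db3 <- read_lr_database(path), "symbols win")
  expect_equal(db3$pairs$ligand, "LEP")

  writeLines(c("lr_pair\tligand_gene_symbol", "LEP_LEPR\tLEP"), path)
  expect_error(read_lr_database(path), "missing required column")
})

test_that("parsed pair set matches an independent line-by-line parse", {
  set.seed(11)
  ligs <- sprintf("L%02d", sample(20, 20, replace = TRUE))
  recs <- sprintf("R%02d", sample(20, 20, replace = TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("lr_pair\tligand_gene_symbol\treceptor_gene_symbol",
               sprintf("%s_%s\t%s\t%s", ligs, recs, ligs, recs)), path)
  db <- read_lr_database(path)
  manual <- unique(t(vapply(readLines(path)[-1], function(l) {
    f <- strsplit(l, "\t")[[1]]
    toupper(f[2:3])
  }, character(2))))
  expect_equal(nrow(db$pairs), nrow(manual))
  expect_setequal(paste(db$pairs$ligand, db$pairs$receptor),
                  paste(manual[, 1], manual[, 2]))
})

test_that("TF catalog case-folds and dedupes; networks validate endpoints", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("esr1", "ESR1"), path)
  expect_equal(unclass(read_tf_catalog(path)), "ESR1")

  net <- signaling_network(
    nodes = data.frame(symbol = c("ACVR1", "SMAD3"),
                       roles = c("receptor,signaling_protein", "TF")),
    edges = data.frame(source = "ACVR1", target = "SMAD3"))
  expect_equal(nrow(net$edges), 1L)
  expect_true("TF" %in% paircomm:::node_roles(net, "SMAD3"))

  expect_error(signaling_network(
    nodes = data.frame(symbol = "ACVR1", roles = "receptor"),
    edges = data.frame(source = "ACVR1", target = "SMAD3")),
    "undeclared node")

  epath <- withr::local_tempfile(fileext = ".tsv")
  npath <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, epath, npath)
  expect_equal(read_network(epath, npath), net)
})

test_that("contrast tables round-trip and reject invalid probabilities", {
  res <- make_contrast(up = c("LEP", "FGF7"), down = "KRT14",
                       ns = c("ACTB", "GAPDH"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contrast_table(res, path)
  back <- read_contrast_table(path)
  expect_equal(as.data.frame(back), as.data.frame(res))
  expect_equal(attr(back, "contrast"), attr(res, "contrast"))
  expect_equal(attr(back, "cells"), attr(res, "cells"))

  writeLines(c("gene_id\tlog2fc\tpvalue\tpadj", "g1\t1\t0.5\t1.2"), path)
  expect_error(read_contrast_table(path), "padj")
})

test_that("pair tables write sorted by CS and round-trip", {
  empty <- paircomm:::empty_pairs()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(empty, path)
  expect_equal(length(readLines(path)), 1L)  # header only

  two <- paircomm:::as_crosstalk_pairs(data.frame(
    ligand = c("A", "B"), receptor = c("X", "Y"), sender = "DPC",
    receiver = "DPC", mode = "autocrine", strategy = 1L,
    fc_ligand = c(1, 3), fc_receptor = c(2, 2), cs = c(2, 6),
    stringsAsFactors = FALSE))
  write_pairs(two, path)
  tab <- read.delim(path)
  expect_equal(tab$cs, c(6, 2))

  set.seed(3)
  n <- 50
  sim <- paircomm:::as_crosstalk_pairs(data.frame(
    ligand = sprintf("L%02d", 1:n), receptor = sprintf("R%02d", 1:n),
    sender = sample(c("DPC", "HMC"), n, TRUE), receiver = "HMC",
    mode = "paracrine", strategy = sample(1:2, n, TRUE),
    fc_ligand = round(2^runif(n, 0, 4), 6),
    fc_receptor = round(2^runif(n, 0, 4), 6), stringsAsFactors = FALSE))
  sim$mode[sim$sender == sim$receiver] <- "autocrine"
  sim$cs <- sim$fc_ligand * sim$fc_receptor
  write_pairs(sim, path)
  back <- read_pairs(path)
  expect_equal(as.data.frame(back), as.data.frame(rank_pairs(sim)),
               tolerance = 1e-12)
})

test_that("axes export to GraphML with roles and to flat TSV", {
  net <- default_network_fixture()
  axes <- structure(data.frame(
    ligand = "INHBA", receptor = "ACVR2A", intermediates = "ACVR1",
    tf = "SMAD3", sender = "DPC", receiver = "HMC",
    path = "INHBA-ACVR2A-ACVR1-SMAD3", n_intermediates = 1L, cs = 64,
    stringsAsFactors = FALSE),
    class = c("signaling_axes", "data.frame"))
  gpath <- withr::local_tempfile(fileext = ".graphml")
  tpath <- withr::local_tempfile(fileext = ".tsv")
  write_axes(axes, net, gpath)
  g <- igraph::read_graph(gpath, format = "graphml")
  expect_setequal(igraph::V(g)$name,
                  c("INHBA", "ACVR2A", "ACVR1", "SMAD3"))
  expect_equal(igraph::V(g)$role[igraph::V(g)$name == "SMAD3"], "TF")
  expect_equal(igraph::ecount(g), 3)
  write_axes_table(axes, tpath)
  expect_equal(read.delim(tpath)$path, axes$path)
})
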