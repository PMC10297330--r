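make_pair <- function(ligand, receptor, sender = "DPC", receiver = "HMC",
                      cs = 16) {
  paircomm:::as_crosstalk_pairs(data.frame(
    ligand = ligand, receptor = receptor, sender = sender,
    receiver = receiver,
    mode = ifelse(sender == receiver, "autocrine", "paracrine"),
    strategy = 1L, fc_ligand = sqrt(cs), fc_receptor = sqrt(cs), cs = cs,
    stringsAsFactors = FALSE))
}

test_that("TF degree ranking on star and edgeless graphs, plus oracle", {
  star <- signaling_network(
    nodes = data.frame(symbol = c("C", "L1", "L2", "L3", "L4"),
                       roles = "TF"),
    edges = data.frame(source = "C", target = c("L1", "L2", "L3", "L4")))
  r <- tf_degree_rank(star, c("C", "L1", "L2", "L3", "L4"))
  expect_equal(r$symbol[1], "C")
  expect_equal(r$degree[1], 4L)

  lonely <- signaling_network(
    nodes = data.frame(symbol = c("B", "A"), roles = "TF"),
    edges = data.frame(source = character(0), target = character(0)))
  r2 <- tf_degree_rank(lonely, c("B", "A"))
  expect_equal(r2$symbol, c("A", "B"))
  expect_equal(r2$degree, c(0L, 0L))
  expect_error(tf_degree_rank(star, character(0)), "empty")

  set.seed(61)
  for (i in 1:30) {
    edges <- random_edges(20, 40)
    nodes <- data.frame(symbol = sprintf("N%02d", 1:20), roles = "TF")
    net <- signaling_network(nodes, edges)
    members <- sample(nodes$symbol, 12)
    got <- tf_degree_rank(net, members)
    want <- degree_brute(net$edges, members)
    expect_equal(got$symbol, want$symbol)
    expect_equal(got$degree, want$degree)
  }

  # invariant to edge-list ordering
  shuf <- signaling_network(star$nodes,
                            star$edges[c(3, 1, 4, 2), ])
  expect_equal(tf_degree_rank(shuf, c("C", "L1", "L2", "L3", "L4")), r)
})

test_that("axis search finds single paths and honors the expression filter", {
  net <- signaling_network(
    nodes = data.frame(symbol = c("R", "S", "T"),
                       roles = c("receptor", "signaling_protein", "TF")),
    edges = data.frame(source = c("R", "S"), target = c("S", "T")))
  pr <- make_pair("L", "R")
  ax <- infer_axes(pr, net, c("R", "S", "T"), "T")
  expect_equal(nrow(ax), 1L)
  expect_equal(ax$path, "L-R-S-T")
  expect_equal(ax$intermediates, "S")
  expect_equal(ax$tf, "T")

  # unexpressed intermediate blocks the path
  expect_equal(nrow(infer_axes(pr, net, c("R", "T"), "T")), 0L)
  # TF not upregulated blocks the path
  expect_equal(nrow(infer_axes(pr, net, c("R", "S", "T"), character(0))),
               0L)
  # receptor missing from the network is skipped and reported
  pr2 <- make_pair("L", "NOTHERE")
  ax2 <- infer_axes(pr2, net, c("R", "S", "T"), "T")
  expect_equal(nrow(ax2), 0L)
  expect_equal(attr(ax2, "skipped_receptors"), "NOTHERE")
  expect_error(infer_axes(pr, net, "R", "T", max_intermediates = -1),
               ">= 0")
})

test_that("the activin cascade yields exactly its four enumerated axes", {
  net <- default_network_fixture()
  pairs <- rbind(make_pair("INHBA", "ACVR2A"), make_pair("INHBA", "ACVR2B"))
  pairs <- paircomm:::as_crosstalk_pairs(pairs)
  expressed <- net$nodes$symbol
  ax <- infer_axes(pairs, net, expressed, "SMAD3")
  expect_equal(nrow(ax), 4L)
  expect_setequal(ax$path, c("INHBA-ACVR2A-ACVR1-SMAD3",
                             "INHBA-ACVR2A-ACVR1B-SMAD3",
                             "INHBA-ACVR2B-ACVR1-SMAD3",
                             "INHBA-ACVR2B-ACVR1B-SMAD3"))
  # matches exhaustive enumeration from each receptor
  for (rec in c("ACVR2A", "ACVR2B")) {
    want <- paths_brute(net$edges, rec, "SMAD3", expressed, 3)
    got <- sub("^INHBA-", "", ax$path[ax$receptor == rec])
    expect_setequal(got, want)
  }
})

test_that("axis search equals brute-force enumeration on random graphs", {
  set.seed(62)
  for (i in 1:40) {
    edges <- random_edges(15, 30)
    syms <- sprintf("N%02d", 1:15)
    roles <- sample(c("receptor", "signaling_protein", "TF"), 15, TRUE)
    net <- signaling_network(data.frame(symbol = syms, roles = roles),
                             edges)
    rec <- sample(syms, 1)
    tf_syms <- syms[roles == "TF"]
    up_tfs <- sample(syms, 5)
    expressed <- sample(syms, 12)
    depth <- sample(0:3, 1)
    pr <- make_pair("LIG", rec)
    ax <- infer_axes(pr, net, expressed, up_tfs,
                     max_intermediates = depth)
    targets <- setdiff(intersect(intersect(tf_syms, up_tfs), expressed),
                       rec)
    want <- if (rec %in% expressed)
      paths_brute(edges, rec, targets, expressed, depth) else character(0)
    expect_setequal(sub("^LIG-", "", ax$path), want)
  }
})

test_that("deeper searches only add axes", {
  set.seed(63)
  edges <- random_edges(12, 30)
  syms <- sprintf("N%02d", 1:12)
  net <- signaling_network(data.frame(symbol = syms, roles = "TF"), edges)
  pr <- make_pair("LIG", syms[1])
  prev <- character(0)
  for (depth in 0:4) {
    ax <- infer_axes(pr, net, syms, syms, max_intermediates = depth)
    expect_true(all(prev %in% ax$path))
    prev <- ax$path
  }
})

test_that("hypergeometric enrichment matches the combinatorial tail", {
  u <- sprintf("G%02d", 1:10)
  res <- hypergeom_enrich(u[1:5], u, list(hit = u[1:5]))
  expect_equal(res$overlap, 5L)
  expect_equal(res$p, 1 / choose(10, 5))
  # query == set == universe has p = 1
  res2 <- hypergeom_enrich(u, u, list(all = u))
  expect_equal(res2$p, 1)
  expect_error(hypergeom_enrich("X", u, list(a = u)), "subset")
  expect_error(hypergeom_enrich("A", character(0), list(a = "A")), "empty")

  set.seed(64)
  for (i in 1:40) {
    N <- sample(8:20, 1)
    uni <- sprintf("G%02d", 1:N)
    query <- sample(uni, sample(2:N, 1))
    sets <- list(s1 = sample(uni, sample(1:N, 1)),
                 s2 = sample(uni, sample(1:N, 1)))
    res <- hypergeom_enrich(query, uni, sets)
    for (term in c("s1", "s2")) {
      row <- res[res$term == term, ]
      expect_equal(row$p,
                   hyper_tail_brute(row$overlap, row$set_size, N,
                                    length(query)),
                   tolerance = 1e-12)
    }
    expect_equal(res$padj, bh_brute(res$p))
  }
})
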