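test_that("communication score is the product of linear fold changes", {
  expect_equal(communication_score(2, 3), 6)
  expect_equal(communication_score(1, 1), 1)
  expect_equal(communication_score(2^1.5, 2^0.5), 4)  # 2^(sum of log2 FCs)
  expect_error(communication_score(-1, 2), "positive")
  expect_error(communication_score(2, 0), "positive")
})

test_that("strategy 1 pairs up-ligands with up-receptors across contrasts", {
  db <- lr_database(c("IL6", "LEP"), c("EGFR", "LEPR"))
  dpc <- make_contrast(up = "IL6", contrast = c("DPCsCO", "DPC"),
                       cells = c("DPC", "DPC"), cultures = c("co", "mono"))
  hmc <- make_contrast(up = "EGFR", contrast = c("HMCsCO", "HMC"),
                       cells = c("HMC", "HMC"), cultures = c("co", "mono"))
  p <- pairs_strategy1(dpc, hmc, db)
  expect_equal(nrow(p), 1L)
  expect_equal(p$ligand, "IL6")
  expect_equal(p$receptor, "EGFR")
  expect_equal(p$mode, "paracrine")
  expect_equal(p$cs, p$fc_ligand * p$fc_receptor)

  # autocrine when the same contrast plays both roles
  dpc2 <- make_contrast(up = c("IL6", "EGFR"), contrast = c("DPCsCO", "DPC"),
                        cells = c("DPC", "DPC"), cultures = c("co", "mono"))
  pa <- pairs_strategy1(dpc2, dpc2, db)
  expect_equal(pa$mode, "autocrine")

  # empty receiver up-set yields no pairs
  hmc0 <- make_contrast(contrast = c("HMCsCO", "HMC"),
                        cells = c("HMC", "HMC"), cultures = c("co", "mono"))
  expect_equal(nrow(pairs_strategy1(dpc, hmc0, db)), 0L)

  # mis-oriented contrast is rejected
  flipped <- make_contrast(up = "IL6", contrast = c("DPC", "DPCsCO"),
                           cells = c("DPC", "DPC"),
                           cultures = c("mono", "co"))
  expect_error(pairs_strategy1(flipped, hmc, db), "cocultured over")
})

test_that("strategy 2 splits one between-coculture contrast into sides", {
  db <- lr_database(c("LEP", "IL1A"), c("LEPR", "IL1R1"))
  # up side = HMC, down side = DPC
  res <- make_contrast(up = "IL1A", down = c("LEP", "LEPR", "IL1R1"),
                       lfc_up = 3, lfc_down = -2,
                       contrast = c("HMCsCO", "DPCsCO"),
                       cells = c("HMC", "DPC"), cultures = c("co", "co"))
  auto <- pairs_strategy2(res, db, "DPC", "DPC")
  expect_equal(auto$ligand, "LEP")
  expect_equal(auto$mode, "autocrine")
  expect_equal(auto$fc_ligand, 4)     # magnitude 2^|-2|
  para <- pairs_strategy2(res, db, "HMC", "DPC")
  expect_equal(para$ligand, "IL1A")
  expect_equal(para$receptor, "IL1R1")
  expect_equal(para$cs, 2^3 * 2^2)
  expect_error(pairs_strategy2(res, db, "DPC", "XXX"), "sender/receiver")
  mono <- make_contrast(up = "IL1A", contrast = c("HMCsCO", "HMC"),
                        cells = c("HMC", "HMC"), cultures = c("co", "mono"))
  expect_error(pairs_strategy2(mono, db, "HMC", "DPC"), "two cocultured")
})

test_that("both strategies match a brute-force double loop on random inputs", {
  set.seed(51)
  for (i in 1:60) {
    pool <- sprintf("G%02d", 1:40)
    db <- lr_database(sample(pool, 25, TRUE), sample(pool, 25, TRUE))
    up_s <- sample(pool, 12)
    up_r <- sample(pool, 12)
    lfc_s <- setNames(round(runif(12, 1, 4), 3), up_s)
    lfc_r <- setNames(round(runif(12, 1, 4), 3), up_r)
    sender <- make_contrast(up = up_s, lfc_up = unname(lfc_s),
                            contrast = c("DPCsCO", "DPC"),
                            cells = c("DPC", "DPC"),
                            cultures = c("co", "mono"))
    receiver <- make_contrast(up = up_r, lfc_up = unname(lfc_r),
                              contrast = c("HMCsCO", "HMC"),
                              cells = c("HMC", "HMC"),
                              cultures = c("co", "mono"))
    got <- pairs_strategy1(sender, receiver, db)
    want <- pairs_brute(lfc_s, lfc_r, db)
    expect_setequal(paste(got$ligand, got$receptor),
                    paste(want$ligand, want$receptor))
    if (nrow(got)) {
      key <- paste(got$ligand, got$receptor)
      expect_equal(got$cs, want$cs[match(key, paste(want$ligand,
                                                    want$receptor))])
      # every pair exists in the database
      expect_true(all(key %in% paste(db$pairs$ligand, db$pairs$receptor)))
    }

    # strategy 2 on a random two-sided contrast
    both <- make_contrast(up = up_s, down = up_r[!(up_r %in% up_s)],
                          lfc_up = unname(lfc_s),
                          lfc_down = -unname(lfc_r[!(up_r %in% up_s)]),
                          contrast = c("HMCsCO", "DPCsCO"),
                          cells = c("HMC", "DPC"), cultures = c("co", "co"))
    got2 <- pairs_strategy2(both, db, "HMC", "DPC")
    dn <- up_r[!(up_r %in% up_s)]
    want2 <- pairs_brute(lfc_s, setNames(unname(lfc_r[dn]), dn), db)
    expect_setequal(paste(got2$ligand, got2$receptor),
                    paste(want2$ligand, want2$receptor))
  }
})

test_that("pair ranking is by CS descending with lexicographic ties", {
  p <- paircomm:::as_crosstalk_pairs(data.frame(
    ligand = c("B", "A", "C"), receptor = c("Y", "X", "Z"),
    sender = "DPC", receiver = "DPC", mode = "autocrine", strategy = 1L,
    fc_ligand = 1, fc_receptor = 1, cs = c(2, 2, 6),
    stringsAsFactors = FALSE))
  r <- rank_pairs(p)
  expect_equal(r$ligand, c("C", "A", "B"))

  set.seed(52)
  n <- 100
  big <- paircomm:::as_crosstalk_pairs(data.frame(
    ligand = sample(LETTERS, n, TRUE), receptor = sample(LETTERS, n, TRUE),
    sender = "DPC", receiver = "DPC", mode = "autocrine", strategy = 1L,
    fc_ligand = 1, fc_receptor = 1,
    cs = sample(round(runif(20, 1, 50)), n, TRUE),
    stringsAsFactors = FALSE))
  r2 <- rank_pairs(big)
  want <- big[order(-big$cs, big$ligand, big$receptor), ]
  expect_equal(as.data.frame(r2), as.data.frame(want), ignore_attr = TRUE)
})

test_that("CS is bilinear: doubling both fold changes multiplies CS by 4", {
  db <- lr_database("IL6", "EGFR")
  mk <- function(lfc) {
    s <- make_contrast(up = "IL6", lfc_up = lfc,
                       contrast = c("DPCsCO", "DPC"),
                       cells = c("DPC", "DPC"), cultures = c("co", "mono"))
    r <- make_contrast(up = "EGFR", lfc_up = lfc,
                       contrast = c("DPCsCO", "DPC"),
                       cells = c("DPC", "DPC"), cultures = c("co", "mono"))
    pairs_strategy1(s, r, db)$cs
  }
  expect_equal(mk(2), mk(1) * 4)
})
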