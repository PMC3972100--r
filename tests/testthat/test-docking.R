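test_that("score-table backend replays injected scores and flags absences", {
  tab <- data.frame(ligand_id = "L1", pdb_id = "1N5U", site = "site_II",
                    score = -9.5)
  be <- scoreTableBackend(tab)
  hit <- be$dock("L1", "1N5U", "site_II")
  expect_equal(hit$score, -9.5)
  expect_equal(hit$status, "ok")
  miss <- be$dock("L2", "1N5U", "site_II")
  expect_equal(miss$status, "failed")
  expect_true(is.na(miss$score))
})

test_that("wide score tables with <pdbid>:<site> columns are accepted", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ligand_id\t2BXP:site_I\t1N5U:site_II",
               "a\t-10.5\t-7.25", "b\t-3\t-4"), f)
  be <- scoreTableBackend(f)
  expect_equal(be$dock("a", "2BXP", "site_I")$score, -10.5)
  expect_equal(be$dock("b", "1N5U", "site_II")$score, -4)
})

test_that("a missing external engine yields failed status, not an error", {
  be <- commandBackend("no-such-docking-engine-on-path",
                       argsFun = function(...) character(0))
  r <- be$dock("L1", "1N5U", "site_I")
  expect_equal(r$status, "failed")
  expect_match(r$message, "not available")
})

test_that("docking ten structures against both sites gives 20 predictions", {
  dex <- dockingExperimentFromTable(fullGridResults(score = -8))
  expect_s4_class(dex, "DockingExperiment")
  agg <- suppressMessages(aggregateBest(dex))
  expect_equal(agg$n_predictions, 20L)
  expect_equal(agg$best_overall, -8)
})

test_that("aggregation takes per-site and overall minima", {
  res <- data.frame(ligand_id = "L1",
                    pdb_id = c("1N5U", "2BXP", "3A73"),
                    site = c("site_I", "site_II", "site_I"),
                    score = c(-3.0, -7.2, -5.1))
  agg <- aggregateBest(dockingExperimentFromTable(res))
  expect_equal(agg$best_overall, -7.2)
  expect_equal(agg$best_site_I, -5.1)
  expect_equal(agg$best_site_II, -7.2)
  expect_true(agg$best_overall <= agg$best_site_I)
  expect_true(agg$best_overall <= agg$best_site_II)
})

test_that("a single result is its own best", {
  res <- data.frame(ligand_id = "L1", pdb_id = "1N5U", site = "site_I",
                    score = -4.2)
  agg <- aggregateBest(dockingExperimentFromTable(res))
  expect_equal(agg$best_overall, -4.2)
  expect_equal(agg$n_predictions, 1L)
})

test_that("aggregation is permutation-invariant and monotone under min", {
  set.seed(11)
  base <- fullGridResults(score = NA)
  base$score <- round(stats::rnorm(nrow(base), -8, 3), 3)
  ref <- suppressMessages(aggregateBest(dockingExperimentFromTable(base)))
  for (k in 1:5) {
    perm <- base[sample(nrow(base)), ]
    agg <- suppressMessages(aggregateBest(dockingExperimentFromTable(perm)))
    expect_equal(agg$best_overall, ref$best_overall)
    expect_equal(agg$best_site_I, ref$best_site_I)
    expect_equal(agg$best_site_II, ref$best_site_II)
  }
  ## adding one more result can never raise the minimum
  extra <- rbind(base, data.frame(ligand_id = "L1", pdb_id = "9XYZ",
                                  site = "site_I", score = 5))
  agg2 <- suppressMessages(aggregateBest(dockingExperimentFromTable(extra)))
  expect_lte(agg2$best_overall, ref$best_overall)
})

test_that("failed results never contribute to minima", {
  res <- data.frame(ligand_id = c("L1", "L1", "L2"),
                    pdb_id = c("1N5U", "2BXP", "1N5U"),
                    site = c("site_I", "site_I", "site_II"),
                    score = c(-3, -99, NA),
                    status = c("ok", "failed", "failed"))
  agg <- suppressMessages(aggregateBest(dockingExperimentFromTable(res)))
  expect_equal(agg$best_overall[agg$ligand_id == "L1"], -3)
  expect_true(is.na(agg$best_overall[agg$ligand_id == "L2"]))
  expect_equal(attr(agg, "unscored"), "L2")
})

test_that("duplicate (ligand, structure, site) results are rejected", {
  res <- data.frame(ligand_id = "L1", pdb_id = "1N5U",
                    site = c("site_I", "site_I"), score = c(-3, -4))
  expect_error(dockingExperimentFromTable(res), "unique")
})

test_that("dockLigands wires ligands, ensemble and backend together", {
  f <- extfile("synthetic_scores.tsv")
  lig <- readLigands(f, format = "score-table")
  be <- scoreTableBackend(f)
  ens <- buildEnsemble(data.frame(pdb_id = c("2BXP", "1N5U"),
                                  resolution = c(2.30, 1.90)))
  dex <- suppressMessages(
    dockLigands(lig, ens, defaultSitePockets(), be))
  expect_equal(dim(dex), c(40L, 4L))  # 2 structures x 2 sites
  agg <- suppressMessages(aggregateBest(dex))
  ## each ligand was injected with one score per site
  expect_true(all(agg$n_predictions == 2L))
  expect_equal(agg$best_overall, pmin(agg$best_site_I, agg$best_site_II))
})
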