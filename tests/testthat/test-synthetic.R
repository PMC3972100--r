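test_that("multi-source evidence is averaged unless discrepant beyond 30 %HSA", {
  d <- data.frame(ligand_id = c("a", "a", "b", "b", "c"),
                  hsa_percent = c(85, 90, 20, 60, 95),
                  source = c("s1", "s2", "s1", "s2", "s1"))
  out <- curateLigands(d)
  cur <- as.data.frame(out$curated)
  expect_equal(cur$hsa_percent_mean[cur$ligand_id == "a"], 87.5)
  expect_equal(cur$category[cur$ligand_id == "a"], "binder_site_unknown")
  ## |60 - 20| = 40 > 30: excluded
  expect_equal(cur$category[cur$ligand_id == "b"], "excluded")
  expect_equal(out$report$ligand_id, "b")
  expect_equal(out$report$difference, 40)
  ## single source: sd absent
  expect_equal(cur$n_sources[cur$ligand_id == "c"], 1)
  expect_true(is.na(cur$hsa_percent_sd[cur$ligand_id == "c"]))
})

test_that("a pairwise gap of exactly 30 is kept", {
  d <- data.frame(ligand_id = "x", hsa_percent = c(50, 80))
  cur <- as.data.frame(curateLigands(d)$curated)
  expect_false(cur$category == "excluded")
  expect_equal(cur$hsa_percent_mean, 65)
})

test_that("site evidence feeds the binder category", {
  d <- data.frame(ligand_id = c("w", "s1c", "s2c"),
                  hsa_percent = c(90, 95, 99),
                  site_evidence = c("", "site_I crystallography",
                                    "site_II displacement"))
  cur <- as.data.frame(curateLigands(d)$curated)
  expect_equal(cur$category, c("binder_site_unknown", "site_I", "site_II"))
})

test_that("curation is idempotent and conserves counts", {
  set.seed(31)
  n <- 60
  d <- data.frame(
    ligand_id = rep(sprintf("m%02d", 1:n), each = 2),
    hsa_percent = pmin(100, pmax(0, rnorm(2 * n, 60, 30))),
    source = rep(c("s1", "s2"), n))
  out <- curateLigands(d)
  cur <- as.data.frame(out$curated)
  expect_equal(nrow(cur), n)                      # kept + excluded = input
  expect_equal(sum(cur$category == "excluded"), nrow(out$report))
  ## re-curating the curated means (one source each) changes nothing
  d2 <- data.frame(ligand_id = cur$ligand_id,
                   hsa_percent = cur$hsa_percent_mean)
  cur2 <- as.data.frame(curateLigands(d2)$curated)
  expect_equal(cur2$hsa_percent_mean, cur$hsa_percent_mean)
  expect_equal(cur2$category == "excluded", rep(FALSE, n))
})

test_that("records without %HSA values are an error", {
  expect_error(curateLigands(data.frame(ligand_id = "a",
                                        hsa_percent = NA_real_)),
               "missing")
})

test_that("the strict set applies the 25/80 cutoffs with strict inequality", {
  cur <- data.frame(ligand_id = c("a", "b", "c", "d"),
                    hsa_percent_mean = c(90, 85, 10, 80))
  s <- suppressMessages(buildStrictSet(cur))
  expect_equal(attr(s, "nPos"), 2)
  expect_equal(attr(s, "nNeg"), 1)
  expect_false("d" %in% s$ligand_id)   # boundary 80 excluded
  allMid <- data.frame(ligand_id = c("x", "y"),
                       hsa_percent_mean = c(50, 60))
  expect_error(buildStrictSet(allMid), "empty strict set")
})

test_that("the generator is deterministic given a seed", {
  s <- syntheticSpec(seed = 12)
  expect_identical(generateSynthetic(s), generateSynthetic(s))
  s2 <- syntheticSpec(seed = 13)
  expect_false(identical(generateSynthetic(s), generateSynthetic(s2)))
})

test_that("generated tables have the requested composition", {
  tab <- generateSynthetic(syntheticSpec(nBinders = 40, nWeak = 15,
                                         seed = 3))
  expect_equal(sum(tab$class == "binder"), 40)
  expect_equal(sum(tab$class == "weak"), 15)
  expect_true(all(tab$hsa_percent >= 0 & tab$hsa_percent <= 100))
  expect_equal(tab$xp_score, pmin(tab$xp_site_I, tab$xp_site_II))
  ## binders sit high on the %HSA scale, weak compounds low
  expect_gt(mean(tab$hsa_percent[tab$class == "binder"]), 70)
  expect_lt(mean(tab$hsa_percent[tab$class == "weak"]), 35)
})

test_that("logP and docking score correlate weakly by construction", {
  tab <- generateSynthetic(syntheticSpec(nBinders = 1672, nWeak = 328,
                                         seed = 8))
  r2 <- cor(tab$logp, tab$xp_score)^2
  expect_gte(r2, 0.05)
  expect_lte(r2, 0.15)
})

test_that("noise-free tables return the generating model exactly", {
  tab <- generateSynthetic(syntheticSpec(noiseSd = 0, seed = 21))
  f <- fitCombined(tab$xp_score, tab$logp, tab$hsa_percent, nBoot = 0)
  expect_equal(unname(coef(f)), c(25.41, -1.95, 7.68), tolerance = 1e-8)
})

test_that("site II compounds receive systematically better site II scores", {
  tab <- generateSynthetic(syntheticSpec(nBinders = 300, nWeak = 60,
                                         seed = 14))
  d <- tab$xp_site_II - tab$xp_site_I
  expect_lt(mean(d[tab$site == "site_II"]), mean(d[tab$site == "site_I"]))
  expect_lt(mean(d[tab$site == "site_II"]), -2)
})

test_that("infeasible generator specs are rejected", {
  expect_error(syntheticSpec(targetR2 = 1), "targetR2")
  ## balanced classes separate the predictors so strongly that a pooled
  ## correlation of zero cannot be reached by any within-class correlation
  expect_error(generateSynthetic(syntheticSpec(nBinders = 10, nWeak = 10,
                                               targetR2 = 0)),
               "infeasible")
})

test_that("synthetic tables round-trip through the score-table format", {
  tab <- generateSynthetic(syntheticSpec(nBinders = 12, nWeak = 3,
                                         seed = 6))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSyntheticScoreTable(tab, f)
  lig <- readLigands(f, format = "score-table")
  expect_length(lig, 15)
  expect_equal(unname(logP(lig)), tab$logp, tolerance = 1e-12)
  be <- scoreTableBackend(f)
  expect_equal(be$dock(tab$ligand_id[1], "0SYN", "site_I")$score,
               tab$xp_site_I[1], tolerance = 1e-12)
})
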