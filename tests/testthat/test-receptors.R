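test_that("default pockets carry the published site geometry", {
  p <- defaultSitePockets()
  expect_equal(p$site_I@centroid, c(30.5, 13.1, 9.7))
  expect_equal(p$site_II@centroid, c(10.25, 2.11, -13.75))
  expect_equal(p$site_I@innerBox, 10)
  expect_equal(p$site_I@outerBox, 30)
  expect_identical(loadSiteDefinitions(NULL), p)
})

test_that("an empty config yields the two default pockets", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines("# nothing here", f)
  p <- loadSiteDefinitions(f)
  expect_named(p, c("site_I", "site_II"))
  expect_equal(p$site_I@centroid, c(30.5, 13.1, 9.7))
})

test_that("site config round-trips losslessly", {
  f <- withr::local_tempfile(fileext = ".cfg")
  p <- loadSiteDefinitions(NULL)
  p$extra_heme <- new("SitePocket", siteName = "extra_heme",
                      centroid = c(1.5, -2.25, 3), innerBox = 8,
                      outerBox = 24)
  writeSiteDefinitions(p, f)
  q <- loadSiteDefinitions(f)
  for (nm in names(p)) {
    expect_equal(q[[nm]]@centroid, p[[nm]]@centroid)
    expect_equal(q[[nm]]@innerBox, p[[nm]]@innerBox)
    expect_equal(q[[nm]]@outerBox, p[[nm]]@outerBox)
  }
})

test_that("invalid site configs are rejected", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines("site_I inner_box 40", f)  # default outer stays 30
  expect_error(loadSiteDefinitions(f), "inner_box > outer_box")
  writeLines("site_Q centroid 0 0 0", f)
  expect_error(loadSiteDefinitions(f), "unknown site name")
})

test_that("the default ensemble lists ten structures sorted by resolution", {
  e <- ensembleEntries(buildEnsemble())
  expect_equal(nrow(e), 10)
  expect_equal(e$pdb_id[1], "1N5U")
  expect_equal(e$resolution[1], 1.90)
  expect_false(is.unsorted(e$resolution))
  expect_setequal(e$pdb_id,
                  c("1N5U", "3A73", "1E7A", "2BXH", "2BXP", "3JRY", "2BXA",
                    "1E7B", "2XW0", "1HK4"))
})

test_that("the reduced model is 2BXP + 1N5U with the fatty acid in 1N5U", {
  e <- ensembleEntries(buildEnsemble(reduced = TRUE))
  expect_setequal(e$pdb_id, c("2BXP", "1N5U"))
  expect_true(e$fatty_acid_retained[e$pdb_id == "1N5U"])
  expect_false(e$fatty_acid_retained[e$pdb_id == "2BXP"])
})

test_that("degenerate ensembles are rejected", {
  expect_error(buildEnsemble(data.frame()), "empty ensemble")
  dup <- data.frame(pdb_id = c("1N5U", "1N5U"), resolution = c(1.9, 2.0))
  expect_error(buildEnsemble(dup), "duplicate")
  bad <- data.frame(pdb_id = "XY", resolution = 2.0)
  expect_error(buildEnsemble(bad), "malformed|invalid")
  neg <- data.frame(pdb_id = "1ABC", resolution = -1)
  expect_error(buildEnsemble(neg), "resolution")
})

test_that("ensemble manifests round-trip through serialization", {
  f <- withr::local_tempfile(fileext = ".tsv")
  e <- buildEnsemble(reduced = TRUE)
  writeEnsembleManifest(e, f)
  e2 <- buildEnsemble(f)
  expect_equal(as.data.frame(ensembleEntries(e2)),
               as.data.frame(ensembleEntries(e)))
})

test_that("ensemble construction is invariant to entry ordering", {
  ent <- as.data.frame(ensembleEntries(buildEnsemble()))
  set.seed(4)
  shuffled <- ent[sample(nrow(ent)), c("pdb_id", "resolution")]
  expect_equal(as.data.frame(ensembleEntries(buildEnsemble(shuffled))),
               as.data.frame(ensembleEntries(
                 buildEnsemble(ent[, c("pdb_id", "resolution")]))))
})
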