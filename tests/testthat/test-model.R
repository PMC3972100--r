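test_that("the combined score reproduces the published arithmetic", {
  m <- defaultCombinedModel()
  expect_equal(combinedScore(m, 0, 0), 25.41)
  expect_equal(combinedScore(m, -12.33, 2.0), 64.8135)
  z <- CombinedModel(0, 0, 0)
  expect_equal(combinedScore(z, -12, 3.7), 0)
  expect_error(combinedScore(m, NA, 1), "non-finite")
})

test_that("the combined score is affine and monotone in its inputs", {
  m <- defaultCombinedModel()
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20); lp <- rnorm(20)
  ## affine: the increment depends only on the increment of the input
  expect_equal(combinedScore(m, a + b, lp) - combinedScore(m, a, lp),
               m@alpha * b)
  ## beta > 0: higher logP raises the score at fixed docking score
  expect_true(all(combinedScore(m, a, lp + 1) > combinedScore(m, a, lp)))
  ## alpha < 0: a more negative docking score raises the score
  expect_true(all(combinedScore(m, a - 1, lp) > combinedScore(m, a, lp)))
})

test_that("noise-free data from known coefficients are recovered exactly", {
  set.seed(42)
  xp <- rnorm(50, -10, 4); lp <- rnorm(50, 2, 1.5)
  y <- 25.41 - 1.95 * xp + 7.68 * lp
  f <- fitCombined(xp, lp, y, nBoot = 0)
  expect_equal(unname(coef(f)), c(25.41, -1.95, 7.68), tolerance = 1e-10)
})

test_that("coefficient bias shrinks as n grows", {
  set.seed(7)
  err <- sapply(c(50, 500), function(n) {
    est <- replicate(40, {
      xp <- rnorm(n, -10, 4); lp <- rnorm(n, 2, 1.5)
      y <- 25.41 - 1.95 * xp + 7.68 * lp + rnorm(n, 0, 10)
      coef(fitCombined(xp, lp, y, nBoot = 0))
    })
    mean(abs(rowMeans(est) - c(25.41, -1.95, 7.68)))
  })
  expect_lt(err[2], err[1])
})

test_that("bootstrap intervals are seeded, reproducible, and cover the truth", {
  tab <- generateSynthetic(syntheticSpec(nBinders = 167, nWeak = 33,
                                         noiseSd = 0, seed = 5))
  set.seed(81)
  y <- tab$hsa_percent + rnorm(nrow(tab), 0, 10)
  f1 <- fitCombined(tab$xp_score, tab$logp, y, nBoot = 500, seed = 9)
  f2 <- fitCombined(tab$xp_score, tab$logp, y, nBoot = 500, seed = 9)
  expect_identical(f1@fitMeta$ci, f2@fitMeta$ci)
  ci <- f1@fitMeta$ci
  truth <- c(25.41, -1.95, 7.68)
  expect_true(all(truth >= ci[, 1] & truth <= ci[, 2]))
})

test_that("degenerate fits are rejected", {
  expect_error(fitCombined(1:2, 1:2, 1:2), "at least 3")
  expect_error(fitCombined(c(1, 2, 3), c(2, 4, 6), c(1, 1, 2)),
               "collinear")
})

test_that("model serialization round-trips", {
  f <- withr::local_tempfile(fileext = ".txt")
  m <- CombinedModel(12.5, -0.75, 3.25)
  writeCombinedModel(m, f)
  m2 <- readCombinedModel(f)
  expect_equal(coef(m2), coef(m))
})

test_that("%HSA / fraction-bound conversions are exact", {
  expect_equal(fbFromPercent(25), 0.25)
  expect_equal(fbFromPercent(0), 0)
  expect_equal(percentFromFb(1), 100)
  expect_error(fbFromPercent(101), "\\[0, 100\\]")
  expect_error(percentFromFb(-0.1), "\\[0, 1\\]")
})

test_that("the single-site isotherm inverts correctly at 0.6 mM albumin", {
  expect_equal(kaFromFb(0), 0)
  expect_equal(kaFromFb(0.5), 1 / 6e-4)          # ~1666.7 per molar
  expect_equal(kiFromKa(kaFromFb(0.5)), 6e-4)
  for (x in c(0.1, 0.25, 0.8, 0.99)) {
    expect_equal(fbFromKa(kaFromFb(x)), x)
    ka <- kaFromFb(x)
    expect_equal(kaFromKi(kiFromKa(ka)), ka)
    expect_equal(ka * kiFromKa(ka), 1)
  }
  expect_error(kaFromFb(1), "\\[0, 1\\)")
  expect_error(kaFromFb(0.5, albuminConc = 0), "positive")
})

test_that("binder classification uses strict cutoffs and flags boundaries", {
  expect_equal(as.character(classifyBinder(c(10, 85, 50))),
               c("weak", "binder", "intermediate"))
  expect_message(cls <- classifyBinder(c(25, 80)), "boundary")
  expect_equal(as.character(cls), c("intermediate", "intermediate"))
  expect_error(classifyBinder(120), "\\[0, 100\\]")
})

test_that("site preference derives from the site II minus site I difference", {
  es <- S4Vectors::DataFrame(ligand_id = c("a", "b", "c"),
                             best_site_I = c(-10, -12, -6),
                             best_site_II = c(-10, -8, NA))
  sp <- sitePreference(es, threshold = 2)
  expect_equal(sp$delta, c(0, 4, NA))
  expect_equal(as.character(sp$predicted_site),
               c("site_I", "site_II", "indeterminate"))
  ## a large negative gap (site II much better) is a site II call
  es2 <- S4Vectors::DataFrame(ligand_id = "d", best_site_I = -8,
                              best_site_II = -13)
  expect_equal(as.character(sitePreference(es2)$predicted_site), "site_II")
})
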