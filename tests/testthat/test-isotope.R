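test_that("isotopologue fractions normalize peak areas", {
  t1 <- isotopologueTable(c(40, 0, 0, 0, 0, 0, 60))
  expect_equal(unname(isotopologueFractions(t1)),
               c(0.4, 0, 0, 0, 0, 0, 0.6))
  expect_named(isotopologueFractions(t1),
               paste0("M+", 0:6))
  t2 <- isotopologueTable(c(0, 5))
  expect_equal(unname(isotopologueFractions(t2)), c(0, 1))
  expect_error(isotopologueTable(c(0, 0)), "positive")
  expect_error(isotopologueTable(5), "M\\+1")
})

test_that("label ratio modes agree with hand-computed values", {
  t1 <- isotopologueTable(c(40, 0, 0, 0, 0, 0, 60))
  expect_equal(labelRatio(t1, "all-labeled"), 1.5)
  expect_equal(labelRatio(t1, "m6-only"), 1.5)
  t2 <- isotopologueTable(c(40, 10, 0, 0, 0, 0, 50))
  expect_equal(labelRatio(t2, "all-labeled"), 1.5)
  expect_equal(labelRatio(t2, "m6-only"), 1.25)
  expect_equal(labelRatio(isotopologueTable(c(100, 0))), 0)
  expect_error(labelRatio(isotopologueTable(c(0, 10))), "M\\+0")
  expect_error(labelRatio(isotopologueTable(c(10, 5)), "m6-only"), "M\\+6")
  # consistency with fractions: ratio_all = (1 - f0)/f0
  f <- isotopologueFractions(t2)
  expect_equal(labelRatio(t2, "all-labeled"), (1 - f[[1]]) / f[[1]])
  # area scale invariance
  t2s <- isotopologueTable(7.3 * c(40, 10, 0, 0, 0, 0, 50))
  expect_equal(labelRatio(t2s, "all-labeled"), labelRatio(t2, "all-labeled"))
  expect_equal(isotopologueFractions(t2s), isotopologueFractions(t2))
})

test_that("generator truth is recovered from synthetic tables", {
  truth <- c(0.37, rep(0.01, 5), 0.58)   # M+0, M+1..5, M+6
  tabs <- genIsotopologueTables(truth, cv = 0.1, nSamples = 200, seed = 42)
  m6 <- vapply(tabs, function(t) isotopologueFractions(t)[[7]], numeric(1))
  se <- sd(m6) / sqrt(length(m6))
  expect_lt(abs(mean(m6) - 0.58), 2 * se + 1e-12)
  # cv = 0 reproduces the truth exactly
  exact <- genIsotopologueTables(truth, cv = 0, nSamples = 3, seed = 1)
  for (t in exact)
    expect_equal(unname(isotopologueFractions(t)), truth, tolerance = 1e-12)
  # determinism
  again <- genIsotopologueTables(truth, cv = 0.1, nSamples = 5, seed = 42)
  expect_identical(lapply(again, function(t) t@areas),
                   lapply(genIsotopologueTables(truth, 0.1, 5, 42),
                          function(t) t@areas))
})

test_that("enrichment summary tests two groups with Bonferroni threshold", {
  lo <- genIsotopologueTables(c(0.45, rep(0.01, 5), 0.50), cv = 0.05,
                              nSamples = 3, seed = 1, group = "carrier")
  hi <- genIsotopologueTables(c(0.30, rep(0.01, 5), 0.65), cv = 0.05,
                              nSamples = 3, seed = 2, group = "cured")
  res <- summarizeEnrichment(c(lo, hi), nTests = 2)
  expect_equal(nrow(res), 1)
  expect_equal(res$alpha_critical, 0.025)
  # carrier line has the lower 13C/12C ratio (more unlabeled synthesis)
  expect_lt(res$mean1, res$mean2)
  expect_lt(res$t, 0)
  # identical groups give t = 0
  same1 <- genIsotopologueTables(c(0.4, rep(0, 5), 0.6), cv = 0,
                                 nSamples = 3, seed = 1, group = "g1")
  same2 <- genIsotopologueTables(c(0.4, rep(0, 5), 0.6), cv = 0,
                                 nSamples = 3, seed = 2, group = "g2")
  res0 <- summarizeEnrichment(c(same1, same2))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  # pairwise design only
  extra <- genIsotopologueTables(c(0.4, rep(0, 5), 0.6), cv = 0,
                                 nSamples = 2, seed = 3, group = "g3")
  expect_error(summarizeEnrichment(c(same1, same2, extra)), "pairwise")
  # single replicate refused
  one <- genIsotopologueTables(c(0.4, rep(0, 5), 0.6), cv = 0,
                               nSamples = 1, seed = 4, group = "g9")
  expect_error(summarizeEnrichment(c(same1, one)), "single replicate")
})

test_that("isotopologue TSV round-trips", {
  tabs <- genIsotopologueTables(c(0.4, 0.1, 0.5), cv = 0.2, nSamples = 4,
                                seed = 7, group = "grp")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeIsotopologueTables(tabs, path)
  back <- readIsotopologueTables(path)
  expect_equal(length(back), 4)
  expect_equal(back[[2]]@areas, tabs[[2]]@areas, tolerance = 1e-6)
  expect_equal(back[[3]]@group, "grp")
})
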