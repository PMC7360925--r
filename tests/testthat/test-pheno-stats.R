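test_that("pooled t from summaries matches the raw-sample pooled t for equal n", {
  # the published r_m comparison: 0.351 +- 0.005 vs 0.347 +- 0.010, n = 10
  res <- pooledTSummary(groupSummary(0.351, 0.005, 10),
                        groupSummary(0.347, 0.010, 10))
  expect_equal(res$statistic, 0.3577709, tolerance = 1e-6)
  expect_equal(res$df, 18)
  expect_gt(res$p, 0.7)
  # identical summaries
  same <- pooledTSummary(groupSummary(1, 0.1, 5), groupSummary(1, 0.1, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_equal(pooledTSummary(groupSummary(2, 0, 4), groupSummary(2, 0, 4))$statistic, 0)
  expect_error(pooledTSummary(groupSummary(1, 0, 4), groupSummary(2, 0, 4)),
               "infinite")
  # brute-force identity against t.test on raw samples (equal n)
  for (seed in 1:5) {
    x <- genPerformanceSamples(0.35, 0.02, 10, seed)
    y <- genPerformanceSamples(0.34, 0.03, 10, seed + 100)
    direct <- t.test(x, y, var.equal = TRUE)
    via_summary <- pooledTSummary(summarizeSamples(x), summarizeSamples(y))
    expect_equal(via_summary$statistic, unname(direct$statistic),
                 tolerance = 1e-12)
    expect_equal(via_summary$p, direct$p.value, tolerance = 1e-12)
  }
})

test_that("Benjamini-Hochberg adjustment matches hand-computed step-up values", {
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(c(0.005, 0.03, 0.5)), c(0.015, 0.045, 0.5))
  # order-preserving with input, monotone when sorted, max preserved
  p <- c(0.5, 0.005, 0.03)
  expect_equal(bhAdjust(p), c(0.5, 0.015, 0.045))
  ps <- sort(runif(20))
  expect_true(all(diff(bhAdjust(ps)) >= 0))
  expect_equal(max(bhAdjust(ps)), max(ps))
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("performance metrics follow their defining formulas", {
  expect_equal(relativeGrowthRate(2, 2), 0)
  expect_equal(relativeGrowthRate(1, 2), log(2) / 5, tolerance = 1e-9)
  expect_equal(relativeGrowthRate(1, 2), 0.13863, tolerance = 1e-4)
  expect_equal(relativeGrowthRate(3 * 1, 3 * 2), relativeGrowthRate(1, 2))
  expect_error(relativeGrowthRate(-1, 2), "positive")
  expect_equal(intrinsicRate(1, 9), 0)
  expect_equal(intrinsicRate(50, 9), 0.745 * log(50) / 9)
  expect_equal(intrinsicRate(50, 9), 0.3238, tolerance = 1e-3)
  expect_equal(intrinsicRate(50, 18), intrinsicRate(50, 9) / 2)
  expect_error(intrinsicRate(0.5, 9), ">= 1")
})

test_that("rank-sum alternative and advisory checks are explicit, never automatic", {
  x <- genPerformanceSamples(0.35, 0.02, 12, 1)
  y <- x + 0.5
  rs <- rankSumTest(x, y)
  expect_identical(rs$method, "mann-whitney")
  expect_lt(rs$p, 0.01)
  expect_equal(rankSumTest(x, x)$p, 1, tolerance = 1e-9)
  adv <- checkDistributionAssumptions(x, y)
  expect_equal(adv$check, c("shapiro_group1", "shapiro_group2", "bartlett"))
  expect_true(all(adv$p >= 0 & adv$p <= 1))
})

test_that("planted status effects survive the two-stage screen, constants are skipped", {
  eff <- rep(0, 40); eff[7] <- 3
  sim <- genMetabolomicsMatrix(nFeatures = 40, nGenotypes = 6, nReps = 5,
                               genotypeSd = 0.3, statusEffects = eff,
                               noiseSd = 0.3, seed = 11)
  sim$matrix[3, ] <- 5   # constant feature
  res <- metaboliteScreen(sim$matrix, sim$design)
  expect_true(res$candidate[7])
  expect_lt(res$p_adj[7], 0.05)
  expect_match(res$note[3], "constant")
  expect_true(is.na(res$t[3]))
})

test_that("screen falls back to t-only with a single genotype per level", {
  sim <- genMetabolomicsMatrix(nFeatures = 5, nGenotypes = 2, nReps = 6,
                               genotypeSd = 0, statusEffects = 0,
                               noiseSd = 0.5, seed = 3)
  expect_warning(res <- metaboliteScreen(sim$matrix, sim$design),
                 "t-only")
  expect_false(attr(res, "mixed_model"))
  cand <- which(res$candidate)
  expect_equal(res$p_mixed[cand], res$p_t[cand])
})

test_that("stage-1 type-I error is nominal on i.i.d. null data", {
  sim <- genMetabolomicsMatrix(nFeatures = 500, nGenotypes = 6, nReps = 4,
                               genotypeSd = 0, statusEffects = 0,
                               noiseSd = 0.5, seed = 5)
  res <- metaboliteScreen(sim$matrix, sim$design)
  flags <- sum(res$candidate)
  bounds <- qbinom(c(0.005, 0.995), 500, 0.05)
  expect_gte(flags, bounds[1])
  expect_lte(flags, bounds[2])
})

test_that("a typical genotype-structured null draw yields no BH-significant features", {
  # strong genotype effects, no status effect: stage 2 must absorb the
  # genotype variance and return nothing significant
  sim <- genMetabolomicsMatrix(nFeatures = 120, nGenotypes = 6, nReps = 4,
                               genotypeSd = 1, statusEffects = 0,
                               noiseSd = 0.3, seed = 8)
  res <- metaboliteScreen(sim$matrix, sim$design)
  expect_equal(sum(res$p_adj < 0.05, na.rm = TRUE), 0)
})
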