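toy <- makeToySymbiosis()

test_that("FBA reaches the closed-form maximum histidine delivery", {
  # relax the pinned host drain and maximize delivery: the PRPP uptake
  # cap (10) is the only remaining limit
  host <- toy$host
  i <- host@reactions$id == "DM_his_host"
  host@reactions$lb[i] <- 0
  host@reactions$ub[i] <- 1000
  spec <- communitySpec(host, list(Buchnera = toy$buchnera),
                        c(Buchnera = 1), medium = c(prpp = 10))
  cm <- assembleCommunity(spec, checkFeasible = FALSE)
  sol <- solveFBA(cm, c(DM_his_host__host = 1), "max")
  expect_identical(solutionStatus(sol), "optimal")
  expect_equal(objectiveValue(sol), 10, tolerance = 1e-9)
})

test_that("degenerate cases: all-zero bounds and unmet demands", {
  m0 <- organismModel("z", data.frame(id = "A", compartment = "c"),
                      data.frame(id = c("EX_A", "R"), lb = 0, ub = 0,
                                 kind = c("exchange", "internal")),
                      list(EX_A = c(A = -1), R = c(A = -1)))
  s0 <- solveFBA(m0, c(R = 1), "max")
  expect_identical(solutionStatus(s0), "optimal")
  expect_true(all(abs(fluxes(s0)) < 1e-12))
  # empty medium + positive demand is infeasible, reported as such
  spec <- communitySpec(toy$host, list(Buchnera = toy$buchnera),
                        c(Buchnera = 1), medium = numeric(0))
  cm <- assembleCommunity(spec, checkFeasible = FALSE)
  expect_identical(solutionStatus(solvePFBA(cm)), "infeasible")
  expect_error(assembleCommunity(spec), "infeasible")
})

test_that("pFBA gives the analytic fluxes and wastes no flux", {
  cm <- assembleCommunity(toy$specTwo)
  sol <- solvePFBA(cm)
  expect_equal(hisdFlux(cm, sol), 1.0, tolerance = 1e-9)
  # hand-computed minimal total flux of the default two-compartment toy:
  # uptake 1 + transport 1 + HisD 1 + purine demand 1 + His export 1 +
  # His host import 1 + host drain 1 = 7; anything above 7 contains a
  # futile cycle
  expect_equal(objectiveValue(sol), 7, tolerance = 1e-9)
  cm5 <- setBiomassRatio(assembleCommunity(toy$spec), "Hamiltonella", 5)
  s5 <- solvePFBA(cm5)
  expect_equal(hisdFlux(cm5, s5), 1.268, tolerance = 1e-9)
})

test_that("pFBA matches exhaustive active-set enumeration on small networks", {
  for (seed in 1:4) {
    net <- randomNetwork(seed, nMets = 4, nRxns = 6)
    sol <- solvePFBA(net)
    expect_identical(solutionStatus(sol), "optimal")
    expect_equal(objectiveValue(sol), oraclePFBATotalFlux(net),
                 tolerance = 1e-6, label = paste("seed", seed))
  }
  net8 <- randomNetwork(99, nMets = 5, nRxns = 8)
  sol8 <- solvePFBA(net8)
  expect_equal(objectiveValue(sol8), oraclePFBATotalFlux(net8),
               tolerance = 1e-6)
})

test_that("optimal fluxes respect bounds, scale invariance and determinism", {
  cm <- assembleCommunity(toy$spec)
  sol <- solvePFBA(cm)
  b <- reactionBounds(cm)[names(fluxes(sol)), ]
  expect_true(all(fluxes(sol) >= b[, "lb"] - 1e-6))
  expect_true(all(fluxes(sol) <= b[, "ub"] + 1e-6))
  # scale invariance: scaling all rates by k scales all fluxes by k
  k <- 3.7
  toyk <- makeToySymbiosis(toyParams(h_A = k, a = k, h_H = k * 0.0536,
                                     uptake = k * 10))
  solk <- solvePFBA(assembleCommunity(toyk$spec))
  expect_equal(fluxes(solk), k * fluxes(sol)[names(fluxes(solk))],
               tolerance = 1e-9)
  # determinism: bit-identical repeat
  expect_identical(fluxes(solvePFBA(cm)), fluxes(sol))
})

test_that("FVA brackets fluxes and widens monotonically in gamma", {
  cm <- assembleCommunity(toy$specTwo)
  fva0 <- fluxVariability(cm, c("HisD__Buchnera", "SINK_aicar__host"), gamma = 0)
  # tightly constrained: HisD flux is unique; the unused free sink is 0
  expect_equal(fva0$min, c(1, 0), tolerance = 1e-9)
  expect_equal(fva0$max, c(1, 0), tolerance = 1e-9)
  fva1 <- fluxVariability(cm, c("HisD__Buchnera", "SINK_aicar__host"), gamma = 0.1)
  expect_true(all(fva1$min <= fva0$min + 1e-9))
  expect_true(all(fva1$max >= fva0$max - 1e-9))
  expect_error(fluxVariability(cm, "no_such_rxn"), "unknown reaction")
})

test_that("checkBalance reports exactly the corrupted metabolites", {
  cm <- assembleCommunity(toy$specTwo)
  sol <- solvePFBA(cm)
  expect_equal(nrow(checkBalance(cm, sol)), 0)
  bad <- sol
  bad@fluxes[["HisD__Buchnera"]] <- bad@fluxes[["HisD__Buchnera"]] + 0.5
  rep <- checkBalance(cm, bad)
  expect_setequal(rep$metabolite,
                  c("prpp__Buchnera", "his__Buchnera", "aicar__Buchnera"))
  expect_equal(nrow(checkBalance(cm, bad, eps = Inf)), 0)
})
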