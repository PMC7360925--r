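toy <- makeToySymbiosis()

test_that("two-compartment assembly: pool wiring, tags, no Hamiltonella", {
  cm <- assembleCommunity(toy$specTwo)
  expect_s4_class(cm, "CommunityModel")
  orgs <- unique(organismOf(cm))
  expect_setequal(orgs, c("host", "Buchnera", "pool"))
  expect_false(any(grepl("Hamiltonella", reactionIds(cm))))
  # every pool transport moves the same species -1/+1
  tids <- grep("^T_", reactionIds(cm), value = TRUE)
  for (tid in tids) {
    st <- stoichiometry(cm)[[tid]]
    expect_equal(sort(unname(st)), c(-1, 1))
    base <- sub("__.*$", "", names(st))
    expect_equal(base[1], base[2])
  }
  # fixed demands are pinned demand reactions
  fd <- cm@fixedDemands
  expect_true(all(reactions(cm)$kind[match(names(fd), reactionIds(cm))] == "demand"))
  expect_equal(unname(fd[c("DM_purine__Buchnera", "DM_his_host__host")]), c(1, 1))
})

test_that("assembly errors: r = 0 rejected, missing linked met, id collision", {
  expect_error(
    communitySpec(toy$host,
                  list(Buchnera = toy$buchnera, Hamiltonella = toy$hamiltonella),
                  c(Buchnera = 1, Hamiltonella = 0),
                  medium = c(prpp = 10)),
    "r must be > 0")
  spec <- toy$spec
  spec@linkedMets <- list(Hamiltonella = c("his", "nonexistent"))
  expect_error(assembleCommunity(spec), "absent from organism 'Hamiltonella'")
  # duplicate organism id
  expect_error(
    assembleCommunity(communitySpec(toy$buchnera, list(Buchnera = toy$buchnera),
                                    c(Buchnera = 1), medium = c(prpp = 10))),
    "duplicate organism")
})

test_that("symbiont demands scale with biomass r", {
  cm <- assembleCommunity(toy$spec)        # r_H = 1
  cm5 <- setBiomassRatio(cm, "Hamiltonella", 5)
  h_H <- toy$params$h_H
  expect_equal(unname(cm5@fixedDemands["DM_his__Hamiltonella"]), 5 * h_H)
  rxn <- reactions(cm5)
  i <- rxn$id == "DM_his__Hamiltonella"
  expect_equal(rxn$lb[i], 5 * h_H)
  expect_equal(rxn$ub[i], 5 * h_H)
  # ratio endpoints of the study design
  expect_equal(parseRatio("10:1"), 0.1)
  expect_equal(parseRatio("1:5"), 5)
  # idempotence: setting the same r twice returns an identical model
  cm5b <- setBiomassRatio(cm5, "Hamiltonella", 5)
  expect_equal(cm5, cm5b)
  expect_error(setBiomassRatio(cm, "nobody", 2), "unknown organism")
  expect_error(setBiomassRatio(cm, "Hamiltonella", -1), "positive")
})

test_that("applyMedium sets uptake bounds and keeps secretion open", {
  cm <- assembleCommunity(toy$specTwo)
  rxn <- reactions(cm)
  expect_equal(rxn$lb[rxn$id == "EX_prpp__pool"], -10)
  # unlisted exchanges blocked for uptake, open for secretion
  expect_equal(rxn$lb[rxn$id == "EX_his__pool"], 0)
  expect_gt(rxn$ub[rxn$id == "EX_his__pool"], 0)
  # rate 0: uptake blocked, secretion still allowed
  cm0 <- applyMedium(cm, c(prpp = 10, his = 0))
  rxn0 <- reactions(cm0)
  expect_equal(rxn0$lb[rxn0$id == "EX_his__pool"], 0)
  expect_gt(rxn0$ub[rxn0$id == "EX_his__pool"], 0)
  expect_error(applyMedium(cm, c(unobtainium = 1)),
               "without a pool exchange")
  # starvation: empty medium makes the demands unmeetable
  cmE <- applyMedium(cm, numeric(0))
  expect_identical(solutionStatus(solvePFBA(cmE)), "infeasible")
})

test_that("scaling consistency: per-gram symbiont fluxes are invariant in r", {
  cm <- assembleCommunity(toy$spec)
  for (r in c(0.5, 2)) {
    s1 <- solvePFBA(setBiomassRatio(cm, "Hamiltonella", r))
    s2 <- solvePFBA(setBiomassRatio(cm, "Hamiltonella", 2 * r))
    f1 <- fluxes(s1)[["DM_his__Hamiltonella"]] / r
    f2 <- fluxes(s2)[["DM_his__Hamiltonella"]] / (2 * r)
    expect_equal(f1, f2, tolerance = 1e-9)
  }
})

test_that("two-compartment model equals three-compartment with symbiont removed", {
  cm2 <- assembleCommunity(toy$specTwo)
  sol2 <- solvePFBA(cm2)
  # r -> 0+ limit of the trio on shared reactions
  cm3 <- setBiomassRatio(assembleCommunity(toy$spec), "Hamiltonella", 1e-12)
  sol3 <- solvePFBA(cm3)
  shared <- intersect(names(fluxes(sol2)), names(fluxes(sol3)))
  expect_gt(length(shared), 5)
  expect_equal(fluxes(sol2)[shared], fluxes(sol3)[shared], tolerance = 1e-6)
})

test_that("community spec YAML round-trips through files", {
  dir <- withr::local_tempdir()
  writeCommunitySpec(toy$spec, dir)
  spec2 <- readCommunitySpec(file.path(dir, "community.yaml"))
  expect_equal(spec2@ratios, toy$spec@ratios)
  expect_equal(spec2@reference, "Buchnera")
  expect_equal(spec2@medium, toy$spec@medium)
  cm <- assembleCommunity(spec2)
  expect_equal(hisdFlux(cm, solvePFBA(cm)),
               toy$expected$vHis(1), tolerance = 1e-9)
})
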