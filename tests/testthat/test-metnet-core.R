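test_that("model validity rejects malformed inputs", {
  expect_error(
    organismModel("m", data.frame(id = "A", compartment = "c"),
                  data.frame(id = "R", lb = 1, ub = -1, kind = "internal"),
                  list(R = c(A = -1))),
    "lb > ub")
  expect_error(
    organismModel("m", data.frame(id = "A", compartment = "c"),
                  data.frame(id = "R", lb = 0, ub = 1, kind = "internal"),
                  list(R = c(Zz = -1))),
    "undeclared metabolite")
  expect_error(
    organismModel("m", data.frame(id = "A", compartment = "c"),
                  data.frame(id = "EX", lb = 0, ub = 1, kind = "exchange"),
                  list(EX = c(A = -1, B = 1))),
    "exactly one metabolite|undeclared")
  # empty reaction set refused
  expect_error(
    organismModel("m", data.frame(id = "A", compartment = "c"),
                  data.frame(id = character(0), lb = numeric(0),
                             ub = numeric(0), kind = character(0)),
                  list()),
    "no reactions")
  # undeclared compartment
  expect_error(
    organismModel("m", data.frame(id = "A", compartment = "q"),
                  data.frame(id = "R", lb = 0, ub = 1, kind = "internal"),
                  list(R = c(A = -1)), compartments = "c"),
    "not declared")
})

test_that("native JSON round-trip is lossless, including rational stoichiometry", {
  toy <- makeToySymbiosis()
  for (m in list(toy$buchnera, toy$host, toy$hamiltonella, tinyModel())) {
    path <- withr::local_tempfile(fileext = ".json")
    writeOrganismModel(m, path, "native-json")
    expect_modelEqual(readOrganismModel(path, "native-json"), m)
  }
  # 1/3 coefficient survives within 1e-12
  m <- organismModel("rat", data.frame(id = c("A", "B"), compartment = "c"),
                     data.frame(id = c("EX_A", "R"), lb = c(-5, 0),
                                ub = c(0, 10), kind = c("exchange", "internal")),
                     list(EX_A = c(A = -1), R = c(A = -1, B = 1 / 3)))
  path <- withr::local_tempfile(fileext = ".json")
  writeOrganismModel(m, path, "native-json")
  back <- readOrganismModel(path, "native-json")
  expect_equal(back@stoichiometry$R[["B"]], 1 / 3, tolerance = 1e-12)
})

test_that("tsv-pair round-trip is lossless for all fields", {
  m <- tinyModel()
  m@objective <- c(R1 = 1)
  m@reactions$gene_rule[2] <- "geneX and geneY"
  prefix <- file.path(withr::local_tempdir(), "tiny")
  writeOrganismModel(m, prefix, "tsv-pair")
  expect_modelEqual(readOrganismModel(prefix, "tsv-pair"), m)
})

test_that("write refuses an invalid model and read reports parse failures", {
  m <- tinyModel()
  m@reactions <- m@reactions[0, ]
  m@stoichiometry <- list()
  path <- withr::local_tempfile(fileext = ".json")
  expect_error(writeOrganismModel(m, path, "native-json"), "no reactions")
  writeLines("this is { not json", path)
  expect_error(readOrganismModel(path, "native-json"), "parse failure")
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(id = "x"), path2, auto_unbox = TRUE)
  expect_error(readOrganismModel(path2, "native-json"), "missing element")
})

test_that("SBML import reads bounds and applies the default-bound rule", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeMiniSBML(path, with_bounds = TRUE)
  m <- readOrganismModel(path, "sbml")
  rxn <- reactions(m)
  expect_equal(rxn$lb[rxn$id == "R1"], -5)
  expect_equal(rxn$ub[rxn$id == "R1"], 8)
  # boundary species dropped from stoichiometry; coefficients kept
  expect_equal(stoichiometry(m)$R1, c(A = -1, B = 2))
  expect_equal(rxn$kind[rxn$id == "R2"], "exchange")

  # no explicit bounds: +-1000 default, irreversible flag honored
  path2 <- withr::local_tempfile(fileext = ".xml")
  writeMiniSBML(path2, with_bounds = FALSE, irreversible_r2 = TRUE)
  m2 <- readOrganismModel(path2, "sbml")
  rxn2 <- reactions(m2)
  expect_equal(rxn2$lb[rxn2$id == "R1"], -1000)  # reversible
  expect_equal(rxn2$ub[rxn2$id == "R1"], 1000)
  expect_equal(rxn2$lb[rxn2$id == "R2"], 0)      # irreversible
  expect_equal(rxn2$ub[rxn2$id == "R2"], 1000)
})

test_that("stoichiometric matrix has sorted deterministic layout", {
  m <- tinyModel()
  S <- stoichiometricMatrix(m)
  expect_identical(rownames(S), sort(metaboliteIds(m)))
  expect_identical(colnames(S), sort(reactionIds(m)))
  expect_equal(dim(S), c(2L, 3L))
  expect_equal(as.numeric(S["A", "R1"]), -1)
  expect_equal(as.numeric(S["B", "R1"]), 1)
  expect_equal(as.numeric(S["A", "EX_A"]), -1)
  # HisD column of the toy Buchnera: PRPP -> His + AICAR
  b <- makeToySymbiosis()$buchnera
  Sb <- stoichiometricMatrix(b)
  expect_equal(as.numeric(Sb[c("aicar", "his", "prpp"), "HisD"]), c(1, 1, -1))
  # no empty columns
  expect_true(all(Matrix::colSums(abs(S)) > 0))
  expect_true(all(Matrix::colSums(abs(Sb)) > 0))
})

test_that("medium tables read and write with validation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeMedium(c(prpp = 10, his = 0), path)
  med <- readMedium(path)
  expect_equal(med, c(prpp = 10, his = 0))
  writeLines("metabolite\tmax_uptake\nprpp\t-3", path)
  expect_error(readMedium(path), "nonnegative")
})
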