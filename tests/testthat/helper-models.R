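# small fixture builders shared across test files

tinyModel <- function() {
  organismModel(
    id = "tiny",
    metabolites = data.frame(id = c("A", "B"), compartment = "c"),
    reactions = data.frame(id = c("EX_A", "R1", "DM_B"),
                           lb = c(-10, 0, 2), ub = c(0, 1000, 2),
                           kind = c("exchange", "internal", "demand")),
    stoichiometry = list(EX_A = c(A = -1), R1 = c(A = -1, B = 1),
                         DM_B = c(B = -1)))
}

expect_modelEqual <- function(m1, m2) {
  expect_identical(m1@id, m2@id)
  expect_setequal(m1@compartments, m2@compartments)
  expect_equal(m1@metabolites, m2@metabolites)
  expect_equal(m1@reactions, m2@reactions)
  expect_equal(m1@stoichiometry[sort(names(m1@stoichiometry))],
               m2@stoichiometry[sort(names(m2@stoichiometry))],
               tolerance = 1e-12)
  expect_identical(m1@biomassId, m2@biomassId)
  expect_equal(m1@objective, m2@objective)
}

# minimal SBML writer for import tests (fbc bounds optional)
writeMiniSBML <- function(path, with_bounds = TRUE, irreversible_r2 = TRUE) {
  fbc <- if (with_bounds)
    ' fbc:lowerFluxBound="lb1" fbc:upperFluxBound="ub1"' else ""
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    '      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    '      level="3" version="1">',
    '<model id="mini">',
    '  <listOfCompartments><compartment id="c"/></listOfCompartments>',
    '  <listOfSpecies>',
    '    <species id="A" compartment="c"/>',
    '    <species id="B" compartment="c"/>',
    '    <species id="X_b" compartment="c" boundaryCondition="true"/>',
    '  </listOfSpecies>',
    if (with_bounds)
      c('  <listOfParameters>',
        '    <parameter id="lb1" value="-5" constant="true"/>',
        '    <parameter id="ub1" value="8" constant="true"/>',
        '  </listOfParameters>') else NULL,
    '  <listOfReactions>',
    paste0('    <reaction id="R1" reversible="true"', fbc, '>'),
    '      <listOfReactants>',
    '        <speciesReference species="A" stoichiometry="1"/>',
    '        <speciesReference species="X_b" stoichiometry="1"/>',
    '      </listOfReactants>',
    '      <listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>',
    '    </reaction>',
    paste0('    <reaction id="R2" reversible="',
           if (irreversible_r2) "false" else "true", '">'),
    '      <listOfReactants><speciesReference species="B"/></listOfReactants>',
    '    </reaction>',
    '  </listOfReactions>',
    '</model>',
    '</sbml>')
  writeLines(unlist(lines), path)
  path
}
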