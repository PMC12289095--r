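# SBML, canonical JSON, and environment TSV input/output.

sbml_header <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">'

minimal_sbml <- function(species, reactions, compartments = c("e", "c")) {
  paste0(sbml_header, '<model id="mini"><listOfCompartments>',
         paste(sprintf('<compartment id="%s" constant="true"/>', compartments),
               collapse = ""),
         '</listOfCompartments><listOfSpecies>', species,
         '</listOfSpecies><listOfReactions>', reactions,
         '</listOfReactions></model></sbml>')
}

test_that("SBML round trip through exchange reactions recovers each fixture model", {
  for (name in c("COMP", "FAC", "OBL1", "OBL2", "DISJOINT")) {
    fx <- make_fixture(name)
    dir <- withr::local_tempdir()
    paths <- write_fixture_sbml(fx, dir)
    expect_length(paths, length(fx$models))
    for (i in seq_along(fx$models)) {
      orig <- fx$models[[i]]
      got <- canonicalize_model(read_sbml_model(paths[i]))
      expect_identical(got$model_id, orig$model_id)
      expect_identical(sort(rownames(got$S)), sort(rownames(orig$S)))
      expect_identical(sort(colnames(got$S)), sort(colnames(orig$S)))
      expect_equal(as.matrix(got$S)[rownames(orig$S), colnames(orig$S)],
                   as.matrix(orig$S))
      expect_equal(got$lb[names(orig$lb)], orig$lb)
      expect_equal(got$ub[names(orig$ub)], orig$ub)
      expect_identical(got$compartment[names(orig$compartment)],
                       orig$compartment)
      expect_equal(got$default_env$lower[order(names(got$default_env$lower))],
                   orig$default_env$lower[order(names(orig$default_env$lower))])
      expect_equal(got$default_env$upper[order(names(got$default_env$upper))],
                   orig$default_env$upper[order(names(orig$default_env$upper))])
    }
  }
})

test_that("re-imported models reproduce growth and classification end to end", {
  fx <- make_fixture("FAC")
  dir <- withr::local_tempdir()
  paths <- write_fixture_sbml(fx, dir)
  a <- canonicalize_model(read_sbml_model(paths[1]))
  b <- canonicalize_model(read_sbml_model(paths[2]))
  asmt <- assess_pair(a, b, fx$env)
  expect_identical(asmt$label, "FACULTATIVE_COOP")
  expect_equal(asmt$lambda_together, c(20, 20), tolerance = 1e-9)
  # every synthetic fixture grows in its default environment after round trip
  for (name in c("COMP", "FAC", "OBL1", "OBL2", "DISJOINT")) {
    fy <- make_fixture(name)
    d2 <- withr::local_tempdir()
    for (p in write_fixture_sbml(fy, d2)) {
      m <- canonicalize_model(read_sbml_model(p))
      expect_gt(solve_individual_growth(m, m$default_env)$lambda, 0)
    }
  }
})

test_that("periplasmic compounds are read and treated as intracellular", {
  xml <- minimal_sbml(
    paste0('<species id="X" compartment="e"/>',
           '<species id="X_p" compartment="p"/>',
           '<species id="X_c" compartment="c"/>'),
    paste0('<reaction id="T1" reversible="false">',
           '<listOfReactants><speciesReference species="X" stoichiometry="1"/></listOfReactants>',
           '<listOfProducts><speciesReference species="X_p" stoichiometry="1"/></listOfProducts>',
           '</reaction>',
           '<reaction id="T2" reversible="false">',
           '<listOfReactants><speciesReference species="X_p" stoichiometry="1"/></listOfReactants>',
           '<listOfProducts><speciesReference species="X_c" stoichiometry="1"/></listOfProducts>',
           '</reaction>',
           '<reaction id="BIOMASS_mini" reversible="false">',
           '<listOfReactants><speciesReference species="X_c" stoichiometry="1"/></listOfReactants>',
           '</reaction>'),
    compartments = c("e", "c", "p"))
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  m <- read_sbml_model(path)
  expect_identical(unname(m$compartment[c("X", "X_p", "X_c")]),
                   c("extracellular", "periplasm", "cytoplasm"))
  expect_identical(m$biomass_id, "BIOMASS_mini")  # pattern fallback
  # periplasmic rows are organism-private in a pair: not shared
  pair <- build_pair_model(m, m)
  shared <- rownames(pair$S)[pair$compartment == "extracellular"]
  expect_identical(shared, "X")
  expect_true(all(c("A#X_p", "B#X_p") %in% rownames(pair$S)))
})

test_that("SBML error contracts: no biomass, unknown compartment, parse failure", {
  no_bio <- minimal_sbml(
    '<species id="X" compartment="e"/><species id="X_c" compartment="c"/>',
    paste0('<reaction id="T1" reversible="false">',
           '<listOfReactants><speciesReference species="X"/></listOfReactants>',
           '<listOfProducts><speciesReference species="X_c"/></listOfProducts>',
           '</reaction>'))
  p1 <- withr::local_tempfile(fileext = ".xml"); writeLines(no_bio, p1)
  expect_error(read_sbml_model(p1), "no fbc objective and no reaction matching")

  bad_comp <- minimal_sbml(
    '<species id="X" compartment="q"/>',
    paste0('<reaction id="biomass" reversible="false">',
           '<listOfReactants><speciesReference species="X"/></listOfReactants>',
           '</reaction>'))
  p2 <- withr::local_tempfile(fileext = ".xml"); writeLines(bad_comp, p2)
  expect_error(read_sbml_model(p2), "unknown compartment code 'q'")

  p3 <- withr::local_tempfile(fileext = ".xml")
  writeLines("not xml at all <<", p3)
  expect_error(read_sbml_model(p3), "cannot parse")
})

test_that("canonicalize_model folds exchange bounds into the environment", {
  m <- model_from_reactions(
    "exch",
    data.frame(id = c("X", "X_c"), compartment = c("extracellular", "cytoplasm")),
    list(EX_X = list(stoich = c(X = -1), lb = -10, ub = 1000),
         TXP = list(stoich = c(X = -1, X_c = 1), lb = 0, ub = 1000),
         BIOMASS = list(stoich = c(X_c = -1), lb = 0, ub = 1000)),
    "BIOMASS")
  got <- canonicalize_model(m)
  expect_false("EX_X" %in% colnames(got$S))
  expect_equal(ncol(got$S), 2)
  expect_equal(got$default_env$lower[["X"]], -10)
  expect_equal(got$default_env$upper[["X"]], 1000)
  # retained stoichiometry untouched
  expect_equal(as.matrix(got$S), as.matrix(m$S[, c("TXP", "BIOMASS")]))
  # growth matches the pre-canonical bounds
  expect_equal(solve_individual_growth(got, got$default_env)$lambda, 10)
  # a model with no exchange columns passes through unchanged
  again <- canonicalize_model(got)
  expect_equal(as.matrix(again$S), as.matrix(got$S))
})

test_that("canonicalize_model rejects malformed exchanges and sinks", {
  two_met <- model_from_reactions(
    "bad",
    data.frame(id = c("X", "Y", "X_c"),
               compartment = c("extracellular", "extracellular", "cytoplasm")),
    list(EX_bad = list(stoich = c(X = -1, Y = -1), lb = -10, ub = 10),
         BIOMASS = list(stoich = c(X_c = -1), lb = 0, ub = 10),
         TXP = list(stoich = c(X = -1, X_c = 1), lb = 0, ub = 10)),
    "BIOMASS")
  expect_error(canonicalize_model(two_met), "EX_bad.*touches 2 metabolites")

  sink <- model_from_reactions(
    "sink",
    data.frame(id = c("X", "X_c"), compartment = c("extracellular", "cytoplasm")),
    list(TXP = list(stoich = c(X = -1, X_c = 1), lb = 0, ub = 10),
         DM_X_c = list(stoich = c(X_c = -1), lb = 0, ub = 10),
         BIOMASS = list(stoich = c(X_c = -1), lb = 0, ub = 10)),
    "BIOMASS")
  expect_error(canonicalize_model(sink), "sink/demand")
  dropped <- canonicalize_model(sink, drop_sinks = TRUE)
  expect_false("DM_X_c" %in% colnames(dropped$S))
})

test_that("canonical model JSON round trip is the identity on all fields", {
  for (name in c("FAC", "OBL2")) {
    m <- make_fixture(name)$models[[1]]
    path <- withr::local_tempfile(fileext = ".json")
    write_model_json(m, path)
    got <- read_model_json(path)
    expect_identical(got$model_id, m$model_id)
    expect_identical(got$biomass_id, m$biomass_id)
    expect_equal(as.matrix(got$S), as.matrix(m$S))
    expect_equal(got$lb, m$lb)
    expect_equal(got$ub, m$ub)
    expect_identical(got$compartment, m$compartment)
    expect_equal(got$default_env$lower, m$default_env$lower)
    expect_equal(got$default_env$upper, m$default_env$upper)
  }
})

test_that("environment TSV round trips exactly, including the empty case", {
  env <- growth_env(lower = c(X = -1000, Y = -0.123456789012345),
                    upper = c(X = 20, Z = 1000))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_environment(env, path)
  got <- read_environment(path)
  ids <- sort(union(names(env$lower), names(env$upper)))
  expect_identical(sapply(ids, function(i) pairfba:::env_lower_for(got, i)),
                   sapply(ids, function(i) pairfba:::env_lower_for(env, i)))
  expect_identical(sapply(ids, function(i) pairfba:::env_upper_for(got, i)),
                   sapply(ids, function(i) pairfba:::env_upper_for(env, i)))

  empty <- growth_env()
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_environment(empty, p2)
  expect_identical(readLines(p2), "compound_id\tlower_bound\tupper_bound")
  got2 <- read_environment(p2)
  expect_length(env_compounds(got2), 0)
})

test_that("environment TSV validation errors name the offending line", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound_id\tlower_bound\tupper_bound", "X\t5\t10"), p)
  expect_error(read_environment(p), "positive lower bound for 'X' at line 2")
  writeLines(c("compound_id\tlower_bound\tupper_bound", "X\t-5"), p)
  expect_error(read_environment(p), "malformed row at line 2")
  writeLines(c("wrong\theader"), p)
  expect_error(read_environment(p), "malformed header")
})
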