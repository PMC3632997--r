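minimal_sbml <- function(body, level = "3") {
  ns <- if (level == "3") {
    "http://www.sbml.org/sbml/level3/version1/core\" level=\"3\" version=\"1"
  } else {
    "http://www.sbml.org/sbml/level2/version4\" level=\"2\" version=\"4"
  }
  tf <- tempfile(fileext = ".xml")
  writeLines(c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
               paste0("<sbml xmlns=\"", ns, "\">"),
               "<model id=\"m\">", body, "</model></sbml>"), tf)
  tf
}

test_that("an SBML file with no reactions yields just its parameters", {
  tf <- minimal_sbml(c(
    "<listOfParameters>",
    "<parameter id=\"a\" value=\"2\" constant=\"true\"/>",
    "<parameter id=\"b\" value=\"3\" constant=\"true\"/>",
    "</listOfParameters>"))
  m <- read_sbml(tf)
  expect_length(m$reactions, 0L)
  expect_length(m$variables, 2L)
  expect_identical(m$nominal_values$a, 2)
})

test_that("unparseable or non-SBML input is refused", {
  tf <- tempfile()
  writeLines("<notes/>", tf)
  expect_error(read_sbml(tf), "not an SBML document")
  tf2 <- tempfile()
  writeLines("<<<", tf2)
  expect_error(read_sbml(tf2), "cannot parse")
})

test_that("the glycolysis fixture round-trips through SBML with equal structure", {
  m <- make_glycolysis_toy()
  spec <- attr(m, "fixture_spec")
  tf <- tempfile(fileext = ".sbml")
  writeLines(attr(m, "sbml"), tf, sep = "")
  r <- read_sbml(tf)

  expect_length(r$reactions, spec$n_reactions)
  expect_identical(sum(vapply(r$reactions, function(rx) length(rx$modifiers),
                              integer(1))), spec$n_modifiers)
  chain_species <- unique(unlist(lapply(r$reactions, function(rx) {
    c(vapply(rx$reactants, `[[`, character(1), "species"),
      vapply(rx$products, `[[`, character(1), "species"))
  })))
  expect_length(chain_species, spec$n_species)
  expect_identical(sort(names(r$variables)), sort(names(m$variables)))

  # annotations survive the round trip
  for (sp in spec$chain) {
    expect_true(annotations_equivalent(r$variables[[sp]]$annotation,
                                       m$variables[[sp]]$annotation),
                label = paste("annotation of", sp))
  }
  # reaction records match order-insensitively
  rec_sig <- function(rx) {
    paste(rx$id,
          paste(sort(vapply(rx$reactants, function(s)
            paste0(s$species, ":", s$stoich), character(1))), collapse = ","),
          paste(sort(vapply(rx$products, function(s)
            paste0(s$species, ":", s$stoich), character(1))), collapse = ","),
          paste(sort(vapply(rx$modifiers, function(s)
            paste0(s$species, ":", s$polarity), character(1))),
            collapse = ","))
  }
  expect_setequal(vapply(r$reactions, rec_sig, character(1)),
                  vapply(m$reactions, rec_sig, character(1)))
})

test_that("SBO terms on modifiers map to polarities", {
  tf <- minimal_sbml(c(
    "<listOfSpecies>",
    "<species id=\"S\" compartment=\"c\" initialAmount=\"1\"/>",
    "<species id=\"P\" compartment=\"c\" initialAmount=\"0\"/>",
    "<species id=\"E\" compartment=\"c\" initialAmount=\"1\"/>",
    "<species id=\"X\" compartment=\"c\" initialAmount=\"1\"/>",
    "</listOfSpecies>",
    "<listOfReactions><reaction id=\"r1\" reversible=\"false\">",
    "<listOfReactants><speciesReference species=\"S\"/></listOfReactants>",
    "<listOfProducts><speciesReference species=\"P\"/></listOfProducts>",
    "<listOfModifiers>",
    "<modifierSpeciesReference species=\"E\" sboTerm=\"SBO:0000020\"/>",
    "<modifierSpeciesReference species=\"X\"/>",
    "</listOfModifiers>",
    "</reaction></listOfReactions>"))
  m <- read_sbml(tf)
  mods <- m$reactions[[1]]$modifiers
  expect_identical(vapply(mods, `[[`, character(1), "species"), c("E", "X"))
  expect_identical(vapply(mods, `[[`, numeric(1), "polarity"), c(-1, 0))
  # missing stoichiometry defaults to 1
  expect_identical(m$reactions[[1]]$reactants[[1]]$stoich, 1)
  # species derivatives were materialized from the stoichiometry
  expect_true(m$variables$S$is_state)
  expect_true(m$variables$P$is_state)
  expect_false(m$variables$E$is_state)
})

test_that("boundary species stay constant and rules become equations", {
  tf <- minimal_sbml(c(
    "<listOfSpecies>",
    "<species id=\"S\" compartment=\"c\" initialAmount=\"5\" ",
    " boundaryCondition=\"true\"/>",
    "<species id=\"P\" compartment=\"c\" initialAmount=\"0\"/>",
    "</listOfSpecies>",
    "<listOfParameters><parameter id=\"w\" value=\"1\"/></listOfParameters>",
    "<listOfRules>",
    "<assignmentRule variable=\"w\"><math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
    "<apply><times/><ci>S</ci><cn>2</cn></apply></math></assignmentRule>",
    "</listOfRules>",
    "<listOfReactions><reaction id=\"r1\">",
    "<listOfReactants><speciesReference species=\"S\"/></listOfReactants>",
    "<listOfProducts><speciesReference species=\"P\"/></listOfProducts>",
    "</reaction></listOfReactions>"), level = "2")
  m <- read_sbml(tf)
  expect_false(m$variables$S$is_state)   # boundary: no derivative minted
  expect_true(m$variables$P$is_state)
  expect_true(m$reactions[[1]]$reversible)  # L2 default
  weq <- m$equations[["w"]]
  expect_identical(weq$rhs_dependencies, "S")
})

test_that("MathML kinetic laws round-trip through the expression language", {
  m <- make_glycolysis_toy()
  tf <- tempfile(fileext = ".sbml")
  writeLines(attr(m, "sbml"), tf, sep = "")
  r <- read_sbml(tf)
  for (rx in m$reactions) {
    orig <- m$equations[[rx$id]]$rhs
    back <- r$equations[[rx$id]]$rhs
    env <- list(glucose = 1.3, G6P = 0.7, F6P = 0.9, HK = 1.1,
                citrate = 0.8, F16BP = 0.6, PEP = 0.5,
                k1 = 0.8, k2 = 1, k3 = 1.2, k4 = 0.9, k5 = 1.1)
    expect_equal(eval(back, env), eval(orig, env), tolerance = 1e-12,
                 label = paste("kinetic law of", rx$id))
  }
})

test_that("unsupported MathML keeps dependencies with a warning", {
  tf <- minimal_sbml(c(
    "<listOfSpecies>",
    "<species id=\"S\" compartment=\"c\" initialAmount=\"1\"/>",
    "<species id=\"P\" compartment=\"c\" initialAmount=\"0\"/>",
    "</listOfSpecies>",
    "<listOfReactions><reaction id=\"r1\" reversible=\"false\">",
    "<listOfReactants><speciesReference species=\"S\"/></listOfReactants>",
    "<listOfProducts><speciesReference species=\"P\"/></listOfProducts>",
    "<kineticLaw><math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
    "<piecewise><piece><ci>S</ci><apply><lt/><ci>S</ci><cn>1</cn></apply>",
    "</piece></piecewise></math></kineticLaw>",
    "</reaction></listOfReactions>"))
  expect_warning(m <- read_sbml(tf), "unsupported MathML")
  eq <- m$equations[["r1"]]
  expect_null(eq$rhs)
  expect_true("S" %in% eq$rhs_dependencies)
})
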