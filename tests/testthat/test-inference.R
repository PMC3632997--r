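test_that("variable roles follow the annotation through the registry", {
  m <- make_cv_circuit(2)
  roles <- classify_variable_role(m)
  expect_identical(roles$F_LV_aorta$role, "flow")
  expect_identical(roles$F_LV_aorta$domain, "opbx:FluidDomain")
  expect_identical(roles$P_LV$role, "force")
  expect_identical(roles$V_LV$role, "amount")
  expect_identical(roles$R_LV$role, "unannotated")

  g <- make_glycolysis_toy()
  groles <- classify_variable_role(g)
  expect_identical(groles$glucose$role, "amount")
  expect_identical(groles$glucose$domain, "opbx:ChemicalDomain")
})

test_that("participant location finds drivers upstream and dependents downstream", {
  m <- make_cv_circuit(2)
  dg <- build_dependency_graph(m)
  roles <- classify_variable_role(m)
  ev <- locate_participants(m, dg, roles, "F_LV_aorta")
  up <- Filter(function(e) e$direction == "upstream", ev)
  down <- Filter(function(e) e$direction == "downstream", ev)
  up_signs <- stats::setNames(vapply(up, `[[`, numeric(1), "sign"),
                              vapply(up, `[[`, character(1), "variable"))
  expect_identical(up_signs[["P_LV"]], 1)
  expect_identical(up_signs[["P_aorta"]], -1)
  down_signs <- stats::setNames(vapply(down, `[[`, numeric(1), "sign"),
                                vapply(down, `[[`, character(1), "variable"))
  expect_identical(down_signs[["V_LV"]], -1)
  expect_identical(down_signs[["V_aorta"]], 1)
})

test_that("multi-hop chains pass through unannotated intermediates", {
  tf <- tempfile(fileext = ".eqn")
  writeLines(c(
    "var F {property: opbx:ChemicalFlowRate, label: F}",
    "var x",
    "var C {property: opbx:ChemicalAmount, entity: chebix:C}",
    "eq x = 2 * F",
    "eq C' = x",
    "init F = 1"), tf)
  m <- read_equation_model(tf)
  dg <- build_dependency_graph(m)
  roles <- classify_variable_role(m)
  ev <- locate_participants(m, dg, roles, "F")
  down <- Filter(function(e) e$direction == "downstream", ev)
  expect_length(down, 1L)
  expect_identical(down[[1]]$variable, "C")
  expect_identical(down[[1]]$sign, 1)
  expect_identical(down[[1]]$hops, 2L)

  # oracle: brute-force path enumeration on the 3-node dependency chain
  # F -> x -> C is the only path, both edges positive
  expect_identical(nrow(dg$edges[dg$edges$from == "F", ]), 1L)
})

test_that("the CV ring infers one flow per resistive law with correct orientation", {
  m <- make_cv_circuit(4)
  spec <- attr(m, "fixture_spec")
  map <- infer_from_dependencies(m)
  flows <- Filter(function(p) p$kind == "flow", map$processes)
  expect_length(flows, spec$n_flows)
  for (fv in names(spec$expected_flows)) {
    p <- map$processes[[paste0("flow_", fv)]]
    expect_identical(p$domain, "opbx:FluidDomain")
    roles <- vapply(p$participants, `[[`, character(1), "role")
    keys <- vapply(p$participants, function(pt) {
      physiomapr:::entity_key(map$entities[[pt$entity_id]]$annotation)
    }, character(1))
    expect_identical(unname(keys[roles == "source"]),
                     spec$expected_flows[[fv]]$source_key,
                     label = paste("source of", fv))
    expect_identical(unname(keys[roles == "sink"]),
                     spec$expected_flows[[fv]]$sink_key,
                     label = paste("sink of", fv))
    expect_identical(p$provenance$method, "dependency-inference")
    expect_identical(p$provenance$flow_variable, fv)
  }
  # the worked example: blood flows from the left ventricle into the aorta
  p <- map$processes$flow_F_LV_aorta
  srcs <- vapply(p$participants, function(pt) {
    if (pt$role == "source") map$entities[[pt$entity_id]]$display_label else ""
  }, character(1))
  expect_true(any(grepl("LeftVentricle", srcs)))
})

test_that("zero evidence yields an unresolved boundary flow into the environment", {
  tf <- tempfile(fileext = ".eqn")
  writeLines(c("var F {property: opbx:ChemicalFlowRate, label: F}",
               "var k", "eq F = k"), tf)
  m <- read_equation_model(tf)
  map <- infer_from_dependencies(m)
  p <- map$processes$flow_F
  expect_true("unresolved" %in% p$flags)
  labels <- vapply(p$participants, function(pt) {
    map$entities[[pt$entity_id]]$display_label
  }, character(1))
  expect_true(all(labels == "environment"))
})

test_that("a symmetric flow demotes its conflicting entity to mediator", {
  tf <- tempfile(fileext = ".eqn")
  writeLines(c(
    "var F {property: opbx:FluidFlowRate, label: F}",
    "var A {property: opbx:FluidPressure, entity: fmax:SamePool}",
    "var B {property: opbx:FluidPressure, entity: fmax:SamePool}",
    "var R",
    "eq F = (A - B) / R",
    "init A = 2", "init B = 1", "init R = 1"), tf)
  m <- read_equation_model(tf)
  map <- infer_from_dependencies(m)
  p <- map$processes$flow_F
  roles <- vapply(p$participants, `[[`, character(1), "role")
  expect_true("mediator" %in% roles)
  expect_true("role-conflict" %in% p$flags)
  expect_true(any(grepl("demoted to mediator", attr(map, "warnings"))))
})

test_that("explicit reaction tags produce flows, stoichiometry and modulations", {
  m <- make_glycolysis_toy()
  spec <- attr(m, "fixture_spec")
  map <- infer_from_reactions(m)
  kinds <- vapply(map$processes, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "flow"), spec$n_flow_processes)
  expect_identical(sum(kinds == "modulation"), spec$n_modulation_processes)
  pols <- vapply(Filter(function(p) p$kind == "modulation", map$processes),
                 `[[`, numeric(1), "polarity")
  expect_setequal(unname(pols), c(1, -1))

  # stoichiometry 2:1 is retained
  m2 <- new_ingested_model(
    variables = list(A = physiomapr:::make_variable("A"),
                     B = physiomapr:::make_variable("B")),
    reactions = list(list(id = "r", reactants = list(list(species = "A",
                                                          stoich = 2)),
                          products = list(list(species = "B", stoich = 1)),
                          modifiers = list(), rate_variable = NULL,
                          reversible = FALSE)),
    source_uri = "test:stoich")
  mp <- infer_from_reactions(m2)
  pt <- mp$processes$flow_r$participants
  stoich <- stats::setNames(vapply(pt, `[[`, numeric(1), "stoich"),
                            vapply(pt, `[[`, character(1), "role"))
  expect_identical(stoich[["source"]], 2)
  expect_identical(stoich[["sink"]], 1)

  # products-only reaction gets an environment source
  m3 <- new_ingested_model(
    variables = list(B = physiomapr:::make_variable("B")),
    reactions = list(list(id = "syn", reactants = list(),
                          products = list(list(species = "B", stoich = 1)),
                          modifiers = list(), rate_variable = NULL,
                          reversible = FALSE)),
    source_uri = "test:synthesis")
  mp3 <- infer_from_reactions(m3)
  p3 <- mp3$processes$flow_syn
  src <- Filter(function(pt) pt$role == "source", p3$participants)
  expect_identical(mp3$entities[[src[[1]]$entity_id]]$display_label,
                   "environment")
})

test_that("both inference paths agree on mass-action fixtures", {
  g <- make_glycolysis_toy()
  expect_true(physiomaps_isomorphic(infer_from_reactions(g),
                                    infer_from_dependencies(g)))
  for (seed in 21:30) {
    m <- make_random_network(6, 7, p_modifier = 0.3, seed = seed)
    a <- infer_from_reactions(m)
    b <- suppressWarnings(infer_from_dependencies(m))
    expect_true(physiomaps_isomorphic(a, b),
                label = paste("two-path agreement, seed", seed))
  }
})

test_that("dependency inference is deterministic and degenerate inputs warn", {
  m <- make_cv_circuit(3)
  x1 <- write_physiomap_xml(infer_from_dependencies(m))
  x2 <- write_physiomap_xml(infer_from_dependencies(m))
  expect_identical(x1, x2)

  tf <- tempfile(fileext = ".eqn")
  writeLines(c("var a {property: opbx:ChemicalAmount, entity: chebix:A}",
               "init a = 1"), tf)
  expect_warning(empty <- infer_from_dependencies(read_equation_model(tf)),
                 "no flow-annotated variables")
  expect_length(empty$processes, 0L)
})
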