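eqn_file <- function(...) {
  tf <- tempfile(fileext = ".eqn")
  writeLines(c(...), tf)
  tf
}

test_that("the equation-model reader parses annotated resistive-flow models", {
  tf <- eqn_file(
    "# resistive flow between two pressurized pools",
    "var F {property: opbx:FluidFlowRate, label: F}",
    "var P1 {property: opbx:FluidPressure, entity: fmax:PoolA}",
    "var P2 {property: opbx:FluidPressure, entity: fmax:PoolB}",
    "var R",
    "eq F = (P1 - P2) / R",
    "init P1 = 2", "init P2 = 1", "init R = 1")
  m <- read_equation_model(tf)
  expect_gte(length(m$variables), 4L)
  expect_length(m$equations, 1L)
  expect_identical(sort(m$equations[[1]]$rhs_dependencies),
                   c("P1", "P2", "R"))
  expect_identical(m$variables$F$annotation$property, "opbx:FluidFlowRate")
  expect_false(m$variables$F$is_state)
})

test_that("an empty file gives an empty model and derivatives mark states", {
  expect_length(read_equation_model(eqn_file(character(0)))$variables, 0L)

  m <- read_equation_model(eqn_file("var V", "var F_in", "var F_out",
                                    "eq V' = F_in - F_out"))
  expect_true(m$variables$V$is_state)
  eq <- m$equations[["d_V"]]
  expect_true(eq$is_derivative)
  expect_identical(sort(eq$rhs_dependencies), c("F_in", "F_out"))
})

test_that("undeclared symbols are auto-declared with a warning and duplicates fail", {
  expect_warning(m <- read_equation_model(eqn_file("var y", "eq y = a + b")),
                 "auto-declaring")
  expect_true(all(c("a", "b") %in% names(m$variables)))
  expect_error(read_equation_model(eqn_file("var x", "var x")),
               "duplicate variable")
  expect_error(read_equation_model(eqn_file("var x", "eq x = sin(x)")),
               "not part of the equation")
  err <- tryCatch(read_equation_model(eqn_file("var x", "this is junk")),
                  error = conditionMessage)
  expect_match(err, ":2")  # error names the line
})

test_that("sidecar annotations set named variables and report unknown names", {
  m <- read_equation_model(eqn_file("var F_LV_aorta", "var Q"))
  side <- tempfile(fileext = ".json")
  jsonlite::write_json(list(variables = list(
    F_LV_aorta = list(property = "opbx:FluidFlowRate"),
    Qx = list(property = "opbx:FluidVolume",
              bearer = list(list("fmax:PortionOfBlood", "none"))))),
    side, auto_unbox = TRUE)
  m2 <- apply_sidecar_annotations(m, side)
  expect_identical(m2$variables$F_LV_aorta$annotation$property,
                   "opbx:FluidFlowRate")
  expect_null(m2$variables$Q$annotation)
  expect_identical(attr(m2, "unknown_variables"), "Qx")

  # empty sidecar leaves the model untouched
  empty <- tempfile(fileext = ".json")
  writeLines("{}", empty)
  m3 <- apply_sidecar_annotations(m, empty)
  expect_identical(m3$variables, m$variables)

  # unknown registry terms are refused by name
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(variables = list(
    Q = list(property = "opbx:NoSuchTerm"))), bad, auto_unbox = TRUE)
  expect_error(apply_sidecar_annotations(m, bad), "opbx:NoSuchTerm")
})

test_that("the dependency graph is the exact union of equation dependencies", {
  tf <- eqn_file("var F", "var P1", "var P2", "var R",
                 "eq F = (P1 - P2) / R")
  g <- build_dependency_graph(read_equation_model(tf))
  expect_identical(g$edges$from, c("P1", "P2", "R"))
  expect_identical(g$edges$to, rep("F", 3L))

  # variables with no equations give nodes and no edges
  g0 <- build_dependency_graph(read_equation_model(eqn_file("var a", "var b")))
  expect_identical(g0$nodes, c("a", "b"))
  expect_identical(nrow(g0$edges), 0L)

  # oracle: independent expression-tree walk over a random fixture model
  m <- make_random_network(6, 8, p_modifier = 0.3, seed = 7)
  g1 <- build_dependency_graph(m)
  expected <- unique(do.call(rbind, lapply(m$equations, function(eq) {
    deps <- sort(unique(all.vars(eq$rhs)))
    if (length(deps) == 0L) return(NULL)
    data.frame(from = deps, to = eq$target, stringsAsFactors = FALSE)
  })))
  expected <- expected[order(expected$from, expected$to), ]
  rownames(expected) <- NULL
  expect_identical(g1$edges, expected)
  # determinism across calls
  expect_identical(g1, build_dependency_graph(m))
})

test_that("numeric dependence signs match analytic derivative signs", {
  tf <- eqn_file(
    "var F", "var P1", "var P2", "var R", "var z", "var u",
    "eq F = (P1 - P2) / R",
    "eq z = u - u",
    "init P1 = 2", "init P2 = 1", "init R = 1")
  m <- read_equation_model(tf)
  expect_identical(partial_dependence_sign(m, "P1", "F"), 1)
  expect_identical(partial_dependence_sign(m, "P2", "F"), -1)
  expect_identical(partial_dependence_sign(m, "u", "z"), 0)
  expect_error(partial_dependence_sign(m, "z", "F"), "no dependency edge")

  # library of hand-derived expressions evaluated at positive nominals
  cases <- list(
    list(rhs = "2 * x + 3", var = "x", sign = 1),
    list(rhs = "5 - 4 * x", var = "x", sign = -1),
    list(rhs = "k * x * y", var = "x", sign = 1),       # mass action
    list(rhs = "k * x * y", var = "y", sign = 1),
    list(rhs = "k * x / y", var = "y", sign = -1),
    list(rhs = "x / (1 + x)", var = "x", sign = 1),     # saturating
    list(rhs = "1 / (1 + x^2)", var = "x", sign = -1),  # Hill-type decay
    list(rhs = "x^2", var = "x", sign = 1),
    list(rhs = "-x^3", var = "x", sign = -1),
    list(rhs = "(x - 1)", var = "x", sign = 1),
    list(rhs = "y - x", var = "x", sign = -1),
    list(rhs = "x^2 / (k + x^2)", var = "x", sign = 1), # Hill activation
    list(rhs = "k / (k + x)", var = "x", sign = -1),    # inhibition
    list(rhs = "x * y / (1 + x * y)", var = "y", sign = 1),
    list(rhs = "(x + y) / z", var = "z", sign = -1),
    list(rhs = "(x - 3 * y) / z", var = "y", sign = -1),
    list(rhs = "x + y - y", var = "y", sign = 0),
    list(rhs = "0 * x + 2", var = "x", sign = 0),
    list(rhs = "x / x", var = "x", sign = 0),
    list(rhs = "2 * x - x", var = "x", sign = 1))
  for (cs in cases) {
    tf2 <- eqn_file("var v", "var x", "var y", "var z", "var k",
                    paste0("eq v = ", cs$rhs))
    m2 <- read_equation_model(tf2)
    expect_identical(partial_dependence_sign(m2, cs$var, "v"), cs$sign,
                     label = paste("d/d", cs$var, "of", cs$rhs))
  }
})
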