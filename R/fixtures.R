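# Reference model generators. Each generator attaches a `fixture_spec`
# attribute declaring its construction counts (species, reactions,
# modifiers, expected processes), computed at generation time from the
# construction itself; tests and the acceptance checks compare against
# these declarations, never against numbers hard-coded elsewhere.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

chain_annotation <- function(base_term, container = "fmax:Cytosol",
                             property = "opbx:ChemicalAmount") {
  composite_annotation(property,
                       bearer = list(c(base_term, "none"),
                                     c(container, "contained-in")))
}

#' Generate the glycolysis-fragment reference model
#'
#' A linear five-reaction chain of irreversible mass-action reactions,
#' glucose through pyruvate, with two enzyme-like modifiers: hexokinase
#' stimulating the first reaction (rate `k1 * glucose * HK`) and citrate
#' inhibiting the third (rate `k3 * F6P / citrate`). All chain metabolites
#' carry chemical-amount annotations on cytosolic chemical entities; the
#' modifier species are constant pools tagged with stimulator/inhibitor SBO
#' terms when serialized. The model emulates the topology of a curated
#' glycolysis pathway fragment (chain plus modulators), not any particular
#' published parameterization.
#'
#' @return An `ingested_model` with attribute `fixture_spec` (declared
#'   counts) and attribute `sbml` (the serialized SBML text).
#' @export
make_glycolysis_toy <- function() {
  chain <- c("glucose", "G6P", "F6P", "F16BP", "PEP", "pyruvate")
  terms <- c("chebix:Glucose", "chebix:GlucoseSixPhosphate",
             "chebix:FructoseSixPhosphate", "chebix:FructoseBisphosphate",
             "chebix:Phosphoenolpyruvate", "chebix:Pyruvate")
  k <- c(0.8, 1.0, 1.2, 0.9, 1.1)

  variables <- list()
  equations <- list()
  nominal <- list()
  for (i in seq_along(chain)) {
    variables[[chain[i]]] <- make_variable(chain[i],
                                           annotation = chain_annotation(terms[i]))
    nominal[[chain[i]]] <- if (i == 1L) 1.0 else 0.2
  }
  for (mod in c("HK", "citrate")) {
    term <- if (mod == "HK") "chebix:Hexokinase" else "chebix:Citrate"
    variables[[mod]] <- make_variable(mod, annotation = chain_annotation(term),
                                      boundary = TRUE)
    nominal[[mod]] <- 1.0
  }
  reactions <- list()
  for (i in 1:5) {
    rid <- paste0("R", i)
    rate_expr <- switch(as.character(i),
                        "1" = str2lang(paste0("k1 * glucose * HK")),
                        "3" = str2lang(paste0("k3 * F6P / citrate")),
                        str2lang(paste0("k", i, " * ", chain[i])))
    modifiers <- switch(as.character(i),
                        "1" = list(list(species = "HK", polarity = +1)),
                        "3" = list(list(species = "citrate", polarity = -1)),
                        list())
    reactions[[i]] <- list(
      id = rid,
      reactants = list(list(species = chain[i], stoich = 1)),
      products = list(list(species = chain[i + 1L], stoich = 1)),
      modifiers = modifiers, rate_variable = rid, reversible = FALSE)
    variables[[rid]] <- make_variable(
      rid, annotation = composite_annotation("opbx:ChemicalFlowRate",
                                             free_label = rid),
      equation_id = rid)
    equations[[rid]] <- make_equation(rid, rid, rate_expr)
    variables[[paste0("k", i)]] <- make_variable(paste0("k", i),
                                                 boundary = TRUE)
    nominal[[paste0("k", i)]] <- k[i]
  }
  for (i in seq_along(chain)) {
    sp <- chain[i]
    inflow <- if (i > 1L) as.name(paste0("R", i - 1L))
    outflow <- if (i < length(chain)) as.name(paste0("R", i))
    rhs <- if (is.null(inflow)) call("-", outflow)
    else if (is.null(outflow)) inflow
    else call("-", inflow, outflow)
    eq_id <- paste0("d_", sp)
    equations[[eq_id]] <- make_equation(eq_id, sp, rhs, is_derivative = TRUE)
    variables[[sp]]$is_state <- TRUE
    variables[[sp]]$equation_id <- eq_id
  }
  variables[["cell"]] <- make_variable("cell", boundary = TRUE)
  nominal[["cell"]] <- 1.0

  model <- new_ingested_model(variables = variables, equations = equations,
                              reactions = reactions, source_format = "sbml",
                              source_uri = "fixture:glycolysis-toy",
                              nominal_values = nominal)
  attr(model, "fixture_spec") <- list(
    name = "glycolysis-toy",
    n_species = length(chain), n_modifier_species = 2L,
    n_reactions = length(reactions), n_modifiers = 2L,
    n_flow_processes = length(reactions), n_modulation_processes = 2L,
    chain = chain, k_min = min(k))
  attr(model, "sbml") <- write_sbml(model, model_id = "glycolysis_toy")
  model
}

#' Generate a lumped-parameter cardiovascular ring model
#'
#' A closed ring of `n` blood compartments. Per compartment `i`: the blood
#' volume integrates flow in minus flow out (`V_i' = F_{i-1,i} - F_{i,i+1}`),
#' pressure follows a linear compliance (`P_i = V_i / C_i`), and the flow to
#' the next compartment obeys a resistive law
#' (`F_{i,i+1} = (P_i - P_{i+1}) / R_i`). Volumes are annotated as fluid
#' amounts of portions of blood in each compartment, pressures as fluid
#' forces of the same entities, and flows as fluid flow rates, so
#' dependency inference can recover each flow's source and sink
#' compartment. The first two compartments are named `LV` and `aorta`,
#' giving the flow variable `F_LV_aorta`.
#'
#' @param n Number of compartments (at least 2).
#' @return An `ingested_model` with attributes `fixture_spec` (declared
#'   construction, including the expected source/sink entity of every flow)
#'   and `eqn` (the serialized equation-model text).
#' @export
make_cv_circuit <- function(n = 4) {
  if (!is.numeric(n) || n < 2) {
    stop("a circulatory ring needs at least 2 compartments", call. = FALSE)
  }
  n <- as.integer(n)
  comp <- c("LV", "aorta", if (n > 2) paste0("comp", 3:n))
  comp_term <- c("fmax:LeftVentricle", "fmax:Aorta",
                 if (n > 2) paste0("fmax:Compartment", 3:n))
  blood_bearer <- function(i) list(c("fmax:PortionOfBlood", "none"),
                                   c(comp_term[i], "contained-in"))
  lines <- character(0)
  expected_flows <- list()
  for (i in seq_len(n)) {
    nxt <- if (i == n) 1L else i + 1L
    fv <- paste0("F_", comp[i], "_", comp[nxt])
    lines <- c(lines,
      paste0("var V_", comp[i], " {property: opbx:FluidVolume, entity: ",
             "fmax:PortionOfBlood contained-in ", comp_term[i], "}"),
      paste0("var P_", comp[i], " {property: opbx:FluidPressure, entity: ",
             "fmax:PortionOfBlood contained-in ", comp_term[i], "}"),
      paste0("var ", fv, " {property: opbx:FluidFlowRate, label: ", fv, "}"),
      paste0("var C_", comp[i]), paste0("var R_", comp[i]))
    expected_flows[[fv]] <- list(
      source_key = entity_key(composite_annotation("opbx:FluidVolume",
                                                   bearer = blood_bearer(i))),
      sink_key = entity_key(composite_annotation("opbx:FluidVolume",
                                                 bearer = blood_bearer(nxt))))
  }
  for (i in seq_len(n)) {
    prv <- if (i == 1L) n else i - 1L
    nxt <- if (i == n) 1L else i + 1L
    lines <- c(lines,
      paste0("eq V_", comp[i], "' = F_", comp[prv], "_", comp[i],
             " - F_", comp[i], "_", comp[nxt]),
      paste0("eq P_", comp[i], " = V_", comp[i], " / C_", comp[i]),
      paste0("eq F_", comp[i], "_", comp[nxt], " = (P_", comp[i],
             " - P_", comp[nxt], ") / R_", comp[i]),
      paste0("init V_", comp[i], " = ", if (i == 1L) "1.5" else "1"),
      paste0("init C_", comp[i], " = 1"),
      paste0("init R_", comp[i], " = 1"))
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  path <- tempfile(fileext = ".eqn")
  writeLines(text, path, sep = "")
  model <- read_equation_model(path)
  unlink(path)
  model$source_uri <- paste0("fixture:cv-circuit-", n)
  attr(model, "fixture_spec") <- list(
    name = "cv-circuit", n_compartments = n, n_flows = n,
    n_pressures = n, n_volumes = n, deps_per_flow = 3L,
    expected_flows = expected_flows)
  attr(model, "eqn") <- text
  model
}

# entity_key() of the annotation entity_key ignores the property, so using
# FluidVolume above is only a convenient constructor; pressure bearers give
# the same key.

#' Generate a random mass-action reaction network
#'
#' Reproducible (seeded) networks of unimolecular mass-action reactions for
#' property-based testing. Each reaction converts one species into another
#' with rate `k * reactant`. With probability `p_modifier` a reaction is
#' instead a modulated boundary-synthesis flux: it has no reactant (stuff
#' enters from the unmodeled environment) and a previously produced species
#' is attached as a modifier with definite random polarity (stimulator:
#' rate `k * M`; inhibitor: rate `k / M`). With `acyclic = TRUE`, reactant,
#' product and modifier indices are ordered so that the derived signed
#' influence graph (depletion edges off) is acyclic.
#'
#' @param n_species Number of species, at least 2.
#' @param n_reactions Number of reactions, at least 1.
#' @param p_modifier Probability that a reaction is modulated.
#' @param seed Integer seed; the same seed reproduces the same model.
#' @param acyclic Guarantee an acyclic influence graph.
#' @return An `ingested_model` with attribute `fixture_spec`.
#' @export
make_random_network <- function(n_species, n_reactions, p_modifier = 0,
                                seed = 1L, acyclic = TRUE) {
  if (n_species < 2 || n_reactions < 1) {
    stop("need at least 2 species and 1 reaction", call. = FALSE)
  }
  with_seed(seed, {
    sp <- sprintf("sp%02d", seq_len(n_species))
    variables <- list()
    equations <- list()
    nominal <- list()
    reactions <- list()
    produced <- character(0)  # species with a producing reaction so far
    n_modifiers <- 0L

    for (nm in sp) {
      variables[[nm]] <- make_variable(
        nm, annotation = chain_annotation(paste0("chebix:", toupper(nm))))
      nominal[[nm]] <- round(stats::runif(1, 0.5, 2), 4)
    }

    for (j in seq_len(n_reactions)) {
      rid <- sprintf("R%02d", j)
      kname <- paste0("k", j)
      kval <- round(stats::runif(1, 0.5, 2), 4)
      if (acyclic) {
        prod_i <- sample(2:n_species, 1L)
        reac_i <- sample(seq_len(prod_i - 1L), 1L)
      } else {
        pair <- sample(seq_len(n_species), 2L)
        reac_i <- pair[1L]; prod_i <- pair[2L]
      }
      modulated <- stats::runif(1) < p_modifier
      mod_candidates <- intersect(
        if (acyclic) sp[seq_len(prod_i - 1L)] else sp, produced)
      mod_candidates <- setdiff(mod_candidates, sp[c(reac_i, prod_i)])
      if (modulated && length(mod_candidates) > 0L) {
        n_modifiers <- n_modifiers + 1L
        mod_sp <- if (length(mod_candidates) == 1L) mod_candidates
        else sample(mod_candidates, 1L)
        polarity <- sample(c(-1, 1), 1L)
        rate_expr <- if (polarity > 0) {
          str2lang(paste0(kname, " * ", mod_sp))
        } else {
          str2lang(paste0(kname, " / ", mod_sp))
        }
        reactions[[j]] <- list(
          id = rid,
          reactants = list(),
          products = list(list(species = sp[prod_i], stoich = 1)),
          modifiers = list(list(species = mod_sp, polarity = polarity)),
          rate_variable = rid, reversible = FALSE)
      } else {
        rate_expr <- str2lang(paste0(kname, " * ", sp[reac_i]))
        reactions[[j]] <- list(
          id = rid,
          reactants = list(list(species = sp[reac_i], stoich = 1)),
          products = list(list(species = sp[prod_i], stoich = 1)),
          modifiers = list(), rate_variable = rid, reversible = FALSE)
      }
      produced <- union(produced, sp[prod_i])
      variables[[rid]] <- make_variable(
        rid, annotation = composite_annotation("opbx:ChemicalFlowRate",
                                               free_label = rid),
        equation_id = rid)
      equations[[rid]] <- make_equation(rid, rid, rate_expr)
      variables[[kname]] <- make_variable(kname, boundary = TRUE)
      nominal[[kname]] <- kval
    }

    # derivative equations for dynamic species; untouched species stay
    # boundary constants
    net <- list()
    for (rx in reactions) {
      for (sr in rx$reactants) {
        net[[sr$species]] <- c(net[[sr$species]], list(c(-1, rx$id)))
      }
      for (sr in rx$products) {
        net[[sr$species]] <- c(net[[sr$species]], list(c(+1, rx$id)))
      }
    }
    for (nm in sp) {
      if (is.null(net[[nm]])) {
        variables[[nm]]$boundary <- TRUE
        next
      }
      rhs <- NULL
      for (term in net[[nm]]) {
        piece <- as.name(term[[2]])
        rhs <- if (is.null(rhs)) {
          if (as.numeric(term[[1]]) < 0) call("-", piece) else piece
        } else {
          call(if (as.numeric(term[[1]]) < 0) "-" else "+", rhs, piece)
        }
      }
      eq_id <- paste0("d_", nm)
      equations[[eq_id]] <- make_equation(eq_id, nm, rhs,
                                          is_derivative = TRUE)
      variables[[nm]]$is_state <- TRUE
      variables[[nm]]$equation_id <- eq_id
    }

    model <- new_ingested_model(
      variables = variables, equations = equations, reactions = reactions,
      source_format = "sbml",
      source_uri = paste0("fixture:random-", seed),
      nominal_values = nominal)
    attr(model, "fixture_spec") <- list(
      name = "random-network", n_species = n_species,
      n_reactions = n_reactions, n_modifiers = n_modifiers,
      seed = seed, acyclic = acyclic,
      dynamic_species = names(net))
    model
  })
}
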