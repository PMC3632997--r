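# Minimal SBML Level 2/3 support on xml2: species, compartments,
# parameters, reactions with kinetic-law MathML, rate/assignment rules,
# MIRIAM-style annotation URIs and SBO modifier terms. Covers the subset of
# SBML needed to ingest explicitly tagged reaction networks; events,
# algebraic rules and function definitions are out of scope.

SBO_POLARITY <- c(
  "SBO:0000020" = -1, "SBO:0000206" = -1, "SBO:0000207" = -1,
  "SBO:0000536" = -1, "SBO:0000537" = -1, "SBO:0000639" = -1,
  "SBO:0000013" = +1, "SBO:0000021" = +1, "SBO:0000459" = +1,
  "SBO:0000460" = +1, "SBO:0000461" = +1, "SBO:0000462" = +1,
  "SBO:0000594" = +1
)

URN_PREFIX <- "urn:x-physiomap:"

#' Read an SBML model
#'
#' Ingests an SBML Level 2 or Level 3 file. Species, compartments and
#' parameters become model variables; each reaction becomes a reaction
#' record plus a rate variable (named after the reaction) whose equation is
#' the kinetic-law math; time-derivative equations for non-boundary species
#' are materialized from the stoichiometry; rate rules and assignment rules
#' become equations. MIRIAM-style biological-qualifier URIs (both `is` and
#' `isVersionOf`) populate composite annotations where a URI maps to a
#' registry term (by external IRI) or encodes a term directly
#' (`urn:x-physiomap:` URIs, the dialect written by [write_sbml()]);
#' unrecognized URIs produce a warning and leave the annotation unset.
#' Modifier polarity is taken from inhibitor-/stimulator-family SBO terms,
#' and is 0 (unknown) otherwise.
#'
#' @param path Path to the SBML file.
#' @param registry A `term_registry` for resolving annotation IRIs.
#' @return An `ingested_model`.
#' @export
read_sbml <- function(path, registry = load_registry()) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("cannot parse SBML file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (xml2::xml_name(doc) != "sbml") {
    stop("not an SBML document: ", path, call. = FALSE)
  }
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, "./model")
  if (inherits(model_node, "xml_missing")) {
    stop("SBML file has no <model> element: ", path, call. = FALSE)
  }

  variables <- list()
  equations <- list()
  reactions <- list()
  nominal <- list()

  for (cp in xml2::xml_find_all(model_node,
                                "./listOfCompartments/compartment")) {
    id <- xml2::xml_attr(cp, "id")
    variables[[id]] <- make_variable(id, boundary = TRUE)
    size <- suppressWarnings(as.numeric(xml2::xml_attr(cp, "size")))
    if (is.finite(size)) nominal[[id]] <- size
  }

  for (sp in xml2::xml_find_all(model_node, "./listOfSpecies/species")) {
    id <- xml2::xml_attr(sp, "id")
    boundary <- isTRUE(xml2::xml_attr(sp, "boundaryCondition") == "true") ||
      isTRUE(xml2::xml_attr(sp, "constant") == "true")
    ann <- read_miriam_annotation(sp, id, registry)
    variables[[id]] <- make_variable(id, annotation = ann,
                                     boundary = boundary)
    init <- suppressWarnings(as.numeric(xml2::xml_attr(sp, "initialAmount")))
    if (!is.finite(init)) {
      init <- suppressWarnings(
        as.numeric(xml2::xml_attr(sp, "initialConcentration")))
    }
    if (is.finite(init)) nominal[[id]] <- init
  }

  for (pm in xml2::xml_find_all(model_node, "./listOfParameters/parameter")) {
    id <- xml2::xml_attr(pm, "id")
    variables[[id]] <- make_variable(id, boundary = TRUE)
    val <- suppressWarnings(as.numeric(xml2::xml_attr(pm, "value")))
    if (is.finite(val)) nominal[[id]] <- val
  }

  for (rx in xml2::xml_find_all(model_node, "./listOfReactions/reaction")) {
    rid <- xml2::xml_attr(rx, "id")
    rev_attr <- xml2::xml_attr(rx, "reversible")
    reversible <- if (is.na(rev_attr)) TRUE else rev_attr == "true"
    read_refs <- function(xp) {
      lapply(xml2::xml_find_all(rx, xp), function(ref) {
        st <- suppressWarnings(as.numeric(xml2::xml_attr(ref,
                                                         "stoichiometry")))
        list(species = xml2::xml_attr(ref, "species"),
             stoich = if (is.finite(st)) st else 1)
      })
    }
    modifiers <- lapply(
      xml2::xml_find_all(rx, "./listOfModifiers/modifierSpeciesReference"),
      function(ref) {
        sbo <- xml2::xml_attr(ref, "sboTerm")
        pol <- if (!is.na(sbo) && sbo %in% names(SBO_POLARITY)) {
          unname(SBO_POLARITY[[sbo]])
        } else 0
        list(species = xml2::xml_attr(ref, "species"), polarity = pol)
      })
    reactions[[length(reactions) + 1L]] <- list(
      id = rid,
      reactants = read_refs("./listOfReactants/speciesReference"),
      products = read_refs("./listOfProducts/speciesReference"),
      modifiers = modifiers,
      rate_variable = rid,
      reversible = reversible
    )
    # rate variable + kinetic-law equation
    if (!is.null(variables[[rid]])) {
      stop("SBML reaction id '", rid, "' collides with a variable name",
           call. = FALSE)
    }
    variables[[rid]] <- make_variable(
      rid,
      annotation = composite_annotation("opbx:ChemicalFlowRate",
                                        free_label = rid),
      equation_id = rid)
    math <- xml2::xml_find_first(rx, "./kineticLaw/math")
    if (!inherits(math, "xml_missing")) {
      for (lp in xml2::xml_find_all(
        rx, "./kineticLaw/listOfLocalParameters/localParameter | ./kineticLaw/listOfParameters/parameter")) {
        pid <- xml2::xml_attr(lp, "id")
        if (is.null(variables[[pid]])) {
          variables[[pid]] <- make_variable(pid, boundary = TRUE)
        }
        val <- suppressWarnings(as.numeric(xml2::xml_attr(lp, "value")))
        if (is.finite(val) && is.null(nominal[[pid]])) nominal[[pid]] <- val
      }
      equations[[rid]] <- mathml_to_equation(math, rid, target = rid,
                                             is_derivative = FALSE)
    }
  }

  for (rl in xml2::xml_find_all(model_node, "./listOfRules/rateRule")) {
    tgt <- xml2::xml_attr(rl, "variable")
    math <- xml2::xml_find_first(rl, "./math")
    eq_id <- paste0("d_", tgt)
    equations[[eq_id]] <- mathml_to_equation(math, eq_id, target = tgt,
                                             is_derivative = TRUE)
  }
  for (rl in xml2::xml_find_all(model_node, "./listOfRules/assignmentRule")) {
    tgt <- xml2::xml_attr(rl, "variable")
    math <- xml2::xml_find_first(rl, "./math")
    equations[[tgt]] <- mathml_to_equation(math, tgt, target = tgt,
                                           is_derivative = FALSE)
  }

  # materialize species time derivatives from the stoichiometry
  net <- list()  # species -> list of (sign*stoich, rate_var)
  for (rx in reactions) {
    for (sr in rx$reactants) {
      net[[sr$species]] <- c(net[[sr$species]],
                             list(list(coef = -sr$stoich, rate = rx$id)))
    }
    for (sr in rx$products) {
      net[[sr$species]] <- c(net[[sr$species]],
                             list(list(coef = +sr$stoich, rate = rx$id)))
    }
  }
  for (sp in names(net)) {
    if (isTRUE(variables[[sp]]$boundary)) next
    eq_id <- paste0("d_", sp)
    if (!is.null(equations[[eq_id]])) next  # a rate rule already defines it
    rhs <- NULL
    for (term in net[[sp]]) {
      mag <- if (abs(term$coef) == 1) as.name(term$rate)
      else call("*", abs(term$coef), as.name(term$rate))
      if (is.null(rhs)) {
        rhs <- if (term$coef < 0) call("-", mag) else mag
      } else {
        rhs <- call(if (term$coef < 0) "-" else "+", rhs, mag)
      }
    }
    equations[[eq_id]] <- make_equation(eq_id, sp, rhs, is_derivative = TRUE)
  }

  for (eq_id in names(equations)) {
    eq <- equations[[eq_id]]
    if (eq$is_derivative) {
      variables[[eq$target]]$is_state <- TRUE
      variables[[eq$target]]$boundary <- FALSE
      variables[[eq$target]]$equation_id <- eq_id
    } else if (is.null(variables[[eq$target]]$equation_id)) {
      variables[[eq$target]]$equation_id <- eq_id
    }
    if (!eq$is_derivative) variables[[eq$target]]$boundary <- FALSE
  }

  # auto-declare any symbols the math references but the lists did not
  referenced <- unique(unlist(lapply(equations, `[[`, "rhs_dependencies")))
  for (nm in sort(setdiff(referenced, names(variables)))) {
    warning("SBML math references undeclared symbol '", nm,
            "'; treating it as an unannotated parameter", call. = FALSE)
    variables[[nm]] <- make_variable(nm, boundary = TRUE)
  }

  new_ingested_model(variables = variables, equations = equations,
                     reactions = reactions, source_format = "sbml",
                     source_uri = path, nominal_values = nominal)
}

read_miriam_annotation <- function(node, species_id, registry) {
  lis <- xml2::xml_find_all(
    node, paste0(".//*[local-name()='annotation']",
                 "//*[local-name()='is' or local-name()='isVersionOf']",
                 "//*[local-name()='li']"))
  if (length(lis) == 0L) return(NULL)
  uris <- vapply(lis, function(li) {
    attrs <- xml2::xml_attrs(li)
    hit <- attrs[grepl("(^|:)resource$", names(attrs))]
    if (length(hit)) hit[[1]] else NA_character_
  }, character(1))
  uris <- uris[!is.na(uris)]
  property <- "opbx:ChemicalAmount"  # SBML species carry amounts
  bearer <- list()
  unknown <- character(0)
  for (uri in uris) {
    if (startsWith(uri, paste0(URN_PREFIX, "prop:"))) {
      property <- sub(paste0(URN_PREFIX, "prop:"), "", uri, fixed = TRUE)
    } else if (startsWith(uri, paste0(URN_PREFIX, "rel:"))) {
      rest <- sub(paste0(URN_PREFIX, "rel:"), "", uri, fixed = TRUE)
      rel <- sub(":.*$", "", rest)
      term <- sub("^[^:]*:", "", rest)
      bearer <- c(bearer, list(c(term, rel)))
    } else if (startsWith(uri, paste0(URN_PREFIX, "term:"))) {
      term <- sub(paste0(URN_PREFIX, "term:"), "", uri, fixed = TRUE)
      bearer <- c(bearer, list(c(term, "none")))
    } else {
      match <- Filter(function(t) identical(t$external_iri, uri),
                      registry$terms)
      if (length(match)) {
        bearer <- c(bearer, list(c(match[[1L]]$id, "none")))
      } else {
        unknown <- c(unknown, uri)
      }
    }
  }
  if (length(unknown)) {
    warning("species '", species_id, "': unrecognized ontology URI(s) ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(bearer) == 0L) return(NULL)
  composite_annotation(property, bearer = bearer)
}

mathml_to_equation <- function(math, eq_id, target, is_derivative) {
  root <- xml2::xml_find_first(math, "./*")
  res <- tryCatch(mathml_to_expr(root), error = function(e) e)
  if (inherits(res, "error")) {
    warning("unsupported MathML in equation for '", target, "' (",
            conditionMessage(res),
            "); retaining dependencies only", call. = FALSE)
    deps <- sort(unique(xml2::xml_text(xml2::xml_find_all(math, ".//ci"))))
    deps <- trimws(deps)
    return(list(id = eq_id, target = target, is_derivative = is_derivative,
                rhs = NULL, rhs_dependencies = deps, unsupported = TRUE))
  }
  make_equation(eq_id, target, res, is_derivative = is_derivative)
}

mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") {
    val <- suppressWarnings(as.numeric(trimws(xml2::xml_text(node))))
    if (!is.finite(val)) stop("bad <cn> literal")
    return(val)
  }
  if (nm != "apply") stop("unsupported MathML element <", nm, ">")
  kids <- xml2::xml_find_all(node, "./*")
  op <- xml2::xml_name(kids[[1L]])
  args <- lapply(kids[-1L], mathml_to_expr)
  rop <- switch(op, plus = "+", minus = "-", times = "*", divide = "/",
                power = "^", NULL)
  if (is.null(rop)) stop("unsupported MathML operator <", op, ">")
  if (op == "minus" && length(args) == 1L) return(call("-", args[[1L]]))
  if (length(args) < 2L) stop("operator <", op, "> needs two operands")
  Reduce(function(a, b) call(rop, a, b), args)
}

expr_to_mathml <- function(expr, indent = "") {
  if (is.numeric(expr)) {
    return(paste0(indent, "<cn> ", format(expr, digits = 15), " </cn>"))
  }
  if (is.symbol(expr)) {
    return(paste0(indent, "<ci> ", as.character(expr), " </ci>"))
  }
  op <- as.character(expr[[1L]])
  if (op == "(") return(expr_to_mathml(expr[[2L]], indent))
  tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                "/" = "divide", "^" = "power",
                stop("operator '", op, "' has no MathML rendering"))
  args <- as.list(expr)[-1L]
  inner <- vapply(args, expr_to_mathml, character(1),
                  indent = paste0(indent, "  "))
  paste0(indent, "<apply>\n", indent, "  <", tag, "/>\n",
         paste(inner, collapse = "\n"), "\n", indent, "</apply>")
}

annotation_to_uris <- function(ann, registry) {
  uris <- character(0)
  if (!identical(ann$property, "opbx:ChemicalAmount")) {
    uris <- c(uris, paste0(URN_PREFIX, "prop:", ann$property))
  }
  for (i in seq_along(ann$bearer)) {
    b <- ann$bearer[[i]]
    if (b$relation == "none") {
      term <- registry$terms[[b$term]]
      if (!is.null(term) && !is.null(term$external_iri) && i == 1L &&
          length(ann$bearer) == 1L) {
        uris <- c(uris, term$external_iri)
      } else {
        uris <- c(uris, paste0(URN_PREFIX, "term:", b$term))
      }
    } else {
      uris <- c(uris, paste0(URN_PREFIX, "rel:", b$relation, ":", b$term))
    }
  }
  uris
}

#' Write an ingested reaction model as SBML
#'
#' Serializes a model with reaction records to a minimal SBML Level 3
#' document (one compartment, species, global parameters, reactions with
#' kinetic-law MathML, MIRIAM-style annotation URIs, SBO modifier terms).
#' Species are the variables referenced by the reaction records; remaining
#' constant variables become parameters. Output ordering is deterministic.
#'
#' @param model An `ingested_model` with reactions.
#' @param path Output path, or `NULL` to return the SBML text.
#' @param model_id Identifier for the `<model>` element.
#' @param registry A `term_registry` used to emit external IRIs.
#' @return SBML text, invisibly when written to a file.
#' @export
write_sbml <- function(model, path = NULL, model_id = "model",
                       registry = load_registry()) {
  species_names <- unique(unlist(lapply(model$reactions, function(rx) {
    c(vapply(rx$reactants, `[[`, character(1), "species"),
      vapply(rx$products, `[[`, character(1), "species"),
      vapply(rx$modifiers, `[[`, character(1), "species"))
  })))
  if (length(species_names) == 0L) {
    species_names <- names(Filter(function(v) {
      !is.null(v$annotation) && length(v$annotation$bearer) > 0L
    }, model$variables))
  }
  species_names <- sort(species_names)
  rate_vars <- vapply(model$reactions, function(rx) {
    if (is.null(rx$rate_variable)) "" else rx$rate_variable
  }, character(1))
  param_names <- sort(setdiff(names(model$variables),
                              c(species_names, rate_vars)))
  param_names <- Filter(function(nm) {
    v <- model$variables[[nm]]
    !isTRUE(v$is_state) && is.null(v$equation_id)
  }, param_names)

  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  nomval <- function(nm, default = 1) {
    v <- model$nominal_values[[nm]]
    if (is.null(v)) default else v
  }

  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "level=\"3\" version=\"1\">"),
    paste0("  <model id=\"", esc(model_id), "\">"),
    "    <listOfCompartments>",
    paste0("      <compartment id=\"cell\" size=\"1\" constant=\"true\"/>"),
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  for (nm in species_names) {
    v <- model$variables[[nm]]
    head <- paste0("      <species id=\"", esc(nm),
                   "\" compartment=\"cell\" initialAmount=\"",
                   format(nomval(nm), digits = 15),
                   "\" hasOnlySubstanceUnits=\"true\" boundaryCondition=\"",
                   if (isTRUE(v$boundary)) "true" else "false",
                   "\" constant=\"false\"")
    if (is.null(v$annotation) || length(v$annotation$bearer) == 0L) {
      out <- c(out, paste0(head, "/>"))
    } else {
      uris <- annotation_to_uris(v$annotation, registry)
      out <- c(out, paste0(head, ">"),
               "        <annotation>",
               paste0("          <rdf:RDF xmlns:rdf=\"http://www.w3.org/",
                      "1999/02/22-rdf-syntax-ns#\" xmlns:bqbiol=\"http://",
                      "biomodels.net/biology-qualifiers/\">"),
               paste0("            <rdf:Description rdf:about=\"#", esc(nm),
                      "\">"),
               "              <bqbiol:is>",
               "                <rdf:Bag>",
               paste0("                  <rdf:li rdf:resource=\"", esc(uris),
                      "\"/>"),
               "                </rdf:Bag>",
               "              </bqbiol:is>",
               "            </rdf:Description>",
               "          </rdf:RDF>",
               "        </annotation>",
               "      </species>")
    }
  }
  out <- c(out, "    </listOfSpecies>")
  if (length(param_names)) {
    out <- c(out, "    <listOfParameters>")
    for (nm in param_names) {
      out <- c(out, paste0("      <parameter id=\"", esc(nm), "\" value=\"",
                           format(nomval(nm), digits = 15),
                           "\" constant=\"true\"/>"))
    }
    out <- c(out, "    </listOfParameters>")
  }
  out <- c(out, "    <listOfReactions>")
  for (rx in model$reactions) {
    out <- c(out, paste0("      <reaction id=\"", esc(rx$id),
                         "\" reversible=\"",
                         if (isTRUE(rx$reversible)) "true" else "false",
                         "\">"))
    ref_block <- function(tag, refs, ref_el) {
      if (length(refs) == 0L) return(character(0))
      c(paste0("        <", tag, ">"),
        vapply(refs, function(sr) {
          if (ref_el == "speciesReference") {
            paste0("          <speciesReference species=\"", esc(sr$species),
                   "\" stoichiometry=\"", format(sr$stoich, digits = 15),
                   "\" constant=\"true\"/>")
          } else {
            sbo <- if (sr$polarity == -1) " sboTerm=\"SBO:0000020\""
            else if (sr$polarity == 1) " sboTerm=\"SBO:0000459\""
            else ""
            paste0("          <modifierSpeciesReference species=\"",
                   esc(sr$species), "\"", sbo, "/>")
          }
        }, character(1)),
        paste0("        </", tag, ">"))
    }
    out <- c(out,
             ref_block("listOfReactants", rx$reactants, "speciesReference"),
             ref_block("listOfProducts", rx$products, "speciesReference"),
             ref_block("listOfModifiers", rx$modifiers,
                       "modifierSpeciesReference"))
    rate_eq <- if (!is.null(rx$rate_variable)) {
      model$equations[[model$variables[[rx$rate_variable]]$equation_id]]
    }
    if (!is.null(rate_eq) && !is.null(rate_eq$rhs)) {
      out <- c(out,
               "        <kineticLaw>",
               paste0("          <math xmlns=\"http://www.w3.org/1998/",
                      "Math/MathML\">"),
               expr_to_mathml(rate_eq$rhs, indent = "            "),
               "          </math>",
               "        </kineticLaw>")
    }
    out <- c(out, "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>", "  </model>", "</sbml>")
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(text, path, sep = "")
  invisible(text)
}
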