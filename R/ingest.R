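#' Ingested model container
#'
#' A uniform in-memory representation of a biosimulation model, shared by
#' the SBML reader, the equation-model reader and the model generators.
#' It holds annotated variables, equations (expression trees), explicit
#' reaction records where the source format supplies them, and nominal
#' numeric values (initial conditions and parameter values).
#'
#' @param variables Named list of variable records (`name`, `annotation`,
#'   `is_state`, `equation_id`, `boundary`).
#' @param equations Named list of equation records (`id`, `target`,
#'   `is_derivative`, `rhs`, `rhs_dependencies`).
#' @param reactions List of reaction records (`id`, `reactants`, `products`,
#'   `modifiers`, `rate_variable`, `reversible`).
#' @param source_format `"sbml"` or `"eqn"`.
#' @param source_uri Provenance string for the model source.
#' @param nominal_values Named list of numeric values.
#' @return An `ingested_model` object.
#' @keywords internal
new_ingested_model <- function(variables = list(), equations = list(),
                               reactions = list(), source_format = "eqn",
                               source_uri = "", nominal_values = list()) {
  m <- structure(list(variables = variables, equations = equations,
                      reactions = reactions, source_format = source_format,
                      source_uri = source_uri,
                      nominal_values = nominal_values),
                 class = "ingested_model")
  check_model_integrity(m)
  m
}

check_model_integrity <- function(m) {
  vn <- names(m$variables)
  if (anyDuplicated(vn)) {
    stop("duplicate variable names: ",
         paste(unique(vn[duplicated(vn)]), collapse = ", "), call. = FALSE)
  }
  for (eq in m$equations) {
    if (!(eq$target %in% vn)) {
      stop("equation '", eq$id, "' targets undeclared variable '",
           eq$target, "'", call. = FALSE)
    }
    missing <- setdiff(eq$rhs_dependencies, vn)
    if (length(missing)) {
      stop("equation '", eq$id, "' references undeclared variables: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  for (rx in m$reactions) {
    if (length(rx$reactants) == 0L && length(rx$products) == 0L) {
      stop("reaction '", rx$id, "' has neither reactants nor products",
           call. = FALSE)
    }
    for (sr in c(rx$reactants, rx$products)) {
      if (!(sr$species %in% vn)) {
        stop("reaction '", rx$id, "' references undeclared species '",
             sr$species, "'", call. = FALSE)
      }
      if (!is.numeric(sr$stoich) || sr$stoich <= 0) {
        stop("reaction '", rx$id, "' has non-positive stoichiometry for '",
             sr$species, "'", call. = FALSE)
      }
    }
    for (md in rx$modifiers) {
      if (!(md$species %in% vn)) {
        stop("reaction '", rx$id, "' references undeclared modifier '",
             md$species, "'", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.ingested_model <- function(x, ...) {
  cat("<ingested_model> [", x$source_format, "] ",
      length(x$variables), " variables, ", length(x$equations),
      " equations, ", length(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

make_variable <- function(name, annotation = NULL, is_state = FALSE,
                          equation_id = NULL, boundary = FALSE) {
  list(name = name, annotation = annotation, is_state = is_state,
       equation_id = equation_id, boundary = boundary)
}

make_equation <- function(id, target, rhs, is_derivative = FALSE) {
  list(id = id, target = target, is_derivative = is_derivative,
       rhs = rhs, rhs_dependencies = expr_dependencies(rhs))
}

# Equation defining a variable (its own, or its derivative's when a state).
defining_equation <- function(model, name) {
  v <- model$variables[[name]]
  if (is.null(v) || is.null(v$equation_id)) return(NULL)
  model$equations[[v$equation_id]]
}

#' Apply sidecar annotations to an ingested model
#'
#' A sidecar is a JSON file supplying composite annotations for models whose
#' source format carries none:
#' `{"variables": {name: {"property": CURIE, "bearer": [[CURIE, rel], ...],
#' "label": text}}}`. Annotations of variables named in the sidecar are set
#' or overwritten; all other variables are untouched. Names that do not
#' match any model variable are reported in the `unknown_variables`
#' attribute of the result.
#'
#' @param model An `ingested_model`.
#' @param sidecar_path Path to the sidecar JSON file.
#' @param registry A `term_registry`; property terms in the sidecar must
#'   resolve in it. Bearer terms are treated as opaque identifiers.
#' @return The updated model, with attribute `unknown_variables`.
#' @export
apply_sidecar_annotations <- function(model, sidecar_path,
                                      registry = load_registry()) {
  side <- jsonlite::read_json(sidecar_path)
  vars <- side$variables
  if (is.null(vars)) vars <- list()
  unknown <- character(0)
  for (nm in names(vars)) {
    spec <- vars[[nm]]
    if (!is.null(spec$property)) {
      registry_term(registry, spec$property)
    } else {
      stop("sidecar entry for '", nm, "' lacks a property term",
           call. = FALSE)
    }
    if (is.null(model$variables[[nm]])) {
      unknown <- c(unknown, nm)
      next
    }
    bearer <- lapply(spec$bearer, function(b) unlist(b))
    if (length(bearer) == 0L) bearer <- NULL
    model$variables[[nm]]$annotation <- composite_annotation(
      property = spec$property, bearer = bearer,
      free_label = if (!is.null(spec$label)) spec$label else
        if (is.null(bearer)) nm else NULL
    )
  }
  attr(model, "unknown_variables") <- unknown
  model
}

#' Build the variable dependency graph of a model
#'
#' Directed edge `u -> v` for every variable `u` appearing on the right-hand
#' side of the equation defining `v` (for a state variable, the equation
#' defining its time derivative). Node and edge orderings are lexicographic,
#' so the graph is identical across repeated calls and platforms.
#'
#' @param model An `ingested_model`.
#' @return A `dependency_graph`: list with `nodes` (character vector) and
#'   `edges` (data frame with columns `from`, `to`).
#' @export
build_dependency_graph <- function(model) {
  nodes <- sort(names(model$variables))
  from <- character(0)
  to <- character(0)
  for (eq in model$equations) {
    deps <- sort(eq$rhs_dependencies)
    from <- c(from, deps)
    to <- c(to, rep(eq$target, length(deps)))
  }
  edges <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  edges <- unique(edges)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "dependency_graph")
}

#' @export
print.dependency_graph <- function(x, ...) {
  cat("<dependency_graph> ", length(x$nodes), " variables, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

dep_predecessors <- function(depgraph, v) {
  depgraph$edges$from[depgraph$edges$to == v]
}

dep_successors <- function(depgraph, v) {
  depgraph$edges$to[depgraph$edges$from == v]
}

#' Sign of the partial dependence of one variable on another
#'
#' Numerically estimates the sign of the partial derivative of the equation
#' defining `v` with respect to `u`, by central finite difference at the
#' model's nominal values (symbols without a value default to 1.0). The
#' relative step is 1e-6; a central difference below 1e-12 in magnitude
#' reports 0; a sign that flips between steps 1e-6 and 1e-4 (or an
#' evaluation failure, e.g. division by zero at the nominal point) reports
#' indeterminate, encoded as `NA`.
#'
#' @param model An `ingested_model`.
#' @param u,v Variable names; `u` must appear in the equation defining `v`.
#' @return `+1`, `-1`, `0`, or `NA` (indeterminate).
#' @export
partial_dependence_sign <- function(model, u, v) {
  eq <- defining_equation(model, v)
  if (is.null(eq) || !(u %in% eq$rhs_dependencies)) {
    stop("no dependency edge ", u, " -> ", v, call. = FALSE)
  }
  bindings <- nominal_bindings(model)
  x0 <- bindings[[u]]
  diff_at <- function(rel_step) {
    h <- rel_step * max(abs(x0), 1.0)
    up <- bindings; up[[u]] <- x0 + h
    dn <- bindings; dn[[u]] <- x0 - h
    fu <- eval_expression(eq$rhs, up)
    fd <- eval_expression(eq$rhs, dn)
    fu - fd
  }
  d1 <- tryCatch(diff_at(1e-6), error = function(e) NA_real_)
  d2 <- tryCatch(diff_at(1e-4), error = function(e) NA_real_)
  if (!is.finite(d1) || !is.finite(d2)) {
    warning("expression for '", v, "' not evaluable near the nominal point; ",
            "sign of dependence on '", u, "' is indeterminate", call. = FALSE)
    return(NA_real_)
  }
  if (abs(d1) < 1e-12) return(0)
  s1 <- sign(d1)
  s2 <- if (abs(d2) < 1e-12) s1 else sign(d2)
  if (s1 != s2) return(NA_real_)
  s1
}
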