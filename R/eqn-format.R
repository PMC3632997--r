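#' Read a declarative annotated equation model
#'
#' Parses the package's line-oriented equation-model format, a minimal
#' stand-in for general equation-based modeling languages. One statement per
#' line:
#' \preformatted{
#' var NAME \{property: CURIE, entity: CURIE [rel CURIE ...], domain: ID\}
#' eq NAME = expression        # algebraic assignment
#' eq NAME' = expression       # time derivative (marks NAME as a state)
#' init NAME = number
#' # comment
#' }
#' The annotation block and all of its parts are optional. Expressions use
#' `+ - * / ^`, unary minus, parentheses, numbers and variable references.
#' Symbols referenced in an equation but never declared are auto-declared as
#' unannotated parameters, with a warning.
#'
#' @param path Path to the model file.
#' @param registry A `term_registry` used to check property terms.
#' @return An `ingested_model`.
#' @export
read_equation_model <- function(path, registry = load_registry()) {
  lines <- readLines(path, warn = FALSE)
  variables <- list()
  equations <- list()
  nominal <- list()

  for (i in seq_along(lines)) {
    line <- trimws(sub("#.*$", "", lines[[i]]))
    if (!nzchar(line)) next
    loc <- paste0(basename(path), ":", i)

    if (grepl("^var\\s+", line)) {
      m <- regmatches(line, regexec(
        "^var\\s+([A-Za-z][A-Za-z0-9_]*)\\s*(\\{(.*)\\})?\\s*$", line))[[1]]
      if (length(m) == 0L) stop("syntax error at ", loc, ": bad var statement",
                                call. = FALSE)
      name <- m[[2]]
      if (!is.null(variables[[name]])) {
        stop("duplicate variable '", name, "' at ", loc, call. = FALSE)
      }
      ann <- if (nzchar(m[[4]])) parse_eqn_annotation(m[[4]], name, registry,
                                                     loc) else NULL
      variables[[name]] <- make_variable(name, annotation = ann)
    } else if (grepl("^eq\\s+", line)) {
      m <- regmatches(line, regexec(
        "^eq\\s+([A-Za-z][A-Za-z0-9_]*)('?)\\s*=\\s*(.+)$", line))[[1]]
      if (length(m) == 0L) stop("syntax error at ", loc, ": bad eq statement",
                                call. = FALSE)
      target <- m[[2]]
      is_deriv <- m[[3]] == "'"
      rhs <- parse_expression(m[[4]], where = loc)
      eq_id <- paste0(if (is_deriv) "d_" else "", target)
      if (!is.null(equations[[eq_id]])) {
        stop("duplicate equation for '", target, "' at ", loc, call. = FALSE)
      }
      equations[[eq_id]] <- make_equation(eq_id, target, rhs,
                                          is_derivative = is_deriv)
    } else if (grepl("^init\\s+", line)) {
      m <- regmatches(line, regexec(
        "^init\\s+([A-Za-z][A-Za-z0-9_]*)\\s*=\\s*([-+0-9.eE]+)\\s*$",
        line))[[1]]
      if (length(m) == 0L) stop("syntax error at ", loc,
                                ": bad init statement", call. = FALSE)
      val <- suppressWarnings(as.numeric(m[[3]]))
      if (is.na(val)) stop("syntax error at ", loc, ": bad number", call. = FALSE)
      nominal[[m[[2]]]] <- val
    } else {
      stop("syntax error at ", loc, ": unrecognized statement", call. = FALSE)
    }
  }

  # auto-declare referenced-but-undeclared symbols
  referenced <- unique(c(unlist(lapply(equations, `[[`, "rhs_dependencies")),
                         vapply(equations, `[[`, character(1), "target"),
                         names(nominal)))
  auto <- setdiff(referenced, names(variables))
  if (length(auto)) {
    warning("auto-declaring unannotated parameters: ",
            paste(sort(auto), collapse = ", "), call. = FALSE)
    for (nm in sort(auto)) variables[[nm]] <- make_variable(nm)
  }

  # wire equations to variables; derivative marks the state
  for (eq_id in names(equations)) {
    eq <- equations[[eq_id]]
    if (eq$is_derivative) {
      variables[[eq$target]]$is_state <- TRUE
      variables[[eq$target]]$equation_id <- eq_id
    } else if (is.null(variables[[eq$target]]$equation_id)) {
      variables[[eq$target]]$equation_id <- eq_id
    }
  }
  # declared variables with neither equation nor derivative are constants
  for (nm in names(variables)) {
    v <- variables[[nm]]
    if (is.null(v$equation_id)) variables[[nm]]$boundary <- TRUE
  }

  new_ingested_model(variables = variables, equations = equations,
                     reactions = list(), source_format = "eqn",
                     source_uri = path, nominal_values = nominal)
}

parse_eqn_annotation <- function(body, var_name, registry, loc) {
  parts <- strsplit(body, ",", fixed = TRUE)[[1]]
  property <- NULL
  bearer <- NULL
  label <- NULL
  for (p in parts) {
    kv <- regmatches(p, regexec("^\\s*([a-z]+)\\s*:\\s*(.+?)\\s*$", p))[[1]]
    if (length(kv) == 0L) stop("syntax error at ", loc,
                               ": bad annotation part '", trimws(p), "'",
                               call. = FALSE)
    key <- kv[[2]]
    val <- kv[[3]]
    if (key == "property") {
      registry_term(registry, val)
      property <- val
    } else if (key == "entity") {
      toks <- strsplit(trimws(val), "\\s+")[[1]]
      if (length(toks) %% 2L != 1L) {
        stop("syntax error at ", loc, ": entity chain must alternate ",
             "term rel term ...", call. = FALSE)
      }
      bearer <- list(c(toks[[1]], "none"))
      k <- 2L
      while (k < length(toks)) {
        bearer <- c(bearer, list(c(toks[[k + 1L]], toks[[k]])))
        k <- k + 2L
      }
    } else if (key == "domain") {
      # accepted and ignored: the property term carries the domain
    } else if (key == "label") {
      label <- val
    } else {
      stop("syntax error at ", loc, ": unknown annotation key '", key, "'",
           call. = FALSE)
    }
  }
  if (is.null(property)) {
    stop("annotation for '", var_name, "' at ", loc,
         " lacks a property term", call. = FALSE)
  }
  if (is.null(bearer) && is.null(label)) label <- var_name
  composite_annotation(property, bearer = bearer, free_label = label)
}

#' Serialize an ingested model to the equation-model format
#'
#' Inverse of [read_equation_model()] for models without reaction records.
#' Output is deterministic: variables, equations and initial values are
#' written in lexicographic order.
#'
#' @param model An `ingested_model`.
#' @param path Output file path, or `NULL` to return the text.
#' @return The text, invisibly when written to a file.
#' @export
write_equation_model <- function(model, path = NULL) {
  lines <- character(0)
  for (nm in sort(names(model$variables))) {
    v <- model$variables[[nm]]
    if (is.null(v$annotation)) {
      lines <- c(lines, paste0("var ", nm))
    } else {
      ann <- v$annotation
      parts <- paste0("property: ", ann$property)
      if (length(ann$bearer)) {
        chain <- ann$bearer[[1L]]$term
        for (b in ann$bearer[-1L]) {
          chain <- paste(chain, b$relation, b$term)
        }
        parts <- c(parts, paste0("entity: ", chain))
      } else if (!is.null(ann$free_label)) {
        parts <- c(parts, paste0("label: ", ann$free_label))
      }
      lines <- c(lines, paste0("var ", nm, " {", paste(parts, collapse = ", "),
                               "}"))
    }
  }
  eq_order <- order(vapply(model$equations, `[[`, character(1), "target"),
                    !vapply(model$equations, `[[`, logical(1), "is_derivative"))
  for (eq in model$equations[eq_order]) {
    lines <- c(lines, paste0("eq ", eq$target,
                             if (eq$is_derivative) "'" else "",
                             " = ", deparse_expression(eq$rhs)))
  }
  for (nm in sort(names(model$nominal_values))) {
    lines <- c(lines, paste0("init ", nm, " = ",
                             format(model$nominal_values[[nm]], digits = 15)))
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(text, path, sep = "")
  invisible(text)
}
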