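# Expression handling for model equations.
#
# Right-hand sides are native R language objects restricted to the
# arithmetic subset +, -, *, /, ^, unary minus, parentheses, numeric
# literals and variable references. Restricting the language keeps numeric
# sign analysis well-defined.

allowed_ops <- c("+", "-", "*", "/", "^", "(")

parse_expression <- function(text, where = NULL) {
  expr <- tryCatch(str2lang(text), error = function(e) {
    stop("cannot parse expression", if (!is.null(where)) paste0(" (", where, ")"),
         ": ", conditionMessage(e), call. = FALSE)
  })
  check_expression(expr, where = where)
  expr
}

check_expression <- function(expr, where = NULL) {
  if (is.numeric(expr) || is.symbol(expr)) return(invisible(TRUE))
  if (is.call(expr)) {
    op <- as.character(expr[[1L]])
    if (!(op %in% allowed_ops)) {
      stop("operator or function '", op, "' is not part of the equation ",
           "language", if (!is.null(where)) paste0(" (", where, ")"),
           call. = FALSE)
    }
    for (arg in as.list(expr)[-1L]) check_expression(arg, where = where)
    return(invisible(TRUE))
  }
  stop("unsupported expression element",
       if (!is.null(where)) paste0(" (", where, ")"), call. = FALSE)
}

expr_dependencies <- function(expr) sort(unique(all.vars(expr)))

deparse_expression <- function(expr) {
  paste(deparse(expr, width.cutoff = 500L), collapse = " ")
}

eval_expression <- function(expr, bindings) {
  eval(expr, envir = bindings, enclos = baseenv())
}

# Numeric bindings for a model at its nominal point; symbols without a
# declared value default to 1.0 (a positive point avoids spurious zeros in
# monotone rate laws).
nominal_bindings <- function(model, override = NULL) {
  vals <- as.list(rep(1.0, length(model$variables)))
  names(vals) <- names(model$variables)
  for (nm in names(model$nominal_values)) {
    vals[[nm]] <- model$nominal_values[[nm]]
  }
  for (nm in names(override)) vals[[nm]] <- override[[nm]]
  vals
}
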