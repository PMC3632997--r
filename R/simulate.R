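#' Simulate an ingested model's ODE system
#'
#' Deterministic fixed-step 4th-order Runge-Kutta integration (via
#' deSolve's `rk4` method on an equally spaced grid). State variables are
#' those with derivative equations; algebraic assignment variables are
#' re-evaluated each step in dependency order; everything else is held at
#' its nominal value (1.0 when unvalued).
#'
#' @param model An `ingested_model` whose equations are all evaluable.
#' @param t_end End time.
#' @param dt Step size; default `t_end / 200`.
#' @return A `trajectory`: list with `time` (strictly increasing grid) and
#'   `values` (named list of numeric series, one per variable, including
#'   assignment and rate variables).
#' @export
simulate_ode <- function(model, t_end, dt = NULL) {
  if (is.null(dt)) dt <- t_end / 200
  stopifnot(t_end > 0, dt > 0)
  plan <- ode_plan(model)
  y0 <- vapply(plan$states, function(nm) {
    v <- model$nominal_values[[nm]]
    if (is.null(v)) 1.0 else v
  }, numeric(1))
  names(y0) <- plan$states
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)

  deriv <- function(t, y, parms) {
    env <- plan$eval_env(y)
    d <- vapply(plan$states, function(nm) {
      val <- eval_expression(model$equations[[paste0("d_", nm)]]$rhs, env)
      if (!is.finite(val)) {
        stop("non-finite derivative for '", nm, "' at t = ",
             format(t, digits = 6), call. = FALSE)
      }
      val
    }, numeric(1))
    list(d)
  }
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "rk4")
  values <- list()
  for (nm in plan$states) values[[nm]] <- unname(sol[, nm])
  # recompute assigned variables along the trajectory
  if (length(plan$assigned) || length(plan$constants)) {
    extra <- matrix(NA_real_, nrow = nrow(sol),
                    ncol = length(plan$assigned) + length(plan$constants),
                    dimnames = list(NULL, c(plan$assigned, plan$constants)))
    for (i in seq_len(nrow(sol))) {
      env <- plan$eval_env(sol[i, plan$states])
      for (nm in colnames(extra)) extra[i, nm] <- get(nm, envir = env)
    }
    for (nm in colnames(extra)) values[[nm]] <- unname(extra[, nm])
  }
  structure(list(time = unname(sol[, "time"]), values = values),
            class = "trajectory")
}

# Integration plan: states, topological order for assignments, constants,
# and an environment builder.
ode_plan <- function(model) {
  states <- sort(names(Filter(function(v) isTRUE(v$is_state),
                              model$variables)))
  for (nm in states) {
    eq <- model$equations[[paste0("d_", nm)]]
    if (is.null(eq) || is.null(eq$rhs)) {
      stop("state variable '", nm, "' lacks an evaluable derivative equation",
           call. = FALSE)
    }
  }
  assigned <- names(Filter(function(v) {
    !isTRUE(v$is_state) && !is.null(v$equation_id)
  }, model$variables))
  # order assignments so dependencies evaluate first
  if (length(assigned)) {
    dep_pairs <- do.call(rbind, lapply(assigned, function(nm) {
      eq <- model$equations[[model$variables[[nm]]$equation_id]]
      if (is.null(eq$rhs)) {
        stop("equation for '", nm, "' is not evaluable", call. = FALSE)
      }
      deps <- intersect(eq$rhs_dependencies, assigned)
      if (length(deps)) cbind(deps, nm) else NULL
    }))
    edges_df <- if (is.null(dep_pairs)) {
      data.frame(from = character(0), to = character(0))
    } else {
      data.frame(from = dep_pairs[, 1], to = dep_pairs[, 2],
                 stringsAsFactors = FALSE)
    }
    g <- igraph::graph_from_data_frame(edges_df, directed = TRUE,
                                       vertices = sort(assigned))
    ord <- suppressWarnings(igraph::as_ids(igraph::topo_sort(g,
                                                             mode = "out")))
    if (length(ord) < length(assigned)) {
      stop("assignment equations form a cycle; cannot order evaluation",
           call. = FALSE)
    }
    assigned <- ord
  }
  constants <- setdiff(names(model$variables), c(states, assigned))
  const_vals <- vapply(constants, function(nm) {
    v <- model$nominal_values[[nm]]
    if (is.null(v)) 1.0 else v
  }, numeric(1))
  names(const_vals) <- constants

  eval_env <- function(y) {
    env <- new.env(parent = baseenv())
    for (nm in constants) assign(nm, const_vals[[nm]], envir = env)
    for (nm in states) assign(nm, unname(y[[nm]]), envir = env)
    for (nm in assigned) {
      eq <- model$equations[[model$variables[[nm]]$equation_id]]
      assign(nm, eval(eq$rhs, envir = env), envir = env)
    }
    env
  }
  list(states = states, assigned = assigned, constants = constants,
       eval_env = eval_env)
}

#' Numeric sign oracle for qualitative perturbation responses
#'
#' Runs a baseline and a perturbed trajectory (the perturbed variable's
#' initial/nominal value scaled by `1 + epsilon`) and reports, per
#' variable, the sign of the response (perturbed minus baseline) at the
#' probe time. Responses below the dead-band report 0. This is the
#' independent quantitative check that qualitative sign propagation is
#' validated against.
#'
#' @param model An `ingested_model`.
#' @param perturb_var Variable whose initial value is perturbed upward.
#' @param t_probe Probe time.
#' @param epsilon Relative perturbation size.
#' @param dt Integration step (see [simulate_ode()]).
#' @param dead_band Absolute response threshold below which the sign is 0.
#' @return Named numeric vector of signs (+1, -1, 0) over all variables.
#' @export
numeric_sign_oracle <- function(model, perturb_var, t_probe,
                                epsilon = 1e-3, dt = NULL,
                                dead_band = 1e-9) {
  if (is.null(model$variables[[perturb_var]])) {
    stop("unknown variable '", perturb_var, "'", call. = FALSE)
  }
  base_val <- model$nominal_values[[perturb_var]]
  if (is.null(base_val)) base_val <- 1.0
  pert_model <- model
  pert_model$nominal_values[[perturb_var]] <- base_val * (1 + epsilon)

  tr0 <- simulate_ode(model, t_end = t_probe, dt = dt)
  tr1 <- simulate_ode(pert_model, t_end = t_probe, dt = dt)
  k <- length(tr0$time)
  signs <- vapply(names(tr0$values), function(nm) {
    d <- tr1$values[[nm]][k] - tr0$values[[nm]][k]
    if (abs(d) < dead_band) 0 else sign(d)
  }, numeric(1))
  names(signs) <- names(tr0$values)
  signs
}
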