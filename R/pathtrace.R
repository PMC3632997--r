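SIGN_STATES <- c("unset", "up", "down", "ambiguous", "clamped")

#' Join two qualitative sign states
#'
#' The qualitative propagation lattice: `unset` is the identity, `up` and
#' `down` are incomparable, and `ambiguous` is the top (conflicting
#' influences). `clamped` marks a node held constant experimentally; it is
#' not joinable (clamped nodes never change state).
#'
#' @param a,b Sign states (`"unset"`, `"up"`, `"down"`, `"ambiguous"`).
#' @return The join of `a` and `b`.
#' @export
combine_signs <- function(a, b) {
  stopifnot(a %in% SIGN_STATES, b %in% SIGN_STATES)
  if (a == "clamped" || b == "clamped") {
    stop("clamped states cannot be joined", call. = FALSE)
  }
  if (a == "unset") return(b)
  if (b == "unset") return(a)
  if (a == b) return(a)
  "ambiguous"
}

flip_state <- function(s) {
  switch(s, up = "down", down = "up", s)
}

# What state an edge transmits given its source's state and the edge sign.
transmit <- function(source_state, edge_sign) {
  if (source_state %in% c("unset", "clamped")) return("unset")
  if (edge_sign == 0) return("ambiguous")
  if (edge_sign < 0) return(flip_state(source_state))
  source_state
}

#' Propagate qualitative perturbations through a signed graph
#'
#' Computes the fixed point of the qualitative influence semantics over the
#' sign lattice: each non-clamped node's state is the join of its initial
#' perturbation (if any) and the transmissions along incoming edges, where
#' a +1 edge preserves the upstream state, a -1 edge flips up/down, and a
#' 0-sign edge (unknown-polarity modulation) transmits `ambiguous` from any
#' perturbed source. Clamped nodes keep their state and transmit nothing.
#' The update is monotone on a finite lattice, so the sweep-based worklist
#' terminates; the number of changed sweeps is reported and is at most
#' twice the node count.
#'
#' @param graph A `signed_graph`.
#' @param perturbations A list of perturbation records, each
#'   `list(node = id, direction = "up"|"down"|"clamp")` (a named character
#'   vector `c(node = direction)` is also accepted).
#' @return A `trace_result`: list with `states` (named character vector
#'   over all nodes; `"unset"` means unaffected), `iterations` (changed
#'   sweeps), and `edges` (the influence edges used).
#' @export
propagate <- function(graph, perturbations) {
  perturbations <- normalize_perturbations(perturbations)
  states <- stats::setNames(rep("unset", nrow(graph$nodes)), graph$nodes$id)
  init <- stats::setNames(rep("unset", nrow(graph$nodes)), graph$nodes$id)
  non_clamp <- 0L
  for (p in perturbations) {
    if (!(p$node %in% names(states))) {
      stop("unknown node id '", p$node, "'", call. = FALSE)
    }
    if (p$direction == "clamp") {
      states[[p$node]] <- "clamped"
    } else {
      stopifnot(p$direction %in% c("up", "down"))
      init[[p$node]] <- p$direction
      states[[p$node]] <- p$direction
      non_clamp <- non_clamp + 1L
    }
  }
  if (non_clamp == 0L) {
    stop("at least one non-clamp perturbation is required", call. = FALSE)
  }

  incoming <- split(seq_len(nrow(graph$edges)), graph$edges$to)
  sweeps <- 0L
  max_sweeps <- 2L * nrow(graph$nodes) + 1L
  repeat {
    changed <- FALSE
    for (v in graph$nodes$id) {
      if (states[[v]] == "clamped") next
      s <- init[[v]]
      for (i in incoming[[v]]) {
        s <- combine_signs(s, transmit(states[[graph$edges$from[i]]],
                                       graph$edges$sign[i]))
      }
      if (!identical(s, states[[v]])) {
        states[[v]] <- s
        changed <- TRUE
      }
    }
    if (!changed) break
    sweeps <- sweeps + 1L
    if (sweeps > max_sweeps) {
      stop("propagation failed to reach a fixed point (non-monotone update?)",
           call. = FALSE)
    }
  }
  structure(list(states = states, iterations = sweeps, edges = graph$edges),
            class = "trace_result")
}

normalize_perturbations <- function(perturbations) {
  if (is.character(perturbations)) {
    perturbations <- lapply(seq_along(perturbations), function(i) {
      list(node = names(perturbations)[[i]],
           direction = unname(perturbations[[i]]))
    })
  }
  perturbations
}

#' @export
print.trace_result <- function(x, ...) {
  aff <- x$states[x$states != "unset"]
  cat("<trace_result> ", length(aff), "/", length(x$states),
      " nodes affected (", x$iterations, " sweeps)\n", sep = "")
  if (length(aff)) {
    for (nm in names(aff)) cat("  ", format(nm, width = 24), aff[[nm]], "\n")
  }
  invisible(x)
}

#' Enumerate signed A-to-B paths
#'
#' Depth-first enumeration of all simple directed paths from one node to
#' another, up to a maximum number of edges, in lexicographic order of the
#' node sequences. Each path carries the product of its edge signs;
#' a 0-sign edge anywhere makes the path sign indeterminate (`NA`).
#'
#' @param graph A `signed_graph`.
#' @param from_node,to_node Node ids.
#' @param max_len Maximum path length in edges (at least 1).
#' @return A list of records `list(path = character vector, sign = +1/-1/NA)`;
#'   empty when unreachable.
#' @export
find_paths <- function(graph, from_node, to_node, max_len = 12L) {
  stopifnot(max_len >= 1L)
  ids <- graph$nodes$id
  if (!(from_node %in% ids) || !(to_node %in% ids)) {
    stop("unknown node id", call. = FALSE)
  }
  out_edges <- split(seq_len(nrow(graph$edges)), graph$edges$from)
  results <- list()
  dfs <- function(node, path, sign_acc, depth) {
    edges_i <- out_edges[[node]]
    if (is.null(edges_i)) return()
    ord <- order(graph$edges$to[edges_i])
    for (i in edges_i[ord]) {
      nxt <- graph$edges$to[i]
      if (nxt %in% path) next
      es <- graph$edges$sign[i]
      s <- if (is.na(sign_acc) || es == 0) NA_real_ else sign_acc * es
      if (nxt == to_node) {
        results[[length(results) + 1L]] <<- list(path = c(path, nxt),
                                                 sign = s)
      } else if (depth < max_len) {
        dfs(nxt, c(path, nxt), s, depth + 1L)
      }
    }
  }
  if (from_node != to_node) dfs(from_node, from_node, 1, 1L)
  results
}

#' Detect feedback loops and classify their polarity
#'
#' Enumerates every elementary directed cycle of the signed graph (up to a
#' length cap) once, in canonical rotation (smallest node id first). Loop
#' polarity follows the parity rule: positive with an even number of -1
#' edges, negative with an odd number, indeterminate if the cycle contains
#' any 0-sign edge.
#'
#' @param graph A `signed_graph`.
#' @param max_len Cycle length cap in edges.
#' @return A list of loop records (`nodes` in canonical order, `polarity`).
#' @export
detect_feedback_loops <- function(graph, max_len = 20L) {
  ids <- sort(graph$nodes$id)
  out_edges <- split(seq_len(nrow(graph$edges)), graph$edges$from)
  loops <- list()
  for (start in ids) {
    # cycles whose lexicographically smallest node is `start`
    dfs <- function(node, path, nneg, nzero, depth) {
      edges_i <- out_edges[[node]]
      if (is.null(edges_i)) return()
      ord <- order(graph$edges$to[edges_i])
      for (i in edges_i[ord]) {
        nxt <- graph$edges$to[i]
        if (nxt < start) next
        es <- graph$edges$sign[i]
        nneg2 <- nneg + (es < 0)
        nzero2 <- nzero + (es == 0)
        if (nxt == start) {
          polarity <- if (nzero2 > 0) "indeterminate"
          else if (nneg2 %% 2 == 0) "positive" else "negative"
          loops[[length(loops) + 1L]] <<- list(nodes = path,
                                               polarity = polarity)
        } else if (!(nxt %in% path) && depth < max_len) {
          dfs(nxt, c(path, nxt), nneg2, nzero2, depth + 1L)
        }
      }
    }
    dfs(start, start, 0L, 0L, 1L)
  }
  loops
}
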