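#' PhysioMap: a process-participant graph
#'
#' A PhysioMap links dynamical processes to the dynamical entities that
#' participate in them. Two process kinds are represented: *flow* processes,
#' in which a quantity of stuff (blood, molecules, charge) moves from source
#' entities to sink entities, optionally enabled by mediators; and
#' *modulation* processes, in which one property affects another without
#' significant energy flow, carrying a polarity (+1 stimulating, -1
#' inhibiting, 0 unknown).
#'
#' Entity identity within a map is semantic: two entities with equivalent
#' annotations (same bearer chain, or same normalized free label) are the
#' same node, and constructors reuse the existing node.
#'
#' @param metadata Named list; `title`, `source`, `method` and
#'   `tool_version` are serialized.
#' @return An empty `physiomap`.
#' @export
physiomap <- function(metadata = list()) {
  defaults <- list(title = "", source = "", method = "manual",
                   tool_version = as.character(
                     utils::packageVersion("physiomapr")))
  for (nm in names(metadata)) defaults[[nm]] <- metadata[[nm]]
  structure(list(entities = list(), processes = list(), metadata = defaults),
            class = "physiomap")
}

#' @export
print.physiomap <- function(x, ...) {
  kinds <- vapply(x$processes, `[[`, character(1), "kind")
  cat("<physiomap> ", length(x$entities), " entities, ",
      sum(kinds == "flow"), " flow + ", sum(kinds == "modulation"),
      " modulation processes\n", sep = "")
  invisible(x)
}

# Add (or reuse) an entity node for an annotation; returns the entity id.
add_entity <- function(map, annotation, display_label = NULL,
                       amount_property = NULL) {
  key <- entity_key(annotation)
  for (e in map$entities) {
    if (identical(attr(e, "key"), key)) {
      if (!is.null(amount_property) && is.null(e$amount_property)) {
        map$entities[[e$id]]$amount_property <- amount_property
      }
      return(list(map = map, id = e$id))
    }
  }
  base <- entity_id_from_annotation(annotation)
  id <- base
  n <- 1L
  while (!is.null(map$entities[[id]])) {
    n <- n + 1L
    id <- paste0(base, ".", n)
  }
  if (is.null(display_label)) display_label <- annotation_display_label(annotation)
  node <- structure(list(id = id, annotation = annotation,
                         display_label = display_label,
                         amount_property = amount_property),
                    key = key)
  map$entities[[id]] <- node
  list(map = map, id = id)
}

environment_annotation <- function() {
  composite_annotation("opbx:ChemicalAmount", free_label = "environment")
}

make_participant <- function(entity_id, role, stoich = 1) {
  stopifnot(role %in% c("source", "sink", "mediator"))
  list(entity_id = entity_id, role = role, stoich = stoich)
}

make_flow_process <- function(id, domain, participants,
                              rate_variable = NULL, provenance = list(),
                              flags = character(0)) {
  list(id = id, kind = "flow", domain = domain, participants = participants,
       rate_variable = rate_variable, provenance = provenance, flags = flags)
}

make_modulation_process <- function(id, regulator_entity_id, target_ref,
                                    polarity, rate_variable = NULL,
                                    provenance = list()) {
  list(id = id, kind = "modulation", regulator_entity_id = regulator_entity_id,
       target_ref = target_ref, polarity = polarity,
       rate_variable = rate_variable, provenance = provenance,
       flags = character(0))
}

add_process <- function(map, process) {
  if (!is.null(map$processes[[process$id]])) {
    stop("duplicate process id '", process$id, "'", call. = FALSE)
  }
  map$processes[[process$id]] <- process
  map
}

#' Validate a PhysioMap
#'
#' Checks structural invariants and returns violations as data, not errors:
#' unique ids, participant and modulation references resolving to entities
#' or processes, at least one source or sink participant per flow process,
#' a biophysical domain on every flow process, positive stoichiometries,
#' polarity present on modulations, and semantic entity uniqueness (no two
#' entity nodes with equivalent annotations).
#'
#' @param map A `physiomap`.
#' @return A data frame with columns `node`, `rule`, `message`; zero rows
#'   when the map is well-formed.
#' @export
validate_physiomap <- function(map) {
  bad <- list()
  flag <- function(node, rule, message) {
    bad[[length(bad) + 1L]] <<- data.frame(node = node, rule = rule,
                                           message = message,
                                           stringsAsFactors = FALSE)
  }
  keys <- vapply(map$entities, function(e) entity_key(e$annotation),
                 character(1))
  if (anyDuplicated(keys)) {
    for (k in unique(keys[duplicated(keys)])) {
      ids <- names(keys)[keys == k]
      flag(ids[[2L]], "duplicate-entity",
           paste0("entities ", paste(ids, collapse = ", "),
                  " share one annotation"))
    }
  }
  for (p in map$processes) {
    if (p$kind == "flow") {
      if (is.null(p$domain) || !nzchar(p$domain)) {
        flag(p$id, "flow-no-domain", "flow process lacks a domain")
      }
      roles <- vapply(p$participants, `[[`, character(1), "role")
      if (!any(roles %in% c("source", "sink"))) {
        flag(p$id, "flow-no-participants",
             "flow process has no source or sink participant")
      }
      for (pt in p$participants) {
        if (is.null(map$entities[[pt$entity_id]])) {
          flag(p$id, "dangling-entity",
               paste0("participant references missing entity '",
                      pt$entity_id, "'"))
        }
        if (!is.numeric(pt$stoich) || pt$stoich <= 0) {
          flag(p$id, "bad-stoichiometry",
               paste0("participant '", pt$entity_id,
                      "' has non-positive stoichiometry"))
        }
        if (!(pt$role %in% c("source", "sink", "mediator"))) {
          flag(p$id, "bad-role", paste0("unknown role '", pt$role, "'"))
        }
      }
    } else if (p$kind == "modulation") {
      if (is.null(p$regulator_entity_id) ||
          is.null(map$entities[[p$regulator_entity_id]])) {
        flag(p$id, "dangling-regulator", "modulation regulator missing")
      }
      if (is.null(p$target_ref) ||
          (is.null(map$processes[[p$target_ref]]) &&
           is.null(map$entities[[p$target_ref]]))) {
        flag(p$id, "dangling-target", "modulation target missing")
      }
      if (is.null(p$polarity) || !(p$polarity %in% c(-1, 0, 1))) {
        flag(p$id, "bad-polarity", "modulation polarity absent or invalid")
      }
    } else {
      flag(p$id, "bad-kind", paste0("unknown process kind '", p$kind, "'"))
    }
  }
  if (length(bad) == 0L) {
    return(data.frame(node = character(0), rule = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, bad)
}

stop_if_invalid <- function(map) {
  v <- validate_physiomap(map)
  if (nrow(v)) {
    stop("PhysioMap fails validation: ",
         paste(paste0(v$node, " [", v$rule, "]"), collapse = "; "),
         call. = FALSE)
  }
  invisible(map)
}

#' Derive the signed influence graph of a PhysioMap
#'
#' Builds the signed influence graph over entity and process nodes that
#' perturbation tracing operates on. The graph is layered: no edge links
#' two entity nodes, and the only process-to-process edges are those from a
#' modulation node to the process it regulates. For each flow process: a +1
#' edge from
#' every source or mediator entity into the process and a +1 edge from the
#' process to every sink entity; with `include_depletion = TRUE`,
#' additionally a -1 edge from the process back to each source entity
#' (consumption of the upstream pool). For each modulation process: a +1
#' edge from the regulator into the modulation node and an edge from the
#' modulation node to its target with the modulation's polarity (0 is kept
#' as a 0-sign edge, meaning unknown direction of influence).
#'
#' @param map A valid `physiomap`.
#' @param include_depletion Emit source-depletion edges (default off).
#' @return A `signed_graph`: list with `nodes` (data frame `id`, `kind`)
#'   and `edges` (data frame `from`, `to`, `sign`, `provenance`).
#' @export
to_signed_graph <- function(map, include_depletion = FALSE) {
  stop_if_invalid(map)
  nodes <- data.frame(
    id = c(names(map$entities), names(map$processes)),
    kind = c(rep("entity", length(map$entities)),
             rep("process", length(map$processes))),
    stringsAsFactors = FALSE)
  from <- character(0); to <- character(0); sgn <- numeric(0)
  prov <- character(0)
  emit <- function(f, t, s, p) {
    from <<- c(from, f); to <<- c(to, t); sgn <<- c(sgn, s)
    prov <<- c(prov, p)
  }
  for (p in map$processes) {
    if (p$kind == "flow") {
      for (pt in p$participants) {
        if (pt$role == "source") {
          emit(pt$entity_id, p$id, +1, "source-role")
          if (include_depletion) emit(p$id, pt$entity_id, -1, "depletion")
        } else if (pt$role == "sink") {
          emit(p$id, pt$entity_id, +1, "sink-role")
        } else {
          emit(pt$entity_id, p$id, +1, "mediator-role")
        }
      }
    } else {
      emit(p$regulator_entity_id, p$id, +1, "modulation")
      emit(p$id, p$target_ref, p$polarity, "modulation")
    }
  }
  edges <- data.frame(from = from, to = to, sign = sgn, provenance = prov,
                      stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edges[c("from", "to", "sign")]), , drop = FALSE]
  edges <- edges[order(edges$from, edges$to, edges$sign), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- nodes[order(nodes$kind, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "signed_graph")
}

#' @export
print.signed_graph <- function(x, ...) {
  cat("<signed_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

signed_graph_as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(graph$edges[, c("from", "to")],
                                     directed = TRUE,
                                     vertices = graph$nodes$id)
  igraph::E(g)$sign <- graph$edges$sign
  g
}
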