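#' Classify every model variable by its annotated physical role
#'
#' Maps each variable's composite annotation through the registry: variables
#' annotated with a flow-rate property get role `flow`, force properties
#' `force`, amount properties `amount`; annotated variables under none of
#' those subtrees get `other`; variables without an annotation get
#' `unannotated`. The biophysical domain is carried along for flow, force
#' and amount roles.
#'
#' @param model An `ingested_model`.
#' @param registry A `term_registry`.
#' @return Named list of role records (`variable`, `role`, `domain`).
#' @export
classify_variable_role <- function(model, registry = load_registry()) {
  roles <- list()
  for (nm in names(model$variables)) {
    v <- model$variables[[nm]]
    if (is.null(v$annotation)) {
      roles[[nm]] <- list(variable = nm, role = "unannotated", domain = NULL)
      next
    }
    term <- registry$terms[[v$annotation$property]]
    if (is.null(term)) {
      stop("variable '", nm, "' is annotated with unknown term '",
           v$annotation$property, "'", call. = FALSE)
    }
    if (term$category != "property") {
      roles[[nm]] <- list(variable = nm, role = "other", domain = NULL)
      next
    }
    cls <- classify_property(registry, v$annotation$property)
    role <- switch(cls$class, "flow-rate" = "flow", "force" = "force",
                   "amount" = "amount", "other")
    roles[[nm]] <- list(variable = nm, role = role, domain = cls$domain)
  }
  roles
}

#' Locate the driver and downstream participants of a flow variable
#'
#' Implements the two traversal rules for dependency-based process
#' inference. Upstream: breadth-first traversal backwards over the variable
#' dependency graph from the flow variable, stopping along each branch at
#' the first force or amount variable of the flow's own biophysical domain;
#' unannotated, other-role and wrong-domain variables are passed through
#' (wrong-domain force/amount encounters are recorded as non-matching
#' evidence). Downstream: the same traversal forwards, finding force and
#' amount variables that depend mathematically on the flow. Each evidence
#' record carries the dependence sign composed along its path (product of
#' edge signs; any indeterminate edge makes the record indeterminate) and
#' the hop count. Traversal is capped at 10 hops and each variable is
#' expanded once per direction, so dependency cycles terminate.
#'
#' @param model An `ingested_model`.
#' @param depgraph Its `dependency_graph`.
#' @param roles Output of [classify_variable_role()].
#' @param flow_var Name of a flow-role variable.
#' @param hop_limit Maximum path length in dependency edges.
#' @return List of evidence records (`flow_var`, `variable`, `direction`,
#'   `sign`, `hops`, `class`, `same_domain`).
#' @export
locate_participants <- function(model, depgraph, roles, flow_var,
                                hop_limit = 10L) {
  fr <- roles[[flow_var]]
  if (is.null(fr) || fr$role != "flow") {
    stop("'", flow_var, "' is not a flow-role variable", call. = FALSE)
  }
  flow_domain <- fr$domain

  traverse <- function(direction) {
    step <- if (direction == "upstream") dep_predecessors else dep_successors
    edge_sign <- function(a, b) {
      if (direction == "upstream") partial_dependence_sign(model, b, a)
      else partial_dependence_sign(model, a, b)
    }
    records <- list()
    visited <- character(0)
    queue <- list(list(var = flow_var, sign = 1, hops = 0L))
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      if (cur$var %in% visited) next
      visited <- c(visited, cur$var)
      if (cur$hops >= hop_limit) next
      for (nb in sort(step(depgraph, cur$var))) {
        es <- suppressWarnings(edge_sign(cur$var, nb))
        sgn <- if (is.na(cur$sign) || is.na(es)) NA_real_ else cur$sign * es
        r <- roles[[nb]]
        if (!is.null(r) && r$role %in% c("force", "amount")) {
          same <- !is.null(flow_domain) && identical(r$domain, flow_domain)
          records[[length(records) + 1L]] <- list(
            flow_var = flow_var, variable = nb, direction = direction,
            sign = sgn, hops = cur$hops + 1L, class = r$role,
            same_domain = same)
          if (same) next  # branch stops at the first same-domain match
        }
        if (!(nb %in% visited)) {
          queue[[length(queue) + 1L]] <- list(var = nb, sign = sgn,
                                              hops = cur$hops + 1L)
        }
      }
    }
    records
  }
  c(traverse("upstream"), traverse("downstream"))
}

# Aggregate a set of signs: all equal and definite -> that sign; any
# disagreement or indeterminate -> NA; zeros only -> 0.
aggregate_sign <- function(signs) {
  if (any(is.na(signs))) return(NA_real_)
  u <- unique(signs[signs != 0])
  if (length(u) > 1L) return(NA_real_)
  if (length(u) == 0L) return(0)
  u
}

#' Instantiate a flow process from participant evidence
#'
#' Converts the evidence gathered by [locate_participants()] into a flow
#' process plus its entity nodes, added to `map`. Role assignment follows
#' the driver orientation implied by resistive flow laws (flow =
#' pressure difference over resistance): upstream dependence with sign +1
#' marks the bearer a source, upstream -1 a sink; downstream +1 a sink,
#' downstream -1 a source. Duplicate (entity, role) pairs collapse. An
#' entity assigned both source and sink by definite signs is demoted to
#' mediator and a `role-conflict` flag recorded. A same-domain amount
#' variable that the flow does not materially couple back into (no
#' downstream evidence for its entity, a dynamic non-boundary variable) is
#' treated as a regulating pool rather than a participant: it becomes a
#' modulation process with the dependence sign as polarity — this is what
#' makes enzyme-like factors in rate laws come out as modulations, matching
#' the explicitly tagged reading. Wrong-domain or indeterminate-sign
#' evidence becomes a polarity-0 modulation. If no definite evidence
#' remains on one side, an implicit environment entity fills it and the
#' process is flagged `unresolved`.
#'
#' @param map A `physiomap` to extend.
#' @param flow_var Flow variable name.
#' @param evidence Records from [locate_participants()].
#' @param model The `ingested_model`.
#' @param roles Output of [classify_variable_role()].
#' @param registry A `term_registry`.
#' @param method Provenance method string.
#' @return The extended `physiomap`; inference warnings are accumulated in
#'   the map's `warnings` attribute.
#' @export
infer_flow_process <- function(map, flow_var, evidence, model, roles,
                               registry = load_registry(),
                               method = "dependency-inference") {
  flow_domain <- roles[[flow_var]]$domain
  prov <- list(source = model$source_uri, method = method,
               flow_variable = flow_var)
  warnings_out <- attr(map, "warnings") %||% character(0)

  # bucket evidence by entity
  buckets <- list()
  for (ev in evidence) {
    ann <- model$variables[[ev$variable]]$annotation
    key <- entity_key(ann)
    if (is.null(buckets[[key]])) {
      buckets[[key]] <- list(annotation = ann, records = list())
    }
    buckets[[key]]$records <- c(buckets[[key]]$records, list(ev))
  }

  participants <- list()
  modulations <- list()  # list of (annotation, polarity, via)
  flags <- character(0)

  for (key in sort(names(buckets))) {
    bk <- buckets[[key]]
    recs <- bk$records
    same <- Filter(function(r) isTRUE(r$same_domain), recs)
    wrong <- Filter(function(r) !isTRUE(r$same_domain), recs)
    definite <- Filter(function(r) !is.na(r$sign) && r$sign != 0, same)
    indef <- Filter(function(r) is.na(r$sign) || r$sign == 0, same)

    if (length(definite)) {
      has_downstream <- any(vapply(definite, function(r)
        r$direction == "downstream", logical(1)))
      has_force_up <- any(vapply(definite, function(r)
        r$direction == "upstream" && r$class == "force", logical(1)))
      coupled <- has_downstream || has_force_up
      if (coupled) {
        tentative <- unique(vapply(definite, function(r) {
          if (r$direction == "upstream") {
            if (r$sign > 0) "source" else "sink"
          } else {
            if (r$sign > 0) "sink" else "source"
          }
        }, character(1)))
        amount_prop <- NULL
        for (r in definite) {
          p <- model$variables[[r$variable]]$annotation$property
          if (r$class %in% c("amount", "force") && is.null(amount_prop)) {
            amount_prop <- p
          }
        }
        role <- if (length(tentative) == 1L) tentative else {
          flags <- c(flags, "role-conflict")
          warnings_out <- c(warnings_out, paste0(
            "flow '", flow_var, "': entity '", key,
            "' assigned both source and sink; demoted to mediator"))
          "mediator"
        }
        participants[[length(participants) + 1L]] <- list(
          annotation = bk$annotation, role = role,
          amount_property = amount_prop)
        next
      }
      # same-domain but not materially coupled: a regulating pool
      modulations[[length(modulations) + 1L]] <- list(
        annotation = bk$annotation,
        polarity = aggregate_sign(vapply(definite, `[[`, numeric(1),
                                         "sign")) %|NA|% 0)
      next
    }
    if (length(indef) || length(wrong)) {
      modulations[[length(modulations) + 1L]] <- list(
        annotation = bk$annotation, polarity = 0)
    }
  }

  # mint entities and assemble participant list
  plist <- list()
  for (pt in participants) {
    res <- add_entity(map, pt$annotation, amount_property = pt$amount_property)
    map <- res$map
    plist[[length(plist) + 1L]] <- make_participant(res$id, pt$role)
  }
  roles_present <- vapply(plist, `[[`, character(1), "role")
  if (!any(roles_present == "source")) {
    res <- add_entity(map, environment_annotation())
    map <- res$map
    plist[[length(plist) + 1L]] <- make_participant(res$id, "source")
    flags <- c(flags, "unresolved")
  }
  if (!any(roles_present == "sink")) {
    res <- add_entity(map, environment_annotation())
    map <- res$map
    plist[[length(plist) + 1L]] <- make_participant(res$id, "sink")
    flags <- c(flags, "unresolved")
  }

  pid <- paste0("flow_", flow_var)
  map <- add_process(map, make_flow_process(
    pid, domain = flow_domain %||% "opbx:ChemicalDomain",
    participants = plist, rate_variable = flow_var, provenance = prov,
    flags = unique(flags)))

  for (mo in modulations) {
    res <- add_entity(map, mo$annotation)
    map <- res$map
    mid <- paste0("mod_", flow_var, "_", res$id)
    map <- add_process(map, make_modulation_process(
      mid, regulator_entity_id = res$id, target_ref = pid,
      polarity = mo$polarity, provenance = prov))
  }
  attr(map, "warnings") <- warnings_out
  map
}

`%|NA|%` <- function(a, b) if (length(a) == 1 && is.na(a)) b else a

species_annotation <- function(model, species) {
  ann <- model$variables[[species]]$annotation
  if (is.null(ann)) {
    ann <- composite_annotation("opbx:ChemicalAmount", free_label = species)
  }
  ann
}

#' Build a PhysioMap from explicitly tagged reactions
#'
#' The fully automatic path available when the source model tags reactants,
#' products and modifiers explicitly (as SBML reaction networks do). Each
#' reaction becomes one chemical flow process with its reactants as source
#' participants and products as sink participants (stoichiometry retained);
#' each modifier becomes a modulation process targeting the reaction's flow
#' process, with polarity taken from the modifier record (SBO-derived, 0
#' when unknown). Entities are minted from species annotations, falling
#' back to the species name as a free label. A reaction with an empty
#' reactant (or product) side gets an implicit environment source (or
#' sink).
#'
#' @param model An `ingested_model` with non-empty reactions.
#' @param registry A `term_registry`.
#' @return A `physiomap`.
#' @export
infer_from_reactions <- function(model, registry = load_registry()) {
  if (length(model$reactions) == 0L) {
    stop("model has no reaction records; use infer_from_dependencies()",
         call. = FALSE)
  }
  map <- physiomap(metadata = list(source = model$source_uri,
                                   method = "explicit-tags"))
  for (rx in model$reactions) {
    prov <- list(source = model$source_uri, method = "explicit-tags",
                 flow_variable = rx$rate_variable %||% rx$id)
    plist <- list()
    flags <- character(0)
    for (side in list(list(refs = rx$reactants, role = "source"),
                      list(refs = rx$products, role = "sink"))) {
      for (sr in side$refs) {
        res <- add_entity(map, species_annotation(model, sr$species),
                          amount_property =
                            species_annotation(model, sr$species)$property)
        map <- res$map
        plist[[length(plist) + 1L]] <- make_participant(res$id, side$role,
                                                        sr$stoich)
      }
      if (length(side$refs) == 0L) {
        res <- add_entity(map, environment_annotation())
        map <- res$map
        plist[[length(plist) + 1L]] <- make_participant(res$id, side$role)
        flags <- c(flags, "unresolved")
      }
    }
    pid <- paste0("flow_", rx$id)
    map <- add_process(map, make_flow_process(
      pid, domain = "opbx:ChemicalDomain", participants = plist,
      rate_variable = rx$rate_variable, provenance = prov, flags = flags))
    for (md in rx$modifiers) {
      res <- add_entity(map, species_annotation(model, md$species))
      map <- res$map
      mid <- paste0("mod_", rx$id, "_", res$id)
      map <- add_process(map, make_modulation_process(
        mid, regulator_entity_id = res$id, target_ref = pid,
        polarity = md$polarity, provenance = prov))
    }
  }
  stop_if_invalid(map)
  map
}

#' Build a PhysioMap by dependency-network inference
#'
#' The fallback path for models without explicit reaction tags: every
#' variable annotated as a flow rate spawns a flow process whose
#' participants are located by signed traversal of the variable dependency
#' graph ([locate_participants()] + [infer_flow_process()]). Minted
#' entities are merged by annotation equivalence, and process ids are
#' deterministic (prefixed with the flow variable name), so identical
#' input models produce byte-identical PhysioMap XML.
#'
#' @param model An `ingested_model` with at least one flow-annotated
#'   variable.
#' @param registry A `term_registry`.
#' @return A `physiomap`; per-flow evidence is attached as the `evidence`
#'   attribute and inference warnings as the `warnings` attribute.
#' @export
infer_from_dependencies <- function(model, registry = load_registry()) {
  roles <- classify_variable_role(model, registry)
  flow_vars <- sort(names(Filter(function(r) r$role == "flow", roles)))
  map <- physiomap(metadata = list(source = model$source_uri,
                                   method = "dependency-inference"))
  if (length(flow_vars) == 0L) {
    warning("model has no flow-annotated variables; returning an empty map",
            call. = FALSE)
    return(map)
  }
  depgraph <- build_dependency_graph(model)
  evidence_report <- list()
  for (fv in flow_vars) {
    ev <- locate_participants(model, depgraph, roles, fv)
    evidence_report[[fv]] <- ev
    map <- infer_flow_process(map, fv, ev, model, roles, registry)
  }
  stop_if_invalid(map)
  attr(map, "evidence") <- evidence_report
  map
}
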