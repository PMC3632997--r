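# Shared helpers: small hand-built maps and node/variable bookkeeping for
# comparing qualitative traces against the numeric oracle.

ann_of <- function(term, property = "opbx:ChemicalAmount") {
  composite_annotation(property,
                       bearer = list(c(term, "none"),
                                     c("fmax:Cytosol", "contained-in")))
}

# A -> (flow F) -> B, optionally modulated by E with the given polarity.
tiny_flow_map <- function(polarity = NULL) {
  map <- physiomap(metadata = list(title = "tiny"))
  ra <- physiomapr:::add_entity(map, ann_of("chebix:A")); map <- ra$map
  rb <- physiomapr:::add_entity(map, ann_of("chebix:B")); map <- rb$map
  map <- physiomapr:::add_process(map, physiomapr:::make_flow_process(
    "F", domain = "opbx:ChemicalDomain",
    participants = list(physiomapr:::make_participant(ra$id, "source"),
                        physiomapr:::make_participant(rb$id, "sink"))))
  if (!is.null(polarity)) {
    re <- physiomapr:::add_entity(map, ann_of("chebix:E")); map <- re$map
    map <- physiomapr:::add_process(map, physiomapr:::make_modulation_process(
      "M", regulator_entity_id = re$id, target_ref = "F",
      polarity = polarity))
  }
  map
}

# Signed graph built directly from an edge table (for pathtrace tests that
# need full control over topology and signs).
graph_from_edges <- function(edges, kinds = NULL) {
  ids <- sort(unique(c(edges$from, edges$to)))
  if (is.null(kinds)) kinds <- rep("entity", length(ids))
  structure(list(nodes = data.frame(id = ids, kind = kinds,
                                    stringsAsFactors = FALSE),
                 edges = edges),
            class = "signed_graph")
}

# Map graph nodes of an explicitly tagged random-network map back to the
# model variables they observe (species for entities, rate variables for
# processes).
node_variable_map <- function(map, model) {
  out <- list()
  for (e in map$entities) {
    ann <- e$annotation
    if (length(ann$bearer)) {
      vn <- tolower(sub("^chebix:", "", ann$bearer[[1L]]$term))
      if (vn %in% names(model$variables)) out[[e$id]] <- vn
    }
  }
  for (p in map$processes) {
    if (!is.null(p$rate_variable)) out[[p$id]] <- p$rate_variable
  }
  out
}

# Entity node id bearing a given model variable's annotation.
entity_id_for_variable <- function(map, model, var) {
  key <- physiomapr:::entity_key(model$variables[[var]]$annotation)
  for (e in map$entities) {
    if (identical(physiomapr:::entity_key(e$annotation), key)) return(e$id)
  }
  NULL
}

# First species that some reaction consumes (deterministic perturbation
# target for concordance checks).
first_reactant <- function(model) {
  reac <- unique(unlist(lapply(model$reactions, function(r) {
    vapply(r$reactants, `[[`, character(1), "species")
  })))
  if (length(reac)) sort(reac)[[1L]] else sort(names(model$variables))[[1L]]
}

expect_no_violations <- function(map) {
  expect_identical(nrow(validate_physiomap(map)), 0L)
}

# Size of the multiset intersection of two signature vectors.
multiset_shared <- function(x, y) {
  tx <- table(x); ty <- table(y)
  common <- intersect(names(tx), names(ty))
  if (length(common) == 0L) return(0L)
  as.integer(sum(pmin(tx[common], ty[common])))
}
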