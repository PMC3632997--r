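# Semantic merging: entities unify by annotation equivalence; processes
# unify only on their full signature (kind, domain, and the complete
# participant set with roles and stoichiometries; for modulations also
# regulator, target and polarity). Equal-signature-except-polarity (or
# stoichiometry) pairs are conflicts: both variants are retained under
# disambiguated ids and reported.

process_signature <- function(map, p, with_polarity = TRUE,
                              with_stoich = TRUE) {
  ekey <- function(id) entity_key(map$entities[[id]]$annotation)
  if (p$kind == "flow") {
    parts <- vapply(p$participants, function(pt) {
      paste0(pt$role, "=", ekey(pt$entity_id),
             if (with_stoich) paste0("*", format(pt$stoich, digits = 15))
             else "")
    }, character(1))
    paste0("flow|", p$domain, "|", paste(sort(parts), collapse = ";"))
  } else {
    tgt <- if (!is.null(map$processes[[p$target_ref]])) {
      paste0("proc:", process_signature(map, map$processes[[p$target_ref]],
                                        with_polarity = FALSE,
                                        with_stoich = with_stoich))
    } else {
      paste0("ent:", ekey(p$target_ref))
    }
    paste0("mod|", ekey(p$regulator_entity_id), "|", tgt,
           if (with_polarity) paste0("|", format(p$polarity)) else "")
  }
}

#' Merge two PhysioMaps by semantic identity
#'
#' Produces a map in which every biophysical process and entity that the
#' two inputs represent identically appears exactly once. Entities are
#' unified by annotation equivalence. Processes are unified only when their
#' full signatures match: kind, domain and the complete participant set
#' (entity identity, role and stoichiometry) for flows; regulator, target
#' and polarity for modulations. A pair matching in everything except
#' polarity or stoichiometry is a conflict: both variants are retained
#' under disambiguated ids and the pair is reported. Unmatched nodes carry
#' over with a source tag in their provenance.
#'
#' @param m1,m2 Valid `physiomap` objects.
#' @return A list with `map` (the merged `physiomap`) and `report` (a
#'   `merge_report`: `entity_matches`, `process_matches`, `conflicts`,
#'   `provenance`).
#' @export
merge_physiomaps <- function(m1, m2) {
  stop_if_invalid(m1)
  stop_if_invalid(m2)
  merged <- physiomap(metadata = list(
    title = paste(Filter(nzchar, c(m1$metadata$title, m2$metadata$title)),
                  collapse = " + "),
    source = paste(Filter(nzchar, c(m1$metadata$source, m2$metadata$source)),
                   collapse = " + "),
    method = "merge"))

  entity_matches <- list()
  process_matches <- list()
  conflicts <- list()
  provenance <- list()

  # entities from m1, then m2 (reusing by key)
  id_map <- list(m1 = list(), m2 = list())
  for (side in c("m1", "m2")) {
    src <- if (side == "m1") m1 else m2
    for (eid in sort(names(src$entities))) {
      e <- src$entities[[eid]]
      before <- names(merged$entities)
      res <- add_entity(merged, e$annotation, display_label = e$display_label,
                        amount_property = e$amount_property)
      merged <- res$map
      id_map[[side]][[eid]] <- res$id
      if (side == "m2" && (res$id %in% before)) {
        pre <- Filter(function(x) identical(id_map$m1[[x]], res$id),
                      names(id_map$m1))
        if (length(pre)) {
          entity_matches[[length(entity_matches) + 1L]] <-
            c(pre[[1L]], eid)
        }
      }
      provenance[[res$id]] <- unique(c(provenance[[res$id]], side))
    }
  }

  remap_process <- function(p, side) {
    if (p$kind == "flow") {
      p$participants <- lapply(p$participants, function(pt) {
        pt$entity_id <- id_map[[side]][[pt$entity_id]]
        pt
      })
    } else {
      p$regulator_entity_id <- id_map[[side]][[p$regulator_entity_id]]
      if (!is.null(id_map[[side]][[p$target_ref]]) &&
          is.null(map_has_process(if (side == "m1") m1 else m2,
                                  p$target_ref))) {
        p$target_ref <- id_map[[side]][[p$target_ref]]
      }
    }
    p
  }
  map_has_process <- function(m, id) m$processes[[id]]

  # processes from m1 verbatim (with remapped entity ids)
  proc_id_map <- list(m1 = list(), m2 = list())
  for (pid in sort(names(m1$processes))) {
    p <- remap_process(m1$processes[[pid]], "m1")
    p$provenance$merged_from <- "m1"
    merged <- add_process(merged, p)
    proc_id_map$m1[[pid]] <- pid
    provenance[[pid]] <- unique(c(provenance[[pid]], "m1"))
  }
  # modulation targets that are process ids need remapping after matching;
  # handle flows first, then modulations, for both orderings
  kind_of <- function(m, pid) m$processes[[pid]]$kind
  m2_order <- sort(names(m2$processes))
  m2_order <- c(Filter(function(id) kind_of(m2, id) == "flow", m2_order),
                Filter(function(id) kind_of(m2, id) == "modulation",
                       m2_order))
  # multiset matching: each m1 process can absorb at most one m2 process
  # with the same full signature, so internal duplicates survive merging
  # symmetrically in either argument order
  sig_avail <- list()
  loose_index <- list()
  for (pid in sort(names(merged$processes))) {
    p <- merged$processes[[pid]]
    sig <- process_signature(merged, p)
    sig_avail[[sig]] <- c(sig_avail[[sig]], pid)
    loose <- process_signature(merged, p, with_polarity = FALSE,
                               with_stoich = FALSE)
    loose_index[[loose]] <- c(loose_index[[loose]], pid)
  }
  for (pid in m2_order) {
    p <- remap_process(m2$processes[[pid]], "m2")
    if (p$kind == "modulation" && !is.null(proc_id_map$m2[[p$target_ref]])) {
      p$target_ref <- proc_id_map$m2[[p$target_ref]]
    }
    # signature computed against the merged map's entities
    probe <- merged
    probe$processes[[".probe"]] <- p
    sig <- process_signature(probe, p)
    loose <- process_signature(probe, p, with_polarity = FALSE,
                               with_stoich = FALSE)
    if (length(sig_avail[[sig]])) {
      hit <- sig_avail[[sig]][[1L]]
      sig_avail[[sig]] <- sig_avail[[sig]][-1L]
      proc_id_map$m2[[pid]] <- hit
      process_matches[[length(process_matches) + 1L]] <- c(hit, pid)
      provenance[[hit]] <- unique(c(provenance[[hit]], "m2"))
      next
    }
    partial <- loose_index[[loose]]
    if (!is.null(partial)) {
      conflicts[[length(conflicts) + 1L]] <- list(
        retained = partial, incoming = pid,
        reason = "same process identity, different polarity or stoichiometry")
    }
    new_id <- pid
    n <- 1L
    while (!is.null(merged$processes[[new_id]])) {
      n <- n + 1L
      new_id <- paste0(pid, ".", n)
    }
    p$id <- new_id
    p$provenance$merged_from <- "m2"
    merged <- add_process(merged, p)
    proc_id_map$m2[[pid]] <- new_id
    provenance[[new_id]] <- unique(c(provenance[[new_id]], "m2"))
    loose_index[[loose]] <- c(loose_index[[loose]], new_id)
  }
  stop_if_invalid(merged)
  report <- structure(list(entity_matches = entity_matches,
                           process_matches = process_matches,
                           conflicts = conflicts, provenance = provenance),
                      class = "merge_report")
  list(map = merged, report = report)
}

#' @export
print.merge_report <- function(x, ...) {
  cat("<merge_report> ", length(x$entity_matches), " entity matches, ",
      length(x$process_matches), " process matches, ",
      length(x$conflicts), " conflicts\n", sep = "")
  invisible(x)
}

#' Test whether two PhysioMaps are semantically isomorphic
#'
#' Compares the semantic content of two maps independent of node ids:
#' the multiset of entity identities (annotation equivalence classes) and
#' the multiset of process signatures. With `strict = TRUE` signatures
#' include participant stoichiometries and modulation polarities; the
#' default compares kinds, domains, participant role sets and
#' regulator/target structure only (the appropriate notion when comparing
#' an explicitly tagged map against a dependency-inferred one, which cannot
#' recover stoichiometry and may know polarity only up to the sign of a
#' derivative).
#'
#' @param a,b Valid `physiomap` objects.
#' @param strict Include stoichiometry and polarity in the comparison.
#' @return Logical scalar.
#' @export
physiomaps_isomorphic <- function(a, b, strict = FALSE) {
  keys_a <- sort(vapply(a$entities, function(e) entity_key(e$annotation),
                        character(1)))
  keys_b <- sort(vapply(b$entities, function(e) entity_key(e$annotation),
                        character(1)))
  if (!identical(unname(keys_a), unname(keys_b))) return(FALSE)
  sigs <- function(m) {
    sort(vapply(m$processes, function(p) {
      process_signature(m, p, with_polarity = strict, with_stoich = strict)
    }, character(1)))
  }
  identical(unname(sigs(a)), unname(sigs(b)))
}
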