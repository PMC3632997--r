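#' Load an ontology term registry
#'
#' Reads the compact physics-for-biology term registry used to classify
#' annotated model variables. The registry is a tab-separated table with one
#' term per row and columns `id`, `label`, `parent`, `category`, `domain`,
#' `iri`. Parent links must form a rooted forest, and each flow-rate, force
#' or amount property term must carry a biophysical domain (directly or via
#' an ancestor).
#'
#' @param path Path to a registry TSV, or `NULL` for the registry shipped
#'   with the package (a small subset of a physics-of-biology vocabulary:
#'   dynamical entities and processes, force/amount/flow-rate properties in
#'   the fluid, chemical, electrical and diffusion domains, plus a few
#'   anatomy- and chemical-style entity terms used by the reference models).
#' @return A `term_registry` object: a list with `terms` (named list of term
#'   records) and `roots` (ids with no parent).
#' @examples
#' reg <- load_registry()
#' classify_property(reg, "opbx:FluidFlowRate")
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "opb_mini.tsv", package = "physiomapr")
  }
  if (!file.exists(path)) {
    stop("registry file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", fill = TRUE,
                           quote = "", strip.white = TRUE)
  needed <- c("id", "label", "parent", "category", "domain", "iri")
  for (col in needed) {
    if (is.null(tab[[col]])) tab[[col]] <- character(nrow(tab))
  }
  tab[is.na(tab)] <- ""

  valid_cat <- c("property", "entity", "process", "dependency", "domain")
  terms <- list()
  for (i in seq_len(nrow(tab))) {
    id <- tab$id[i]
    if (!nzchar(id)) stop("registry parse error at line ", i + 1L,
                          ": empty term id", call. = FALSE)
    if (!is.null(terms[[id]])) stop("registry parse error at line ", i + 1L,
                                    ": duplicate term id '", id, "'",
                                    call. = FALSE)
    if (!(tab$category[i] %in% valid_cat)) {
      stop("registry parse error at line ", i + 1L, ": unknown category '",
           tab$category[i], "'", call. = FALSE)
    }
    terms[[id]] <- list(
      id = id,
      label = tab$label[i],
      parent_id = if (nzchar(tab$parent[i])) tab$parent[i] else NULL,
      category = tab$category[i],
      domain_id = if (nzchar(tab$domain[i])) tab$domain[i] else NULL,
      external_iri = if (nzchar(tab$iri[i])) tab$iri[i] else NULL
    )
  }

  reg <- structure(list(terms = terms, roots = character(0)),
                   class = "term_registry")
  # referential integrity + acyclicity of parent links
  for (t in terms) {
    if (!is.null(t$parent_id) && is.null(terms[[t$parent_id]])) {
      stop("registry integrity error: term '", t$id,
           "' has unknown parent '", t$parent_id, "'", call. = FALSE)
    }
    if (!is.null(t$domain_id) && is.null(terms[[t$domain_id]])) {
      stop("registry integrity error: term '", t$id,
           "' has unknown domain '", t$domain_id, "'", call. = FALSE)
    }
  }
  for (t in terms) {
    seen <- character(0)
    cur <- t$id
    while (!is.null(cur)) {
      if (cur %in% seen) {
        stop("registry integrity error: parent cycle at term '", cur, "'",
             call. = FALSE)
      }
      seen <- c(seen, cur)
      cur <- terms[[cur]]$parent_id
    }
  }
  reg$roots <- sort(names(terms)[vapply(terms,
                                        function(t) is.null(t$parent_id),
                                        logical(1))])
  # every flow-rate/force/amount property must resolve a domain
  anchors <- c("opbx:DynamicalFlowRate", "opbx:ForceProperty",
               "opbx:AmountProperty")
  for (t in terms) {
    if (t$category == "property" && !(t$id %in% anchors)) {
      cls <- classify_property(reg, t$id)
      if (cls$class %in% c("flow-rate", "force", "amount") &&
          is.null(cls$domain)) {
        stop("registry integrity error: property term '", t$id,
             "' of class ", cls$class, " has no biophysical domain",
             call. = FALSE)
      }
    }
  }
  reg
}

#' @export
print.term_registry <- function(x, ...) {
  cats <- table(vapply(x$terms, `[[`, character(1), "category"))
  cat("<term_registry> ", length(x$terms), " terms (",
      paste(names(cats), unname(cats), sep = ": ", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

registry_term <- function(registry, term_id) {
  t <- registry$terms[[term_id]]
  if (is.null(t)) stop("unknown registry term: ", term_id, call. = FALSE)
  t
}

#' Test subsumption between two registry terms
#'
#' `TRUE` iff `ancestor_id` equals `term_id` or lies on its parent chain.
#' Reflexive by definition.
#'
#' @param registry A `term_registry`.
#' @param term_id,ancestor_id Term ids; both must resolve.
#' @return Logical scalar.
#' @export
is_subclass_of <- function(registry, term_id, ancestor_id) {
  registry_term(registry, ancestor_id)
  cur <- registry_term(registry, term_id)$id
  while (!is.null(cur)) {
    if (identical(cur, ancestor_id)) return(TRUE)
    cur <- registry$terms[[cur]]$parent_id
  }
  FALSE
}

#' Classify a property term as flow-rate, force, amount or other
#'
#' The classification is determined by the nearest ancestor among the
#' dynamical flow rate, force property and amount property terms; the
#' biophysical domain is taken from the term itself or the nearest ancestor
#' carrying one. Property terms under none of the three subtrees classify as
#' `"other"` with a `NULL` domain.
#'
#' @param registry A `term_registry`.
#' @param term_id A term id with category `property`.
#' @return A list with elements `class` (one of `"flow-rate"`, `"force"`,
#'   `"amount"`, `"other"`) and `domain` (a domain term id or `NULL`).
#' @export
classify_property <- function(registry, term_id) {
  t <- registry_term(registry, term_id)
  if (t$category != "property") {
    stop("term '", term_id, "' has category '", t$category,
         "', not 'property'", call. = FALSE)
  }
  anchors <- c("opbx:DynamicalFlowRate" = "flow-rate",
               "opbx:ForceProperty" = "force",
               "opbx:AmountProperty" = "amount")
  cls <- "other"
  domain <- NULL
  cur <- term_id
  while (!is.null(cur)) {
    node <- registry$terms[[cur]]
    if (is.null(domain) && !is.null(node$domain_id)) domain <- node$domain_id
    if (cls == "other" && cur %in% names(anchors)) cls <- unname(anchors[[cur]])
    cur <- node$parent_id
  }
  if (cls == "other") domain <- NULL
  list(class = cls, domain = domain)
}
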