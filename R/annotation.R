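#' Construct a composite annotation
#'
#' A composite annotation pairs a physical-property term with the physical
#' entity that bears it. The bearer is an ordered chain of entity terms,
#' each refined by a structural relation (`part-of`, `contained-in`,
#' `connected-to`, or `none` for the base entity). A variable whose entity
#' cannot be mapped to a term may instead carry a free-text label.
#'
#' @param property Property term id (CURIE string).
#' @param bearer A list of `c(term, relation)` pairs (or a single character
#'   vector of term ids, taken as `none`/`contained-in`-free base chain with
#'   relation `"none"` for the first and `"contained-in"` for the rest), or
#'   `NULL`.
#' @param free_label Free-text entity label used when no bearer terms exist.
#' @return A `composite_annotation` object.
#' @export
composite_annotation <- function(property, bearer = NULL, free_label = NULL) {
  if (!is.character(property) || length(property) != 1L || !nzchar(property)) {
    stop("property must be a single term id", call. = FALSE)
  }
  bearer <- normalize_bearer(bearer)
  if (length(bearer) == 0L && (is.null(free_label) || !nzchar(free_label))) {
    stop("composite annotation needs a non-empty bearer chain or a free label",
         call. = FALSE)
  }
  structure(list(property = property, bearer = bearer,
                 free_label = free_label),
            class = "composite_annotation")
}

valid_relations <- c("none", "part-of", "contained-in", "connected-to")

normalize_bearer <- function(bearer) {
  if (is.null(bearer)) return(list())
  if (is.character(bearer)) {
    bearer <- lapply(seq_along(bearer), function(i) {
      c(bearer[[i]], if (i == 1L) "none" else "contained-in")
    })
  }
  lapply(seq_along(bearer), function(i) {
    el <- bearer[[i]]
    if (length(el) == 1L) el <- c(el, if (i == 1L) "none" else "contained-in")
    if (length(el) != 2L || !all(nzchar(el))) {
      stop("bearer elements must be (term, relation) pairs", call. = FALSE)
    }
    if (!(el[[2]] %in% valid_relations)) {
      stop("unknown structural relation '", el[[2]], "'", call. = FALSE)
    }
    list(term = el[[1]], relation = el[[2]])
  })
}

#' @export
print.composite_annotation <- function(x, ...) {
  cat("<annotation> ", format_annotation(x), "\n", sep = "")
  invisible(x)
}

format_annotation <- function(ann) {
  if (is.null(ann)) return("<none>")
  bearer <- if (length(ann$bearer)) {
    paste(vapply(ann$bearer, function(b) {
      if (b$relation == "none") b$term else paste(b$relation, b$term)
    }, character(1)), collapse = " ")
  } else {
    paste0("\"", ann$free_label, "\"")
  }
  paste0(ann$property, " of ", bearer)
}

#' Test whether two composite annotations are semantically equivalent
#'
#' Equivalence is exact: property term ids must match and the bearer chains
#' must match element-wise (term id and structural relation). When both
#' annotations are bearer-free, their free labels are compared
#' case-insensitively after whitespace normalization. No ontology
#' subsumption is consulted.
#'
#' @param a,b `composite_annotation` objects.
#' @return Logical scalar.
#' @export
annotations_equivalent <- function(a, b) {
  if (!identical(a$property, b$property)) return(FALSE)
  if (length(a$bearer) != length(b$bearer)) return(FALSE)
  if (length(a$bearer) == 0L) {
    return(normalize_label(a$free_label) == normalize_label(b$free_label))
  }
  for (i in seq_along(a$bearer)) {
    if (!identical(a$bearer[[i]]$term, b$bearer[[i]]$term)) return(FALSE)
    if (!identical(a$bearer[[i]]$relation, b$bearer[[i]]$relation)) {
      return(FALSE)
    }
  }
  TRUE
}

normalize_label <- function(x) {
  if (is.null(x)) return("")
  tolower(gsub("\\s+", " ", trimws(x)))
}

# Identity key for the *entity* described by an annotation's bearer chain.
# Entity identity deliberately ignores the property term: fluid pressure and
# fluid volume observed on the same portion of blood describe one entity.
entity_key <- function(ann) {
  if (is.null(ann) || length(ann$bearer) == 0L) {
    lbl <- if (is.null(ann)) "" else normalize_label(ann$free_label)
    return(paste0("label:", lbl))
  }
  paste(vapply(ann$bearer, function(b) paste0(b$relation, ":", b$term),
               character(1)), collapse = "|")
}

curie_local <- function(id) sub("^[^:]*:", "", id)

# Deterministic display-oriented identifier for an entity key.
entity_id_from_annotation <- function(ann) {
  if (is.null(ann) || length(ann$bearer) == 0L) {
    lbl <- if (is.null(ann)) "entity" else normalize_label(ann$free_label)
    return(sanitize_id(lbl))
  }
  parts <- vapply(ann$bearer, function(b) curie_local(b$term), character(1))
  sanitize_id(paste(parts, collapse = "_"))
}

sanitize_id <- function(x) {
  x <- gsub("[^A-Za-z0-9_.-]+", "_", x)
  x <- gsub("^_+|_+$", "", x)
  if (!nzchar(x)) x <- "entity"
  x
}

annotation_display_label <- function(ann) {
  if (is.null(ann)) return("(unannotated)")
  if (length(ann$bearer) == 0L) return(ann$free_label)
  base <- curie_local(ann$bearer[[1L]]$term)
  rest <- vapply(ann$bearer[-1L], function(b) curie_local(b$term), character(1))
  if (length(rest)) paste0(base, " (", paste(rest, collapse = ", "), ")")
  else base
}
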