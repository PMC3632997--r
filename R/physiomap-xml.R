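PHYSIOMAP_SCHEMA_VERSION <- "1.0"

xml_escape_attr <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Serialize a PhysioMap to XML
#'
#' Writes the canonical PhysioMap XML form: entities and processes sorted
#' lexicographically by id, participants sorted by entity then role,
#' attributes in a fixed order, UTF-8, LF line endings. Writing followed by
#' [read_physiomap_xml()] and writing again is byte-identical.
#'
#' @param map A valid `physiomap`.
#' @param path Output path, or `NULL` to return the XML text.
#' @return XML text, invisibly when written to a file.
#' @export
write_physiomap_xml <- function(map, path = NULL) {
  stop_if_invalid(map)
  md <- map$metadata
  out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
           paste0("<physiomap version=\"", PHYSIOMAP_SCHEMA_VERSION,
                  "\" title=\"", xml_escape_attr(md$title %||% ""),
                  "\" source=\"", xml_escape_attr(md$source %||% ""),
                  "\" method=\"", xml_escape_attr(md$method %||% ""),
                  "\" tool-version=\"",
                  xml_escape_attr(md$tool_version %||% ""), "\">"))
  for (id in sort(names(map$entities))) {
    e <- map$entities[[id]]
    head <- paste0("  <entity id=\"", xml_escape_attr(id), "\" label=\"",
                   xml_escape_attr(e$display_label %||% ""), "\"")
    if (!is.null(e$amount_property)) {
      head <- paste0(head, " amount-property=\"",
                     xml_escape_attr(e$amount_property), "\"")
    }
    out <- c(out, paste0(head, ">"))
    ann <- e$annotation
    ahead <- paste0("    <annotation property=\"",
                    xml_escape_attr(ann$property), "\"")
    if (length(ann$bearer) == 0L) {
      out <- c(out, paste0(ahead, " label=\"",
                           xml_escape_attr(ann$free_label), "\"/>"))
    } else {
      out <- c(out, paste0(ahead, ">"))
      for (b in ann$bearer) {
        out <- c(out, paste0("      <bearer term=\"",
                             xml_escape_attr(b$term), "\" rel=\"",
                             xml_escape_attr(b$relation), "\"/>"))
      }
      out <- c(out, "    </annotation>")
    }
    out <- c(out, "  </entity>")
  }
  for (id in sort(names(map$processes))) {
    p <- map$processes[[id]]
    head <- paste0("  <process id=\"", xml_escape_attr(id), "\" kind=\"",
                   p$kind, "\"")
    if (p$kind == "flow") {
      head <- paste0(head, " domain=\"", xml_escape_attr(p$domain), "\"")
    }
    if (!is.null(p$rate_variable)) {
      head <- paste0(head, " rate-var=\"", xml_escape_attr(p$rate_variable),
                     "\"")
    }
    if (!is.null(p$provenance$method)) {
      head <- paste0(head, " method=\"",
                     xml_escape_attr(p$provenance$method), "\"")
    }
    if (!is.null(p$provenance$flow_variable)) {
      head <- paste0(head, " flow-var=\"",
                     xml_escape_attr(p$provenance$flow_variable), "\"")
    }
    if (length(p$flags)) {
      head <- paste0(head, " flags=\"",
                     xml_escape_attr(paste(sort(p$flags), collapse = " ")),
                     "\"")
    }
    out <- c(out, paste0(head, ">"))
    if (p$kind == "flow") {
      parts <- p$participants
      ord <- order(vapply(parts, `[[`, character(1), "entity_id"),
                   vapply(parts, `[[`, character(1), "role"))
      for (pt in parts[ord]) {
        out <- c(out, paste0("    <participant entity=\"",
                             xml_escape_attr(pt$entity_id), "\" role=\"",
                             pt$role, "\" stoich=\"",
                             format(pt$stoich, digits = 15), "\"/>"))
      }
    } else {
      out <- c(out, paste0("    <modulation regulator=\"",
                           xml_escape_attr(p$regulator_entity_id),
                           "\" target=\"", xml_escape_attr(p$target_ref),
                           "\" polarity=\"", format(p$polarity), "\"/>"))
    }
    out <- c(out, "  </process>")
  }
  out <- c(out, "</physiomap>")
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(text), con)
  invisible(text)
}

schema_error <- function(where, msg) {
  stop("PhysioMap XML schema violation at ", where, ": ", msg,
       call. = FALSE)
}

#' Read a PhysioMap from XML
#'
#' Parses PhysioMap XML written by [write_physiomap_xml()] (or by hand).
#' Schema violations (unknown roles, kinds, polarities, missing required
#' attributes) raise errors naming the offending location.
#'
#' @param path Path to the XML file.
#' @return A `physiomap`.
#' @export
read_physiomap_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("cannot parse PhysioMap XML '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  if (xml2::xml_name(doc) != "physiomap") {
    schema_error("/", "root element must be <physiomap>")
  }
  map <- physiomap(metadata = list(
    title = xml2::xml_attr(doc, "title") %||% "",
    source = xml2::xml_attr(doc, "source") %||% "",
    method = xml2::xml_attr(doc, "method") %||% "",
    tool_version = xml2::xml_attr(doc, "tool-version") %||% ""))

  for (en in xml2::xml_find_all(doc, "./entity")) {
    id <- xml2::xml_attr(en, "id")
    where <- paste0("/physiomap/entity[@id='", id, "']")
    if (is.na(id) || !nzchar(id)) schema_error("/physiomap/entity",
                                               "missing id attribute")
    ann_node <- xml2::xml_find_first(en, "./annotation")
    if (inherits(ann_node, "xml_missing")) {
      schema_error(where, "missing <annotation>")
    }
    property <- xml2::xml_attr(ann_node, "property")
    if (is.na(property)) schema_error(where, "annotation lacks property")
    bearers <- xml2::xml_find_all(ann_node, "./bearer")
    ann <- if (length(bearers)) {
      chain <- lapply(bearers, function(b) {
        rel <- xml2::xml_attr(b, "rel")
        if (!(rel %in% valid_relations)) {
          schema_error(where, paste0("unknown bearer relation '", rel, "'"))
        }
        c(xml2::xml_attr(b, "term"), rel)
      })
      composite_annotation(property, bearer = chain)
    } else {
      lbl <- xml2::xml_attr(ann_node, "label")
      if (is.na(lbl)) schema_error(where, "annotation has neither bearers nor label")
      composite_annotation(property, free_label = lbl)
    }
    amount_prop <- xml2::xml_attr(en, "amount-property")
    node <- structure(list(id = id, annotation = ann,
                           display_label = xml2::xml_attr(en, "label"),
                           amount_property = if (is.na(amount_prop)) NULL
                           else amount_prop),
                      key = entity_key(ann))
    if (!is.null(map$entities[[id]])) schema_error(where, "duplicate entity id")
    map$entities[[id]] <- node
  }

  for (pn in xml2::xml_find_all(doc, "./process")) {
    id <- xml2::xml_attr(pn, "id")
    where <- paste0("/physiomap/process[@id='", id, "']")
    kind <- xml2::xml_attr(pn, "kind")
    if (!(kind %in% c("flow", "modulation"))) {
      schema_error(where, paste0("unknown process kind '", kind, "'"))
    }
    attr_or_null <- function(a) {
      v <- xml2::xml_attr(pn, a)
      if (is.na(v)) NULL else v
    }
    prov <- list(method = attr_or_null("method"),
                 flow_variable = attr_or_null("flow-var"))
    prov <- prov[!vapply(prov, is.null, logical(1))]
    flags <- attr_or_null("flags")
    flags <- if (is.null(flags)) character(0)
    else strsplit(flags, " ", fixed = TRUE)[[1]]
    if (kind == "flow") {
      domain <- xml2::xml_attr(pn, "domain")
      if (is.na(domain)) schema_error(where, "flow process lacks domain")
      participants <- lapply(xml2::xml_find_all(pn, "./participant"),
                             function(pt) {
        role <- xml2::xml_attr(pt, "role")
        if (!(role %in% c("source", "sink", "mediator"))) {
          schema_error(paste0(where, "/participant"),
                       paste0("unknown role '", role, "'"))
        }
        st <- suppressWarnings(as.numeric(xml2::xml_attr(pt, "stoich")))
        if (!is.finite(st) || st <= 0) {
          schema_error(paste0(where, "/participant"),
                       "stoichiometry must be a positive number")
        }
        make_participant(xml2::xml_attr(pt, "entity"), role, st)
      })
      proc <- make_flow_process(id, domain, participants,
                                rate_variable = attr_or_null("rate-var"),
                                provenance = prov, flags = flags)
    } else {
      mo <- xml2::xml_find_first(pn, "./modulation")
      if (inherits(mo, "xml_missing")) {
        schema_error(where, "modulation process lacks <modulation>")
      }
      pol <- suppressWarnings(as.numeric(xml2::xml_attr(mo, "polarity")))
      if (!isTRUE(pol %in% c(-1, 0, 1))) {
        schema_error(where, "polarity must be -1, 0 or +1")
      }
      proc <- make_modulation_process(id, xml2::xml_attr(mo, "regulator"),
                                      xml2::xml_attr(mo, "target"), pol,
                                      rate_variable = attr_or_null("rate-var"),
                                      provenance = prov)
      proc$flags <- flags
    }
    if (!is.null(map$processes[[id]])) schema_error(where, "duplicate process id")
    map$processes[[id]] <- proc
  }
  stop_if_invalid(map)
  map
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
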