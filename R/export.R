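#' Export a PhysioMap for graph tools
#'
#' Renders the process-participant graph in Graphviz DOT or GraphML, one
#' node per entity (drawn as a circle/ellipse) and per process (drawn as a
#' rectangle), one edge per flow participant and per modulation link, with
#' role and polarity attributes. Both outputs load in standard graph tools.
#'
#' @param map A valid `physiomap`.
#' @param format `"dot"` or `"graphml"`.
#' @return The serialized graph as a single string.
#' @export
export_graph <- function(map, format = c("dot", "graphml")) {
  if (!is.character(format) || !(format[[1]] %in% c("dot", "graphml"))) {
    stop("unknown export format: ", format[[1]],
         " (use \"dot\" or \"graphml\")", call. = FALSE)
  }
  format <- format[[1]]
  stop_if_invalid(map)
  edges <- export_edges(map)
  if (format == "dot") export_dot(map, edges) else export_graphml(map, edges)
}

# One row per participant/modulation link, oriented as drawn.
export_edges <- function(map) {
  rows <- list()
  for (p in map$processes) {
    if (p$kind == "flow") {
      for (pt in p$participants) {
        if (pt$role == "sink") {
          rows[[length(rows) + 1L]] <- list(from = p$id, to = pt$entity_id,
                                            label = "sink", polarity = 1)
        } else {
          rows[[length(rows) + 1L]] <- list(from = pt$entity_id, to = p$id,
                                            label = pt$role, polarity = 1)
        }
      }
    } else {
      rows[[length(rows) + 1L]] <- list(from = p$regulator_entity_id,
                                        to = p$id, label = "regulator",
                                        polarity = 1)
      rows[[length(rows) + 1L]] <- list(from = p$id, to = p$target_ref,
                                        label = "modulation",
                                        polarity = p$polarity)
    }
  }
  rows
}

dot_quote <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")

export_dot <- function(map, edges) {
  out <- c("digraph physiomap {", "  rankdir=LR;")
  for (id in sort(names(map$entities))) {
    e <- map$entities[[id]]
    out <- c(out, paste0("  ", dot_quote(id), " [shape=circle, label=",
                         dot_quote(e$display_label %||% id), "];"))
  }
  for (id in sort(names(map$processes))) {
    p <- map$processes[[id]]
    out <- c(out, paste0("  ", dot_quote(id), " [shape=rectangle, label=",
                         dot_quote(id),
                         if (p$kind == "modulation") ", style=dashed" else "",
                         "];"))
  }
  for (ed in edges) {
    style <- if (ed$polarity < 0) " arrowhead=tee," else ""
    out <- c(out, paste0("  ", dot_quote(ed$from), " -> ", dot_quote(ed$to),
                         " [label=", dot_quote(ed$label), ",", style,
                         " polarity=", format(ed$polarity), "];"))
  }
  paste0(paste(c(out, "}"), collapse = "\n"), "\n")
}

export_graphml <- function(map, edges) {
  esc <- xml_escape_attr
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\" ",
           "xmlns:xsi=\"http://www.w3.org/2001/XMLSchema-instance\" ",
           "xsi:schemaLocation=\"http://graphml.graphdrawing.org/xmlns ",
           "http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd\">"),
    paste0("  <key id=\"d0\" for=\"node\" attr.name=\"kind\" ",
           "attr.type=\"string\"/>"),
    paste0("  <key id=\"d1\" for=\"node\" attr.name=\"shape\" ",
           "attr.type=\"string\"/>"),
    paste0("  <key id=\"d2\" for=\"node\" attr.name=\"label\" ",
           "attr.type=\"string\"/>"),
    paste0("  <key id=\"d3\" for=\"edge\" attr.name=\"role\" ",
           "attr.type=\"string\"/>"),
    paste0("  <key id=\"d4\" for=\"edge\" attr.name=\"polarity\" ",
           "attr.type=\"double\"/>"),
    "  <graph id=\"physiomap\" edgedefault=\"directed\">")
  for (id in sort(names(map$entities))) {
    e <- map$entities[[id]]
    out <- c(out, paste0("    <node id=\"", esc(id), "\">"),
             "      <data key=\"d0\">entity</data>",
             "      <data key=\"d1\">circle</data>",
             paste0("      <data key=\"d2\">", esc(e$display_label %||% id),
                    "</data>"),
             "    </node>")
  }
  for (id in sort(names(map$processes))) {
    out <- c(out, paste0("    <node id=\"", esc(id), "\">"),
             paste0("      <data key=\"d0\">process</data>"),
             "      <data key=\"d1\">rectangle</data>",
             paste0("      <data key=\"d2\">", esc(id), "</data>"),
             "    </node>")
  }
  for (i in seq_along(edges)) {
    ed <- edges[[i]]
    out <- c(out,
             paste0("    <edge id=\"e", i, "\" source=\"", esc(ed$from),
                    "\" target=\"", esc(ed$to), "\">"),
             paste0("      <data key=\"d3\">", esc(ed$label), "</data>"),
             paste0("      <data key=\"d4\">", format(ed$polarity),
                    "</data>"),
             "    </edge>")
  }
  paste0(paste(c(out, "  </graph>", "</graphml>"), collapse = "\n"), "\n")
}
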