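# GEXF 1.3 export/import (Gephi-native), with geographic node attributes so a
# viewer can lay the network out on the territory; GraphML offered through
# igraph as an alternative.

#' Export a flow network to GEXF
#'
#' Writes a directed GEXF 1.3 graph with the journey count as edge `weight`,
#' `distance_km` as an edge attribute, and `lat`, `lon`, `macroregion` as
#' node attributes. An empty network yields a valid GEXF file with empty
#' node/edge lists.
#'
#' @param net A `flow_network`.
#' @param path Output path.
#' @export
export_gexf <- function(net, path) {
  stopifnot(inherits(net, "flow_network"))
  doc <- xml2::xml_new_root("gexf",
    xmlns = "http://gexf.net/1.3", version = "1.3")
  graph <- xml2::xml_add_child(doc, "graph",
                               defaultedgetype = "directed", mode = "static")
  nattr <- xml2::xml_add_child(graph, "attributes", class = "node")
  for (a in list(c("0", "lat", "double"), c("1", "lon", "double"),
                 c("2", "macroregion", "string")))
    xml2::xml_add_child(nattr, "attribute", id = a[1], title = a[2], type = a[3])
  eattr <- xml2::xml_add_child(graph, "attributes", class = "edge")
  xml2::xml_add_child(eattr, "attribute", id = "0", title = "distance_km",
                      type = "double")
  nodes <- xml2::xml_add_child(graph, "nodes")
  v <- net$vertices
  for (i in seq_len(nrow(v))) {
    nd <- xml2::xml_add_child(nodes, "node", id = v$code[i], label = v$name[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0",
                        value = format(v$lat[i], digits = 15))
    xml2::xml_add_child(av, "attvalue", `for` = "1",
                        value = format(v$lon[i], digits = 15))
    mr <- if ("macroregion" %in% names(v) && !is.na(v$macroregion[i]))
      v$macroregion[i] else ""
    xml2::xml_add_child(av, "attvalue", `for` = "2", value = mr)
  }
  edges <- xml2::xml_add_child(graph, "edges")
  e <- net$edges
  for (i in seq_len(nrow(e))) {
    ed <- xml2::xml_add_child(edges, "edge", id = as.character(i - 1L),
                              source = e$origin[i], target = e$dest[i],
                              weight = format(e$weight[i], digits = 15))
    av <- xml2::xml_add_child(ed, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0",
                        value = format(e$distance_km[i], digits = 15))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GEXF file back into node and edge tables
#'
#' Inverse of [export_gexf()] up to column order; used for round-trip checks
#' and for re-importing networks exported by other tools.
#'
#' @param path GEXF file.
#' @return List with `nodes` (`data.table`: `code,label,lat,lon,macroregion`),
#'   `edges` (`data.table`: `origin,dest,weight,distance_km`) and `directed`.
#' @export
read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  graph <- xml2::xml_find_first(doc, ".//g:graph", ns)
  directed <- identical(xml2::xml_attr(graph, "defaultedgetype"), "directed")
  node_els <- xml2::xml_find_all(doc, ".//g:nodes/g:node", ns)
  attval <- function(el, id) xml2::xml_attr(
    xml2::xml_find_first(el, sprintf(".//g:attvalue[@for='%s']", id), ns), "value")
  nodes <- data.table::data.table(
    code = xml2::xml_attr(node_els, "id"),
    label = xml2::xml_attr(node_els, "label"),
    lat = as.numeric(vapply(node_els, attval, character(1), id = "0")),
    lon = as.numeric(vapply(node_els, attval, character(1), id = "1")),
    macroregion = vapply(node_els, attval, character(1), id = "2")
  )
  edge_els <- xml2::xml_find_all(doc, ".//g:edges/g:edge", ns)
  edges <- data.table::data.table(
    origin = xml2::xml_attr(edge_els, "source"),
    dest = xml2::xml_attr(edge_els, "target"),
    weight = as.numeric(xml2::xml_attr(edge_els, "weight")),
    distance_km = as.numeric(vapply(edge_els, attval, character(1), id = "0"))
  )
  list(nodes = nodes, edges = edges, directed = directed)
}

#' Export a flow network as GraphML
#' @param net A `flow_network`.
#' @param path Output path.
#' @export
export_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
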