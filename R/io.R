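#' Read and write LCN networks as JSON
#'
#' The canonical on-disk format ("LCN-JSON") stores the node table, edge table
#' and metadata under top-level keys `nodes`, `edges` and `metadata`, with all
#' coordinates and lengths in um, plus a `format_version` field. Writing the
#' same network twice produces byte-identical files; a write/read round trip
#' reproduces ids exactly and numeric fields to full double precision.
#'
#' @param net An `osteon_network`.
#' @param path File path.
#' @param solution Optional [lcn_flow()] solution; its per-node pressures and
#'   per-edge flows/velocities are stored in a `solution` sidecar block.
#' @return `write_lcn_json` returns `path` invisibly; `read_lcn_json` returns
#'   the `osteon_network` (with a `solution` attribute when present).
#' @export
write_lcn_json <- function(net, path, solution = NULL) {
  stopifnot(inherits(net, "osteon_network"))
  obj <- list(format_version = "1.0",
              metadata = net$metadata,
              nodes = net$nodes,
              edges = net$edges[setdiff(names(net$edges), "polyline")])
  if (!is.null(solution)) {
    stopifnot(inherits(solution, "lcn_flow"))
    obj$solution <- list(approach = solution$approach,
                         applied = solution$applied,
                         node_pressure = solution$node_pressure,
                         edge_flow = solution$edge_flow,
                         edge_velocity = solution$edge_velocity,
                         boundary_flux = solution$boundary_flux)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_lcn_json
#' @export
read_lcn_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(obj$edges, stringsAsFactors = FALSE)
  md <- obj$metadata
  md$center <- as.numeric(md$center)
  net <- osteon_network(nodes, edges, md, validate = FALSE)
  if (!is.null(obj$solution)) attr(net, "solution") <- obj$solution
  net
}

#' Export and import the node/edge CSV pair
#'
#' Interoperability tables: `<stem>_nodes.csv` with columns
#' `id,x,y,z,kind,boundary` and `<stem>_edges.csv` with `id,from,to,length`.
#' Metadata is written to `<stem>_metadata.json`. `read_lcn_csv` rebuilds the
#' network from the same triple.
#'
#' @param net An `osteon_network`.
#' @param stem Path stem (without suffix) for the three files.
#' @return `write_lcn_csv` returns the three paths invisibly; `read_lcn_csv`
#'   returns an `osteon_network`.
#' @export
write_lcn_csv <- function(net, stem) {
  paths <- paste0(stem, c("_nodes.csv", "_edges.csv", "_metadata.json"))
  utils::write.csv(net$nodes, paths[1], row.names = FALSE)
  utils::write.csv(net$edges[setdiff(names(net$edges), "polyline")],
                   paths[2], row.names = FALSE)
  jsonlite::write_json(net$metadata, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_lcn_csv
#' @export
read_lcn_csv <- function(stem) {
  nodes <- utils::read.csv(paste0(stem, "_nodes.csv"), stringsAsFactors = FALSE)
  edges <- utils::read.csv(paste0(stem, "_edges.csv"), stringsAsFactors = FALSE)
  md <- jsonlite::read_json(paste0(stem, "_metadata.json"), simplifyVector = TRUE)
  md$center <- as.numeric(md$center)
  osteon_network(nodes, edges, md, validate = FALSE)
}

#' Export the network topology as GraphML
#'
#' Writes the LCN as an undirected GraphML graph with node attributes
#' (position, kind, boundary) and the edge length attribute, for use in
#' external graph tools.
#'
#' @param net An `osteon_network`.
#' @param path Output file path.
#' @export
write_lcn_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::V(g)$x <- net$nodes$x
  igraph::V(g)$y <- net$nodes$y
  igraph::V(g)$z <- net$nodes$z
  igraph::V(g)$kind <- net$nodes$kind
  igraph::V(g)$boundary <- net$nodes$boundary
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
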