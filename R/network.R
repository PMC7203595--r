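#' Construct an osteon LCN network
#'
#' Builds the spatial multigraph representation of a lacunocanalicular network
#' (LCN): nodes are lacunae, canalicular intersection points or endpoints with
#' 3D coordinates in um; edges are canaliculi with an arc length in um.
#' Boundary tags mark nodes lying on the Haversian canal surface (the
#' low-pressure reservoir) or on the cement line (the sealed outer boundary).
#'
#' @param nodes data.frame with columns `id` (unique integers), `x`, `y`, `z`
#'   (um), `kind` (one of `"lacuna"`, `"branch"`, `"endpoint"`) and `boundary`
#'   (one of `"none"`, `"haversian"`, `"cement"`).
#' @param edges data.frame with columns `id` (unique integers), `from`, `to`
#'   (node ids; the stored order fixes the reference orientation) and `length`
#'   (arc length, um).
#' @param metadata list with `center` (xy position of the osteon axis, um),
#'   `haversian_radius`, `osteon_radius`, `slab_thickness` (um), `osteon_type`
#'   (`"ordinary"`, `"osteon_in_osteon"` or `"synthetic_oracle"`) and
#'   `evaluated_volume` (bone volume used for densities, um^3).
#' @param validate Run [validate_network()] on the result (default `TRUE`).
#' @return An object of class `osteon_network`.
#' @seealso [validate_network()], [generate_osteon()], [read_lcn_json()]
#' @export
osteon_network <- function(nodes, edges, metadata = list(), validate = TRUE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  nodes$id <- as.integer(nodes$id)
  for (cl in intersect(c("id", "from", "to"), names(edges)))
    edges[[cl]] <- as.integer(edges[[cl]])
  meta_defaults <- list(center = c(0, 0), haversian_radius = NA_real_,
                        osteon_radius = NA_real_, slab_thickness = NA_real_,
                        osteon_type = "ordinary", evaluated_volume = NA_real_)
  metadata <- utils::modifyList(meta_defaults, as.list(metadata))
  net <- structure(list(nodes = nodes, edges = edges, metadata = metadata),
                   class = "osteon_network")
  if (validate) validate_network(net) else net
}

node_kinds <- c("lacuna", "branch", "endpoint")
boundary_tags <- c("none", "haversian", "cement")

#' Validate an osteon network
#'
#' Checks the structural invariants of the data model: unique node ids, edges
#' referring to existing distinct nodes (no self-loops), positive edge lengths
#' no shorter than the Euclidean chord between their endpoints (tortuosity at
#' least 1), valid node kinds and boundary tags, presence of at least one
#' Haversian-tagged node, and — when the osteon geometry is given — positions
#' inside the osteon cylinder and slab. All violations are reported together.
#'
#' @param net An [osteon_network()] object.
#' @param require_haversian Require at least one Haversian-tagged node
#'   (needed by the solvers; default `TRUE`).
#' @param geometry_tol Slack, in um, allowed outside the nominal cylinder
#'   radius and slab (default 1e-6).
#' @return `net`, invisibly unchanged, if valid; otherwise an error listing
#'   every violated invariant.
#' @export
validate_network <- function(net, require_haversian = TRUE, geometry_tol = 1e-6) {
  stopifnot(inherits(net, "osteon_network"))
  nodes <- net$nodes; edges <- net$edges
  problems <- character()
  need_n <- c("id", "x", "y", "z", "kind", "boundary")
  need_e <- c("id", "from", "to", "length")
  if (!all(need_n %in% names(nodes)))
    stop("nodes table must have columns ", paste(need_n, collapse = ", "))
  if (!all(need_e %in% names(edges)))
    stop("edges table must have columns ", paste(need_e, collapse = ", "))

  if (anyDuplicated(nodes$id))
    problems <- c(problems, "duplicate node ids")
  if (nrow(edges) && anyDuplicated(edges$id))
    problems <- c(problems, "duplicate edge ids")
  if (!all(nodes$kind %in% node_kinds))
    problems <- c(problems, "unknown node kind (expected lacuna/branch/endpoint)")
  if (!all(nodes$boundary %in% boundary_tags))
    problems <- c(problems, "unknown boundary tag (expected none/haversian/cement)")

  fi <- match(edges$from, nodes$id)
  ti <- match(edges$to, nodes$id)
  if (anyNA(fi) || anyNA(ti)) {
    bad <- edges$id[is.na(fi) | is.na(ti)]
    problems <- c(problems, paste0("dangling edge endpoints (edge ids ",
                                   paste(utils::head(bad, 5), collapse = ", "), ")"))
  } else if (nrow(edges)) {
    if (any(fi == ti))
      problems <- c(problems, "self-loop edges are not allowed")
    if (any(!is.finite(edges$length) | edges$length <= 0))
      problems <- c(problems, "non-positive edge length")
    chord <- sqrt((nodes$x[fi] - nodes$x[ti])^2 +
                  (nodes$y[fi] - nodes$y[ti])^2 +
                  (nodes$z[fi] - nodes$z[ti])^2)
    short <- is.finite(edges$length) & edges$length < chord * (1 - 1e-9)
    if (any(short)) {
      bad <- edges$id[short]
      problems <- c(problems, paste0("edge length shorter than chord between endpoints (edge ids ",
                                     paste(utils::head(bad, 5), collapse = ", "), ")"))
    }
  }
  if (require_haversian && !any(nodes$boundary == "haversian"))
    problems <- c(problems,
                  "no reference boundary: no node is tagged 'haversian'")

  md <- net$metadata
  if (is.finite(md$osteon_radius) && length(md$center) == 2) {
    r <- sqrt((nodes$x - md$center[1])^2 + (nodes$y - md$center[2])^2)
    if (any(r > md$osteon_radius + geometry_tol))
      problems <- c(problems, "node positions outside the osteon cylinder radius")
  }
  if (is.finite(md$slab_thickness)) {
    if (any(nodes$z < -geometry_tol | nodes$z > md$slab_thickness + geometry_tol))
      problems <- c(problems, "node positions outside the imaged slab thickness")
  }
  if (length(problems))
    stop("invalid osteon network:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  invisible(net)
}

#' @export
print.osteon_network <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("Osteon LCN network (%s)\n", md$osteon_type))
  cat(sprintf("  nodes: %d (%d lacunae, %d haversian, %d cement)\n",
              nrow(x$nodes), sum(x$nodes$kind == "lacuna"),
              sum(x$nodes$boundary == "haversian"),
              sum(x$nodes$boundary == "cement")))
  cat(sprintf("  edges: %d, total canalicular length %.1f um\n",
              nrow(x$edges), sum(x$edges$length)))
  if (is.finite(md$osteon_radius))
    cat(sprintf("  geometry: On.Rd %.4g um, HCa.Rd %.4g um, slab %.4g um\n",
                md$osteon_radius, md$haversian_radius, md$slab_thickness))
  invisible(x)
}

#' @export
summary.osteon_network <- function(object, ...) {
  s <- structural_summary(object)
  print(object)
  cat("Structural summary:\n")
  print(unlist(s))
  invisible(s)
}

#' Plot an osteon network projection
#'
#' Draws the xy-projection of the network with canaliculi as segments; node
#' colour marks boundary tags and lacunae. An optional per-node quantity
#' (e.g. solved pressure) colours the nodes instead.
#'
#' @param x An `osteon_network`.
#' @param node_value Optional numeric per-node quantity to colour by.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.osteon_network <- function(x, node_value = NULL, ...) {
  nodes <- x$nodes; edges <- x$edges
  fi <- match(edges$from, nodes$id); ti <- match(edges$to, nodes$id)
  graphics::plot(nodes$x, nodes$y, type = "n", asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  graphics::segments(nodes$x[fi], nodes$y[fi], nodes$x[ti], nodes$y[ti],
                     col = "grey70")
  if (!is.null(node_value)) {
    pal <- grDevices::hcl.colors(64, "viridis")
    v <- node_value
    idx <- 1 + floor(63 * (v - min(v, na.rm = TRUE)) /
                       max(1e-300, diff(range(v, na.rm = TRUE))))
    graphics::points(nodes$x, nodes$y, pch = 16, cex = 0.4, col = pal[idx])
  } else {
    col <- ifelse(nodes$boundary == "haversian", "red3",
                  ifelse(nodes$boundary == "cement", "blue3",
                         ifelse(nodes$kind == "lacuna", "orange", "grey30")))
    graphics::points(nodes$x, nodes$y, pch = 16, cex = 0.35, col = col)
  }
  invisible(x)
}

#' Oriented edge-node incidence matrix
#'
#' Sparse incidence matrix with one row per edge and one column per node:
#' +1 at the node an edge points towards (its stored `to` endpoint), -1 at the
#' node it points away from. The orientation is a bookkeeping reference for
#' signed flows — the physics is orientation-covariant — but it is fixed and
#' reproducible from the stored endpoint order.
#'
#' @param net A validated `osteon_network`.
#' @return A `dgCMatrix` of dimension edges x nodes; row/column names carry the
#'   edge and node ids.
#' @export
incidence_matrix <- function(net) {
  nodes <- net$nodes; edges <- net$edges
  fi <- match(edges$from, nodes$id); ti <- match(edges$to, nodes$id)
  m <- nrow(edges); n <- nrow(nodes)
  A <- Matrix::sparseMatrix(i = c(seq_len(m), seq_len(m)),
                            j = c(ti, fi),
                            x = c(rep(1, m), rep(-1, m)),
                            dims = c(m, n))
  dimnames(A) <- list(as.character(edges$id), as.character(nodes$id))
  A
}

as_igraph <- function(net) {
  nodes <- net$nodes; edges <- net$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to),
               weight = edges$length, eid = edges$id),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$id)))
  g
}

#' Shortest network path length to the Haversian canal
#'
#' For every node, the minimum sum of canalicular lengths over paths to any
#' Haversian-tagged node (Dijkstra on the edge-length-weighted graph; all
#' canal-surface nodes act as one merged target at distance zero). Nodes with
#' no path to the canal get `Inf`.
#'
#' @param net A validated `osteon_network`.
#' @return Numeric vector of distances in um, one per node, named by node id.
#' @export
shortest_paths_to_canal <- function(net) {
  nodes <- net$nodes
  hav <- which(nodes$boundary == "haversian")
  if (!length(hav)) stop("no reference boundary: no node tagged 'haversian'")
  g <- as_igraph(net)
  d <- igraph::distances(g, v = as.character(nodes$id[hav]),
                         algorithm = "dijkstra")
  out <- apply(d, 2, min)
  out <- out[as.character(nodes$id)]
  names(out) <- as.character(nodes$id)
  out
}

#' Angular sector of each node
#'
#' Assigns each node to one of `n_sectors` equal angular sectors around the
#' osteon centre (xy-plane). Sectors are half-open: a node whose angle falls
#' exactly on a boundary belongs to the sector whose lower edge it is, so
#' angle 0 is sector 0 and angles just below 2*pi land in the last sector.
#'
#' @param net An `osteon_network` with `metadata$center` set.
#' @param n_sectors Number of sectors (default 36, i.e. 10-degree opening).
#' @return Integer vector of 0-based sector indices, one per node.
#' @export
sector_partition <- function(net, n_sectors = 36) {
  if (n_sectors < 1) stop("n_sectors must be >= 1")
  ctr <- net$metadata$center
  if (length(ctr) != 2 || anyNA(ctr)) stop("metadata$center must be set")
  theta <- atan2(net$nodes$y - ctr[2], net$nodes$x - ctr[1])
  theta <- theta %% (2 * pi)
  idx <- floor(n_sectors * theta / (2 * pi))
  as.integer(pmin(idx, n_sectors - 1L))
}

#' Structural summary of an LCN network
#'
#' The six structural parameters characterising an osteonal LCN: node number
#' density, canalicular number density, canalicular length density (`Can.Dn`),
#' mean node degree, mean weighted node degree (sum of incident canalicular
#' lengths per node) and the mean shortest path length to the Haversian canal.
#' Densities are normalised by the evaluated bone volume in
#' `metadata$evaluated_volume`.
#'
#' @param net A validated `osteon_network` with positive evaluated volume.
#' @param path_nodes Which nodes enter the mean shortest-path length:
#'   `"all"` (default) or `"lacuna"` only.
#' @return An object of class `structural_summary`: a list with fields
#'   `node_density` (1/um^3), `canalicular_number_density` (1/um^3),
#'   `canalicular_length_density` (um/um^3), `mean_node_degree`,
#'   `mean_weighted_node_degree` (um), `mean_shortest_path_to_canal` (um),
#'   and `n_unreachable`.
#' @export
structural_summary <- function(net, path_nodes = c("all", "lacuna")) {
  path_nodes <- match.arg(path_nodes)
  bv <- net$metadata$evaluated_volume
  if (!is.finite(bv) || bv <= 0)
    stop("metadata$evaluated_volume must be positive")
  n <- nrow(net$nodes); m <- nrow(net$edges)
  wdeg <- weighted_node_degree(net)
  d <- shortest_paths_to_canal(net)
  if (path_nodes == "lacuna") d <- d[net$nodes$kind == "lacuna"]
  reach <- is.finite(d)
  structure(list(
    node_density = n / bv,
    canalicular_number_density = m / bv,
    canalicular_length_density = sum(net$edges$length) / bv,
    mean_node_degree = if (n) 2 * m / n else 0,
    mean_weighted_node_degree = mean(wdeg),
    mean_shortest_path_to_canal = mean(d[reach]),
    n_unreachable = sum(!reach)
  ), class = "structural_summary")
}

#' @export
print.structural_summary <- function(x, ...) {
  cat("LCN structural summary\n")
  cat(sprintf("  node density              : %.4g 1/um^3\n", x$node_density))
  cat(sprintf("  canalicular number density: %.4g 1/um^3\n", x$canalicular_number_density))
  cat(sprintf("  canalicular length density: %.4g um/um^3\n", x$canalicular_length_density))
  cat(sprintf("  mean node degree          : %.3f\n", x$mean_node_degree))
  cat(sprintf("  mean weighted node degree : %.3f um\n", x$mean_weighted_node_degree))
  cat(sprintf("  mean shortest path to canal: %.2f um (%d unreachable)\n",
              x$mean_shortest_path_to_canal, x$n_unreachable))
  invisible(x)
}

# sum of incident edge lengths per node, in node-table order
weighted_node_degree <- function(net) {
  nodes <- net$nodes; edges <- net$edges
  w <- numeric(nrow(nodes))
  if (nrow(edges)) {
    fi <- match(edges$from, nodes$id); ti <- match(edges$to, nodes$id)
    add <- tapply(c(edges$length, edges$length), c(fi, ti), sum)
    w[as.integer(names(add))] <- as.numeric(add)
  }
  names(w) <- as.character(nodes$id)
  w
}

# radial distance of nodes from the osteon axis, um
node_radius <- function(net) {
  ctr <- net$metadata$center
  sqrt((net$nodes$x - ctr[1])^2 + (net$nodes$y - ctr[2])^2)
}

#' Normalized radial distance of each node
#'
#' Rescales the radial coordinate so the Haversian canal surface maps to 0 and
#' the cement line to 1: `(r - HCa.Rd) / (On.Rd - HCa.Rd)` for the concentric
#' circular geometry used here. Values are clamped to `[0, 1]`.
#'
#' @param net An `osteon_network` with geometry metadata set.
#' @return Numeric vector in `[0, 1]`, one value per node.
#' @export
normalized_distance <- function(net) {
  md <- net$metadata
  if (!is.finite(md$haversian_radius) || !is.finite(md$osteon_radius))
    stop("metadata haversian_radius and osteon_radius must be set")
  r <- node_radius(net)
  pmin(1, pmax(0, (r - md$haversian_radius) /
                    (md$osteon_radius - md$haversian_radius)))
}
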