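#' Assemble the hydraulic system of an LCN network
#'
#' Builds the Kirchhoff/Darcy linear system for a validated network. All
#' Haversian-tagged nodes are merged into a single reference supernode `i0`
#' (the canal is one constant low-pressure reservoir), edge conductivities are
#' computed from arc lengths, and the weighted graph Laplacian
#' `L = t(A) %*% C %*% A` is formed on the merged node set. Nodes with no path
#' to `i0` are flagged; they are excluded from the unknowns of any solve (their
#' pressure is physically undefined) but remain part of the data model.
#'
#' @param net A validated `osteon_network` with at least one Haversian node.
#' @param params A [hydraulic_params()] object.
#' @return A list with the merged incidence matrix `A` (edges x merged nodes),
#'   conductivity vector `C` (um^3/(Pa s)), Laplacian `L`, the supernode index
#'   `i0 = 1`, `merged_of` (merged index per original node), `connected`
#'   (logical per merged node), `active_edge` (edges not collapsed onto the
#'   supernode self-loop and not touching a disconnected component) and the
#'   source network.
#' @export
assemble_system <- function(net, params = hydraulic_params()) {
  validate_network(net)
  nodes <- net$nodes; edges <- net$edges
  if (!nrow(edges)) stop("empty network: no edges to assemble")
  hav <- nodes$boundary == "haversian"
  n_free <- sum(!hav)
  merged_of <- integer(nrow(nodes))
  merged_of[hav] <- 1L
  merged_of[!hav] <- seq_len(n_free) + 1L
  nm <- n_free + 1L

  fi <- merged_of[match(edges$from, nodes$id)]
  ti <- merged_of[match(edges$to, nodes$id)]
  Cv <- edge_conductivity(edges$length, params)
  m <- nrow(edges)
  # +1 at head (to), -1 at tail (from); duplicate (i,j) entries sum, so an
  # edge with both ends on the canal collapses to an all-zero row
  A <- Matrix::sparseMatrix(i = c(seq_len(m), seq_len(m)), j = c(ti, fi),
                            x = c(rep(1, m), rep(-1, m)), dims = c(m, nm))
  L <- Matrix::t(A) %*% (Cv * A)
  L <- Matrix::forceSymmetric((L + Matrix::t(L)) / 2)

  g <- igraph::graph_from_edgelist(cbind(fi, ti), directed = FALSE)
  if (igraph::vcount(g) < nm) g <- igraph::add_vertices(g, nm - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  connected <- comp == comp[1L]
  active_edge <- connected[fi] & connected[ti] & (fi != ti)

  list(A = A, C = Cv, L = L, i0 = 1L, merged_of = merged_of,
       connected = connected, active_edge = active_edge,
       edge_tail = fi, edge_head = ti, net = net, params = params)
}

# reverse Cuthill-McKee ordering of a symmetric sparse pattern
rcm_order <- function(L) {
  n <- nrow(L)
  Lt <- as(as(L, "generalMatrix"), "TsparseMatrix")
  adj <- split(Lt@j + 1L, Lt@i + 1L)
  deg <- lengths(adj)
  visited <- logical(n)
  order <- integer(0)
  while (length(order) < n) {
    start <- which(!visited)[which.min(deg[!visited])]
    queue <- start; visited[start] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      order <- c(order, v)
      nb <- adj[[as.character(v)]]
      nb <- nb[!visited[nb] & nb != v]
      if (length(nb)) {
        nb <- nb[order(deg[nb])]
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  rev(order)
}

# sparse SPD solve with two steps of iterative refinement, so per-node
# Kirchhoff residuals sit at the local roundoff scale
solve_spd <- function(L, b) {
  L <- Matrix::forceSymmetric(L)
  ch <- Matrix::Cholesky(L, LDL = TRUE, perm = TRUE)
  x <- Matrix::solve(ch, b, system = "A")
  for (i in 1:2) {
    r <- b - L %*% x
    x <- x + Matrix::solve(ch, r, system = "A")
  }
  as.numeric(x)
}

# solve L[u,u] p = rhs, optionally with RCM reordering (result-invariant)
solve_reduced <- function(L_uu, rhs, reorder = c("none", "rcm")) {
  reorder <- match.arg(reorder)
  if (reorder == "rcm") {
    perm <- rcm_order(L_uu)
    p <- numeric(length(rhs))
    p[perm] <- solve_spd(L_uu[perm, perm, drop = FALSE], rhs[perm])
    p
  } else {
    solve_spd(L_uu, rhs)
  }
}

new_lcn_flow <- function(sys, approach, p_merged, applied,
                         leak = NULL) {
  net <- sys$net; nodes <- net$nodes
  p_nodes <- p_merged[sys$merged_of]
  q <- sys$C * (p_merged[sys$edge_tail] - p_merged[sys$edge_head])
  q[sys$edge_tail == sys$edge_head] <- 0          # canal-internal edges
  q[!sys$active_edge & sys$edge_tail != sys$edge_head] <- NA_real_
  v <- q / sys$params$annulus_area
  into_i0 <- numeric(length(q))
  at_head <- sys$edge_head == sys$i0 & sys$edge_tail != sys$i0
  at_tail <- sys$edge_tail == sys$i0 & sys$edge_head != sys$i0
  into_i0[at_head] <- q[at_head]
  into_i0[at_tail] <- -q[at_tail]
  boundary_flux <- sum(into_i0, na.rm = TRUE)
  if (!is.null(leak)) boundary_flux <- c(haversian = boundary_flux,
                                         cement_leak = leak$total_flux)
  excluded <- nodes$id[!sys$connected[sys$merged_of]]
  p_nodes[!sys$connected[sys$merged_of]] <- NA_real_
  names(p_nodes) <- as.character(nodes$id)
  structure(list(approach = approach,
                 node_pressure = p_nodes,
                 edge_flow = stats::setNames(q, as.character(net$edges$id)),
                 edge_velocity = stats::setNames(v, as.character(net$edges$id)),
                 boundary_flux = boundary_flux,
                 excluded_nodes = excluded,
                 applied = applied,
                 leak = leak,
                 params = sys$params,
                 network = net,
                 system = sys),
            class = "lcn_flow")
}

#' Solve interstitial fluid flow through an LCN network
#'
#' Central solver: computes steady-state node pressures and canalicular flows
#' for one osteon under one of the two boundary-condition approaches.
#'
#' `"fixed_pressure"` applies a fixed trans-osteonal pressure difference:
#' cement-line nodes are held at `delta_p`, the Haversian supernode at 0, and
#' interior pressures follow from Kirchhoff's current law with no sources
#' (a discrete Dirichlet problem; interior pressures obey the maximum
#' principle and lie in `[0, delta_p]`). This is the configuration used to
#' measure the intrinsic permeability of the osteon.
#'
#' `"strain_sources"` models load-induced flow: homogeneous compression at
#' volumetric strain rate `strain_rate` squeezes fluid out of every pore, so
#' each node injects `strain_rate` times its pore volume (half the volume of
#' its incident canaliculi, plus the lacunar volume for lacunae) and the
#' Haversian canal absorbs the total, like water squeezed from a steadily
#' compressed sponge.
#'
#' @param net A validated `osteon_network`.
#' @param params A [hydraulic_params()] object.
#' @param approach `"fixed_pressure"` or `"strain_sources"`.
#' @param delta_p Applied cement-line pressure, Pa (approach 1; default 13 kPa).
#' @param strain_rate Volumetric strain rate, 1/s (approach 2; defaults to
#'   `params$strain_rate`).
#' @param reorder `"none"` or `"rcm"` (reverse Cuthill-McKee reordering of the
#'   reduced system before factorisation; result-invariant).
#' @return An object of class `lcn_flow` with per-node pressures (Pa; the
#'   reference canal at 0, disconnected nodes `NA`), signed per-edge volumetric
#'   flows (um^3/s, along the stored edge orientation), per-edge velocities
#'   (um/s), the volumetric flux into the Haversian canal (um^3/s), the set of
#'   excluded (disconnected) node ids and the applied boundary conditions.
#' @examples
#' net <- generate_chain(5, 10)
#' sol <- lcn_flow(net, approach = "strain_sources")
#' summary(sol)
#' @export
lcn_flow <- function(net, params = hydraulic_params(),
                     approach = c("fixed_pressure", "strain_sources"),
                     delta_p = 13000, strain_rate = NULL,
                     reorder = c("none", "rcm")) {
  approach <- match.arg(approach)
  reorder <- match.arg(reorder)
  sys <- assemble_system(net, params)
  if (approach == "fixed_pressure") {
    solve_fixed_pressure_sys(sys, delta_p, reorder)
  } else {
    if (is.null(strain_rate)) strain_rate <- params$strain_rate
    solve_strain_sources_sys(sys, strain_rate, reorder)
  }
}

solve_fixed_pressure_sys <- function(sys, delta_p, reorder = "none") {
  net <- sys$net; nodes <- net$nodes
  nm <- nrow(sys$L)
  cement_m <- unique(sys$merged_of[nodes$boundary == "cement"])
  cement_m <- setdiff(cement_m[sys$connected[cement_m]], sys$i0)
  p <- numeric(nm)
  if (!length(cement_m)) {
    warning("no cement-line node connected to the Haversian canal; zero-flow solution")
  }
  p[cement_m] <- delta_p
  dirichlet <- c(sys$i0, cement_m)
  unknown <- setdiff(which(sys$connected), dirichlet)
  if (length(unknown)) {
    rhs <- -as.numeric(sys$L[unknown, dirichlet, drop = FALSE] %*% p[dirichlet])
    p[unknown] <- solve_reduced(sys$L[unknown, unknown, drop = FALSE], rhs,
                                reorder)
  }
  new_lcn_flow(sys, "fixed_pressure", p,
               applied = list(delta_p_osteon = delta_p))
}

#' @rdname lcn_flow
#' @export
solve_fixed_pressure <- function(net, params = hydraulic_params(),
                                 delta_p = 13000,
                                 reorder = c("none", "rcm")) {
  lcn_flow(net, params, "fixed_pressure", delta_p = delta_p,
           reorder = match.arg(reorder))
}

#' @rdname lcn_flow
#' @export
solve_strain_sources <- function(net, params = hydraulic_params(),
                                 strain_rate = params$strain_rate,
                                 reorder = c("none", "rcm")) {
  lcn_flow(net, params, "strain_sources", strain_rate = strain_rate,
           reorder = match.arg(reorder))
}

solve_strain_sources_sys <- function(sys, strain_rate, reorder = "none",
                                     leak_conductance = NULL) {
  net <- sys$net
  vol <- node_source_volumes(net, sys$params)
  nm <- nrow(sys$L)
  # pore volume per merged node; the reference supernode's row is removed, so
  # its own half-volumes are never injected
  vol_m <- numeric(nm)
  keep <- sys$merged_of != sys$i0
  vol_m[sys$merged_of[keep]] <- vol[keep]
  unknown <- setdiff(which(sys$connected), sys$i0)
  v_olcn <- sum(vol_m[unknown])
  if (v_olcn <= 0) stop("V_OLCN is zero: network has no pore volume to drain")
  p <- numeric(nm)
  if (length(unknown)) {
    L_uu <- sys$L[unknown, unknown, drop = FALSE]
    if (!is.null(leak_conductance))
      L_uu <- L_uu + Matrix::Diagonal(length(unknown),
                                      leak_conductance[unknown])
    p[unknown] <- solve_reduced(L_uu, strain_rate * vol_m[unknown], reorder)
  }
  leak <- NULL
  if (!is.null(leak_conductance)) {
    lf <- leak_conductance * p
    leak <- list(conductance = leak_conductance,
                 node_flux = lf[sys$merged_of],
                 total_flux = sum(lf))
  }
  out <- new_lcn_flow(sys, "strain_sources", p,
                      applied = list(strain_rate = strain_rate,
                                     V_OLCN = v_olcn),
                      leak = leak)
  out
}

#' Pore volume attributed to each network node
#'
#' The fluid volume each node contributes as a source under homogeneous
#' compression: half the annular volume of its incident canaliculi,
#' `(weighted degree / 2) * A`, plus the lacunar volume for lacuna nodes (a
#' per-node `lacuna_volume` column in the node table overrides the constant
#' from `params`).
#'
#' @param net A validated `osteon_network`.
#' @param params A [hydraulic_params()] object.
#' @return Numeric vector of volumes in um^3, one per node, named by node id.
#' @export
node_source_volumes <- function(net, params = hydraulic_params()) {
  wdeg <- weighted_node_degree(net)
  vol <- (wdeg / 2) * params$annulus_area
  lac <- net$nodes$kind == "lacuna"
  if ("lacuna_volume" %in% names(net$nodes)) {
    vol[lac] <- vol[lac] + net$nodes$lacuna_volume[lac]
  } else {
    vol[lac] <- vol[lac] + params$lacuna_volume
  }
  vol
}

#' Strain-driven flow with a leaking cement line
#'
#' Variant of the strain-source solve in which a seeded random subset of the
#' cement-line dead-end nodes is connected to an external zero-pressure
#' reservoir through a virtual canaliculus of standard conductivity (one mean
#' edge length), letting part of the squeezed fluid escape outward instead of
#' draining into the Haversian canal. `leak_fraction = 0` reproduces
#' [solve_strain_sources()] exactly; the two boundary fluxes always sum to
#' `strain_rate * V_OLCN`.
#'
#' @param net A validated `osteon_network`.
#' @param params A [hydraulic_params()] object.
#' @param leak_fraction Fraction of cement-tagged nodes that leak, in `[0, 1]`.
#' @param strain_rate Volumetric strain rate, 1/s.
#' @param seed Integer seed selecting the leaking subset.
#' @return An `lcn_flow` object whose `boundary_flux` has components
#'   `haversian` and `cement_leak`, and whose `leak` field records the leaking
#'   nodes and per-node leak fluxes.
#' @export
leaky_cement_variant <- function(net, params = hydraulic_params(),
                                 leak_fraction, strain_rate = params$strain_rate,
                                 seed = 1L) {
  if (leak_fraction < 0 || leak_fraction > 1)
    stop("leak_fraction must be in [0, 1]")
  sys <- assemble_system(net, params)
  if (leak_fraction == 0)
    return(solve_strain_sources_sys(sys, strain_rate))
  cem <- which(net$nodes$boundary == "cement")
  n_leak <- round(leak_fraction * length(cem))
  pick <- if (n_leak >= length(cem)) cem else
    with_seed(seed, sample(cem, n_leak))
  cond <- numeric(nrow(sys$L))
  c_std <- edge_conductivity(mean(net$edges$length), params)
  cond[sys$merged_of[pick]] <- cond[sys$merged_of[pick]] + c_std
  solve_strain_sources_sys(sys, strain_rate, leak_conductance = cond)
}

#' @export
print.lcn_flow <- function(x, ...) {
  cat(sprintf("LCN flow solution (%s)\n", x$approach))
  ap <- x$applied
  if (x$approach == "fixed_pressure")
    cat(sprintf("  applied pressure: %.4g Pa (cement line vs Haversian canal)\n",
                ap$delta_p_osteon))
  else
    cat(sprintf("  strain rate %.3g 1/s, V_OLCN %.4g um^3\n",
                ap$strain_rate, ap$V_OLCN))
  cat(sprintf("  nodes solved: %d (%d disconnected)\n",
              sum(!is.na(x$node_pressure)), length(x$excluded_nodes)))
  bf <- x$boundary_flux
  cat(sprintf("  flux into Haversian canal: %.4g um^3/s\n",
              if (length(bf) > 1) bf[["haversian"]] else bf))
  if (length(bf) > 1)
    cat(sprintf("  flux through leaking cement line: %.4g um^3/s\n",
                bf[["cement_leak"]]))
  invisible(x)
}

#' @export
summary.lcn_flow <- function(object, ...) {
  x <- object
  print(x)
  v <- abs(x$edge_velocity)
  w <- x$network$edges$length
  ok <- !is.na(v)
  cat(sprintf("  mean |velocity| (length-weighted): %.4g um/s\n",
              sum(v[ok] * w[ok]) / sum(w[ok])))
  cat(sprintf("  pressure range: [%.4g, %.4g] Pa\n",
              min(x$node_pressure, na.rm = TRUE),
              max(x$node_pressure, na.rm = TRUE)))
  tau <- shear_stress(v[ok], x$params)
  cat(sprintf("  shear stress: median %.3g Pa, max %.3g Pa\n",
              stats::median(tau), max(tau)))
  invisible(x)
}

#' Kirchhoff residuals of a flow solution
#'
#' Net volumetric imbalance `t(A) q + f` at every solved (non-reference) node;
#' machine-precision zeros certify mass conservation of the solve.
#'
#' @param object An `lcn_flow` solution.
#' @param ... Unused.
#' @return Numeric vector of residual fluxes (um^3/s) per solved merged node.
#' @export
residuals.lcn_flow <- function(object, ...) {
  sys <- object$system
  q <- object$edge_flow
  q[is.na(q)] <- 0
  div <- as.numeric(Matrix::t(sys$A) %*% q)   # net inflow per merged node
  unknown <- setdiff(which(sys$connected), sys$i0)
  f <- numeric(nrow(sys$L))
  if (object$approach == "strain_sources") {
    vol <- node_source_volumes(object$network, object$params)
    keep <- sys$merged_of != sys$i0
    f[sys$merged_of[keep]] <- object$applied$strain_rate * vol[keep]
  }
  res <- div + f
  if (!is.null(object$leak)) {
    p_m <- numeric(nrow(sys$L))
    p_m[sys$merged_of] <- ifelse(is.na(object$node_pressure), 0,
                                 object$node_pressure)
    res <- res - object$leak$conductance * p_m
  }
  res[unknown]
}

#' Plot a flow solution
#'
#' Scatter of node pressure against normalized radial distance (canal = 0,
#' cement line = 1) with the smoothed pressure profile overlaid.
#'
#' @param x An `lcn_flow` solution.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lcn_flow <- function(x, ...) {
  d <- normalized_distance(x$network)
  p <- x$node_pressure
  graphics::plot(d, p, pch = 16, cex = 0.3, col = "grey50",
                 xlab = "normalized distance from Haversian canal",
                 ylab = "pressure (Pa)", ...)
  prof <- try(pressure_profile(x$network, x), silent = TRUE)
  if (!inherits(prof, "try-error"))
    graphics::lines(prof$distance, prof$pressure, col = "red3", lwd = 2)
  invisible(x)
}
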