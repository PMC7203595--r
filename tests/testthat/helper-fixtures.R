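# Small fixture builders and independent brute-force oracles used across the
# suite. Everything is generated in code; no data files.

# bare-bones network from coordinate/edge tables, skipping geometry metadata
tiny_network <- function(nodes, edges, validate = TRUE, meta = list()) {
  osteon_network(nodes, edges,
                 metadata = utils::modifyList(
                   list(center = c(0, 0), osteon_type = "synthetic_oracle",
                        evaluated_volume = sum(edges$length)), meta),
                 validate = validate)
}

# a 3-node chain with a longer detour edge between its ends
detour_network <- function() {
  nodes <- data.frame(id = 1:3,
                      x = c(0, 10, 20), y = 0, z = 0,
                      kind = c("endpoint", "branch", "endpoint"),
                      boundary = c("cement", "none", "haversian"))
  edges <- data.frame(id = 1:3,
                      from = c(1, 2, 1), to = c(2, 3, 3),
                      length = c(10, 10, 35))
  tiny_network(nodes, edges)
}

# seeded random connected multigraph with n <= 12 nodes; node 1 area is the
# canal; ensures every node reachable
random_small_network <- function(seed, n_nodes = NULL) {
  set.seed(seed)
  n <- if (is.null(n_nodes)) sample(4:12, 1) else n_nodes
  xyz <- matrix(runif(3 * n, 0, 50), ncol = 3)
  # random spanning tree plus extra edges (parallel edges allowed)
  from <- integer(0); to <- integer(0)
  for (i in 2:n) {
    from <- c(from, sample(seq_len(i - 1), 1)); to <- c(to, i)
  }
  n_extra <- sample(0:4, 1)
  for (k in seq_len(n_extra)) {
    pr <- sample(n, 2)
    from <- c(from, pr[1]); to <- c(to, pr[2])
  }
  chord <- sqrt(rowSums((xyz[from, , drop = FALSE] -
                           xyz[to, , drop = FALSE])^2))
  lens <- chord * runif(length(from), 1, 1.8)
  n_hav <- sample(1:2, 1)
  boundary <- rep("none", n)
  boundary[sample(n, n_hav)] <- "haversian"
  free <- which(boundary == "none")
  if (length(free)) boundary[sample(free, 1)] <- "cement"
  kind <- rep("branch", n)
  kind[sample(n, 1)] <- "lacuna"
  nodes <- data.frame(id = seq_len(n), x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], kind = kind, boundary = boundary)
  edges <- data.frame(id = seq_along(from), from = from, to = to,
                      length = lens)
  tiny_network(nodes, edges)
}

# flip the stored orientation of the given edges
flip_edges <- function(net, which_edges) {
  e <- net$edges
  tmp <- e$from[which_edges]
  e$from[which_edges] <- e$to[which_edges]
  e$to[which_edges] <- tmp
  net$edges <- e
  net
}

# Independent dense oracle: assembles the full Laplacian with plain loops and
# solves with base R dense algebra. Shares no code with the package solver.
dense_oracle_pressures <- function(net, params,
                                   approach = c("fixed_pressure",
                                                "strain_sources"),
                                   delta_p = 13000,
                                   strain_rate = params$strain_rate) {
  approach <- match.arg(approach)
  nodes <- net$nodes; edges <- net$edges
  n <- nrow(nodes)
  mob <- (params$k_p_eff * 1e12) / params$mu
  # merge haversian nodes: map them all to one index
  hav <- which(nodes$boundary == "haversian")
  map <- integer(n)
  map[hav] <- 1L
  map[-hav] <- seq_len(n - length(hav)) + 1L
  nm <- n - length(hav) + 1L
  L <- matrix(0, nm, nm)
  for (r in seq_len(nrow(edges))) {
    i <- map[match(edges$from[r], nodes$id)]
    j <- map[match(edges$to[r], nodes$id)]
    if (i == j) next
    cc <- mob * params$annulus_area / edges$length[r]
    L[i, i] <- L[i, i] + cc; L[j, j] <- L[j, j] + cc
    L[i, j] <- L[i, j] - cc; L[j, i] <- L[j, i] - cc
  }
  p <- numeric(nm)
  if (approach == "fixed_pressure") {
    cem <- unique(map[nodes$boundary == "cement"])
    p[cem] <- delta_p
    fixed <- c(1L, cem)
    un <- setdiff(seq_len(nm), fixed)
    if (length(un))
      p[un] <- solve(L[un, un, drop = FALSE],
                     -L[un, fixed, drop = FALSE] %*% p[fixed])
  } else {
    vol <- numeric(nm)
    for (r in seq_len(nrow(edges))) {
      for (end in c(match(edges$from[r], nodes$id),
                    match(edges$to[r], nodes$id))) {
        if (map[end] != 1L)
          vol[map[end]] <- vol[map[end]] +
            (edges$length[r] / 2) * params$annulus_area
      }
    }
    for (i in which(nodes$kind == "lacuna"))
      if (map[i] != 1L) vol[map[i]] <- vol[map[i]] + params$lacuna_volume
    un <- setdiff(seq_len(nm), 1L)
    p[un] <- solve(L[un, un, drop = FALSE], strain_rate * vol[un])
  }
  out <- p[map]
  names(out) <- as.character(nodes$id)
  out
}

# exhaustive shortest path to any haversian node by enumerating simple paths
brute_force_shortest_to_canal <- function(net) {
  nodes <- net$nodes; edges <- net$edges
  n <- nrow(nodes)
  targets <- which(nodes$boundary == "haversian")
  best <- rep(Inf, n)
  adj <- lapply(seq_len(n), function(i) {
    sel <- which(match(edges$from, nodes$id) == i |
                   match(edges$to, nodes$id) == i)
    other <- ifelse(match(edges$from[sel], nodes$id) == i,
                    match(edges$to[sel], nodes$id),
                    match(edges$from[sel], nodes$id))
    cbind(other, edges$length[sel])
  })
  # enumerate all simple paths from each start node
  for (s in seq_len(n)) {
    stack_walk <- function(v, dist, visited) {
      if (v %in% targets) {
        best[s] <<- min(best[s], dist)
        return(invisible())
      }
      if (!nrow(adj[[v]])) return(invisible())
      for (r in seq_len(nrow(adj[[v]]))) {
        w <- adj[[v]][r, 1]; l <- adj[[v]][r, 2]
        if (visited[w]) next
        visited[w] <- TRUE
        stack_walk(w, dist + l, visited)
        visited[w] <- FALSE
      }
    }
    vis <- rep(FALSE, n); vis[s] <- TRUE
    stack_walk(s, 0, vis)
  }
  names(best) <- as.character(nodes$id)
  best
}

# exact permutation two-sided rank-sum p-value (no ties)
perm_ranksum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  pl <- mean(ws <= w_obs); pu <- mean(ws >= w_obs)
  min(1, 2 * min(pl, pu))
}

default_cohort_seed <- 20L
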