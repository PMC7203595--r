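params <- hydraulic_params()

test_that("annulus area and single-canaliculus conductivity match hand evaluation", {
  # A = (Ca.Rd^2 - CP.Rd^2) * pi with radii in nm -> um^2
  expect_equal(params$annulus_area, (0.1575^2 - 0.073^2) * pi)
  # C(1 um) = (k_p_eff / mu) * A / l, hand-converted to um^3/(Pa s)
  expect_equal(edge_conductivity(1, params),
               (1.53e-17 / 1.06e-3) * 1e12 * params$annulus_area,
               tolerance = 1e-12)
  expect_equal(edge_conductivity(2, params), edge_conductivity(1, params) / 2)
  expect_error(edge_conductivity(0, params), "positive")
  expect_error(edge_conductivity(-3, params), "positive")
})

test_that("hydraulic params validate radii and area overrides", {
  expect_error(hydraulic_params(process_radius = 200), "smaller")
  expect_error(hydraulic_params(mu = -1), "positive")
  expect_error(hydraulic_params(annulus_area = 0.05), "disagrees")
  p2 <- hydraulic_params(annulus_area = 0.061)
  expect_equal(p2$annulus_area, 0.061)
})

test_that("assembled Laplacian has zero row sums and merges parallel edges", {
  net <- random_small_network(4)
  sys <- assemble_system(net, params)
  expect_lt(max(abs(Matrix::rowSums(sys$L))), 1e-12)

  # two parallel edges between the same pair: off-diagonal is -(C1 + C2)
  nodes <- data.frame(id = 1:2, x = c(0, 10), y = 0, z = 0,
                      kind = "endpoint", boundary = c("haversian", "none"))
  edges <- data.frame(id = 1:2, from = c(1, 1), to = c(2, 2),
                      length = c(12, 20))
  pm <- tiny_network(nodes, edges)
  sysp <- assemble_system(pm, params)
  expect_equal(sysp$L[1, 2],
               -(edge_conductivity(12, params) + edge_conductivity(20, params)))

  # single edge to the canal: reduced system is 1x1 with C11
  single <- tiny_network(nodes, data.frame(id = 1, from = 1, to = 2, length = 12))
  syss <- assemble_system(single, params)
  expect_equal(as.numeric(syss$L[2, 2]), edge_conductivity(12, params))
})

test_that("fixed-pressure solve reproduces the series-resistor closed form", {
  # two segments l1 (cement side) and l2 (canal side):
  # interior pressure = delta_p * l2 / (l1 + l2)
  for (lens in list(c(10, 10), c(3, 7), c(25, 5))) {
    net <- generate_chain(2, 1)   # short chords, lengths overridden below
    net$edges$length <- lens
    sol <- solve_fixed_pressure(net, params, delta_p = 13000)
    expect_equal(unname(sol$node_pressure[2]),
                 13000 * lens[2] / sum(lens), tolerance = 1e-12)
    expect_equal(unname(sol$node_pressure[1]), 13000)
    expect_equal(unname(sol$node_pressure[3]), 0)
  }
})

test_that("spoke osteon under 13 kPa has the analytic uniform velocity", {
  sp <- generate_spoke_osteon(10, 4)
  sol <- solve_fixed_pressure(sp, params)
  dR <- sp$metadata$osteon_radius - sp$metadata$haversian_radius
  v_expect <- (params$k_p_eff * 1e12 / params$mu) * 13000 / dR
  expect_equal(unname(abs(sol$edge_velocity)),
               rep(v_expect, nrow(sp$edges)), tolerance = 1e-10)
})

test_that("discrete maximum principle holds for the fixed-pressure approach", {
  net <- generate_osteon(generator_params(seed = 2, osteon_radius = 60))
  sol <- solve_fixed_pressure(net, params)
  p <- sol$node_pressure[!is.na(sol$node_pressure)]
  expect_equal(max(p), 13000)
  expect_equal(min(p), 0)
  interior <- p[net$nodes$boundary == "none"]
  expect_true(all(interior >= -1e-9 * 13000 & interior <= 13000 * (1 + 1e-9)))
})

test_that("node source volumes follow the half-canaliculus rule", {
  net <- generate_chain(2, 10)
  vol <- node_source_volumes(net, params)
  # interior node with two 10 um canaliculi: (20/2) * A
  expect_equal(unname(vol[2]), 10 * params$annulus_area)

  # flagged as lacuna it additionally carries the lacunar volume
  netl <- generate_chain(2, 10, lacuna_nodes = 2)
  voll <- node_source_volumes(netl, params)
  expect_equal(unname(voll[2]), 10 * params$annulus_area + 350)

  # chain of N segments: total over non-canal nodes telescopes to A*l*(N-1/2)
  for (n in c(1, 4, 9)) {
    ch <- generate_chain(n, 7)
    v <- node_source_volumes(ch, params)
    non_canal <- ch$nodes$boundary != "haversian"
    expect_equal(sum(v[non_canal]), params$annulus_area * 7 * (n - 0.5))
  }

  # per-lacuna override column wins over the constant
  netl$nodes$lacuna_volume <- ifelse(netl$nodes$kind == "lacuna", 420, NA)
  vo <- node_source_volumes(netl, params)
  expect_equal(unname(vo[2]), 10 * params$annulus_area + 420)
})

test_that("strain-source chain velocities follow v_k = eps*l*(k - 1/2)", {
  for (cfg in list(c(5, 10), c(8, 4))) {
    net <- generate_chain(cfg[1], cfg[2])
    sol <- solve_strain_sources(net, params)
    k <- seq_len(cfg[1])
    expect_equal(unname(sol$edge_velocity), 0.015 * cfg[2] * (k - 0.5),
                 tolerance = 1e-10)
    expect_equal(sol$boundary_flux, 0.015 * sol$applied$V_OLCN,
                 tolerance = 1e-12)
  }
  # one upstream lacuna raises every downstream velocity by eps*V_lac/A
  base <- solve_strain_sources(generate_chain(5, 10), params)
  withl <- solve_strain_sources(generate_chain(5, 10, lacuna_nodes = 1), params)
  expect_equal(unname(withl$edge_velocity - base$edge_velocity),
               rep(0.015 * 350 / params$annulus_area, 5), tolerance = 1e-9)
})

test_that("solutions are linear in the driving terms", {
  net <- random_small_network(9)
  s1 <- solve_strain_sources(net, params, strain_rate = 0.015)
  s2 <- solve_strain_sources(net, params, strain_rate = 0.0075)
  expect_equal(s2$node_pressure, s1$node_pressure / 2, tolerance = 1e-12)
  expect_equal(s2$edge_velocity, s1$edge_velocity / 2, tolerance = 1e-12)

  f1 <- solve_fixed_pressure(net, params, delta_p = 13000)
  f2 <- solve_fixed_pressure(net, params, delta_p = 26000)
  expect_equal(f2$node_pressure, 2 * f1$node_pressure, tolerance = 1e-12)

  # superposition of sources: eps_a + eps_b
  sa <- solve_strain_sources(net, params, strain_rate = 0.01)
  sb <- solve_strain_sources(net, params, strain_rate = 0.005)
  expect_equal(sa$node_pressure + sb$node_pressure, s1$node_pressure,
               tolerance = 1e-12)
})

test_that("flipping edge orientation negates its flow and nothing else", {
  net <- random_small_network(13)
  s1 <- solve_strain_sources(net, params)
  net2 <- flip_edges(net, c(2, 4))
  s2 <- solve_strain_sources(net2, params)
  expect_equal(s2$node_pressure, s1$node_pressure, tolerance = 1e-12)
  sgn <- rep(1, nrow(net$edges)); sgn[c(2, 4)] <- -1
  expect_equal(unname(s2$edge_flow), unname(sgn * s1$edge_flow),
               tolerance = 1e-12)
})

test_that("sparse reduced solve matches the dense brute-force oracle", {
  for (seed in 1:25) {
    net <- random_small_network(seed)
    for (ap in c("fixed_pressure", "strain_sources")) {
      sol <- lcn_flow(net, params, ap)
      oracle <- dense_oracle_pressures(net, params, ap)
      scale <- max(abs(oracle), 1e-30)
      expect_lt(max(abs(sol$node_pressure - oracle)) / scale, 1e-10)
    }
  }
})

test_that("reverse Cuthill-McKee reordering leaves the solution unchanged", {
  net <- generate_osteon(generator_params(seed = 6, osteon_radius = 60))
  s1 <- solve_fixed_pressure(net, params)
  s2 <- solve_fixed_pressure(net, params, reorder = "rcm")
  scale <- max(abs(s1$node_pressure), na.rm = TRUE)
  expect_lt(max(abs(s1$node_pressure - s2$node_pressure), na.rm = TRUE) / scale,
            1e-8)
})

test_that("disconnected fragments are excluded, not grounded", {
  nodes <- data.frame(id = 1:5, x = c(0, 10, 20, 50, 60), y = 0, z = 0,
                      kind = c("endpoint", "branch", "endpoint",
                               "endpoint", "endpoint"),
                      boundary = c("haversian", "none", "cement",
                                   "none", "none"))
  edges <- data.frame(id = 1:3, from = c(1, 2, 4), to = c(2, 3, 5),
                      length = c(10, 10, 10))
  net <- tiny_network(nodes, edges)
  sol <- solve_fixed_pressure(net, params)
  expect_setequal(sol$excluded_nodes, c(4, 5))
  expect_true(all(is.na(sol$node_pressure[c("4", "5")])))
  expect_true(is.na(sol$edge_flow[3]))
  expect_false(anyNA(sol$node_pressure[c("1", "2", "3")]))
})

test_that("zero-flow fallback when no cement node reaches the canal", {
  nodes <- data.frame(id = 1:2, x = c(0, 10), y = 0, z = 0,
                      kind = "endpoint", boundary = c("haversian", "none"))
  edges <- data.frame(id = 1, from = 1, to = 2, length = 10)
  net <- tiny_network(nodes, edges)
  expect_warning(sol <- solve_fixed_pressure(net, params), "no cement")
  expect_equal(max(abs(sol$edge_flow)), 0)
})

test_that("leaky cement line conserves mass and lowers pressure monotonically", {
  net <- generate_osteon(generator_params(seed = 8, osteon_radius = 60))
  s0 <- solve_strain_sources(net, params)
  l0 <- leaky_cement_variant(net, params, leak_fraction = 0)
  expect_equal(l0$node_pressure, s0$node_pressure, tolerance = 1e-12)

  fracs <- c(0.25, 0.5, 1)
  means <- mean(s0$node_pressure, na.rm = TRUE)
  for (fr in fracs) {
    sl <- leaky_cement_variant(net, params, leak_fraction = fr, seed = 5)
    expect_equal(sum(sl$boundary_flux), 0.015 * sl$applied$V_OLCN,
                 tolerance = 1e-9)
    expect_gt(sl$boundary_flux[["cement_leak"]], 0)
    means <- c(means, mean(sl$node_pressure, na.rm = TRUE))
  }
  expect_true(all(diff(means) < 0))
  expect_error(leaky_cement_variant(net, params, leak_fraction = 1.2), "leak_fraction")
})

test_that("leaky chain splits the flux between the two reservoirs", {
  net <- generate_chain(5, 10)
  sl <- leaky_cement_variant(net, params, leak_fraction = 1)
  expect_equal(sum(sl$boundary_flux), 0.015 * sl$applied$V_OLCN,
               tolerance = 1e-12)
  expect_gt(sl$boundary_flux[["cement_leak"]], 0)
  expect_gt(sl$boundary_flux[["haversian"]], 0)
})

test_that("Kirchhoff residuals vanish at solved nodes for both approaches", {
  for (seed in c(3, 14)) {
    net <- random_small_network(seed)
    for (ap in c("fixed_pressure", "strain_sources")) {
      sol <- lcn_flow(net, params, ap)
      res <- residuals(sol)
      # interior unknowns only: drop cement Dirichlet rows for approach 1
      if (ap == "fixed_pressure") {
        sysm <- sol$system
        cement_m <- unique(sysm$merged_of[net$nodes$boundary == "cement"])
        res <- res[!(setdiff(which(sysm$connected), sysm$i0) %in% cement_m)]
      }
      expect_lt(max(abs(res)), 1e-9 * max(abs(sol$edge_flow), na.rm = TRUE) + 1e-20)
    }
  }
})
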