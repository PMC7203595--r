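params <- hydraulic_params()

test_that("shear stress converts velocities with the right units", {
  expect_equal(shear_stress(1, params), 1.06e-3 * 465)
  expect_equal(shear_stress(0, params), 0)
  expect_equal(shear_stress(-2, params), shear_stress(2, params))
  # the 0.4 Pa osteogenic threshold maps back to ~0.81 um/s
  expect_equal(0.4 / (params$mu * params$shear_constant), 0.8115, tolerance = 1e-3)
})

test_that("intrinsic permeability hits k_p_eff on spokes and halves with tortuosity 2", {
  sp <- generate_spoke_osteon(40, 4)
  sol <- solve_fixed_pressure(sp, params)
  k <- intrinsic_permeability(sp, sol)
  expect_equal(k$k_osteon, params$k_p_eff, tolerance = 1e-9)

  # doubling arc lengths at the same radial span doubles resistance
  sp2 <- sp
  sp2$edges$length <- sp2$edges$length * 2
  k2 <- intrinsic_permeability(sp2, solve_fixed_pressure(sp2, params))
  expect_equal(k2$k_osteon, params$k_p_eff / 2, tolerance = 1e-9)

  # linear in nothing: k is invariant under rescaling the applied pressure
  k3 <- intrinsic_permeability(sp, solve_fixed_pressure(sp, params, delta_p = 39000))
  expect_equal(k3$k_osteon, k$k_osteon, tolerance = 1e-12)

  # tortuous networks can only fall below the single-canaliculus value
  net <- generate_osteon(generator_params(seed = 12, osteon_radius = 60))
  kn <- intrinsic_permeability(net, solve_fixed_pressure(net, params))
  expect_lte(kn$k_osteon, params$k_p_eff * (1 + 1e-9))
  expect_gte(kn$k_osteon, 0)
})

test_that("pressure profile reproduces lines and constants", {
  sp <- generate_spoke_osteon(30, 4)
  sol <- solve_fixed_pressure(sp, params)
  pr <- pressure_profile(sp, sol)
  # the exact solution is the linear reference profile
  expect_lt(max(abs(pr$pressure - 13000 * pr$distance)) / 13000, 1e-6)

  fake <- structure(list(node_pressure =
                           stats::setNames(rep(500, nrow(sp$nodes)),
                                           as.character(sp$nodes$id))),
                    class = "lcn_flow")
  prc <- pressure_profile(sp, fake)
  expect_equal(prc$pressure, rep(500, nrow(prc)))

  few <- generate_chain(3, 10)
  sfew <- solve_fixed_pressure(few, params)
  expect_error(pressure_profile(few, sfew), "at least 10")
})

test_that("sector heterogeneity matches direct arithmetic on the sector means", {
  # 36 nodes at sector centres: 35 sectors at pressure 1, one at 2
  ang <- 2 * pi * (0:35 + 0.5) / 36
  nodes <- data.frame(id = 1:36, x = 10 * cos(ang), y = 10 * sin(ang), z = 0,
                      kind = "branch", boundary = "none")
  nodes$boundary[1] <- "haversian"
  edges <- data.frame(id = 1:35, from = 1:35, to = 2:36, length = 5)
  net <- tiny_network(nodes, edges)
  p <- c(2, rep(1, 35))
  fake <- structure(list(node_pressure = stats::setNames(p, 1:36)),
                    class = "lcn_flow")
  h <- sector_heterogeneity(net, fake)
  m <- c(2, rep(1, 35))
  expect_equal(h$relative_sd, sqrt(mean((m - mean(m))^2)) / mean(m))
  expect_equal(h$relative_sd, 0.1600, tolerance = 1e-3)
  expect_equal(h$n_empty, 0)

  # uniform pressure field has zero heterogeneity
  fake0 <- structure(list(node_pressure = stats::setNames(rep(3, 36), 1:36)),
                     class = "lcn_flow")
  expect_equal(sector_heterogeneity(net, fake0)$relative_sd, 0)
})

test_that("sector statistics shift but do not change under rigid rotation", {
  net <- generate_osteon(generator_params(seed = 21, osteon_radius = 60))
  sol <- solve_strain_sources(net, params)
  h1 <- sector_heterogeneity(net, sol)
  rot <- 2 * pi * 5 / 36
  net2 <- net
  net2$nodes$x <- cos(rot) * net$nodes$x - sin(rot) * net$nodes$y
  net2$nodes$y <- sin(rot) * net$nodes$x + cos(rot) * net$nodes$y
  sol2 <- solve_strain_sources(net2, params)
  h2 <- sector_heterogeneity(net2, sol2)
  expect_equal(h2$relative_sd, h1$relative_sd, tolerance = 1e-9)
  expect_equal(unname(h2$sector_means),
               unname(h1$sector_means[c(32:36, 1:31)]), tolerance = 1e-9)
})

test_that("exceedance curves are monotone, bounded and step-like for ties", {
  # all canaliculi at one shear level: step function from 1 to 0
  sp <- generate_spoke_osteon(20, 4)
  sol <- solve_fixed_pressure(sp, params)
  ex <- exceedance_distribution(list(sol), params)
  tau0 <- shear_stress(abs(sol$edge_velocity[1]), params)
  expect_equal(ex$mean[ex$tau < tau0 * 0.999], rep(1, sum(ex$tau < tau0 * 0.999)))
  expect_equal(ex$mean[ex$tau > tau0 * 1.001], rep(0, sum(ex$tau > tau0 * 1.001)))
  expect_true(all(diff(ex$mean) <= 1e-12))
  expect_true(all(ex$mean >= 0 & ex$mean <= 1))
})

test_that("rescaling the strain rate rescales the shear distribution exactly", {
  net <- generate_osteon(generator_params(seed = 31, osteon_radius = 60))
  s1 <- solve_strain_sources(net, params, strain_rate = 0.015)
  s2 <- solve_strain_sources(net, params, strain_rate = 0.0015)
  t1 <- shear_stress(abs(s1$edge_velocity), params)
  t2 <- shear_stress(abs(s2$edge_velocity), params)
  expect_equal(t2, t1 / 10, tolerance = 1e-12)
  # hence the exceedance curve maps tau -> tau/10 on matched grids, up to
  # single-atom flips where a threshold lands within roundoff of a shear atom
  grid <- seq(0, 0.98 * max(t1), length.out = 150)
  e1 <- exceedance_distribution(list(s1), params, tau_grid = grid)
  e2 <- exceedance_distribution(list(s2), params, tau_grid = grid / 10)
  expect_lt(max(abs(e2$mean - e1$mean)), 3 / length(t1))
})

test_that("the intersection of two exceedance curves is located by bisection", {
  # two synthetic shear populations crossing at a known threshold
  mk <- function(v) {
    structure(list(edge_velocity = v,
                   network = list(edges = data.frame(length = rep(1, length(v)))),
                   params = params), class = "lcn_flow")
  }
  # group a: uniform 0..2; group b: uniform 1..1.5 (in velocity units)
  va <- seq(0.001, 2, length.out = 400)
  vb <- seq(1, 1.5, length.out = 400)
  grid <- seq(0, shear_stress(2, params), length.out = 400)
  ea <- exceedance_distribution(list(mk(va)), params, tau_grid = grid)
  eb <- exceedance_distribution(list(mk(vb)), params, tau_grid = grid)
  x <- exceedance_intersection(ea, eb)
  # crossing where 1 - v/2 = (1.5 - v)/0.5 -> v = 4/3
  expect_equal(x, shear_stress(4 / 3, params), tolerance = 0.02 * x)
})

test_that("velocities are higher near the canal than near the cement line", {
  # spoke under fixed pressure: both halves identical
  sp <- generate_spoke_osteon(20, 4)
  vh <- velocity_by_half(sp, solve_fixed_pressure(sp, params))
  expect_equal(unname(vh["hc_half"]), unname(vh["cl_half"]), tolerance = 1e-9)

  # chain under strain sources: flow accumulates toward the canal
  ch <- generate_chain(10, 10)
  vch <- velocity_by_half(ch, solve_strain_sources(ch, params))
  expect_gt(vch[["hc_half"]], vch[["cl_half"]])

  # and the same holds on default synthetic osteons for both approaches
  net <- generate_osteon(generator_params(seed = 23, osteon_radius = 70))
  for (ap in c("fixed_pressure", "strain_sources")) {
    v <- velocity_by_half(net, lcn_flow(net, params, ap))
    expect_gt(v[["hc_half"]], v[["cl_half"]])
  }
})

test_that("velocity-pathlength relations have the expected signs", {
  # fixed pressure on spokes of growing tortuosity: v ~ 1/SPL
  torts <- c(1, 1.25, 1.5, 1.75, 2)
  spl <- vbar1 <- numeric(0)
  for (tf in torts) {
    sp <- generate_spoke_osteon(15, 4)
    sp$edges$length <- sp$edges$length * tf
    sol <- solve_fixed_pressure(sp, params)
    spl <- c(spl, structural_summary(sp)$mean_shortest_path_to_canal)
    vbar1 <- c(vbar1, mean_velocity(sol))
  }
  r1 <- velocity_pathlength_relation(spl, vbar1, "fixed_pressure")
  expect_gt(r1$coefficients[["x"]], 0)      # v rises with 1/SPL
  expect_gt(r1$correlation, 0.99)

  # strain sources on chains of growing length: v ~ SPL with ~zero intercept
  ns <- c(4, 8, 12, 16, 20)
  spl2 <- vbar2 <- numeric(0)
  for (n in ns) {
    ch <- generate_chain(n, 10)
    sol <- solve_strain_sources(ch, params)
    spl2 <- c(spl2, structural_summary(ch)$mean_shortest_path_to_canal)
    vbar2 <- c(vbar2, mean_velocity(sol))
  }
  r2 <- velocity_pathlength_relation(spl2, vbar2, "strain_sources")
  expect_gt(r2$coefficients[["x"]], 0)
  expect_gt(r2$correlation, 0.999)
  expect_lt(abs(r2$coefficients[["(Intercept)"]]),
            0.05 * max(vbar2))

  # shuffled pairing destroys the correlation
  set.seed(42)
  shuffled <- velocity_pathlength_relation(spl2, sample(vbar2), "strain_sources")
  expect_lt(abs(shuffled$correlation), 0.95)
  expect_error(velocity_pathlength_relation(c(1, 1, 1, 1), 1:4), "degenerate")
  expect_error(velocity_pathlength_relation(1:3, 1:3), "at least 4")
})

test_that("rank-sum comparison is exact and matches permutation enumeration", {
  # identical groups: exact two-sided p = 1
  expect_equal(compare_groups(1:4, 1:4)$p_value, 1, tolerance = 0.05)

  # fully separated 8 vs 9: the extreme tail has probability 2/C(17,8)
  a <- 1:8; b <- 100 + 1:9
  expect_equal(compare_groups(a, b)$p_value, 2 / choose(17, 8),
               tolerance = 1e-12)

  # random configurations cross-checked against full permutation enumeration
  set.seed(3)
  for (rep in 1:5) {
    x <- sample(100, 4); y <- sample(200, 4) + 0.5
    expect_equal(compare_groups(x, y)$p_value, perm_ranksum_p(x, y),
                 tolerance = 1e-12)
  }
  expect_error(compare_groups(1, 1:3), "at least 2")
})
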