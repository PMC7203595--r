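#' Length-weighted mean canalicular speed
#'
#' `v_bar = sum(|v_j| * l_j) / sum(l_j)` over all canaliculi with a solved
#' flow. Absolute velocities are used so antiparallel canaliculi do not
#' cancel.
#'
#' @param solution An [lcn_flow()] solution.
#' @param weighting `"length"` (default) or `"count"` (plain mean).
#' @return Mean speed in um/s.
#' @export
mean_velocity <- function(solution, weighting = c("length", "count")) {
  weighting <- match.arg(weighting)
  v <- abs(solution$edge_velocity)
  ok <- !is.na(v)
  if (weighting == "length") {
    w <- solution$network$edges$length
    sum(v[ok] * w[ok]) / sum(w[ok])
  } else mean(v[ok])
}

#' Intrinsic permeability of an osteon
#'
#' Darcy permeability of the osteon as a whole, inferred from the
#' fixed-pressure solve: `k_osteon = v_bar * mu * delta_R / delta_p`, with
#' `v_bar` the length-weighted mean speed and `delta_R` the osteon wall
#' thickness (`On.Rd - HCa.Rd`). Network connectivity and canalicular
#' tortuosity can only increase flow resistance, so `k_osteon <= k_p_eff`,
#' with equality for straight radial spokes of tortuosity 1.
#'
#' @param net The solved `osteon_network`.
#' @param solution The corresponding approach-1 (`fixed_pressure`) solution.
#' @param delta_p Applied pressure, Pa; defaults to the one stored in the
#'   solution.
#' @param delta_r Wall thickness, um; defaults to `On.Rd - HCa.Rd` from the
#'   network metadata.
#' @return An object of class `permeability_result` with fields
#'   `mean_velocity` (um/s), `wall_thickness` (um), `applied_pressure` (Pa)
#'   and `k_osteon` (m^2).
#' @export
intrinsic_permeability <- function(net, solution,
                                   delta_p = solution$applied$delta_p_osteon,
                                   delta_r = NULL) {
  if (solution$approach != "fixed_pressure")
    warning("intrinsic permeability is defined for the fixed-pressure approach")
  if (is.null(delta_p) || delta_p == 0)
    stop("delta_p must be nonzero")
  if (is.null(delta_r)) {
    md <- net$metadata
    delta_r <- md$osteon_radius - md$haversian_radius
  }
  vbar <- mean_velocity(solution, "length")
  # v in um/s, mu in Pa s, delta_R in um -> k in m^2 via 1 um = 1e-6 m
  k <- (vbar * 1e-6) * solution$params$mu * (delta_r * 1e-6) / delta_p
  structure(list(mean_velocity = vbar, wall_thickness = delta_r,
                 applied_pressure = delta_p, k_osteon = k),
            class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat("Intrinsic osteon permeability\n")
  cat(sprintf("  mean velocity (length-weighted): %.4g um/s\n", x$mean_velocity))
  cat(sprintf("  wall thickness: %.4g um at %.4g Pa\n",
              x$wall_thickness, x$applied_pressure))
  cat(sprintf("  k_osteon: %.4g m^2\n", x$k_osteon))
  invisible(x)
}

#' Smoothed radial pressure profile
#'
#' Maps every solved node to its normalized distance from the Haversian canal
#' (0) to the cement line (1) and fits a LOWESS curve (tricube-weighted local
#' linear regression over the nearest `span` fraction of points) evaluated on
#' a uniform grid.
#'
#' @param net The solved `osteon_network`.
#' @param solution An [lcn_flow()] solution on `net`.
#' @param span Fraction of points in each local window (default 0.10).
#' @param grid_n Number of evaluation points on `[0, 1]`.
#' @return data.frame with columns `distance` and `pressure` (Pa).
#' @export
pressure_profile <- function(net, solution, span = 0.10, grid_n = 101) {
  d <- normalized_distance(net)
  p <- solution$node_pressure
  ok <- !is.na(p)
  if (sum(ok) < 10) stop("need at least 10 solved nodes for a profile")
  d <- d[ok]; p <- p[ok]
  grid <- seq(0, 1, length.out = grid_n)
  data.frame(distance = grid, pressure = lowess_grid(d, p, grid, span))
}

# LOWESS evaluated on a grid: tricube-weighted degree-1 local regression over
# the nearest span-fraction of points, no robustness iterations. Implemented
# directly (rather than via predict on a fitted smoother) so that heavily tied
# abscissae - e.g. nodes at discrete radii - stay well-conditioned: when the
# local window has no x-spread the fit falls back to the weighted mean.
lowess_grid <- function(x, y, grid, span = 0.10) {
  n <- length(x)
  k <- max(2L, ceiling(span * n))
  vapply(grid, function(g) {
    dist <- abs(x - g)
    h <- sort(dist, partial = k)[k]
    if (h == 0) h <- max(dist) / n
    if (h == 0) return(mean(y))
    xrange <- diff(range(x))
    # widen the window until the weighted x-spread identifies the local
    # slope; needed when x is heavily tied (e.g. nodes at discrete radii)
    for (it in 1:12) {
      w <- (1 - pmin(1, dist / h)^3)^3
      if (sum(w) <= 0) w <- as.numeric(dist <= h)
      sw <- sum(w)
      mx <- sum(w * x) / sw
      sxx <- sum(w * (x - mx)^2)
      if (sxx / sw >= (0.05 * h)^2 || h >= xrange) break
      h <- 1.5 * h
    }
    my <- sum(w * y) / sw
    beta <- if (sxx > 1e-10 * sw * h^2) sum(w * (x - mx) * (y - my)) / sxx else 0
    my + beta * (g - mx)
  }, numeric(1))
}

#' Angular heterogeneity of the pressure field
#'
#' Subdivides the osteon into `n_sectors` equal angular sectors around the
#' canal centre, averages node pressure per sector, and reports the relative
#' standard deviation of the sector means (population standard deviation over
#' mean). Empty sectors are excluded and counted.
#'
#' @param net The solved `osteon_network`.
#' @param solution An [lcn_flow()] solution on `net`.
#' @param n_sectors Number of sectors (default 36).
#' @return List with `relative_sd`, `sector_means` and `n_empty`.
#' @export
sector_heterogeneity <- function(net, solution, n_sectors = 36) {
  sec <- sector_partition(net, n_sectors)
  p <- solution$node_pressure
  ok <- !is.na(p)
  means <- tapply(p[ok], factor(sec[ok], levels = 0:(n_sectors - 1)), mean)
  n_empty <- sum(is.na(means))
  m <- means[!is.na(means)]
  if (!length(m)) stop("all sectors are empty")
  mu <- mean(m)
  sd_pop <- sqrt(mean((m - mu)^2))
  list(relative_sd = if (mu == 0) 0 else sd_pop / abs(mu),
       sector_means = means, n_empty = n_empty)
}

#' Cumulative shear-stress exceedance distribution
#'
#' For each osteon, the fraction of canaliculi whose cell-process wall shear
#' stress exceeds each threshold on a common grid; across osteons the mean
#' curve and a t-based confidence band of the mean are reported. The curves
#' answer: what percentage of canaliculi is stimulated above a given shear
#' stress?
#'
#' @param solutions A list of [lcn_flow()] solutions (one per osteon).
#' @param params A [hydraulic_params()] object.
#' @param weighting `"count"` (fraction of canaliculi, default) or `"length"`
#'   (length-weighted fraction).
#' @param tau_grid Thresholds in Pa; defaults to 200 points spanning the
#'   observed range.
#' @param conf Confidence level for the band (default 0.99).
#' @return An object of class `shear_exceedance`: list with `tau`, `mean`,
#'   `lower`, `upper` and the per-osteon matrix `curves`.
#' @export
exceedance_distribution <- function(solutions, params = hydraulic_params(),
                                    weighting = c("count", "length"),
                                    tau_grid = NULL, conf = 0.99) {
  weighting <- match.arg(weighting)
  if (!length(solutions)) stop("need at least one solution")
  if (inherits(solutions, "lcn_flow")) solutions <- list(solutions)
  taus <- lapply(solutions, function(s) {
    v <- abs(s$edge_velocity); v <- v[!is.na(v)]
    shear_stress(v, params)
  })
  if (is.null(tau_grid)) {
    hi <- max(unlist(lapply(taus, max)), 1e-12)
    tau_grid <- seq(0, hi, length.out = 200)
  }
  curves <- vapply(seq_along(solutions), function(i) {
    tt <- taus[[i]]
    if (weighting == "length") {
      w <- solutions[[i]]$network$edges$length
      w <- w[!is.na(solutions[[i]]$edge_velocity)]
      vapply(tau_grid, function(x) sum(w[tt > x]) / sum(w), numeric(1))
    } else {
      vapply(tau_grid, function(x) mean(tt > x), numeric(1))
    }
  }, numeric(length(tau_grid)))
  curves <- matrix(curves, nrow = length(tau_grid))
  mu <- rowMeans(curves)
  n <- ncol(curves)
  if (n > 1) {
    se <- apply(curves, 1, stats::sd) / sqrt(n)
    tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
    lower <- pmax(0, mu - tq * se); upper <- pmin(1, mu + tq * se)
  } else {
    lower <- upper <- mu
  }
  structure(list(tau = tau_grid, mean = mu, lower = lower, upper = upper,
                 curves = curves, weighting = weighting, conf = conf),
            class = "shear_exceedance")
}

#' @export
plot.shear_exceedance <- function(x, add = FALSE, col = "blue3", ...) {
  if (!add)
    graphics::plot(x$tau, 100 * x$mean, type = "n", ylim = c(0, 100),
                   xlab = "shear stress threshold (Pa)",
                   ylab = "canaliculi above threshold (%)", ...)
  graphics::polygon(c(x$tau, rev(x$tau)), 100 * c(x$lower, rev(x$upper)),
                    col = grDevices::adjustcolor(col, 0.2), border = NA)
  graphics::lines(x$tau, 100 * x$mean, col = col, lwd = 2)
  invisible(x)
}

#' Threshold at which two exceedance curves intersect
#'
#' Locates, by bisection on the interpolated difference of the two mean
#' curves, the shear-stress threshold where the curves cross.
#'
#' @param a,b `shear_exceedance` objects on comparable grids.
#' @return Shear stress in Pa, or `NA` if the curves do not cross.
#' @export
exceedance_intersection <- function(a, b) {
  lo <- max(min(a$tau), min(b$tau)); hi <- min(max(a$tau), max(b$tau))
  fa <- stats::approxfun(a$tau, a$mean, rule = 2)
  fb <- stats::approxfun(b$tau, b$mean, rule = 2)
  dfun <- function(x) fa(x) - fb(x)
  grid <- seq(lo, hi, length.out = 512)
  dv <- dfun(grid)
  sw <- which(dv[-1] * dv[-length(dv)] < 0)
  if (!length(sw)) return(NA_real_)
  stats::uniroot(dfun, c(grid[sw[1]], grid[sw[1] + 1]), tol = 1e-10)$root
}

#' Mean speeds in the inner and outer osteon halves
#'
#' Splits canaliculi by the normalized distance of their midpoint (< 0.5 means
#' the half close to the Haversian canal) and reports the length-weighted mean
#' absolute velocity in each half.
#'
#' @param net The solved `osteon_network`.
#' @param solution An [lcn_flow()] solution on `net`.
#' @return Named numeric vector `c(hc_half = ..., cl_half = ...)` in um/s.
#' @export
velocity_by_half <- function(net, solution) {
  nodes <- net$nodes; edges <- net$edges
  fi <- match(edges$from, nodes$id); ti <- match(edges$to, nodes$id)
  md <- net$metadata
  mx <- (nodes$x[fi] + nodes$x[ti]) / 2 - md$center[1]
  my <- (nodes$y[fi] + nodes$y[ti]) / 2 - md$center[2]
  nd <- (sqrt(mx^2 + my^2) - md$haversian_radius) /
    (md$osteon_radius - md$haversian_radius)
  v <- abs(solution$edge_velocity); w <- edges$length
  ok <- !is.na(v)
  wm <- function(sel) {
    sel <- sel & ok
    if (!any(sel)) return(NA_real_)
    sum(v[sel] * w[sel]) / sum(w[sel])
  }
  c(hc_half = wm(nd < 0.5), cl_half = wm(nd >= 0.5))
}

#' Relation between mean velocity and shortest path length
#'
#' Fits the velocity/structure relationship across a cohort of osteons: under
#' the fixed-pressure approach the mean velocity is inversely related to the
#' mean shortest path length to the canal (`v = a / SPL`); under strain-driven
#' flow it is linearly related (`v = a * SPL + b`). Simple least squares.
#'
#' @param spl Numeric vector of mean shortest path lengths, um (one per
#'   osteon).
#' @param vbar Numeric vector of mean speeds, um/s, matching `spl`.
#' @param approach `"fixed_pressure"` or `"strain_sources"`.
#' @return List with the fitted `lm` object, `coefficients`, and `correlation`
#'   (Pearson r between `vbar` and the transformed predictor).
#' @export
velocity_pathlength_relation <- function(spl, vbar,
                                         approach = c("fixed_pressure",
                                                      "strain_sources")) {
  approach <- match.arg(approach)
  if (length(spl) < 4) stop("need at least 4 osteons per approach")
  if (stats::sd(spl) == 0) stop("degenerate cohort: constant shortest path length")
  if (approach == "fixed_pressure") {
    x <- 1 / spl
    fit <- stats::lm(vbar ~ x)
  } else {
    x <- spl
    fit <- stats::lm(vbar ~ x)
  }
  list(fit = fit, coefficients = stats::coef(fit),
       correlation = stats::cor(vbar, x),
       approach = approach)
}

#' Two-group rank-sum comparison
#'
#' Two-tailed Wilcoxon rank-sum test between two osteon groups, exact for
#' small samples without ties, with mean and standard deviation descriptives.
#'
#' @param values_a,values_b Numeric vectors (each of length >= 2).
#' @return List with `p_value`, `mean_a`, `sd_a`, `mean_b`, `sd_b` and the
#'   underlying `htest` object.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 values")
  ht <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  list(p_value = ht$p.value,
       mean_a = mean(values_a), sd_a = stats::sd(values_a),
       mean_b = mean(values_b), sd_b = stats::sd(values_b),
       test = ht)
}
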