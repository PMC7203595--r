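#' Configuration for the generate-solve-analyze pipeline
#'
#' Describes a reproducible cohort run: how many synthetic osteons of each
#' type, the generator and hydraulic parameter overrides, the
#' boundary-condition approaches and strain rates, and a global seed that
#' fans out deterministically to per-osteon child seeds.
#'
#' @param n_ordinary,n_osteon_in_osteon Cohort sizes (defaults 8 and 9).
#' @param ordinary_params,oio_params Optional [generator_params()] overrides
#'   per type (their `seed` is replaced by the derived child seed).
#' @param hydraulic A [hydraulic_params()] object.
#' @param approaches Character vector of approaches to run.
#' @param strain_rates Strain rates (1/s) for the strain-source approach;
#'   defaults to exercise (0.015) and walking (0.0015).
#' @param delta_p Applied pressure for the fixed-pressure approach, Pa.
#' @param network_paths Optional character vector of LCN-JSON files to analyze
#'   instead of generating networks (their group is taken from the stored
#'   `osteon_type`).
#' @param output_dir Optional directory for artifacts (networks, solutions,
#'   report, manifest).
#' @param seed Global integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_ordinary = 8, n_osteon_in_osteon = 9,
                       ordinary_params = NULL, oio_params = NULL,
                       hydraulic = hydraulic_params(),
                       approaches = c("fixed_pressure", "strain_sources"),
                       strain_rates = c(0.015, 0.0015),
                       delta_p = 13000,
                       network_paths = NULL,
                       output_dir = NULL, seed = 1L) {
  if (!length(approaches)) stop("at least one approach is required")
  approaches <- match.arg(approaches, several.ok = TRUE)
  if (any(strain_rates <= 0)) stop("strain rates must be positive")
  structure(list(n_ordinary = n_ordinary,
                 n_osteon_in_osteon = n_osteon_in_osteon,
                 ordinary_params = ordinary_params, oio_params = oio_params,
                 hydraulic = hydraulic, approaches = approaches,
                 strain_rates = strain_rates, delta_p = delta_p,
                 network_paths = network_paths,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

pipeline_networks <- function(config) {
  if (!is.null(config$network_paths)) {
    nets <- lapply(config$network_paths, read_lcn_json)
  } else {
    specs <- c(rep("ordinary", config$n_ordinary),
               rep("osteon_in_osteon", config$n_osteon_in_osteon))
    nets <- vector("list", length(specs))
    for (i in seq_along(specs)) {
      base <- if (specs[i] == "ordinary") config$ordinary_params else
        config$oio_params
      if (is.null(base)) base <- generator_params(specs[i])
      base$seed <- child_seed(config$seed, i)
      nets[[i]] <- tryCatch(generate_osteon(base),
                            error = function(e)
                              stop(sprintf("stage 'generate' failed for osteon %d (%s): %s",
                                           i, specs[i], conditionMessage(e)),
                                   call. = FALSE))
    }
  }
  nets
}

#' Run the full generate-solve-analyze pipeline
#'
#' Generates (or loads) the osteon cohort, solves every requested
#' boundary-condition approach on every osteon, and assembles the analysis
#' report: structural summaries, per-osteon mean velocities and intrinsic
#' permeabilities, sector heterogeneity, velocity/path-length relations,
#' group rank-sum comparisons and shear-exceedance distributions at each
#' strain rate. Deterministic given the seed; artifacts are written when
#' `output_dir` is set.
#'
#' @param config A [run_config()] object.
#' @return An object of class `analysis_report` (a nested list; see fields
#'   `structure`, `per_osteon`, `comparisons`, `exceedance`, `relations`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  nets <- pipeline_networks(config)
  group <- vapply(nets, function(n) n$metadata$osteon_type, character(1))
  hp <- config$hydraulic

  summaries <- lapply(nets, structural_summary)
  spl <- vapply(summaries, function(s) s$mean_shortest_path_to_canal, numeric(1))

  per <- data.frame(osteon = seq_along(nets), group = group,
                    mean_spl = spl,
                    can_dn = vapply(summaries, function(s)
                      s$canalicular_length_density, numeric(1)),
                    node_degree = vapply(summaries, function(s)
                      s$mean_node_degree, numeric(1)))
  solutions <- list(); exceed <- list()

  solve_stage <- function(fun, label) {
    lapply(seq_along(nets), function(i)
      tryCatch(fun(i),
               error = function(e)
                 stop(sprintf("stage 'solve/%s' failed for osteon %d: %s",
                              label, i, conditionMessage(e)), call. = FALSE)))
  }
  if ("fixed_pressure" %in% config$approaches) {
    sols <- solve_stage(function(i)
      solve_fixed_pressure(nets[[i]], hp, delta_p = config$delta_p), "fixed_pressure")
    solutions$fixed_pressure <- sols
    per$vbar_a1 <- vapply(sols, mean_velocity, numeric(1))
    per$k_osteon <- vapply(seq_along(sols), function(i)
      intrinsic_permeability(nets[[i]], sols[[i]])$k_osteon, numeric(1))
    per$het_a1 <- vapply(seq_along(sols), function(i)
      sector_heterogeneity(nets[[i]], sols[[i]])$relative_sd, numeric(1))
  }
  if ("strain_sources" %in% config$approaches) {
    rate1 <- config$strain_rates[1]
    sols <- solve_stage(function(i)
      solve_strain_sources(nets[[i]], hp, strain_rate = rate1), "strain_sources")
    solutions$strain_sources <- sols
    per$vbar_a2 <- vapply(sols, mean_velocity, numeric(1))
    per$het_a2 <- vapply(seq_along(sols), function(i)
      sector_heterogeneity(nets[[i]], sols[[i]])$relative_sd, numeric(1))
    per$mean_pressure_a2 <- vapply(sols, function(s)
      mean(s$node_pressure, na.rm = TRUE), numeric(1))
    for (rate in config$strain_rates) {
      sols_r <- if (rate == rate1) sols else
        solve_stage(function(i)
          solve_strain_sources(nets[[i]], hp, strain_rate = rate),
          paste0("strain_sources@", rate))
      for (gr in unique(group)) {
        key <- sprintf("%s_rate_%g", gr, rate)
        exceed[[key]] <- exceedance_distribution(sols_r[group == gr], hp)
      }
    }
  }

  ord <- group == "ordinary"; oio <- group == "osteon_in_osteon"
  comparisons <- list()
  two_groups <- sum(ord) >= 2 && sum(oio) >= 2
  if (two_groups) {
    comparisons$mean_spl <- compare_groups(per$mean_spl[ord], per$mean_spl[oio])
    if (!is.null(per$vbar_a1))
      comparisons$vbar_a1 <- compare_groups(per$vbar_a1[ord], per$vbar_a1[oio])
    if (!is.null(per$vbar_a2))
      comparisons$vbar_a2 <- compare_groups(per$vbar_a2[ord], per$vbar_a2[oio])
    if (!is.null(per$k_osteon))
      comparisons$k_osteon <- compare_groups(per$k_osteon[ord], per$k_osteon[oio])
    if (!is.null(per$het_a1) && !is.null(per$het_a2))
      comparisons$heterogeneity_a2_vs_a1 <-
        compare_groups(per$het_a2, per$het_a1)
  }

  relations <- list()
  if (!is.null(per$vbar_a1) && length(unique(per$mean_spl)) > 1 &&
        nrow(per) >= 4)
    relations$fixed_pressure <-
      velocity_pathlength_relation(per$mean_spl, per$vbar_a1, "fixed_pressure")
  if (!is.null(per$vbar_a2) && length(unique(per$mean_spl)) > 1 &&
        nrow(per) >= 4)
    relations$strain_sources <-
      velocity_pathlength_relation(per$mean_spl, per$vbar_a2, "strain_sources")

  report <- structure(list(config = config, per_osteon = per,
                           structure = summaries,
                           comparisons = comparisons,
                           exceedance = exceed,
                           relations = relations,
                           networks = nets, solutions = solutions),
                      class = "analysis_report")
  if (!is.null(config$output_dir)) write_report_artifacts(report)
  report
}

write_report_artifacts <- function(report) {
  dir <- report$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nets <- report$networks
  for (i in seq_along(nets)) {
    sol <- report$solutions[[1]][[i]]
    write_lcn_json(nets[[i]],
                   file.path(dir, sprintf("osteon_%02d.json", i)),
                   solution = sol)
  }
  utils::write.csv(report$per_osteon, file.path(dir, "per_osteon.csv"),
                   row.names = FALSE)
  comp <- lapply(report$comparisons, function(cc)
    cc[c("p_value", "mean_a", "sd_a", "mean_b", "sd_b")])
  jsonlite::write_json(list(
    seed = report$config$seed,
    software = as.character(utils::packageVersion("lcnflow")),
    approaches = report$config$approaches,
    strain_rates = report$config$strain_rates,
    comparisons = comp), file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  per <- x$per_osteon
  cat(sprintf("LCN flow analysis report: %d osteons (%s)\n", nrow(per),
              paste(sprintf("%d %s", table(per$group),
                            names(table(per$group))), collapse = ", ")))
  agg <- stats::aggregate(per[, setdiff(names(per), c("osteon", "group")),
                              drop = FALSE],
                          by = list(group = per$group), FUN = mean)
  print(agg, digits = 4)
  if (length(x$comparisons)) {
    cat("Rank-sum comparisons (p-values):\n")
    for (nm in names(x$comparisons))
      cat(sprintf("  %-24s p = %.3g\n", nm, x$comparisons[[nm]]$p_value))
  }
  invisible(x)
}
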