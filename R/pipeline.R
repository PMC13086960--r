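# Pipeline configuration and the staged build -> compose -> synthetic ->
# metrics -> kinetics -> pmf driver. Every stochastic stage receives a
# seed derived from the single global seed, so (config, seed) determines
# every numeric output.

.CONFIG_KEYS <- c("stages", "seed", "outdir", "lattice", "pore",
                  "functionalization", "solution", "synthetic", "region",
                  "kinetics", "pmf", "log_level")
.STAGES <- c("build", "pore", "functionalize", "compose", "synth",
             "metrics", "kinetics", "pmf")

#' Pipeline run configuration
#'
#' Collects the stage selection and all stage specifications. Unknown
#' keys are rejected before any stage runs; the configuration round-trips
#' losslessly through YAML ([write_run_config()] / [read_run_config()]).
#'
#' @param stages character subset of
#'   `c("build", "pore", "functionalize", "compose", "synth", "metrics",
#'   "kinetics", "pmf")`.
#' @param seed global integer seed; per-stage seeds are derived from it.
#' @param outdir output directory.
#' @param lattice,pore,functionalization,solution argument lists for
#'   [lattice_spec()], [pore_spec()], [functionalization_spec()],
#'   [solution_spec()] (seeds are filled in from the global seed).
#' @param synthetic list with `A_true`, `prefactor_true`, `noise_sigma`,
#'   `t_end` (ns), `n_samples` for [simulate_penetration()].
#' @param region list with `radius`, `z_top`, `z_bottom` for
#'   [pore_region()] (axis defaults to the pore center).
#' @param kinetics reserved list of fit options.
#' @param pmf optional list with `profile` (path to a PMF table),
#'   `xi_surface`, `xi_bulk`, `xi_entrance`, `xi_inside`.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(stages = c("build", "pore", "compose", "synth",
                                  "metrics", "kinetics"),
                       seed = 1L, outdir = tempfile("waxpore_run_"),
                       lattice = list(layer_count = 4), pore = list(),
                       functionalization = NULL,
                       solution = list(), synthetic = list(),
                       region = list(radius = 0.975),
                       kinetics = list(), pmf = NULL,
                       log_level = c("info", "quiet")) {
  bad <- setdiff(stages, .STAGES)
  if (length(bad) > 0) stop("unknown stages: ", paste(bad, collapse = ", "))
  cfg <- list(stages = stages, seed = as.integer(seed), outdir = outdir,
              lattice = lattice, pore = pore,
              functionalization = functionalization, solution = solution,
              synthetic = synthetic, region = region, kinetics = kinetics,
              pmf = pmf, log_level = match.arg(log_level))
  validate_run_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg a list (e.g. parsed from YAML).
#' @return the validated `run_config`.
#' @export
validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  bad <- setdiff(cfg$stages, .STAGES)
  if (length(bad) > 0) stop("unknown stages: ", paste(bad, collapse = ", "))
  if (is.null(cfg$seed)) stop("configuration needs a global seed")
  structure(cfg, class = "run_config")
}

#' Write a run configuration as YAML
#'
#' @param cfg a [run_config()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path YAML path written by [write_run_config()] or by hand.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Run the staged pipeline
#'
#' Executes the selected stages in order: slab build, pore carving,
#' functionalization, solution composition, synthetic trajectory
#' generation, trajectory metrics, kinetics fitting, and PMF
#' post-processing. Each stage writes its artifacts under `outdir`; a
#' manifest lists every output with the configuration hash and the
#' derived per-stage seeds. Any stage failure aborts with the stage name.
#'
#' @param cfg a [run_config()] (or a list / YAML path coercible to one).
#' @return invisibly, the manifest list: `outputs` (files), `results`
#'   (named numeric summary), `config_hash`, `seeds`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (!inherits(cfg, "run_config")) cfg <- validate_run_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) {
    if (!identical(cfg$log_level, "quiet")) message("[waxpore] ", ...)
  }
  seeds <- stats::setNames(cfg$seed + seq_along(.STAGES) * 101L, .STAGES)

  outputs <- character(0)
  results <- list()
  model <- NULL
  traj <- NULL
  trace <- NULL
  pore_center <- NULL

  run_stage <- function(name, fn) {
    if (!(name %in% cfg$stages)) return(invisible(NULL))
    say("stage: ", name)
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  run_stage("build", function() {
    lat <- do.call(lattice_spec, cfg$lattice)
    model <<- build_crystal_slab(lattice = lat)
    results$n_chains <<- model$provenance$n_chains
  })

  run_stage("pore", function() {
    if (is.null(model)) stop("no slab built")
    ps <- do.call(pore_spec, cfg$pore)
    carved <- carve_pore(model, ps)
    model <<- carved$model
    pore_center <<- model$provenance$pore$center
    results$chains_removed_per_layer <<- carved$removed[1]
  })

  run_stage("functionalize", function() {
    if (is.null(cfg$functionalization)) stop("no functionalization spec given")
    fs <- do.call(functionalization_spec,
                  utils::modifyList(cfg$functionalization,
                                    list(seed = seeds[["functionalize"]])))
    model <<- functionalize_surface(model, fs)
    results$wax_charge <<- total_charge(model)
  })

  run_stage("compose", function() {
    ss <- do.call(solution_spec,
                  utils::modifyList(cfg$solution,
                                    list(seed = seeds[["compose"]])))
    out <- compose_solution(model, ss)
    model <<- out$model
    rep <- out$report
    results$n_surfactant_per_interface <<- rep$n_surfactant_per_interface
    results$n_ai <<- rep$n_ai
    results$n_water <<- rep$n_water
    results$realized_gamma <<- rep$realized_gamma
    results$net_charge <<- rep$net_charge
    p <- file.path(cfg$outdir, "composition_report.txt")
    writeLines(c(
      sprintf("n_surfactant_per_interface %d", rep$n_surfactant_per_interface),
      sprintf("n_ai %d", rep$n_ai),
      sprintf("n_water %d", rep$n_water),
      sprintf("realized_gamma %.6e", rep$realized_gamma),
      sprintf("realized_ai_concentration %.6f",
              rep$realized_ai_concentration %||% NA_real_),
      sprintf("net_charge %d", rep$net_charge)
    ), p)
    outputs <<- c(outputs, p)
  })

  if (!is.null(model)) {
    p <- file.path(cfg$outdir, "system.gro")
    write_gro(model, p)
    outputs <- c(outputs, p)
  }

  run_stage("synth", function() {
    sy <- cfg$synthetic
    truth <- kinetics_truth(
      A_true = sy$A_true %||% 0.02,
      prefactor_true = sy$prefactor_true %||% 3,
      noise_sigma = sy$noise_sigma %||% 0.05,
      seed = seeds[["synth"]]
    )
    times <- seq(0, sy$t_end %||% 200, length.out = sy$n_samples %||% 401)
    axis <- pore_center %||% c(3, 3)
    sim <- simulate_penetration(truth, times, axis = axis)
    traj <<- sim$trajectory
    p1 <- file.path(cfg$outdir, "synthetic.gro")
    write_trajectory(traj, p1)
    p2 <- file.path(cfg$outdir, "species_map.tsv")
    write_species_map(traj, p2)
    p3 <- file.path(cfg$outdir, "truth.txt")
    writeLines(c(sprintf("A_true %g", truth$A_true),
                 sprintf("prefactor_true %g", truth$prefactor_true),
                 sprintf("noise_sigma %g", truth$noise_sigma),
                 sprintf("seed %d", truth$seed)), p3)
    outputs <<- c(outputs, p1, p2, p3)
  })

  run_stage("metrics", function() {
    if (is.null(traj)) stop("no trajectory available")
    axis <- pore_center %||% c(3, 3)
    region <- pore_region(axis = axis,
                          radius = cfg$region$radius %||% 0.975,
                          z_top = cfg$region$z_top %||% 0,
                          z_bottom = cfg$region$z_bottom %||% -15)
    trace <<- penetration_trace(traj, "surfactant", region)
    p1 <- file.path(cfg$outdir, "trace.tsv")
    write_trace(trace, p1)
    dm <- density_scan(traj, plane = "side_view", bin_width = 0.2)
    p2 <- file.path(cfg$outdir, "density_side.tsv")
    write_density_map(dm, p2)
    outputs <<- c(outputs, p1, p2)
    results$final_depth <<- trace$depths[length(trace$depths)]
  })

  run_stage("kinetics", function() {
    if (is.null(trace)) stop("no penetration trace available")
    fit <- fit_penetration_rate(trace)
    results$A_fit <<- fit$A
    results$prefactor_fit <<- fit$prefactor
    p <- file.path(cfg$outdir, "uptake_fit.txt")
    writeLines(c(sprintf("A_per_ns %.8g", fit$A),
                 sprintf("prefactor_nm %.8g", fit$prefactor),
                 sprintf("residual_rms_nm %.8g", fit$residual_rms)), p)
    outputs <<- c(outputs, p)
  })

  run_stage("pmf", function() {
    if (is.null(cfg$pmf$profile)) stop("no PMF profile path given")
    prof <- read_pmf(cfg$pmf$profile)
    dg <- free_energy_difference(prof, cfg$pmf$xi_surface %||% 3.0,
                                 cfg$pmf$xi_bulk %||% 0.25)
    results$dG_ads <<- dg
    if (!is.null(cfg$pmf$xi_entrance)) {
      results$barrier <<- penetration_barrier(prof, cfg$pmf$xi_entrance,
                                              cfg$pmf$xi_inside %||% -3.0)
    }
  })

  cfg_path <- file.path(cfg$outdir, "config.yaml")
  write_run_config(cfg, cfg_path)
  manifest <- list(
    outputs = basename(outputs),
    results = results,
    config_hash = unname(tools::md5sum(cfg_path)),
    seeds = seeds
  )
  mpath <- file.path(cfg$outdir, "manifest.txt")
  writeLines(c(
    paste("config_hash", manifest$config_hash),
    paste("seed", cfg$seed),
    paste("outputs:", paste(manifest$outputs, collapse = " ")),
    vapply(names(results), function(k) {
      sprintf("%s %.10g", k, as.numeric(results[[k]]))
    }, "")
  ), mpath)
  say("manifest written to ", mpath)
  invisible(manifest)
}
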