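#' Experiment presets
#'
#' `"full"` mirrors the published input-versus-output sweep conditions
#' (20 x 20 x 20 um region, 2.5e6 growth nodes; several hours per phantom);
#' `"reduced"` (10 um region, 2e5 nodes) keeps the same morphological
#' targets at desk scale; `"mini"` (6 um region, 3e4 nodes) is sized for the
#' mechanism-ablation harness and test suites.
#'
#' @param name One of `"full"`, `"reduced"`, `"mini"`.
#' @return Named list of [growth_config()] arguments.
#' @export
experiment_preset <- function(name = c("reduced", "full", "mini")) {
  name <- match.arg(name)
  switch(name,
    full = list(region_size = c(20, 20, 20), n_nodes = 2.5e6),
    reduced = list(region_size = c(10, 10, 10), n_nodes = 2e5),
    mini = list(region_size = c(6, 6, 6), n_nodes = 3e4)
  )
}

#' Run the full pipeline: grow, mesh, measure
#'
#' Executes the three stages end-to-end and writes every artefact class:
#' skeleton CSVs, PLY meshes, a morphometry report and a JSON run manifest
#' that (together with the master seed) fully determines a rerun.
#'
#' @param config A [growth_config()] or a path to a YAML/JSON config.
#' @param output_dir Output directory.
#' @param mechanisms Mechanism set (see [grow_all()]); `"minimal"` disables
#'   collapse, the dynamic network, fasciculation and the global relaxation.
#' @param mesh Also mesh the phantom and write PLY files?
#' @param measure Also run morphometry (density, orientation stats)?
#' @param density_voxel Voxel for the density measurement (um).
#' @param verbose Progress output?
#' @return The run manifest (list), invisibly; artefacts are on disk.
#' @export
run_pipeline <- function(config, output_dir, mechanisms = "all", mesh = TRUE,
                         measure = TRUE, density_voxel = 0.1,
                         verbose = FALSE) {
  if (is.character(config)) config <- read_growth_config(config)
  mechanisms <- expand_mechanisms(mechanisms)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[3]
  phantom <- grow_all(config, mechanisms, verbose = verbose)
  t_grow <- proc.time()[3] - t0
  write_skeleton_csv(phantom, file.path(output_dir, "skeletons"))
  write_growth_config(config, file.path(output_dir, "config.yaml"))

  timings <- list(grow_s = unname(t_grow))
  morph <- NULL
  pm <- NULL
  if (mesh && any(phantom$fibres$status == "complete")) {
    t0 <- proc.time()[3]
    pm <- mesh_phantom(phantom, verbose = verbose)
    timings$mesh_s <- unname(proc.time()[3] - t0)
    write_ply(pm, file.path(output_dir, "meshes"))
  }
  if (measure) {
    t0 <- proc.time()[3]
    mean_r <- mean(unlist(lapply(phantom_skeletons(phantom),
                                 function(s) s[, 4])), na.rm = TRUE)
    segs <- phantom_segment_directions(
      phantom, smooth_window = if (is.finite(mean_r)) 3 * mean_r else NULL
    )
    stats <- if (!is.null(segs$directions) && nrow(segs$directions) > 1) {
      orientation_stats(segs$directions)
    } else {
      list(mu_theta = NA_real_, sigma_theta = NA_real_, n = 0L)
    }
    fvf_capsule <- capsule_density(phantom, voxel = density_voxel)
    morph <- list(
      fvf_capsule_central = fvf_capsule,
      mu_theta = stats$mu_theta,
      sigma_theta = stats$sigma_theta
    )
    if (!is.null(pm) && length(pm$meshes)) {
      L <- config$region_size
      half <- L * 0.75 / 2
      roi <- list(lo = L / 2 - half, hi = L / 2 + half)
      morph$fvf_mesh_central <- measure_density(pm, roi, voxel = density_voxel)
    }
    report <- tibble(metric = names(unlist(morph)), value = unlist(morph))
    utils::write.csv(as.data.frame(report),
                     file.path(output_dir, "morphometry.csv"),
                     row.names = FALSE)
    timings$measure_s <- unname(proc.time()[3] - t0)
  }
  gl <- glance(phantom)
  manifest <- list(
    config = file.path(output_dir, "config.yaml"),
    master_seed = config$master_seed,
    mechanisms = mechanisms,
    fibres = list(
      seeded = gl$n_seeded, complete = gl$n_complete, removed = gl$n_removed
    ),
    morphometry = morph,
    mesh_failures = if (!is.null(pm)) nrow(pm$failures) else NA_integer_,
    timings = timings
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, phantom = phantom, meshes = pm))
}

#' Input-versus-output morphology sweep (Watson dispersion)
#'
#' For each Watson concentration, grows a phantom at 75% target density with
#' all mechanisms, then measures the achieved density and angle-from-axis
#' statistics of the grown fibres; target statistics come from 10^4 Watson
#' samples at the same concentration. Run at `"full"` scale this reproduces
#' the published sweep conditions; the `"reduced"` preset keeps the same
#' targets at desk scale.
#'
#' @param kappas Watson concentrations to sweep.
#' @param preset `"full"`, `"reduced"` or `"mini"` (see
#'   [experiment_preset()]).
#' @param seed Master seed.
#' @param target_density Target fibre volume fraction.
#' @param n_target_samples Watson sample count for the target statistics.
#' @param verbose Progress output?
#' @return Tibble: kappa, input/target/output density and angle statistics,
#'   fibre counts.
#' @export
run_table2_experiment <- function(kappas = c(8, 10, 15, 20, 30, 50, 100),
                                  preset = "reduced", seed = 1,
                                  target_density = 0.75,
                                  n_target_samples = 1e4, verbose = FALSE) {
  ps <- experiment_preset(preset)
  rows <- list()
  for (k in kappas) {
    tgt_dirs <- sample_watson(k, c(0, 0, 1), n_target_samples,
                              seed = derive_seed(seed, round(1e3 + k)))
    tgt <- orientation_stats(tgt_dirs)
    cfg <- growth_config(
      region_size = ps$region_size, n_nodes = ps$n_nodes,
      target_density = target_density,
      dispersion_model = "watson", watson_kappa = k,
      master_seed = derive_seed(seed, round(k))
    )
    ph <- grow_all(cfg, mechanisms = "all", verbose = verbose)
    mean_r <- mean(unlist(lapply(phantom_skeletons(ph), function(s) s[, 4])))
    segs <- phantom_segment_directions(ph, smooth_window = 3 * mean_r)
    out_stats <- if (!is.null(segs$directions) && nrow(segs$directions) > 1) {
      orientation_stats(segs$directions)
    } else {
      list(mu_theta = NA_real_, sigma_theta = NA_real_)
    }
    rows[[length(rows) + 1]] <- tibble(
      kappa = k,
      input_density = target_density,
      output_density = capsule_density(ph),
      target_mu_theta = tgt$mu_theta,
      output_mu_theta = out_stats$mu_theta,
      target_sigma_theta = tgt$sigma_theta,
      output_sigma_theta = out_stats$sigma_theta,
      n_fibres = sum(ph$fibres$status == "complete")
    )
    if (verbose) message(sprintf("kappa %g done", k))
  }
  bind_rows(rows)
}

ablation_scenarios <- function() {
  list(
    parallel = list(
      target_density = 0.75, dispersion_model = "parallel",
      bundles = function() list(bundle_spec(1L, c(0, 0, 1)))
    ),
    watson8 = list(
      target_density = 0.75, dispersion_model = "watson", watson_kappa = 8,
      bundles = function() list(bundle_spec(1L, c(0, 0, 1)))
    ),
    crossing2 = list(
      target_density = 0.4, dispersion_model = "parallel",
      bundles = function() list(
        bundle_spec(1L, c(0, 0, 1)), bundle_spec(2L, c(1, 0, 0))
      )
    ),
    crossing3 = list(
      target_density = 0.3, dispersion_model = "parallel",
      bundles = function() list(
        bundle_spec(1L, c(0, 0, 1)), bundle_spec(2L, c(1, 0, 0)),
        bundle_spec(3L, c(0, 1, 0))
      )
    )
  )
}

#' Mechanism-ablation experiment
#'
#' Grows matched phantoms (same initial conditions per seed) under different
#' mechanism sets -- minimal (chemoattraction only), each mechanism alone,
#' and all together -- and reports the mean achieved density with its
#' standard error over seeds.
#'
#' @param scenarios Subset of `c("parallel", "watson8", "crossing2",
#'   "crossing3")` (single parallel bundle at 75%, Watson kappa 8 at 75%,
#'   two perpendicular bundles at 40% each, three mutually perpendicular at
#'   30% each).
#' @param mechanism_sets Named list of mechanism vectors; the default covers
#'   minimal, each single mechanism, and all.
#' @param seeds Master seeds (results averaged across them).
#' @param preset Scale preset (see [experiment_preset()]).
#' @param verbose Progress output?
#' @return Tibble: scenario, mechanism set, per-seed densities, mean and
#'   standard error (`sd / sqrt(n_seeds)`).
#' @export
run_ablation_experiment <- function(scenarios = "parallel",
                                    mechanism_sets = NULL,
                                    seeds = 1:3, preset = "mini",
                                    verbose = FALSE) {
  if (is.null(mechanism_sets)) {
    mechanism_sets <- list(
      minimal = character(0),
      collapse = "collapse",
      dynamic = "dynamic",
      fasciculation = "fasciculation",
      optimise = "optimise",
      all = c("collapse", "dynamic", "fasciculation", "optimise")
    )
  }
  ps <- experiment_preset(preset)
  scen_defs <- ablation_scenarios()
  rows <- list()
  for (sc in scenarios) {
    def <- scen_defs[[sc]]
    if (is.null(def)) abort(paste("unknown scenario:", sc))
    for (ms_name in names(mechanism_sets)) {
      dens <- numeric(0)
      for (sd_ in seeds) {
        cfg_args <- list(
          region_size = ps$region_size, n_nodes = ps$n_nodes,
          target_density = def$target_density,
          dispersion_model = def$dispersion_model,
          bundles = def$bundles(),
          master_seed = sd_
        )
        if (!is.null(def$watson_kappa)) cfg_args$watson_kappa <- def$watson_kappa
        cfg <- do.call(growth_config, cfg_args)
        ph <- grow_all(cfg, mechanisms = mechanism_sets[[ms_name]])
        dens <- c(dens, capsule_density(ph))
        if (verbose) {
          message(sprintf("%s / %s / seed %d: %.1f%%", sc, ms_name, sd_,
                          100 * tail(dens, 1)))
        }
      }
      rows[[length(rows) + 1]] <- tibble(
        scenario = sc, mechanisms = ms_name,
        densities = list(dens),
        mean_density = mean(dens),
        se_density = stats::sd(dens) / sqrt(length(dens)),
        n_seeds = length(dens)
      )
    }
  }
  bind_rows(rows)
}
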