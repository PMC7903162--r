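#' Bundle specification
#'
#' Describes one fibre bundle: its mean growth direction, the region face its
#' fibres start from, and optional per-bundle overrides of the global target
#' density and orientation-dispersion parameters.
#'
#' @param bundle_index Integer bundle identifier (unique within a phantom).
#' @param mean_direction Unit 3-vector, the bundle's mean growth direction.
#' @param entry_face Region face fibres start from, one of `"x-"`, `"x+"`,
#'   `"y-"`, `"y+"`, `"z-"`, `"z+"`. Defaults to the face whose inward normal
#'   best matches `mean_direction`.
#' @param density Per-bundle target fibre volume fraction; `NULL` inherits the
#'   global target.
#' @param dispersion Optional per-bundle dispersion override, a list with the
#'   same fields as the global dispersion settings (`model`, `kappa`,
#'   `esag_mu`, `esag_gamma`).
#'
#' @return A `bundle_spec` list.
#' @export
bundle_spec <- function(bundle_index, mean_direction, entry_face = NULL,
                        density = NULL, dispersion = NULL) {
  mean_direction <- as.numeric(mean_direction)
  if (length(mean_direction) != 3) abort("mean_direction must be a 3-vector")
  if (abs(vec3_norm(mean_direction) - 1) > 1e-9) {
    mean_direction <- unitize(mean_direction)
  }
  if (is.null(entry_face)) {
    ax <- which.max(abs(mean_direction))
    entry_face <- paste0(c("x", "y", "z")[ax], if (mean_direction[ax] >= 0) "-" else "+")
  }
  stopifnot(entry_face %in% c("x-", "x+", "y-", "y+", "z-", "z+"))
  structure(
    list(
      bundle_index = as.integer(bundle_index),
      mean_direction = mean_direction,
      entry_face = entry_face,
      density = density,
      dispersion = dispersion
    ),
    class = "bundle_spec"
  )
}

# Tested practical parameter ranges; values outside them warn but do not error.
practical_limits <- list(
  region_size = c(0, 50),
  target_density = c(0, 0.8),
  radius_mean = c(0.5, 2),
  radius_std = c(0.1, 0.5),
  watson_kappa = c(4, 100),
  esag_mu_norm = c(2, 10),
  n_nodes = c(0, 1e7),
  cost_weight = c(0, 0.5),
  collapse_initial = c(1, 5),
  collapse_increment = c(1, 5),
  n_added = c(0, 5000)
)

#' Growth configuration
#'
#' Collects every parameter governing phantom generation: the growth region,
#' the target morphology (density, radius distribution, orientation
#' dispersion), and the growth-algorithm parameters (node count, cost weight,
#' collapse schedule, dynamic-network size). Defaults follow the published
#' algorithm settings: cost weight `f = 0.2`, collapse schedule
#' `g0 = 2` um and `delta = 5` um with 5 escalations (maximum retreat 27 um),
#' and 2500 dynamically added nodes per grown fibre.
#'
#' @param region_size Region edge lengths in um (length-3, or scalar cube).
#' @param target_density Target fibre volume fraction in `[0, 1]`.
#' @param radius_mean,radius_std Mean and standard deviation of the fibre
#'   radius distribution (um); radii are gamma-distributed with these moments.
#' @param dispersion_model One of `"parallel"`, `"watson"`, `"esag"`.
#' @param watson_kappa Watson concentration (used when
#'   `dispersion_model = "watson"`).
#' @param esag_mu ESAG mean vector (its norm acts as concentration).
#' @param esag_gamma ESAG anisotropy 2-vector.
#' @param n_nodes Number of pseudorandom growth nodes.
#' @param cost_weight Weight `f` of the diameter cost against the direction
#'   cost.
#' @param collapse_initial,collapse_increment Initial retreat `g0` and
#'   per-escalation increment `delta` (um) of the fibre-collapse schedule.
#' @param collapse_max_attempts Number of retreat escalations beyond the
#'   first; with the defaults the retreat sequence is 2, 7, 12, 17, 22, 27 um.
#' @param n_added Nodes added around each completed fibre (dynamic network).
#' @param bundles List of [bundle_spec()] objects; default one bundle along z.
#' @param master_seed Integer master seed; all stage seeds derive from it.
#' @param node_padding Padding (um) added around the region when scattering
#'   growth nodes so boundary fibres are not starved of candidates; default
#'   `2 * radius_mean`.
#' @param track_radius Clearance tracking cutoff (um): nodes farther than this
#'   from every fibre surface keep an infinite sustainable diameter.
#' @param min_radius_frac Nodes offering less than this fraction of the target
#'   diameter are treated as inaccessible during growth.
#'
#' @return A `growth_config` object (a validated list).
#' @export
growth_config <- function(region_size = c(10, 10, 10),
                          target_density = 0.75,
                          radius_mean = 0.5,
                          radius_std = 0.1,
                          dispersion_model = c("parallel", "watson", "esag"),
                          watson_kappa = 8,
                          esag_mu = c(0, 0, 4),
                          esag_gamma = c(0, 0),
                          n_nodes = 2e5,
                          cost_weight = 0.2,
                          collapse_initial = 2,
                          collapse_increment = 5,
                          collapse_max_attempts = 5,
                          n_added = 2500,
                          bundles = NULL,
                          master_seed = 1L,
                          node_padding = NULL,
                          track_radius = 6,
                          min_radius_frac = 0.1) {
  dispersion_model <- match.arg(dispersion_model)
  if (length(region_size) == 1) region_size <- rep(region_size, 3)
  stopifnot(length(region_size) == 3, all(region_size > 0))
  if (target_density < 0 || target_density > 1) {
    abort("target_density must lie in [0, 1]")
  }
  if (radius_mean <= 0) abort("radius_mean must be positive")
  if (radius_std < 0) abort("radius_std must be non-negative")
  if (dispersion_model == "watson" && watson_kappa <= 0) {
    abort("watson_kappa must be positive")
  }
  if (dispersion_model == "esag" && vec3_norm(esag_mu) <= 0) {
    abort("esag_mu must be non-zero")
  }
  if (n_nodes < 4) abort("n_nodes must be at least 4")
  if (cost_weight < 0) abort("cost_weight must be non-negative")
  if (is.null(bundles)) {
    bundles <- list(bundle_spec(1L, c(0, 0, 1)))
  }
  idx <- vapply(bundles, function(b) b$bundle_index, integer(1))
  if (anyDuplicated(idx)) abort("bundle indices must be unique")
  if (is.null(node_padding)) node_padding <- 2 * radius_mean

  cfg <- structure(
    list(
      region_size = as.numeric(region_size),
      target_density = target_density,
      radius_mean = radius_mean,
      radius_std = radius_std,
      dispersion_model = dispersion_model,
      watson_kappa = watson_kappa,
      esag_mu = as.numeric(esag_mu),
      esag_gamma = as.numeric(esag_gamma),
      n_nodes = as.integer(n_nodes),
      cost_weight = cost_weight,
      collapse_initial = collapse_initial,
      collapse_increment = collapse_increment,
      collapse_max_attempts = as.integer(collapse_max_attempts),
      n_added = as.integer(n_added),
      bundles = bundles,
      master_seed = as.integer(master_seed),
      node_padding = node_padding,
      track_radius = track_radius,
      min_radius_frac = min_radius_frac
    ),
    class = "growth_config"
  )
  check_practical_limits(cfg)
  cfg
}

check_practical_limits <- function(cfg) {
  note <- function(name, value, range) {
    if (any(value < range[1] - 1e-12) || any(value > range[2] + 1e-12)) {
      warn(sprintf(
        "%s = %s is outside the tested practical range [%g, %g]",
        name, paste(signif(value, 4), collapse = ", "), range[1], range[2]
      ))
    }
  }
  note("region_size", cfg$region_size, practical_limits$region_size)
  note("target_density", cfg$target_density, practical_limits$target_density)
  note("radius_mean", cfg$radius_mean, practical_limits$radius_mean)
  note("radius_std", cfg$radius_std, practical_limits$radius_std)
  if (cfg$dispersion_model == "watson") {
    note("watson_kappa", cfg$watson_kappa, practical_limits$watson_kappa)
  }
  if (cfg$dispersion_model == "esag") {
    note("esag_mu norm", vec3_norm(cfg$esag_mu), practical_limits$esag_mu_norm)
  }
  note("n_nodes", as.double(cfg$n_nodes), practical_limits$n_nodes)
  note("cost_weight", cfg$cost_weight, practical_limits$cost_weight)
  note("collapse_initial", cfg$collapse_initial, practical_limits$collapse_initial)
  note("collapse_increment", cfg$collapse_increment, practical_limits$collapse_increment)
  note("n_added", as.double(cfg$n_added), practical_limits$n_added)
  invisible(cfg)
}

#' @export
print.growth_config <- function(x, ...) {
  cat("<growth_config>\n")
  cat(sprintf("  region: %s um, target density %.0f%%\n",
              paste(x$region_size, collapse = " x "), 100 * x$target_density))
  cat(sprintf("  radii: gamma(mean %.2f, sd %.2f) um\n", x$radius_mean, x$radius_std))
  disp <- switch(x$dispersion_model,
    parallel = "parallel",
    watson = sprintf("Watson (kappa = %g)", x$watson_kappa),
    esag = sprintf("ESAG (|mu| = %.2f, gamma = %s)", vec3_norm(x$esag_mu),
                   paste(signif(x$esag_gamma, 3), collapse = ", "))
  )
  cat(sprintf("  dispersion: %s; bundles: %d\n", disp, length(x$bundles)))
  cat(sprintf("  network: %d nodes (+%d per fibre), f = %g, seed %d\n",
              x$n_nodes, x$n_added, x$cost_weight, x$master_seed))
  invisible(x)
}

#' Read a growth configuration from YAML or JSON
#'
#' Field names mirror the arguments of [growth_config()] exactly; bundles are
#' given as a list of records with `bundle_index`, `mean_direction` and the
#' optional overrides of [bundle_spec()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param ... Overrides applied on top of the file contents.
#' @return A `growth_config` object.
#' @export
read_growth_config <- function(path, ...) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  over <- list(...)
  raw[names(over)] <- over
  if (!is.null(raw$bundles) && !inherits(raw$bundles[[1]], "bundle_spec")) {
    raw$bundles <- lapply(raw$bundles, function(b) {
      do.call(bundle_spec, b)
    })
  }
  do.call(growth_config, raw)
}

#' Write a growth configuration to YAML
#'
#' @param config A `growth_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_growth_config <- function(config, path) {
  x <- unclass(config)
  x$bundles <- lapply(x$bundles, function(b) unclass(b)[!vapply(b, is.null, logical(1))])
  yaml::write_yaml(x, path)
  invisible(path)
}

region_box <- function(config) {
  list(lo = c(0, 0, 0), hi = config$region_size)
}

padded_box <- function(config) {
  p <- config$node_padding
  list(lo = c(0, 0, 0) - p, hi = config$region_size + p)
}
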