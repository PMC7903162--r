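#' Choose the next growth node
#'
#' Evaluates the step cost for every accessible Delaunay neighbour of the
#' fibre's head node and returns the argmin (ties broken by lowest node
#' index), or `NA` when the fibre is stuck.
#'
#' @param network A `growth_network`.
#' @param head Current head node index.
#' @param head_pos Position of the head (3-vector).
#' @param target Target point (3-vector).
#' @param d0 Target diameter.
#' @param bundle Fibre bundle index.
#' @param excluded Integer vector of node indices that may not be entered
#'   (visited path and blacklist).
#' @param f Cost weight.
#' @param fasciculation Use the bundle-conditional diameter cost?
#' @param min_radius_frac Accessibility floor: nodes with
#'   `dc < min_radius_frac * d0` are skipped.
#' @return A list with `node` (or `NA` if stuck), `cost`, `dc`, and the
#'   evaluated candidate table.
#' @export
choose_next_node <- function(network, head, head_pos, target, d0, bundle,
                             excluded = integer(0), f = 0.2,
                             fasciculation = FALSE, min_radius_frac = 0.1,
                             bundle_active = FALSE) {
  nbrs <- ge_neighbours(network$ptr, as.integer(head))
  if (length(excluded)) nbrs <- nbrs[!(nbrs %in% excluded)]
  if (length(nbrs) == 0) return(list(node = NA_integer_))
  st <- ge_state(network$ptr, nbrs)
  ok <- !st$occupied & (st$dc >= min_radius_frac * d0)
  if (!any(ok)) return(list(node = NA_integer_))
  nbrs <- nbrs[ok]
  dc <- st$dc[ok]
  bc <- st$bc[ok]
  pos <- ge_positions(network$ptr, nbrs)
  lt <- cost_direction(head_pos, pos, target)
  if (fasciculation && bundle_active) {
    # The bundle-attraction branch is evaluated with the clearance saturated
    # at 2 d0, so it stays in [0, 1] like every other cost term: without
    # saturation the attraction grows without bound with distance from the
    # bundle and, at finite network resolution, overwhelms the direction
    # term and traps fibres whose targets lie laterally off the bundle.
    # Nodes beyond the tracking cutoff (infinite dc) are also at least 2 d0
    # away, so they take the saturated penalty.
    dc_eff <- pmin(dc, 2 * d0)
    bc_eff <- bc
    bc_eff[is.infinite(dc)] <- bundle
    ld <- cost_diameter_fasciculation(d0, dc_eff, bc_eff, bundle)
  } else if (fasciculation) {
    ld <- cost_diameter_fasciculation(d0, dc, bc, bundle)
  } else {
    ld <- cost_diameter(d0, dc)
  }
  l <- total_cost(lt, ld, f)
  best <- which(l == min(l))
  best <- best[which.min(nbrs[best])]  # deterministic tie-break
  list(
    node = nbrs[best], cost = l[best], dc = dc[best],
    position = pos[best, ],
    candidates = tibble(node = nbrs, lt = lt, ld = ld, l = l, dc = dc)
  )
}

#' Retreat distance of the k-th fibre collapse
#'
#' `g0 + k * delta` for escalation `k = 0, 1, ...`; with the defaults the
#' sequence is 2, 7, 12, 17, 22, 27 um, so the maximum retreat (after 5
#' escalations) is 27 um.
#'
#' @param k Escalation index (0-based).
#' @param g0 Initial retreat (um).
#' @param delta Increment per escalation (um).
#' @return Retreat distance (um).
#' @export
collapse_retreat_distance <- function(k, g0 = 2, delta = 5) {
  g0 + k * delta
}

# retreat the skeleton by arc length `g`; returns truncated skeleton and the
# node indices abandoned (for the blacklist)
retreat_skeleton <- function(skeleton, g) {
  m <- nrow(skeleton)
  if (m <= 1) return(list(skeleton = skeleton, abandoned = integer(0)))
  pts <- as.matrix(skeleton[, c("x", "y", "z")])
  seg <- polyline_lengths(pts)
  walked <- 0
  cut <- m
  # clamp at the first network node (row 1 is the start point itself)
  while (cut > 2 && walked < g) {
    walked <- walked + seg[cut - 1]
    cut <- cut - 1
  }
  abandoned <- skeleton$node[(cut + 1):m]
  abandoned <- abandoned[!is.na(abandoned)]
  list(skeleton = skeleton[seq_len(cut), , drop = FALSE], abandoned = abandoned)
}

#' Grow a single fibre
#'
#' Greedy best-first growth from the seed's start point towards its target
#' along the network, with optional collapse-and-regrow on dead ends. The
#' realised radius at each node is `min(d0, dc) / 2`, i.e. the fibre shrinks
#' where space is tight. The fibre completes when the head comes within the
#' completion tolerance of the target (or passes the target face plane) and
#' is then snapped onto the target point; a fibre that exhausts its collapse
#' budget is removed.
#'
#' @param network A `growth_network`.
#' @param seed One-row tibble from [make_fibre_seeds()] (or a list with
#'   `start_*`, `target_*`, `d0`, `bundle`).
#' @param config A [growth_config()] providing cost and collapse parameters.
#' @param mechanisms Character vector among
#'   `c("collapse", "dynamic", "fasciculation", "optimise")`.
#' @param completion_tol Completion tolerance (um); default the network's
#'   90th-percentile Delaunay edge length.
#' @param max_steps Safety cap on growth steps.
#' @return A `fibre` list: `skeleton` tibble (x, y, z, radius, node),
#'   `status` (`"complete"` or `"removed"`), `collapses`, `d0`, `bundle`.
#' @export
grow_fibre <- function(network, seed, config, mechanisms = c("collapse"),
                       completion_tol = NULL, max_steps = 10000,
                       bundle_active = FALSE) {
  start <- c(seed$start_x, seed$start_y, seed$start_z)
  target <- c(seed$target_x, seed$target_y, seed$target_z)
  d0 <- seed$d0
  bundle <- seed$bundle
  tol <- completion_tol %||% network$edge_q90
  use_collapse <- "collapse" %in% mechanisms
  fascic <- "fasciculation" %in% mechanisms

  # target face plane (for the passed-the-plane completion test); the
  # growth region excludes the node padding
  reg <- network$growth_region %||% network$region
  L <- reg$hi
  lo <- reg$lo
  t_ax <- which(abs(target - L) < 1e-6 | abs(target - lo) < 1e-6)[1]
  t_hi <- if (!is.na(t_ax)) abs(target[t_ax] - L[t_ax]) < 1e-6 else NA

  head <- ge_nearest_node(network$ptr, start, TRUE)
  if (head <= 0) {
    return(fibre_obj(empty_skeleton(start, d0), "removed", 0L, d0, bundle, target))
  }
  st0 <- ge_state(network$ptr, head)
  if (st0$occupied || st0$dc < config$min_radius_frac * d0) {
    return(fibre_obj(empty_skeleton(start, d0), "removed", 0L, d0, bundle, target))
  }
  hp <- drop(ge_positions(network$ptr, head))
  skeleton <- tibble(
    x = c(start[1], hp[1]), y = c(start[2], hp[2]), z = c(start[3], hp[3]),
    radius = c(d0 / 2, min(d0, st0$dc) / 2),
    node = c(NA_integer_, head)
  )
  visited <- c(head)
  blacklist <- integer(0)
  collapses <- 0L

  step <- 0
  while (step < max_steps) {
    step <- step + 1
    head_pos <- c(skeleton$x[nrow(skeleton)], skeleton$y[nrow(skeleton)],
                  skeleton$z[nrow(skeleton)])
    # completion test
    done <- sqrt(sum((head_pos - target)^2)) <= tol
    if (!done && !is.na(t_ax)) {
      done <- if (t_hi) head_pos[t_ax] >= L[t_ax] - 1e-9 else head_pos[t_ax] <= lo[t_ax] + 1e-9
    }
    if (done) {
      last_r <- skeleton$radius[nrow(skeleton)]
      skeleton <- dplyr::bind_rows(skeleton, tibble(
        x = target[1], y = target[2], z = target[3],
        radius = last_r, node = NA_integer_
      ))
      return(fibre_obj(skeleton, "complete", collapses, d0, bundle, target))
    }
    nxt <- choose_next_node(
      network, skeleton$node[nrow(skeleton)], head_pos, target, d0, bundle,
      excluded = c(visited, blacklist), f = config$cost_weight,
      fasciculation = fascic, min_radius_frac = config$min_radius_frac,
      bundle_active = bundle_active
    )
    if (is.na(nxt$node)) {
      # stuck: collapse or remove
      if (!use_collapse || collapses > config$collapse_max_attempts) {
        return(fibre_obj(skeleton, "removed", collapses, d0, bundle, target))
      }
      g <- collapse_retreat_distance(collapses, config$collapse_initial,
                                     config$collapse_increment)
      collapses <- collapses + 1L
      rt <- retreat_skeleton(skeleton, g)
      skeleton <- rt$skeleton
      blacklist <- c(blacklist, rt$abandoned)
      if (nrow(skeleton) <= 1 && collapses > config$collapse_max_attempts) {
        return(fibre_obj(skeleton, "removed", collapses, d0, bundle, target))
      }
      next
    }
    skeleton <- dplyr::bind_rows(skeleton, tibble(
      x = nxt$position[1], y = nxt$position[2], z = nxt$position[3],
      radius = min(d0, nxt$dc) / 2, node = nxt$node
    ))
    visited <- c(visited, nxt$node)
  }
  fibre_obj(skeleton, "removed", collapses, d0, bundle, target)
}

empty_skeleton <- function(start, d0) {
  tibble(
    x = start[1], y = start[2], z = start[3],
    radius = d0 / 2, node = NA_integer_
  )
}

fibre_obj <- function(skeleton, status, collapses, d0, bundle, target) {
  structure(
    list(
      skeleton = skeleton, status = status, collapses = collapses,
      d0 = d0, bundle = bundle, target = target
    ),
    class = "fibre"
  )
}

#' Grow a complete phantom
#'
#' Grows all seeded fibres sequentially in a seeded random order. After each
#' completed fibre the network is updated with the space it occupies and
#' (when enabled) densified with dynamic nodes around its path; after all
#' fibres have grown, the global position relaxation runs (when enabled).
#' The four growth mechanisms can be toggled independently to reproduce
#' mechanism-ablation experiments.
#'
#' @param config A [growth_config()].
#' @param mechanisms Character vector among `"collapse"`, `"dynamic"`,
#'   `"fasciculation"`, `"optimise"` (`"all"` and `"minimal"` shorthands are
#'   accepted).
#' @param seeds Optional precomputed seed tibble (default
#'   [make_fibre_seeds()]).
#' @param network Optional prebuilt `growth_network`.
#' @param verbose Print per-fibre progress?
#' @return A `phantom` object: tibble of fibres with list-column skeletons,
#'   the seeds, config, mechanisms and a growth log.
#' @export
grow_all <- function(config, mechanisms = c("collapse", "dynamic",
                                            "fasciculation", "optimise"),
                     seeds = NULL, network = NULL, verbose = FALSE) {
  mechanisms <- expand_mechanisms(mechanisms)
  if (is.null(seeds)) seeds <- make_fibre_seeds(config)
  if (nrow(seeds) == 0) {
    warn("no fibre seeds; returning an empty phantom")
    return(new_phantom(list(), seeds, config, mechanisms, NULL))
  }
  if (is.null(network)) {
    nodes <- with_stage_seed(config$master_seed, 3, {
      generate_growth_nodes(region_box(config), config$n_nodes,
                            padding = config$node_padding)
    })
    network <- build_network(nodes, padded_box(config),
                             track_radius = config$track_radius)
    network$growth_region <- region_box(config)
  }
  order_idx <- with_stage_seed(config$master_seed, 4, sample(nrow(seeds)))
  pad <- padded_box(config)
  fibres <- vector("list", nrow(seeds))
  grown_per_bundle <- integer(0)
  for (pos in seq_along(order_idx)) {
    i <- order_idx[pos]
    bkey <- as.character(seeds$bundle[i])
    active <- isTRUE(grown_per_bundle[bkey] > 0)
    fb <- with_stage_seed(config$master_seed, 1000 + i, {
      grow_fibre(network, seeds[i, ], config, mechanisms, bundle_active = active)
    })
    fibres[[i]] <- fb
    if (fb$status == "complete") {
      grown_per_bundle[bkey] <- if (is.na(grown_per_bundle[bkey])) 1L else
        grown_per_bundle[bkey] + 1L
      update_network(network, fb$skeleton, fb$bundle)
      if ("dynamic" %in% mechanisms && config$n_added > 0) {
        with_stage_seed(config$master_seed, 20000 + i, {
          add_dynamic_nodes(network, fb$skeleton, config$n_added, pad)
        })
      }
    }
    if (verbose) {
      message(sprintf("fibre %d/%d (%s, %d collapses)", pos, length(order_idx),
                      fb$status, fb$collapses))
    }
  }
  ph <- new_phantom(fibres, seeds, config, mechanisms, network)
  ph$growth_order <- order_idx
  if (sum(ph$fibres$status == "complete") == 0) {
    warn("no fibre completed; the phantom is empty")
  }
  if ("optimise" %in% mechanisms) {
    ph <- with_stage_seed(config$master_seed, 5, global_optimise(ph))
  }
  ph
}

expand_mechanisms <- function(mechanisms) {
  if (length(mechanisms) == 1 && mechanisms == "all") {
    return(c("collapse", "dynamic", "fasciculation", "optimise"))
  }
  if (length(mechanisms) == 1 && mechanisms %in% c("minimal", "none")) {
    return(character(0))
  }
  bad <- setdiff(mechanisms, c("collapse", "dynamic", "fasciculation", "optimise"))
  if (length(bad)) abort(paste("unknown mechanism:", paste(bad, collapse = ", ")))
  mechanisms
}

new_phantom <- function(fibres, seeds, config, mechanisms, network) {
  tbl <- if (length(fibres)) {
    tibble(
      fibre = seq_along(fibres),
      bundle = vapply(fibres, function(f) as.integer(f$bundle), integer(1)),
      status = vapply(fibres, function(f) f$status, character(1)),
      d0 = vapply(fibres, function(f) f$d0, numeric(1)),
      collapses = vapply(fibres, function(f) f$collapses, integer(1)),
      n_points = vapply(fibres, function(f) nrow(f$skeleton), integer(1)),
      skeleton = lapply(fibres, function(f) f$skeleton)
    )
  } else {
    tibble(
      fibre = integer(0), bundle = integer(0), status = character(0),
      d0 = numeric(0), collapses = integer(0), n_points = integer(0),
      skeleton = list()
    )
  }
  structure(
    list(fibres = tbl, seeds = seeds, config = config,
         mechanisms = mechanisms, network = network),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  n <- nrow(x$fibres)
  nc <- sum(x$fibres$status == "complete")
  cat(sprintf(
    "<phantom> %d fibres seeded, %d complete, %d removed; mechanisms: %s\n",
    n, nc, n - nc,
    if (length(x$mechanisms)) paste(x$mechanisms, collapse = ", ") else "minimal"
  ))
  invisible(x)
}

#' @export
#' @method tidy phantom
tidy.phantom <- function(x, ...) {
  comp <- x$fibres
  out <- lapply(seq_len(nrow(comp)), function(i) {
    sk <- comp$skeleton[[i]]
    sk$fibre <- comp$fibre[i]
    sk$bundle <- comp$bundle[i]
    sk$point <- seq_len(nrow(sk))
    sk
  })
  bind_rows(out)
}

#' @export
#' @method glance phantom
glance.phantom <- function(x, ...) {
  comp <- x$fibres[x$fibres$status == "complete", ]
  tibble(
    n_seeded = nrow(x$fibres),
    n_complete = nrow(comp),
    n_removed = nrow(x$fibres) - nrow(comp),
    mean_collapses = mean(x$fibres$collapses),
    target_density = x$config$target_density,
    master_seed = x$config$master_seed
  )
}

#' Completed-fibre skeletons as a list of matrices
#'
#' @param phantom A `phantom`.
#' @return List of `m x 4` matrices (x, y, z, radius), one per completed
#'   fibre, named by fibre index.
#' @export
phantom_skeletons <- function(phantom) {
  comp <- phantom$fibres[phantom$fibres$status == "complete", ]
  out <- lapply(comp$skeleton, function(sk) {
    as.matrix(sk[, c("x", "y", "z", "radius")])
  })
  names(out) <- comp$fibre
  out
}

#' Write per-fibre skeleton CSVs
#'
#' @param phantom A `phantom`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_skeleton_csv <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pts <- tidy(phantom)
  utils::write.csv(as.data.frame(pts), file.path(dir, "skeletons.csv"),
                   row.names = FALSE)
  invisible(dir)
}
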