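# Automated medial opening-wedge HTO planning: wedge simulation, the three
# fitness functions (target MA deviation, target TS deviation, plate-bone
# gap), configurable feasibility rules, and an NSGA-II search over the
# twelve plan parameters.

#' Planning targets
#' @param MA,TS target mechanical axis and tibial slope (deg)
#' @return list of class `planning_targets`
#' @export
planning_targets <- function(MA = 0, TS = 5) {
  stopifnot(is.finite(MA), is.finite(TS))
  structure(list(MA = MA, TS = TS), class = "planning_targets")
}

#' Twelve-parameter osteotomy plan
#'
#' Parameters: frontal-plane hinge-axis position (2: ML and SI, mm), axis
#' direction angles (2: azimuth from +Y in the axial plane and elevation
#' toward +Z, deg), opening angle (1, deg), cutting-plane inclination about
#' the axis (1, deg), fixation-plate position (3, mm) and orientation
#' (3, deg, applied about X, Y, Z in that order).
#'
#' @param x numeric vector of length 12 (or the 12 scalars via `...`)
#' @param side leg side the plan belongs to
#' @param case_id patient frame identifier
#' @return object of class `osteotomy_plan`
#' @export
osteotomy_plan <- function(x, side = "right", case_id = NA_character_) {
  x <- as.numeric(x)
  stopifnot(length(x) == 12, x[5] >= 0)
  structure(list(par = stats::setNames(x, plan_par_names()),
                 side = side, case_id = case_id),
            class = "osteotomy_plan")
}

plan_par_names <- function() {
  c("axis_ml", "axis_si", "axis_azimuth", "axis_elevation",
    "opening_angle", "plane_inclination",
    "plate_x", "plate_y", "plate_z", "plate_rx", "plate_ry", "plate_rz")
}

#' @export
print.osteotomy_plan <- function(x, ...) {
  cat("<osteotomy_plan> ", x$side, " leg, opening ",
      round(x$par["opening_angle"], 2), " deg\n", sep = "")
  print(round(x$par, 2))
  invisible(x)
}

# hinge axis direction from the two angles
plan_axis_dir <- function(par) {
  a <- deg2rad(par[["axis_azimuth"]]); e <- deg2rad(par[["axis_elevation"]])
  c(sin(a) * cos(e), cos(a) * cos(e), sin(e))
}

# cutting plane normal: the superior-pointing vector orthogonal to the axis,
# tilted about the axis by the inclination angle
plan_plane_normal <- function(par) {
  d <- plan_axis_dir(par)
  n0 <- c(0, 0, 1) - sum(c(0, 0, 1) * d) * d
  n0 <- unit3(n0)
  drop(rotation_about_axis(d, par[["plane_inclination"]]) %*% n0)
}

#' Rigid sample-point model of the fixation plate
#'
#' A planar rectangular footprint sampled on a grid plus four screw entry
#' points, in the plate-local frame (footprint in the local XZ plane,
#' normal +Y).
#'
#' @param length,width footprint extent (mm)
#' @param n_grid points per side of the sampling grid
#' @return matrix of local sample points (class `plate_model`)
#' @export
plate_model <- function(length = 70, width = 18, n_grid = c(7, 3)) {
  zs <- seq(-length / 2, length / 2, length.out = n_grid[1])
  xs <- seq(-width / 2, width / 2, length.out = n_grid[2])
  g <- as.matrix(expand.grid(x = xs, y = 0, z = zs))
  screws <- cbind(x = c(-1, 1, -1, 1) * width / 4, y = 0,
                  z = c(-1, -1, 1, 1) * length * 0.4)
  pts <- rbind(g, screws)
  stopifnot(nrow(pts) >= 20)
  structure(pts, class = c("plate_model", "matrix"))
}

# plate sample points in world coordinates under the plan's pose
plate_points_world <- function(plate, par) {
  R <- rotation_about_axis(c(0, 0, 1), par[["plate_rz"]]) %*%
    rotation_about_axis(c(0, 1, 0), par[["plate_ry"]]) %*%
    rotation_about_axis(c(1, 0, 0), par[["plate_rx"]])
  sweep(unclass(plate) %*% t(R), 2,
        c(par[["plate_x"]], par[["plate_y"]], par[["plate_z"]]), `+`)
}

#' Simulate a medial opening-wedge correction
#'
#' The tibia distal to the cutting plane (plus the ankle center) is rotated
#' rigidly about the hinge axis by the opening angle; the rotation sign is
#' chosen per side so that a positive opening angle reduces varus. Achieved
#' MA and TS are re-measured from the corrected geometry: MA from the
#' corrected joint centers, TS from the (unmoved) plateau plane and the
#' corrected knee-ankle line.
#'
#' @param landmarks list with `HC`, `KC`, `AC` (mm)
#' @param mesh proximal tibia `trimesh`
#' @param plan an [osteotomy_plan()]
#' @param plateau_plane optional precomputed [fit_plateau_plane()] result
#' @return list with `landmarks`, `mesh` (corrected), `achieved`
#'   (`MA`, `TS`), `moved` (logical vertex mask), `feasible`
#' @export
simulate_correction <- function(landmarks, mesh, plan, plateau_plane = NULL) {
  par <- plan$par
  K <- landmarks$KC
  p0 <- c(par[["axis_ml"]], K[2], par[["axis_si"]])
  d <- plan_axis_dir(par)
  n <- plan_plane_normal(par)
  feasible <- axis_inside_mesh(p0, mesh)
  # sign convention: a positive opening angle reduces varus on either side
  sgn <- if (plan$side == "right") -1 else 1
  R <- rotation_about_axis(d, sgn * par[["opening_angle"]])
  below <- drop(sweep(mesh$vertices, 2, p0) %*% n) < 0
  v <- mesh$vertices
  if (any(below))
    v[below, ] <- apply_rigid(v[below, , drop = FALSE], R, center = p0)
  lm <- landmarks
  lm$AC <- apply_rigid(landmarks$AC, R, center = p0)
  mesh2 <- trimesh(v, mesh$faces)
  MA <- mechanical_axis_angle(lm$HC, lm$KC, lm$AC, plan$side)
  TS <- NA_real_
  pl <- plateau_plane
  if (is.null(pl))
    pl <- tryCatch(fit_plateau_plane(mesh2), error = function(e) NULL)
  if (!is.null(pl)) TS <- tibial_slope(pl, lm$KC, lm$AC)
  list(landmarks = lm, mesh = mesh2, achieved = list(MA = MA, TS = TS),
       moved = below, feasible = feasible)
}

# frontal-plane containment test near the hinge height
axis_inside_mesh <- function(p0, mesh, slab = 6) {
  v <- mesh$vertices
  near <- abs(v[, 3] - p0[3]) <= slab
  if (!any(near)) return(FALSE)
  rx <- range(v[near, 1]); ry <- range(v[near, 2])
  p0[1] >= rx[1] && p0[1] <= rx[2]
}

#' Evaluate the three fitness functions of a plan
#'
#' (1) absolute deviation of the achieved MA from the target, (2) absolute
#' deviation of the achieved TS from the target, (3) mean distance between
#' the plate sample points and the corrected bone surface. An infeasible
#' plan returns `Inf` sentinels.
#'
#' @param plan an [osteotomy_plan()]
#' @param case list with `landmarks` and `mesh`
#' @param targets a [planning_targets()]
#' @param plate a [plate_model()]
#' @param plateau_plane optional precomputed plateau plane
#' @return named numeric `c(dMA, dTS, plate_gap)`
#' @export
plan_fitness <- function(plan, case, targets, plate = plate_model(),
                         plateau_plane = NULL) {
  sim <- simulate_correction(case$landmarks, case$mesh, plan, plateau_plane)
  if (!sim$feasible)
    return(c(dMA = Inf, dTS = Inf, plate_gap = Inf))
  pts <- plate_points_world(plate, plan$par)
  gap <- mean(mesh_point_dist_cpp(pts, sim$mesh$vertices, sim$mesh$faces, -1))
  c(dMA = abs(sim$achieved$MA - targets$MA),
    dTS = if (is.na(sim$achieved$TS)) Inf else abs(sim$achieved$TS - targets$TS),
    plate_gap = gap)
}

#' Check clinical feasibility rules of a plan
#'
#' Default rules: the hinge keeps at least `h_min` mm of lateral cortical
#' bridge, the cutting plane passes at least `d_min` mm below the plateau,
#' and the plate footprint stays entirely on the medial side of the knee
#' center (`plate_overhang` mm of lateral overshoot allowed). Each rule is
#' reported individually; the plate-to-bone distance itself is a planning
#' objective, not a rule.
#'
#' @param plan an [osteotomy_plan()]
#' @param case list with `landmarks` and `mesh`
#' @param rules list of thresholds `h_min`, `d_min` (mm), `plate_overhang`
#'   (mm, default 0)
#' @return data.frame with one row per rule (`rule`, `value`, `threshold`,
#'   `pass`) and an attribute `feasible`
#' @export
check_constraints <- function(plan, case,
                              rules = list(h_min = 10, d_min = 15,
                                           plate_overhang = 0)) {
  par <- plan$par
  mesh <- case$mesh; K <- case$landmarks$KC
  p0 <- c(par[["axis_ml"]], K[2], par[["axis_si"]])
  lat_sgn <- if (plan$side == "right") 1 else -1
  near <- abs(mesh$vertices[, 3] - p0[3]) <= 6
  lat_x <- if (any(near)) {
    xs <- mesh$vertices[near, 1]
    if (lat_sgn > 0) max(xs) else min(xs)
  } else NA_real_
  hinge_bridge <- abs(lat_x - p0[1])
  n <- plan_plane_normal(par)
  ztop <- max(mesh$vertices[, 3])
  # cutting-plane height below the knee center (x, y)
  zk <- p0[3] + (sum(n[1:2] * (K[1:2] - p0[1:2]))) / -n[3]
  depth <- ztop - zk
  pts <- plate_points_world(plate_model(), par)
  overhang <- max(lat_sgn * (pts[, 1] - K[1]))
  allowed <- rules$plate_overhang %||% 0
  out <- data.frame(
    rule = c("hinge_lateral_bridge", "plane_below_plateau",
             "plate_on_medial_cortex"),
    value = c(hinge_bridge, depth, overhang),
    threshold = c(rules$h_min, rules$d_min, allowed),
    pass = c(isTRUE(hinge_bridge >= rules$h_min),
             isTRUE(depth >= rules$d_min),
             isTRUE(overhang <= allowed)))
  attr(out, "feasible") <- all(out$pass)
  out
}

# parameter bounds for the search, relative to the case geometry
plan_bounds <- function(case, side) {
  K <- case$landmarks$KC
  lat <- if (side == "right") 1 else -1
  v <- case$mesh$vertices
  lo <- c(axis_ml = min(K[1] - lat * 10, K[1] + lat * 12), axis_si = K[3] - 45,
          axis_azimuth = -25, axis_elevation = -25,
          opening_angle = 0, plane_inclination = -15,
          plate_x = K[1] - lat * 35, plate_y = K[2] - 18, plate_z = K[3] - 70,
          plate_rx = -20, plate_ry = -20, plate_rz = -20)
  hi <- c(axis_ml = max(K[1] - lat * 10, K[1] + lat * 12), axis_si = K[3] - 18,
          axis_azimuth = 25, axis_elevation = 25,
          opening_angle = 20, plane_inclination = 15,
          plate_x = K[1] - lat * 10, plate_y = K[2] + 18, plate_z = K[3] - 18,
          plate_rx = 20, plate_ry = 20, plate_rz = 20)
  if (lat < 0) { # left leg: plate_x bounds flip ordering
    tmp <- lo["plate_x"]; lo["plate_x"] <- min(lo["plate_x"], hi["plate_x"])
    hi["plate_x"] <- max(tmp, hi["plate_x"])
  }
  list(lo = lo[plan_par_names()], hi = hi[plan_par_names()])
}

# fast non-dominated sort (returns list of index vectors per front)
nds_fronts <- function(F) {
  n <- nrow(F)
  dominates <- function(i, j)
    all(F[i, ] <= F[j, ]) && any(F[i, ] < F[j, ])
  S <- vector("list", n); nd <- integer(n)
  for (i in seq_len(n)) {
    S[[i]] <- integer(0)
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(i, j)) S[[i]] <- c(S[[i]], j)
      else if (dominates(j, i)) nd[i] <- nd[i] + 1L
    }
  }
  fronts <- list(which(nd == 0L))
  k <- 1
  while (length(fronts[[k]])) {
    nxt <- integer(0)
    for (i in fronts[[k]]) for (j in S[[i]]) {
      nd[j] <- nd[j] - 1L
      if (nd[j] == 0L) nxt <- c(nxt, j)
    }
    k <- k + 1
    fronts[[k]] <- nxt
  }
  fronts[lengths(fronts) > 0]
}

crowding_distance <- function(F) {
  n <- nrow(F); d <- numeric(n)
  for (m in seq_len(ncol(F))) {
    o <- order(F[, m])
    rng <- F[o[n], m] - F[o[1], m]
    d[o[c(1, n)]] <- Inf
    if (n > 2 && rng > 0)
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (F[o[3:n], m] - F[o[1:(n - 2)], m]) / rng
  }
  d
}

sbx_crossover <- function(p1, p2, lo, hi, eta = 15) {
  u <- runif(length(p1))
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  list(pmin(pmax(c1, lo), hi), pmin(pmax(c2, lo), hi))
}

poly_mutation <- function(p, lo, hi, pm, eta = 20) {
  for (i in seq_along(p)) {
    if (runif(1) < pm) {
      u <- runif(1)
      delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1
        else 1 - (2 * (1 - u))^(1 / (eta + 1))
      p[i] <- min(max(p[i] + delta * (hi[i] - lo[i]), lo[i]), hi[i])
    }
  }
  p
}

#' Multi-objective search for an osteotomy plan
#'
#' NSGA-II (non-dominated sorting, crowding distance, simulated binary
#' crossover, polynomial mutation) over the 12 plan parameters, minimizing
#' the three fitness components. Returns the final non-dominated front and
#' a selected plan: minimal target-MA deviation, ties broken by target-TS
#' deviation, then plate gap.
#'
#' @param case list with `landmarks` and `mesh` (proximal tibia)
#' @param targets a [planning_targets()]
#' @param plate a [plate_model()]
#' @param side leg side
#' @param population,generations GA size (defaults 100 / 100)
#' @param seed RNG seed (the whole search is deterministic given it)
#' @param crossover_prob,mutation_prob GA rates
#' @param init_budget random probes used to verify the feasible region is
#'   nonempty
#' @param rules hard feasibility rules enforced during the search (hinge
#'   bridge and cut depth; the plate's fit is already the third objective);
#'   `NULL` disables them
#' @return list with `pareto` (data.frame of parameters + fitness),
#'   `selected` (an [osteotomy_plan()]), `selected_fitness`, `history`
#' @export
optimize_plan <- function(case, targets, plate = plate_model(),
                          side = "right", population = 100,
                          generations = 100, seed = 1L,
                          crossover_prob = 0.9, mutation_prob = 1 / 12,
                          init_budget = 200,
                          rules = list(h_min = 10, d_min = 15)) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  b <- plan_bounds(case, side)
  lo <- b$lo; hi <- b$hi
  plateau <- tryCatch(fit_plateau_plane(case$mesh), error = function(e) NULL)
  K <- case$landmarks$KC
  lat_sgn <- if (side == "right") 1 else -1
  ztop <- max(case$mesh$vertices[, 3])
  rules_ok <- function(par) {
    if (is.null(rules)) return(TRUE)
    near <- abs(case$mesh$vertices[, 3] - par[["axis_si"]]) <= 6
    if (!any(near)) return(FALSE)
    xs <- case$mesh$vertices[near, 1]
    lat_x <- if (lat_sgn > 0) max(xs) else min(xs)
    if (abs(lat_x - par[["axis_ml"]]) < rules$h_min) return(FALSE)
    n <- plan_plane_normal(par)
    zk <- par[["axis_si"]] -
      sum(n[1:2] * (K[1:2] - c(par[["axis_ml"]], K[2]))) / n[3]
    (ztop - zk) >= rules$d_min
  }
  evalp <- function(x) {
    plan <- osteotomy_plan(x, side)
    if (!rules_ok(plan$par)) return(c(dMA = Inf, dTS = Inf, plate_gap = Inf))
    plan_fitness(plan, case, targets, plate, plateau_plane = plateau)
  }
  rand_ind <- function() lo + runif(12) * (hi - lo)
  # feasibility probing
  ok <- FALSE
  for (i in seq_len(init_budget)) {
    if (all(is.finite(evalp(rand_ind())))) { ok <- TRUE; break }
  }
  if (!ok) stop("optimization error: no feasible plan found while probing")
  P <- t(replicate(population, rand_ind()))
  F <- t(apply(P, 1, evalp))
  history <- data.frame()
  for (g in seq_len(generations)) {
    fronts <- nds_fronts(F)
    rank <- integer(nrow(F))
    for (k in seq_along(fronts)) rank[fronts[[k]]] <- k
    crowd <- numeric(nrow(F))
    for (k in seq_along(fronts)) {
      Fi <- F[fronts[[k]], , drop = FALSE]
      Fi[!is.finite(Fi)] <- 1e9
      crowd[fronts[[k]]] <- crowding_distance(Fi)
    }
    tournament <- function() {
      i <- sample(nrow(P), 2)
      if (rank[i[1]] < rank[i[2]]) i[1]
      else if (rank[i[2]] < rank[i[1]]) i[2]
      else if (crowd[i[1]] >= crowd[i[2]]) i[1] else i[2]
    }
    Q <- matrix(0, population, 12)
    i <- 1
    while (i <= population) {
      p1 <- P[tournament(), ]; p2 <- P[tournament(), ]
      if (runif(1) < crossover_prob) {
        ch <- sbx_crossover(p1, p2, lo, hi)
      } else ch <- list(p1, p2)
      Q[i, ] <- poly_mutation(ch[[1]], lo, hi, mutation_prob)
      if (i + 1 <= population)
        Q[i + 1, ] <- poly_mutation(ch[[2]], lo, hi, mutation_prob)
      i <- i + 2
    }
    FQ <- t(apply(Q, 1, evalp))
    PA <- rbind(P, Q); FA <- rbind(F, FQ)
    fronts <- nds_fronts(FA)
    keep <- integer(0)
    for (fr in fronts) {
      if (length(keep) + length(fr) <= population) keep <- c(keep, fr)
      else {
        Fi <- FA[fr, , drop = FALSE]; Fi[!is.finite(Fi)] <- 1e9
        cd <- crowding_distance(Fi)
        keep <- c(keep, fr[order(cd, decreasing = TRUE)][
          seq_len(population - length(keep))])
        break
      }
    }
    P <- PA[keep, , drop = FALSE]; F <- FA[keep, , drop = FALSE]
    history <- rbind(history,
                     data.frame(generation = g, best_dMA = min(F[, 1]),
                                best_dTS = min(F[, 2]),
                                best_gap = min(F[, 3])))
  }
  fronts <- nds_fronts(F)
  fr1 <- fronts[[1]]
  fin <- fr1[is.finite(rowSums(F[fr1, , drop = FALSE]))]
  if (!length(fin)) fin <- fr1
  # selection: minimal dMA, ties (within 0.25 deg) broken by dTS, then gap
  cand <- fin[F[fin, 1] <= min(F[fin, 1]) + 0.25]
  cand <- cand[F[cand, 2] <= min(F[cand, 2]) + 0.25]
  sel <- cand[which.min(F[cand, 3])]
  pareto <- cbind(as.data.frame(P[fin, , drop = FALSE]),
                  F[fin, , drop = FALSE])
  names(pareto) <- c(plan_par_names(), "dMA", "dTS", "plate_gap")
  list(pareto = pareto,
       selected = osteotomy_plan(P[sel, ], side, case_id = case$case_id %||% NA),
       selected_fitness = F[sel, ],
       history = history,
       control = list(population = population, generations = generations,
                      seed = seed, crossover_prob = crossover_prob,
                      mutation_prob = mutation_prob))
}

#' Compare two osteotomy plans
#'
#' Reports the frontal-plane Euclidean offset of the hinge axes with its
#' medial-lateral and superior-inferior components, the cutting-plane
#' normal angle difference projected to the frontal and sagittal planes,
#' the correction-angle difference, the plate translation (3D and per
#' axis) and per-axis plate angle differences.
#'
#' @param plan_a,plan_b [osteotomy_plan()] objects in the same patient frame
#' @return list of comparison quantities, with a `frame_mismatch` flag if
#'   the case ids differ
#' @export
compare_plans <- function(plan_a, plan_b) {
  a <- plan_a$par; b <- plan_b$par
  axis_d <- c(ml = unname(b[["axis_ml"]] - a[["axis_ml"]]),
              si = unname(b[["axis_si"]] - a[["axis_si"]]))
  na <- plan_plane_normal(a); nb <- plan_plane_normal(b)
  ang2 <- function(u, v) {
    if (sqrt(sum(u^2)) < 1e-12 || sqrt(sum(v^2)) < 1e-12) return(NA_real_)
    rad2deg(acos(pmin(1, pmax(-1, sum(u * v) /
                                sqrt(sum(u^2) * sum(v^2))))))
  }
  plate_t <- c(b[["plate_x"]] - a[["plate_x"]], b[["plate_y"]] - a[["plate_y"]],
               b[["plate_z"]] - a[["plate_z"]])
  list(axis_offset = sqrt(sum(axis_d^2)),
       axis_offset_ml = unname(abs(axis_d["ml"])),
       axis_offset_si = unname(abs(axis_d["si"])),
       plane_normal_frontal = ang2(na[c(1, 3)], nb[c(1, 3)]),
       plane_normal_sagittal = ang2(na[c(2, 3)], nb[c(2, 3)]),
       correction_angle = unname(abs(b[["opening_angle"]] - a[["opening_angle"]])),
       plate_translation = sqrt(sum(plate_t^2)),
       plate_translation_xyz = plate_t,
       plate_rotation_xyz = c(abs(b[["plate_rx"]] - a[["plate_rx"]]),
                              abs(b[["plate_ry"]] - a[["plate_ry"]]),
                              abs(b[["plate_rz"]] - a[["plate_rz"]])),
       frame_mismatch = !identical(plan_a$case_id, plan_b$case_id))
}

#' Serialize a plan to JSON
#' @param plan an [osteotomy_plan()]
#' @param path output file
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(list(parameters = as.list(plan$par), side = plan$side,
                            case_id = plan$case_id),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a plan from JSON
#' @param path JSON file written by [write_plan()]
#' @return an [osteotomy_plan()]
#' @export
read_plan <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  osteotomy_plan(unlist(j$parameters), j$side, j$case_id)
}
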