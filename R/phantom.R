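#' Phantom parameters for one synthetic leg
#'
#' Defines the analytic lower-limb surrogate: femur (shaft cylinder plus
#' femoral-head sphere), tibia (shaft cylinder capped by an elliptic plateau
#' slab), and a soft-tissue envelope. The frontal-plane deviation of the
#' tibial mechanical axis (`varus_angle`, positive = varus) and the posterior
#' inclination of the plateau (`slope_angle`) are the controlled deformity
#' parameters whose ground truth the rest of the pipeline must recover.
#'
#' @param leg_length hip-to-ankle distance along the femoral axis (mm)
#' @param femur_radius,tibia_radius shaft radii (mm)
#' @param head_radius femoral head radius (mm)
#' @param plateau_width,plateau_depth elliptic plateau footprint (mm,
#'   medial-lateral x anterior-posterior)
#' @param plateau_thickness slab thickness (mm)
#' @param varus_angle frontal-plane tibial axis deviation (deg, |x| <= 20)
#' @param slope_angle posterior plateau inclination (deg, 0..20)
#' @param soft_tissue_radius envelope radius around each bone axis (mm)
#' @param bone_intensity,soft_intensity attenuation values in [0, 1]
#' @param voxel_spacing isotropic voxel edge (mm)
#' @param seed integer RNG seed recorded with the phantom
#' @return object of class `phantom_params`
#' @export
phantom_params <- function(leg_length = 360, femur_radius = 14,
                           tibia_radius = 13, head_radius = 22,
                           plateau_width = 62, plateau_depth = 46,
                           plateau_thickness = 14, varus_angle = 0,
                           slope_angle = 5, soft_tissue_radius = 42,
                           bone_intensity = 1, soft_intensity = 0.25,
                           voxel_spacing = 3.5, seed = 1L) {
  p <- list(leg_length = leg_length, femur_radius = femur_radius,
            tibia_radius = tibia_radius, head_radius = head_radius,
            plateau_width = plateau_width, plateau_depth = plateau_depth,
            plateau_thickness = plateau_thickness, varus_angle = varus_angle,
            slope_angle = slope_angle, soft_tissue_radius = soft_tissue_radius,
            bone_intensity = bone_intensity, soft_intensity = soft_intensity,
            voxel_spacing = voxel_spacing, seed = as.integer(seed))
  stopifnot(femur_radius > 0, tibia_radius > 0, head_radius > 0,
            voxel_spacing > 0, soft_tissue_radius > 0,
            bone_intensity >= 0, bone_intensity <= 1,
            soft_intensity >= 0, soft_intensity <= 1,
            bone_intensity > soft_intensity,
            abs(varus_angle) <= 20, slope_angle >= 0, slope_angle <= 20)
  structure(p, class = "phantom_params")
}

# label codes: right femur 1 / tibia 2, left femur 11 / tibia 12
bone_label <- function(side, bone) {
  base <- if (side == "right") 0L else 10L
  base + switch(bone, femur = 1L, tibia = 2L, fibula = 3L, 0L)
}

# ---- analytic primitive scene -----------------------------------------------

prim_cylinder <- function(p0, p1, r, side, bone, label, intensity) {
  list(type = "cylinder", p0 = p0, p1 = p1, r = r, side = side, bone = bone,
       label = label, intensity = intensity)
}
prim_sphere <- function(c0, r, side, bone, label, intensity) {
  list(type = "sphere", c0 = c0, r = r, side = side, bone = bone,
       label = label, intensity = intensity)
}
prim_slab <- function(c0, e1, e2, n, a, b, half_t, side, bone, label, intensity) {
  list(type = "slab", c0 = c0, e1 = e1, e2 = e2, n = n, a = a, b = b,
       half_t = half_t, side = side, bone = bone, label = label,
       intensity = intensity)
}

prim_bbox <- function(p) {
  switch(p$type,
    cylinder = rbind(pmin(p$p0, p$p1) - p$r, pmax(p$p0, p$p1) + p$r),
    sphere = rbind(p$c0 - p$r, p$c0 + p$r),
    slab = {
      ext <- abs(p$e1) * p$a + abs(p$e2) * p$b + abs(p$n) * p$half_t
      rbind(p$c0 - ext, p$c0 + ext)
    })
}

transform_prim <- function(p, R = diag(3), center = c(0, 0, 0),
                           translation = c(0, 0, 0)) {
  tp <- function(x) apply_rigid(x, R, center, translation)
  tv <- function(v) drop(R %*% v)
  switch(p$type,
    cylinder = { p$p0 <- tp(p$p0); p$p1 <- tp(p$p1); p },
    sphere = { p$c0 <- tp(p$c0); p },
    slab = { p$c0 <- tp(p$c0); p$e1 <- tv(p$e1); p$e2 <- tv(p$e2)
             p$n <- tv(p$n); p })
}

# Leg geometry for one side. The knee center sits at `knee_at`; the femoral
# axis is vertical, the tibial axis is tilted by varus_angle in the frontal
# (XZ) plane so that the ankle deviates medially for positive varus.
leg_scene <- function(params, side, knee_at = c(0, 0, 0)) {
  stopifnot(inherits(params, "phantom_params"), side %in% c("left", "right"))
  sgn <- if (side == "right") 1 else -1       # leg sits at x = sgn * stance/2
  Lf <- 0.52 * params$leg_length
  Lt <- 0.48 * params$leg_length
  v <- deg2rad(params$varus_angle)
  K <- knee_at
  H <- K + c(0, 0, Lf)
  tdir <- c(-sgn * sin(v), 0, -cos(v))        # medial deviation = varus
  A <- K + Lt * tdir
  phi <- deg2rad(params$slope_angle)
  n <- c(0, -sin(phi), cos(phi))              # posterior tilt of the plateau
  e1 <- c(1, 0, 0)
  e2 <- unit3(pracma_cross(n, e1))
  e1 <- unit3(pracma_cross(e2, n))
  bi <- params$bone_intensity; si <- params$soft_intensity
  joint_gap <- params$plateau_thickness / 2 + 4  # femur clears the plateau
  prims <- list(
    prim_cylinder(K + c(0, 0, joint_gap), H, params$femur_radius, side, "femur",
                  bone_label(side, "femur"), bi),
    prim_sphere(H, params$head_radius, side, "femur",
                bone_label(side, "femur"), bi),
    prim_cylinder(A, K - params$plateau_thickness / 2 * c(0, 0, 1),
                  params$tibia_radius, side, "tibia",
                  bone_label(side, "tibia"), bi),
    prim_slab(K, e1, e2, n, params$plateau_width / 2, params$plateau_depth / 2,
              params$plateau_thickness / 2, side, "tibia",
              bone_label(side, "tibia"), bi),
    prim_cylinder(K, H, params$soft_tissue_radius, side, "soft", 0L, si),
    prim_cylinder(A, K, params$soft_tissue_radius, side, "soft", 0L, si)
  )
  list(prims = prims,
       landmarks = list(HC = H, KC = K, AC = A),
       truth = list(MA_true = params$varus_angle,
                    TS_true = params$slope_angle))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

scene_bbox <- function(prims) {
  bb <- sapply(prims, prim_bbox, simplify = "array")  # 2 x 3 x n
  rbind(apply(bb[1, , , drop = FALSE], 2, min), apply(bb[2, , , drop = FALSE], 2, max))
}

# mask of grid points inside a primitive; xs/ys/zs are voxel-center coords
prim_mask <- function(p, xs, ys, zs) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  X <- array(rep(xs, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(ys, each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), c(nx, ny, nz))
  if (p$type == "sphere") {
    return((X - p$c0[1])^2 + (Y - p$c0[2])^2 + (Z - p$c0[3])^2 <= p$r^2)
  }
  if (p$type == "cylinder") {
    d <- p$p1 - p$p0; L <- norm3(d); d <- d / L
    dx <- X - p$p0[1]; dy <- Y - p$p0[2]; dz <- Z - p$p0[3]
    t <- dx * d[1] + dy * d[2] + dz * d[3]
    rad2 <- dx^2 + dy^2 + dz^2 - t^2
    return(t >= 0 & t <= L & rad2 <= p$r^2)
  }
  # slab
  dx <- X - p$c0[1]; dy <- Y - p$c0[2]; dz <- Z - p$c0[3]
  q1 <- dx * p$e1[1] + dy * p$e1[2] + dz * p$e1[3]
  q2 <- dx * p$e2[1] + dy * p$e2[2] + dz * p$e2[3]
  qn <- dx * p$n[1] + dy * p$n[2] + dz * p$n[3]
  (q1 / p$a)^2 + (q2 / p$b)^2 <= 1 & abs(qn) <= p$half_t
}

#' Voxelize an analytic scene into an annotated volume
#'
#' @param prims list of primitives (internal representation)
#' @param spacing isotropic voxel spacing (mm)
#' @param margin extra space around the scene bounding box (mm)
#' @param landmarks named list of per-side landmark lists
#' @param bbox optional fixed 2 x 3 world bounding box (mm)
#' @return an `annotated_volume`
#' @keywords internal
voxelize_scene <- function(prims, spacing, margin = 8, landmarks = list(),
                           bbox = NULL) {
  if (is.null(bbox)) {
    bb <- scene_bbox(prims)
    bb[1, ] <- bb[1, ] - margin; bb[2, ] <- bb[2, ] + margin
  } else bb <- bbox
  dims <- pmax(2L, as.integer(ceiling((bb[2, ] - bb[1, ]) / spacing)))
  origin <- bb[1, ] + spacing / 2
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing
  intensity <- array(0, dims)
  labels <- array(0L, dims)
  # soft tissue first so bone labels/intensities overwrite it
  ord <- order(sapply(prims, function(p) p$label != 0L))
  for (p in prims[ord]) {
    pb <- prim_bbox(p)
    ix <- which(xs >= pb[1, 1] - spacing & xs <= pb[2, 1] + spacing)
    iy <- which(ys >= pb[1, 2] - spacing & ys <= pb[2, 2] + spacing)
    iz <- which(zs >= pb[1, 3] - spacing & zs <= pb[2, 3] + spacing)
    if (!length(ix) || !length(iy) || !length(iz)) next
    m <- prim_mask(p, xs[ix], ys[iy], zs[iz])
    sub_i <- intensity[ix, iy, iz, drop = FALSE]
    sub_i[m] <- pmax(sub_i[m], p$intensity)
    intensity[ix, iy, iz] <- sub_i
    if (p$label != 0L) {
      sub_l <- labels[ix, iy, iz, drop = FALSE]
      sub_l[m] <- p$label
      labels[ix, iy, iz] <- sub_l
    }
  }
  structure(list(intensity = intensity, labels = labels,
                 spacing = rep(spacing, 3), origin = origin,
                 landmarks = landmarks, scene = prims),
            class = "annotated_volume")
}

#' @export
print.annotated_volume <- function(x, ...) {
  cat("<annotated_volume> ", paste(dim(x$intensity), collapse = " x "),
      " voxels @ ", x$spacing[1], " mm; sides: ",
      paste(names(x$landmarks), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Generate a single synthetic leg
#'
#' Builds the analytic leg for one side, voxelizes it, and returns the
#' annotated volume together with the analytic ground truth (mechanical-axis
#' deviation and tibial slope), computed from the constructed geometry rather
#' than re-measured from voxels.
#'
#' @param params a [phantom_params()] object
#' @param side `"left"` or `"right"`
#' @return list with elements `volume` (annotated_volume) and `truth`
#'   (`MA_true`, `TS_true`, both degrees)
#' @export
generate_leg <- function(params, side = "right") {
  sc <- leg_scene(params, side)
  vol <- voxelize_scene(sc$prims, params$voxel_spacing,
                        landmarks = stats::setNames(list(sc$landmarks), side))
  check_landmarks_inside(vol)
  list(volume = vol, truth = sc$truth)
}

check_landmarks_inside <- function(vol) {
  lo <- vol$origin - vol$spacing / 2
  hi <- vol$origin + (dim(vol$intensity) - 1) * vol$spacing + vol$spacing / 2
  for (side in names(vol$landmarks))
    for (lm in vol$landmarks[[side]])
      if (any(lm < lo) || any(lm > hi))
        stop("phantom sizing error: landmark outside the voxel grid")
  invisible(TRUE)
}

#' Generate a two-leg standing subject
#'
#' Places the two legs at pelvis-width stance separation in a shared grid.
#' The right leg sits on the +X side of the midline. Errors if the stance
#' separation would make the bones of the two legs overlap.
#'
#' @param params_left,params_right per-leg [phantom_params()]
#' @param stance_separation knee-center to knee-center distance (mm)
#' @param seed RNG seed recorded in the output
#' @param anterior_headroom extra Y grid space (mm) so the clinical
#'   right-leg shift and sagittal rotation stay inside the grid
#' @return an `annotated_volume` with both legs and both landmark sets
#' @export
generate_subject <- function(params_left, params_right,
                             stance_separation = 190, seed = 1L,
                             anterior_headroom = 85) {
  stopifnot(params_left$voxel_spacing == params_right$voxel_spacing)
  scL <- leg_scene(params_left, "left", knee_at = c(-stance_separation / 2, 0, 0))
  scR <- leg_scene(params_right, "right", knee_at = c(stance_separation / 2, 0, 0))
  check_leg_clearance(scL$prims, scR$prims)
  prims <- c(scL$prims, scR$prims)
  bb <- scene_bbox(prims)
  bb[1, ] <- bb[1, ] - 8; bb[2, ] <- bb[2, ] + 8
  # the clinical shift (up to 60 mm) plus a 20 degree rotation about the
  # volume centre can move the leg ends ~80 mm in Y in either direction
  bb[1, 2] <- bb[1, 2] - anterior_headroom
  bb[2, 2] <- bb[2, 2] + anterior_headroom + 60
  vol <- voxelize_scene(prims, params_left$voxel_spacing,
                        landmarks = list(left = scL$landmarks,
                                         right = scR$landmarks), bbox = bb)
  vol$truth <- list(left = scL$truth, right = scR$truth)
  vol$params <- list(left = params_left, right = params_right)
  vol$seed <- as.integer(seed)
  check_landmarks_inside(vol)
  vol
}

# conservative bone-to-bone clearance check by axis sampling
check_leg_clearance <- function(primsL, primsR) {
  segs <- function(prims) Filter(function(p) p$type == "cylinder" &&
                                   p$bone != "soft", prims)
  pts <- function(p) {
    t <- seq(0, 1, length.out = 24)
    cbind(p$p0[1] + t * (p$p1[1] - p$p0[1]),
          p$p0[2] + t * (p$p1[2] - p$p0[2]),
          p$p0[3] + t * (p$p1[3] - p$p0[3]))
  }
  for (a in segs(primsL)) for (b in segs(primsR)) {
    pa <- pts(a); pb <- pts(b)
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
    if (sqrt(max(0, min(d2))) < a$r + b$r)
      stop("placement error: left and right legs overlap at this stance separation")
  }
  invisible(TRUE)
}

#' Generate a cohort of synthetic subjects
#'
#' Per-patient parameters are drawn from the variability specification
#' (uniform ranges `c(min, max)` or normal `list(mean, sd)`) applied on top
#' of `base_params`; both legs share size parameters but draw deformity
#' angles independently. The draws are recorded in the returned manifest.
#'
#' @param n_patients number of subjects (>= 1)
#' @param base_params baseline [phantom_params()]
#' @param variability named list of per-field distributions; defaults draw
#'   varus 2-12 deg, slope 2-12 deg, leg length N(360, 12), tibia radius
#'   N(13, 0.8)
#' @param seed RNG seed controlling every draw
#' @param stance_separation knee-to-knee distance (mm)
#' @return list with `cases` (list of annotated volumes) and `manifest`
#'   (data.frame of per-patient draws)
#' @export
generate_cohort <- function(n_patients, base_params = phantom_params(),
                            variability = NULL, seed = 1L,
                            stance_separation = 190) {
  stopifnot(n_patients >= 1)
  if (is.null(variability))
    variability <- list(varus_angle = c(2, 12), slope_angle = c(2, 12),
                        leg_length = list(mean = 360, sd = 12),
                        tibia_radius = list(mean = 13, sd = 0.8))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draw <- function(spec) {
    if (is.list(spec)) rnorm(1, spec$mean, spec$sd) else runif(1, spec[1], spec[2])
  }
  cases <- vector("list", n_patients)
  rows <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    pl <- base_params; pr <- base_params
    rec <- list(patient = sprintf("P%03d", i))
    for (f in names(variability)) {
      if (f %in% c("varus_angle", "slope_angle")) {
        vl <- draw(variability[[f]]); vr <- draw(variability[[f]])
        pl[[f]] <- vl; pr[[f]] <- vr
        rec[[paste0(f, "_left")]] <- vl; rec[[paste0(f, "_right")]] <- vr
      } else {
        v <- draw(variability[[f]])
        pl[[f]] <- v; pr[[f]] <- v
        rec[[f]] <- v
      }
    }
    class(pl) <- class(pr) <- "phantom_params"
    cases[[i]] <- generate_subject(pl, pr, stance_separation, seed = seed + i)
    cases[[i]]$patient <- rec$patient
    rows[[i]] <- as.data.frame(rec, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  manifest$seed <- seed
  list(cases = cases, manifest = manifest)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Binary mask of the proximal tibia
#'
#' The reconstruction target: tibia voxels within `span` mm of the knee
#' center of the given side.
#'
#' @param vol annotated volume
#' @param side `"left"` or `"right"`
#' @param span distance from the knee center (mm, default 120)
#' @return logical array of the volume's shape
#' @export
proximal_tibia_mask <- function(vol, side, span = 120) {
  lab <- bone_label(side, "tibia")
  K <- vol$landmarks[[side]]$KC
  dims <- dim(vol$labels)
  xs <- vol$origin[1] + (seq_len(dims[1]) - 1) * vol$spacing[1]
  ys <- vol$origin[2] + (seq_len(dims[2]) - 1) * vol$spacing[2]
  zs <- vol$origin[3] + (seq_len(dims[3]) - 1) * vol$spacing[3]
  X <- array(rep(xs, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dims)
  vol$labels == lab &
    (X - K[1])^2 + (Y - K[2])^2 + (Z - K[3])^2 <= span^2
}
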