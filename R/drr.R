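#' Biplanar projection geometry
#'
#' Describes one detector of an EOS-style biplanar acquisition. The frontal
#' view integrates along -Y (posterior->anterior axis), the sagittal view
#' along -X; both views share the vertical Z axis, so a 3D point maps to the
#' same vertical detector row in both images (the moving-emitter property).
#' In `fan` mode the emitter is a horizontal fan beam translated vertically:
#' magnification applies to the horizontal detector axis only, never to v.
#'
#' Pixel coordinates are continuous and 0-based: pixel (0, 0) is the
#' top-left pixel center, u runs along +X (frontal) or +Y (sagittal) and v
#' runs top-down (-Z).
#'
#' @param view `"frontal"` or `"sagittal"`
#' @param mode `"parallel"` (exact, closed-form triangulation) or `"fan"`
#' @param detector_size pixels `c(nu, nv)`
#' @param pixel_spacing mm per pixel `c(su, sv)` (scalar recycled)
#' @param center world coordinates `c(cu, cv)` of the detector center: cu is
#'   the X (frontal) or Y (sagittal) coordinate, cv the Z coordinate
#' @param source_axis_distance,axis_detector_distance fan-mode distances (mm)
#' @param step ray integration step (mm); defaults to `min(pixel_spacing)`
#' @return object of class `projection_geometry`
#' @export
projection_geometry <- function(view = c("frontal", "sagittal"),
                                mode = c("parallel", "fan"),
                                detector_size = c(128, 128),
                                pixel_spacing = 3.5,
                                center = c(0, 10),
                                source_axis_distance = 1300,
                                axis_detector_distance = 300,
                                step = NULL) {
  view <- match.arg(view); mode <- match.arg(mode)
  pixel_spacing <- rep(pixel_spacing, length.out = 2)
  if (mode == "fan")
    stopifnot(source_axis_distance > 0, axis_detector_distance > 0)
  structure(list(view = view, mode = mode,
                 nu = as.integer(detector_size[1]),
                 nv = as.integer(detector_size[2]),
                 su = pixel_spacing[1], sv = pixel_spacing[2],
                 cu = center[1], cv = center[2],
                 iso_r = 0,
                 sad = source_axis_distance, add = axis_detector_distance,
                 step = step %||% min(pixel_spacing)),
            class = "projection_geometry")
}

#' Simulate a radiograph from an annotated volume
#'
#' Computes line integrals of the intensity grid along the geometry's rays
#' (trilinear sampling at the configured step) and min-max normalizes the
#' result to `[0, 1]`. An empty volume yields an all-zero image.
#'
#' @param volume an `annotated_volume`
#' @param geom a [projection_geometry()]
#' @param mask optional integer vector of label codes; voxels with other
#'   labels are zeroed before projection
#' @param normalize min-max normalize to `[0, 1]` (default TRUE)
#' @return object of class `radiograph`
#' @export
project <- function(volume, geom, mask = NULL, normalize = TRUE) {
  stopifnot(inherits(geom, "projection_geometry"))
  vol <- volume$intensity
  if (!is.null(mask)) vol <- vol * (volume$labels %in% mask)
  raw <- drr_project_cpp(vol, volume$spacing, volume$origin,
                         if (geom$view == "frontal") 0L else 1L,
                         if (geom$mode == "parallel") 0L else 1L,
                         geom$nu, geom$nv, geom$su, geom$sv,
                         geom$cu, geom$cv, geom$iso_r,
                         geom$sad, geom$add, geom$step)
  rng <- range(raw)
  px <- raw
  if (normalize) {
    if (rng[2] > rng[1]) px <- (raw - rng[1]) / (rng[2] - rng[1]) else px[] <- 0
  }
  structure(list(pixels = px, view = geom$view, geom = geom,
                 norm = rng, spacing = c(geom$su, geom$sv)),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat("<radiograph> ", x$view, " ", ncol(x$pixels), "x", nrow(x$pixels),
      " px @ ", x$spacing[1], " mm\n", sep = "")
  invisible(x)
}

#' Project a 3D point to detector pixel coordinates
#'
#' @param p 3D point in mm (patient frame)
#' @param geom a [projection_geometry()]
#' @return `c(u, v)` continuous 0-based pixel coordinates
#' @export
project_point <- function(p, geom) {
  pu <- if (geom$view == "frontal") p[1] else p[2]
  pr <- if (geom$view == "frontal") p[2] else p[1]
  if (geom$mode == "parallel") {
    umm <- pu
  } else {
    s_r <- geom$iso_r + geom$sad
    d_r <- geom$iso_r - geom$add
    if (pr >= s_r) stop("geometry error: point behind the fan source")
    umm <- geom$cu + (pu - geom$cu) * (s_r - d_r) / (s_r - pr)
  }
  u <- (umm - geom$cu) / geom$su + (geom$nu - 1) / 2
  v <- (geom$cv - p[3]) / geom$sv + (geom$nv - 1) / 2
  c(u = u, v = v)
}

#' Clinical right-leg augmentation
#'
#' Mimics the standing-instruction pose: the right leg is shifted anteriorly
#' (+Y) by a draw from U(40, 60) mm and rotated by U(10, 20) degrees (random
#' sign) about the medial-lateral axis through the sagittal image center.
#' The left leg is untouched; the applied transform is recorded in the
#' returned volume. The transform acts on the analytic scene and the volume
#' is re-voxelized, so a zero transform reproduces the input bit-exactly. If
#' the moved leg leaves the original grid the grid is padded with a warning.
#'
#' @param volume two-leg `annotated_volume`
#' @param shift anterior shift in mm; `NULL` draws from U(40, 60)
#' @param rotation rotation in degrees; `NULL` draws magnitude from
#'   U(10, 20) with random sign
#' @param center `c(y, z)` of the rotation axis (sagittal image center);
#'   defaults to the volume center
#' @return augmented `annotated_volume` with an `augmentation` record
#' @export
augment_right_leg <- function(volume, shift = NULL, rotation = NULL,
                              center = NULL) {
  sides <- vapply(volume$scene, function(p) p$side, "")
  if (!any(sides == "right")) stop("right-leg labels not present")
  if (is.null(shift)) shift <- runif(1, 40, 60)
  if (is.null(rotation)) rotation <- runif(1, 10, 20) * sample(c(-1, 1), 1)
  dims <- dim(volume$intensity)
  if (is.null(center)) {
    ctr <- volume$origin + (dims - 1) * volume$spacing / 2
    center <- c(ctr[2], ctr[3])
  }
  R <- rotation_about_axis(c(1, 0, 0), rotation)
  cen <- c(0, center[1], center[2])
  tra <- c(0, shift, 0)
  scene <- lapply(volume$scene, function(p) {
    if (p$side == "right") transform_prim(p, R, cen, tra) else p
  })
  lms <- volume$landmarks
  lms$right <- lapply(lms$right, function(lm) apply_rigid(lm, R, cen, tra))
  bb0 <- rbind(volume$origin - volume$spacing / 2,
               volume$origin + (dims - 1) * volume$spacing + volume$spacing / 2)
  bb1 <- scene_bbox(scene)
  bb <- bb0
  if (any(bb1[1, ] < bb0[1, ]) || any(bb1[2, ] > bb0[2, ])) {
    warning("augmented leg exceeds the grid; padding applied")
    bb[1, ] <- pmin(bb0[1, ], bb1[1, ] - 4)
    bb[2, ] <- pmax(bb0[2, ], bb1[2, ] + 4)
  }
  out <- voxelize_scene(scene, volume$spacing[1], landmarks = lms, bbox = bb)
  out$truth <- volume$truth
  out$params <- volume$params
  out$patient <- volume$patient
  out$augmentation <- list(shift = shift, rotation = rotation,
                           center = center)
  out
}

#' Sigmoid contrast enhancement of a radiograph
#'
#' Per-pixel transform `f(x) = 1 / (1 + exp(-(x - x0) / k))` used to isolate
#' bone from the surrounding soft tissue in the separated-leg target images.
#' The defaults are the empirically chosen constants `x0 = 0.45`,
#' `k = 0.12`.
#'
#' @param image a `radiograph` (or plain numeric array in `[0, 1]`)
#' @param x0 sigmoid midpoint
#' @param k sigmoid width
#' @return same type as the input with transformed pixels
#' @export
contrast_enhance <- function(image, x0 = 0.45, k = 0.12) {
  f <- function(x) 1 / (1 + exp(-(x - x0) / k))
  if (inherits(image, "radiograph")) {
    image$pixels <- f(image$pixels)
    image$contrast <- c(x0 = x0, k = k)
    image
  } else f(image)
}

# re-voxelize one leg (with its soft tissue) on the same grid
side_volume <- function(volume, side) {
  prims <- Filter(function(p) p$side == side, volume$scene)
  dims <- dim(volume$intensity)
  bb <- rbind(volume$origin - volume$spacing / 2,
              volume$origin + (dims - 1) * volume$spacing + volume$spacing / 2)
  voxelize_scene(prims, volume$spacing[1],
                 landmarks = volume$landmarks[side], bbox = bb)
}

#' Assemble a biplanar study from a two-leg volume
#'
#' Produces the frontal and sagittal full radiographs, the two separated
#' single-leg sagittal targets (projected from the per-leg scene and then
#' contrast enhanced), and all projected 2D landmarks (6 on the frontal
#' view, 3 per single-leg sagittal).
#'
#' @param volume two-leg `annotated_volume`
#' @param geom_frontal,geom_sagittal [projection_geometry()] objects
#' @param case_id identifier stored with the study
#' @return object of class `biplanar_study`
#' @export
make_study <- function(volume, geom_frontal, geom_sagittal,
                       case_id = volume$patient %||% "case") {
  sides <- intersect(c("left", "right"), names(volume$landmarks))
  I_fron <- project(volume, geom_frontal)
  I_sag <- project(volume, geom_sagittal)
  seps <- list(); lm_sag <- list()
  for (s in sides) {
    sv <- side_volume(volume, s)
    seps[[s]] <- contrast_enhance(project(sv, geom_sagittal))
    lm_sag[[s]] <- lapply(volume$landmarks[[s]],
                          function(p) project_point(p, geom_sagittal))
  }
  lm_fron <- lapply(volume$landmarks[sides], function(lmset)
    lapply(lmset, function(p) project_point(p, geom_frontal)))
  single_leg <- length(sides) < 2
  if (single_leg) seps <- list()
  structure(list(I_fron = I_fron, I_sag = I_sag,
                 I_sag_L = seps$left, I_sag_R = seps$right,
                 landmarks2d = list(frontal = lm_fron, sagittal = lm_sag),
                 landmarks3d = volume$landmarks[sides],
                 truth = volume$truth, case_id = case_id,
                 single_leg = single_leg,
                 augmentation = volume$augmentation %||%
                   list(shift = 0, rotation = 0)),
            class = "biplanar_study")
}

#' @export
print.biplanar_study <- function(x, ...) {
  cat("<biplanar_study> ", x$case_id, " (",
      ncol(x$I_fron$pixels), " px, shift ",
      round(x$augmentation$shift, 1), " mm, rot ",
      round(x$augmentation$rotation, 1), " deg)\n", sep = "")
  invisible(x)
}

upsample_image <- function(m, factor) {
  m[rep(seq_len(nrow(m)), each = factor), rep(seq_len(ncol(m)), each = factor)]
}

clamp_window <- function(start, width, n) min(max(start, 0L), n - width)

#' Knee-centered reconstruction inputs for one leg
#'
#' Crops a `crop_px` window around the knee from the frontal image and from
#' the (separated or full) sagittal image, upsamples both by `upsample` so
#' the reconstruction network's two-level downsampling lands back on the
#' crop grid (the fusion-cube rule: input edge / 4 voxels), and samples the
#' ground-truth proximal-tibia label volume analytically on that grid. The
#' crop is centered on the knee's detected or ground-truth 2D position; the
#' frontal and sagittal crops share their vertical rows (common Z axis).
#' Sagittal crops are contrast enhanced so all sagittal inputs live in the
#' separation-target domain.
#'
#' @param study a `biplanar_study` (with its volume attached for targets)
#' @param side `"left"` or `"right"`
#' @param crop_px crop edge in pixels of the study images
#' @param upsample integer upsampling factor of the network input
#' @param sagittal `"separated"` (single-leg target image) or `"full"`
#'   (both legs; the ablation condition)
#' @param sag_image optional full-size sagittal matrix to crop instead
#'   (e.g. the separation network's prediction)
#' @param knee2d optional list with `frontal` and `sagittal` `c(u, v)`
#'   positions; defaults to the ground-truth projected knee center
#' @param knee_row row of the crop at which the knee sits (px from top)
#' @param prox_span proximal-tibia span from the knee center (mm)
#' @return list with `frontal`, `sagittal` (input matrices), `target`
#'   (`n x n x n` logical array, axes v (top-down), x, y; `NULL` without a
#'   volume), and `grid` (world coordinates of the target voxel centers)
#' @export
make_recon_inputs <- function(study, side, crop_px = 32, upsample = 4,
                              sagittal = c("separated", "full"),
                              sag_image = NULL, knee2d = NULL,
                              knee_row = 6, prox_span = 90) {
  sagittal <- match.arg(sagittal)
  gf <- study$I_fron$geom; gs <- study$I_sag$geom
  if (is.null(knee2d))
    knee2d <- list(frontal = study$landmarks2d$frontal[[side]]$KC,
                   sagittal = study$landmarks2d$sagittal[[side]]$KC)
  u0f <- clamp_window(round(knee2d$frontal["u"]) - crop_px %/% 2, crop_px, gf$nu)
  v0 <- clamp_window(round(knee2d$frontal["v"]) - knee_row, crop_px, gf$nv)
  u0s <- clamp_window(round(knee2d$sagittal["u"]) - crop_px %/% 2, crop_px, gs$nu)
  rows <- v0 + seq_len(crop_px)
  fr <- study$I_fron$pixels[rows, u0f + seq_len(crop_px), drop = FALSE]
  sg_src <- if (!is.null(sag_image)) sag_image
    else if (sagittal == "separated") {
      img <- if (side == "right") study$I_sag_R else study$I_sag_L
      if (is.null(img)) stop("separated sagittal target absent for this study")
      img$pixels
    } else contrast_enhance(study$I_sag$pixels)
  sg <- sg_src[rows, u0s + seq_len(crop_px), drop = FALSE]
  xs <- gf$cu + (u0f + seq_len(crop_px) - 1 - (gf$nu - 1) / 2) * gf$su
  ys <- gs$cu + (u0s + seq_len(crop_px) - 1 - (gs$nu - 1) / 2) * gs$su
  zs <- gf$cv - (v0 + seq_len(crop_px) - 1 - (gf$nv - 1) / 2) * gf$sv
  target <- NULL
  if (!is.null(study$volume))
    target <- recon_target_grid(study$volume, side, xs, ys, zs, prox_span)
  list(frontal = upsample_image(fr, upsample),
       sagittal = upsample_image(sg, upsample),
       target = target,
       grid = list(xs = xs, ys = ys, zs = zs, voxel = gf$su, side = side))
}

#' Convert a reconstruction prediction to a world-frame label volume
#'
#' @param arr `n x n x n` array or `n^3 x 1` logical/numeric vector in the
#'   network's (v, x, y) order
#' @param grid the `grid` element of [make_recon_inputs()]
#' @return a `label_volume`: binary array in (x, y, z ascending) order with
#'   `spacing` and `origin`
#' @export
recon_label_volume <- function(arr, grid) {
  n <- length(grid$xs)
  a <- array(as.numeric(arr), c(n, n, n))  # (v, x, y)
  lab <- array(0L, c(n, n, n))             # (x, y, z ascending)
  for (k in seq_len(n)) lab[, , k] <- (a[n + 1 - k, , ] > 0.5) * 1L
  structure(list(labels = lab, spacing = rep(grid$voxel, 3),
                 origin = c(min(grid$xs), min(grid$ys), min(grid$zs))),
            class = "label_volume")
}

# evaluate the proximal-tibia mask analytically at grid points,
# ordered (v = top-down z, x, y)
recon_target_grid <- function(volume, side, xs, ys, zs, prox_span) {
  K <- volume$landmarks[[side]]$KC
  lab <- bone_label(side, "tibia")
  prims <- Filter(function(p) identical(p$label, lab), volume$scene)
  n1 <- length(zs); n2 <- length(xs); n3 <- length(ys)
  acc <- array(FALSE, c(n1, n2, n3))
  Z <- array(rep(zs, times = n2 * n3), c(n1, n2, n3))
  X <- array(rep(rep(xs, each = n1), times = n3), c(n1, n2, n3))
  Y <- array(rep(ys, each = n1 * n2), c(n1, n2, n3))
  for (p in prims) {
    m <- prim_mask_points(p, X, Y, Z)
    acc <- acc | m
  }
  within <- (X - K[1])^2 + (Y - K[2])^2 + (Z - K[3])^2 <= prox_span^2
  acc & within
}

# primitive membership on arbitrary coordinate arrays
prim_mask_points <- function(p, X, Y, Z) {
  if (p$type == "sphere")
    return((X - p$c0[1])^2 + (Y - p$c0[2])^2 + (Z - p$c0[3])^2 <= p$r^2)
  if (p$type == "cylinder") {
    d <- p$p1 - p$p0; L <- norm3(d); d <- d / L
    dx <- X - p$p0[1]; dy <- Y - p$p0[2]; dz <- Z - p$p0[3]
    t <- dx * d[1] + dy * d[2] + dz * d[3]
    return(t >= 0 & t <= L & dx^2 + dy^2 + dz^2 - t^2 <= p$r^2)
  }
  dx <- X - p$c0[1]; dy <- Y - p$c0[2]; dz <- Z - p$c0[3]
  q1 <- dx * p$e1[1] + dy * p$e1[2] + dz * p$e1[3]
  q2 <- dx * p$e2[1] + dy * p$e2[2] + dz * p$e2[3]
  qn <- dx * p$n[1] + dy * p$n[2] + dz * p$n[3]
  (q1 / p$a)^2 + (q2 / p$b)^2 <= 1 & abs(qn) <= p$half_t
}

#' Gaussian target heatmaps for landmark localization
#'
#' One channel per landmark: an unnormalized Gaussian with peak value 1 at
#' the rounded landmark pixel, values in `[0, 1]`.
#'
#' @param landmarks2d named list of `c(u, v)` 0-based pixel coordinates
#' @param sigma Gaussian spread in pixels (> 0)
#' @param shape image shape `c(nv, nu)` (rows, cols)
#' @return array `nv x nu x n_landmarks` with channel dimnames
#' @export
make_heatmaps <- function(landmarks2d, sigma = 5, shape) {
  if (sigma <= 0) stop("parameter error: sigma must be > 0")
  nv <- shape[1]; nu <- shape[2]
  out <- array(0, c(nv, nu, length(landmarks2d)),
               dimnames = list(NULL, NULL, names(landmarks2d)))
  us <- matrix(rep(0:(nu - 1), each = nv), nv, nu)
  vs <- matrix(rep(0:(nv - 1), times = nu), nv, nu)
  for (i in seq_along(landmarks2d)) {
    lm <- landmarks2d[[i]]
    if (lm[1] < 0 || lm[1] > nu - 1 || lm[2] < 0 || lm[2] > nv - 1)
      stop("landmark outside the image")
    cu <- round(lm[1]); cv <- round(lm[2])
    out[, , i] <- exp(-((us - cu)^2 + (vs - cv)^2) / (2 * sigma^2))
  }
  out
}

#' Patient-level dataset split
#'
#' Test count is `round(0.10 * n)` with a minimum of 1 patient; the
#' validation count is `round(0.20 * train_pool)`. All augmented copies of a
#' patient share its partition.
#'
#' @param patient_ids character vector of unique patient ids
#' @param seed RNG seed for the shuffle
#' @return list with `train`, `val`, `test` id vectors and `seed`
#' @export
dataset_split <- function(patient_ids, seed = 1L) {
  n <- length(patient_ids)
  if (n < 3) stop("split error: need at least 3 patients")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ids <- sample(patient_ids)
  n_test <- max(1L, round(0.10 * n))
  pool <- n - n_test
  n_val <- round(0.20 * pool)
  list(test = sort(ids[seq_len(n_test)]),
       val = sort(ids[n_test + seq_len(n_val)]),
       train = sort(ids[-seq_len(n_test + n_val)]),
       seed = as.integer(seed))
}

#' Build the training dataset from a cohort
#'
#' For each patient, applies the right-leg augmentation `n_aug` times and
#' assembles a biplanar study per copy, then splits the patients 90/10 into
#' a train pool and test set, and the pool 80/20 into train and validation.
#' One shared split serves all three networks.
#'
#' @param cohort result of [generate_cohort()] (or a list of volumes)
#' @param n_aug augmented copies per patient (>= 1)
#' @param seed RNG seed for augmentation draws and the split
#' @param geom_frontal,geom_sagittal view geometries
#' @return list with `studies` (list of `biplanar_study`) and `split`
#' @export
build_dataset <- function(cohort, n_aug = 3, seed = 1L,
                          geom_frontal = projection_geometry("frontal"),
                          geom_sagittal = projection_geometry("sagittal")) {
  stopifnot(n_aug >= 1)
  cases <- if (!is.null(cohort$cases)) cohort$cases else cohort
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  studies <- list()
  for (ci in seq_along(cases)) {
    vol <- cases[[ci]]
    pid <- vol$patient %||% sprintf("P%03d", ci)
    for (a in seq_len(n_aug)) {
      av <- augment_right_leg(vol)
      st <- make_study(av, geom_frontal, geom_sagittal,
                       case_id = sprintf("%s_a%d", pid, a))
      st$patient <- pid
      st$volume <- av
      studies[[length(studies) + 1L]] <- st
    }
  }
  pids <- vapply(cases, function(v) v$patient %||% "", "")
  if (any(pids == "")) pids <- sprintf("P%03d", seq_along(cases))
  split <- dataset_split(pids, seed = seed)
  list(studies = studies, split = split)
}

#' Studies belonging to one partition
#' @param dataset result of [build_dataset()]
#' @param part `"train"`, `"val"` or `"test"`
#' @return list of studies
#' @export
studies_in <- function(dataset, part) {
  ids <- dataset$split[[part]]
  Filter(function(s) s$patient %in% ids, dataset$studies)
}
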