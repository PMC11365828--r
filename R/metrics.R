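# Deformity measurement and reconstruction scoring.

#' Triangulate one landmark from its two detector positions
#'
#' Parallel mode: X comes from the frontal u, Y from the sagittal u, and Z
#' is the mean of the two v-derived heights (the views share the vertical
#' axis). Fan mode: the two detector pixels are back-projected to rays from
#' their per-row source positions and the least-squares midpoint of the two
#' skew rays is returned. The residual is the ray gap (mm): |z_f - z_s| in
#' parallel mode, the closest-approach distance in fan mode.
#'
#' @param uv_frontal,uv_sagittal `c(u, v)` 0-based pixel coordinates; NAs
#'   propagate to an NA point
#' @param geom_f,geom_s the two [projection_geometry()] objects
#' @return list with `point` (length-3 mm) and `residual` (mm)
#' @export
triangulate_landmark <- function(uv_frontal, uv_sagittal, geom_f, geom_s) {
  if (anyNA(uv_frontal) || anyNA(uv_sagittal))
    return(list(point = rep(NA_real_, 3), residual = NA_real_))
  if (geom_f$mode == "parallel" && geom_s$mode == "parallel") {
    x <- geom_f$cu + (uv_frontal[1] - (geom_f$nu - 1) / 2) * geom_f$su
    y <- geom_s$cu + (uv_sagittal[1] - (geom_s$nu - 1) / 2) * geom_s$su
    zf <- geom_f$cv - (uv_frontal[2] - (geom_f$nv - 1) / 2) * geom_f$sv
    zs <- geom_s$cv - (uv_sagittal[2] - (geom_s$nv - 1) / 2) * geom_s$sv
    return(list(point = c(x, y, (zf + zs) / 2), residual = abs(zf - zs)))
  }
  rayf <- backproject_ray(uv_frontal, geom_f)
  rays <- backproject_ray(uv_sagittal, geom_s)
  closest_point_rays(rayf, rays)
}

# origin + unit direction of the ray through a detector pixel
backproject_ray <- function(uv, geom) {
  z <- geom$cv - (uv[2] - (geom$nv - 1) / 2) * geom$sv
  umm <- geom$cu + (uv[1] - (geom$nu - 1) / 2) * geom$su
  if (geom$mode == "parallel") {
    o_u <- umm; o_r <- geom$iso_r + 1000; d_u <- 0; d_r <- -1
  } else {
    s_r <- geom$iso_r + geom$sad; d_det <- geom$iso_r - geom$add
    o_u <- geom$cu; o_r <- s_r
    dvec <- c(umm - geom$cu, d_det - s_r)
    dvec <- dvec / sqrt(sum(dvec^2))
    d_u <- dvec[1]; d_r <- dvec[2]
  }
  if (geom$view == "frontal")
    list(o = c(o_u, o_r, z), d = c(d_u, d_r, 0))
  else
    list(o = c(o_r, o_u, z), d = c(d_r, d_u, 0))
}

closest_point_rays <- function(r1, r2) {
  d1 <- r1$d; d2 <- r2$d; w <- r1$o - r2$o
  a <- sum(d1 * d1); b <- sum(d1 * d2); c2 <- sum(d2 * d2)
  d <- sum(d1 * w); e <- sum(d2 * w)
  den <- a * c2 - b * b
  if (abs(den) < 1e-12) stop("geometry error: near-parallel rays")
  s <- (b * e - c2 * d) / den
  t <- (a * e - b * d) / den
  p1 <- r1$o + s * d1; p2 <- r2$o + t * d2
  list(point = (p1 + p2) / 2, residual = norm3(p1 - p2))
}

#' Frontal-plane mechanical axis deviation
#'
#' Projects the hip, knee and ankle centers to the frontal (XZ) plane and
#' measures the deviation from collinearity of the hip-knee and knee-ankle
#' lines: 0 deg is a straight leg, positive is varus for the measured side
#' (lateral bowing of the knee).
#'
#' @param H,K,A 3D joint centers (mm)
#' @param side `"right"` or `"left"` (flips the varus sign)
#' @return signed angle in degrees
#' @export
mechanical_axis_angle <- function(H, K, A, side = "right") {
  if (norm3(H - K) < 1e-9 || norm3(A - K) < 1e-9)
    stop("degenerate error: coincident joint centers")
  hk <- (H - K)[c(1, 3)]; ak <- (A - K)[c(1, 3)]
  dev <- 180 - angle_between(hk, ak)
  u <- unit3(c((A - H)[1], 0, (A - H)[3]))
  w <- c((K - H)[1], 0, (K - H)[3])
  perp <- w - sum(w * u) * u
  sgn <- sign(perp[1]) * (if (side == "right") 1 else -1)
  if (sgn == 0) sgn <- 1
  sgn * dev
}

#' Fit the articular surface plane of a proximal tibia mesh
#'
#' Candidate vertices lie within `band_mm` of the most superior vertex and
#' carry outward normals within `cone_deg` of +Z; the plane is the total
#' least squares fit (smallest singular direction) through them, with its
#' normal oriented superiorly. The RMS point-plane residual is exposed as a
#' quality flag because articular-plane fitting is the dominant failure
#' mode of slope measurement.
#'
#' @param mesh a `trimesh` of the proximal tibia
#' @param K knee joint center (used only for sanity checks)
#' @param band_mm vertical band below the most superior vertex
#' @param cone_deg half-angle of the upward normal cone
#' @return list with `point`, `normal` (unit, superior), `residual` (mm,
#'   RMS), `n_candidates`
#' @export
fit_plateau_plane <- function(mesh, K = NULL, band_mm = 8, cone_deg = 30) {
  vn <- vertex_normals(mesh)
  ztop <- max(mesh$vertices[, 3])
  keep <- mesh$vertices[, 3] >= ztop - band_mm &
    vn[, 3] > cos(deg2rad(cone_deg))
  if (sum(keep) < 10) stop("fitting error: too few plateau candidate vertices")
  pts <- mesh$vertices[keep, , drop = FALSE]
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  n <- sv$v[, 3]
  if (n[3] < 0) n <- -n
  res <- sqrt(mean((sweep(pts, 2, ctr) %*% n)^2))
  structure(list(point = ctr, normal = n, residual = res,
                 n_candidates = sum(keep)), class = "plane")
}

#' @export
print.plane <- function(x, ...) {
  cat("<plane> normal (", paste(round(x$normal, 3), collapse = ", "),
      "), residual ", round(x$residual, 3), " mm, n = ", x$n_candidates,
      "\n", sep = "")
  invisible(x)
}

#' Tibial slope from the plateau plane and the tibial mechanical axis
#'
#' Projects the plane normal and the knee-to-ankle line to the sagittal
#' (YZ) plane and returns the signed angle between the projections,
#' positive for posterior inclination of the plateau.
#'
#' @param plane result of [fit_plateau_plane()] (or any list with `normal`)
#' @param K,A knee and ankle joint centers (mm)
#' @return signed angle in degrees
#' @export
tibial_slope <- function(plane, K, A) {
  a <- (K - A)[2:3]
  n <- plane$normal[2:3]
  if (sqrt(sum(a^2)) < 1e-9 || sqrt(sum(n^2)) < 1e-9)
    stop("degenerate error: zero-length sagittal projection")
  rad2deg(atan2(a[1] * n[2] - a[2] * n[1], sum(a * n)))
}

#' Per-landmark Euclidean errors
#'
#' @param pred,truth named lists of points (2D px or 3D mm); names are
#'   matched, missing predictions are reported as NA with a warning
#' @return data.frame with landmark, error, plus mean/sd attributes
#' @export
landmark_errors <- function(pred, truth) {
  nms <- names(truth)
  err <- vapply(nms, function(nm) {
    p <- pred[[nm]]
    if (is.null(p) || anyNA(p)) return(NA_real_)
    sqrt(sum((as.numeric(p) - as.numeric(truth[[nm]]))^2))
  }, 0)
  if (anyNA(err)) warning("missing landmarks excluded from the summary")
  out <- data.frame(landmark = nms, error = unname(err))
  attr(out, "mean") <- mean(err, na.rm = TRUE)
  attr(out, "sd") <- stats::sd(err, na.rm = TRUE)
  out
}

#' Measure MA and TS of one leg from landmarks and (optionally) a mesh
#'
#' @param landmarks list with `HC`, `KC`, `AC` 3D points
#' @param mesh optional proximal tibia `trimesh` for the slope plane
#' @param side leg side for the varus sign
#' @param ... passed to [fit_plateau_plane()]
#' @return list with `MA` (deg), `TS` (deg or NA without a mesh),
#'   `plane` (or NULL)
#' @export
measure_deformity <- function(landmarks, mesh = NULL, side = "right", ...) {
  MA <- mechanical_axis_angle(landmarks$HC, landmarks$KC, landmarks$AC, side)
  TS <- NA_real_; plane <- NULL
  if (!is.null(mesh)) {
    plane <- fit_plateau_plane(mesh, landmarks$KC, ...)
    TS <- tibial_slope(plane, landmarks$KC, landmarks$AC)
  }
  list(MA = MA, TS = TS, plane = plane)
}
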