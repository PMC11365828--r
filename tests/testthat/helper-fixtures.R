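# Shared fixtures, built once per test run. Everything is generated in code
# at small scale; geometry defaults (128 px at 3.5 mm) match the desk preset.

.fix <- new.env()

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

fix_subject <- function() fixture("subject", function() {
  generate_subject(phantom_params(varus_angle = 4, slope_angle = 6),
                   phantom_params(varus_angle = 7, slope_angle = 8),
                   seed = 42)
})

fix_geoms <- function() fixture("geoms", function() {
  list(f = projection_geometry("frontal"),
       s = projection_geometry("sagittal"))
})

fix_study <- function() fixture("study", function() {
  g <- fix_geoms()
  st <- make_study(fix_subject(), g$f, g$s)
  st$volume <- fix_subject()
  st
})

# coarse two-leg subject for augmentation-heavy loops
fix_coarse_subject <- function() fixture("coarse", function() {
  generate_subject(phantom_params(voxel_spacing = 8),
                   phantom_params(voxel_spacing = 8, varus_angle = 6),
                   seed = 7)
})

# proximal tibia mesh of the fixture subject's right leg at fine spacing
fix_tibia_mesh <- function() fixture("tibia_mesh", function() {
  p <- phantom_params(varus_angle = 7, slope_angle = 8, voxel_spacing = 1.5)
  lg <- generate_leg(p, "right")
  mask <- proximal_tibia_mask(lg$volume, "right", span = 110)
  marching_cubes(mask * 1, spacing = lg$volume$spacing,
                 origin = lg$volume$origin)
})

# independent brute-force oracles (plain loops, no package internals)

oracle_gradient_images <- function(img) {
  nv <- nrow(img); nu <- ncol(img)
  gx <- matrix(0, nv, nu); gy <- matrix(0, nv, nu)
  for (i in seq_len(nv)) for (j in seq_len(nu)) {
    if (j > 1 && j < nu) gx[i, j] <- (img[i, j + 1] - img[i, j - 1]) / 2
    if (i > 1 && i < nv) gy[i, j] <- (img[i + 1, j] - img[i - 1, j]) / 2
  }
  list(gx = gx, gy = gy)
}

oracle_ncc <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  num <- 0; da <- 0; db <- 0
  for (i in seq_along(a)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  num / (sqrt(da) * sqrt(db))
}

oracle_gc <- function(y, yhat) {
  g1 <- oracle_gradient_images(y); g2 <- oracle_gradient_images(yhat)
  0.5 * (oracle_ncc(g1$gx, g2$gx) + oracle_ncc(g1$gy, g2$gy))
}

oracle_bce <- function(y, yhat, eps = 1e-7) {
  s <- 0
  for (i in seq_along(y)) {
    p <- min(max(yhat[i], eps), 1 - eps)
    s <- s + y[i] * log(p) + (1 - y[i]) * log(1 - p)
  }
  -s / length(y)
}

oracle_dice_ce <- function(y, yhat, eps = 1e-7) {
  total <- 0
  for (c in seq_len(ncol(y))) {
    num <- 2 * sum(y[, c] * yhat[, c])
    den <- sum(y[, c]) + sum(yhat[, c])
    total <- total + (1 - if (den > 0) num / den else 1)
  }
  ce <- 0
  for (i in seq_len(nrow(y))) for (c in seq_len(ncol(y)))
    ce <- ce - y[i, c] * log(min(max(yhat[i, c], eps), 1 - eps))
  as.numeric(total + ce / nrow(y))
}

# intersection of the ray from a fan source through p with the detector plane
oracle_fan_u <- function(p, geom) {
  s_r <- geom$iso_r + geom$sad
  d_r <- geom$iso_r - geom$add
  pu <- if (geom$view == "frontal") p[1] else p[2]
  pr <- if (geom$view == "frontal") p[2] else p[1]
  t <- (s_r - d_r) / (s_r - pr)
  umm <- geom$cu + t * (pu - geom$cu)
  (umm - geom$cu) / geom$su + (geom$nu - 1) / 2
}
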