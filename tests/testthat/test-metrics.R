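test_that("triangulation round-trips projected points", {
  g <- fix_geoms()
  set.seed(21)
  for (i in 1:25) {
    p <- c(runif(1, -150, 150), runif(1, -60, 60), runif(1, -180, 180))
    tr <- triangulate_landmark(project_point(p, g$f), project_point(p, g$s),
                               g$f, g$s)
    expect_lt(max(abs(tr$point - p)), 1e-9)
  }
  gf <- projection_geometry("frontal", "fan")
  gs <- projection_geometry("sagittal", "fan")
  for (i in 1:25) {
    p <- c(runif(1, -150, 150), runif(1, -60, 60), runif(1, -180, 180))
    tr <- triangulate_landmark(project_point(p, gf), project_point(p, gs),
                               gf, gs)
    expect_lt(max(abs(tr$point - p)), 0.01)
    expect_lt(tr$residual, 1e-9)
  }
  # axis decoupling: 1 px frontal u moves X by one pixel spacing only
  p <- c(10, 20, 30)
  uvf <- project_point(p, g$f); uvs <- project_point(p, g$s)
  t1 <- triangulate_landmark(uvf, uvs, g$f, g$s)
  t2 <- triangulate_landmark(uvf + c(1, 0), uvs, g$f, g$s)
  expect_equal(t2$point[1] - t1$point[1], g$f$su, ignore_attr = TRUE)
  expect_equal(t2$point[2], t1$point[2])
  # missing landmarks propagate as NA
  tna <- triangulate_landmark(c(NA, NA), uvs, g$f, g$s)
  expect_true(all(is.na(tna$point)))
})

test_that("mechanical axis angle recovers the constructed deformity", {
  H <- c(0, 0, 400); K <- c(0, 0, 0); A <- c(0, 0, -380)
  expect_equal(mechanical_axis_angle(H, K, A), 0)
  # anterior offset of the knee is invisible in the frontal projection
  expect_equal(mechanical_axis_angle(H, c(0, 25, 0), A, "right"), 0)
  lg <- generate_leg(phantom_params(varus_angle = 7), "right")
  lm <- lg$volume$landmarks$right
  expect_equal(mechanical_axis_angle(lm$HC, lm$KC, lm$AC, "right"), 7,
               tolerance = 1e-6)
  lgl <- generate_leg(phantom_params(varus_angle = 5), "left")
  lml <- lgl$volume$landmarks$left
  expect_equal(mechanical_axis_angle(lml$HC, lml$KC, lml$AC, "left"), 5,
               tolerance = 1e-6)
  # rigid translation and uniform scaling invariance
  off <- c(12, -7, 31)
  expect_equal(mechanical_axis_angle(lm$HC + off, lm$KC + off, lm$AC + off,
                                     "right"), 7, tolerance = 1e-6)
  expect_equal(mechanical_axis_angle(lm$HC * 2, lm$KC * 2, lm$AC * 2,
                                     "right"), 7, tolerance = 1e-6)
  expect_error(mechanical_axis_angle(K, K, A), "degenerate")
})

test_that("plateau plane fitting recovers the constructed slope", {
  for (slope in c(0, 5)) {
    p <- phantom_params(varus_angle = 0, slope_angle = slope,
                        voxel_spacing = 1.5)
    lg <- generate_leg(p, "right")
    mask <- proximal_tibia_mask(lg$volume, "right", span = 110)
    mesh <- marching_cubes(mask * 1, spacing = lg$volume$spacing,
                           origin = lg$volume$origin)
    pl <- fit_plateau_plane(mesh)
    tilt <- acos(min(1, pl$normal[3])) * 180 / pi
    expect_equal(tilt, slope, tolerance = 0.5)
    # least-squares plane passes near the candidate centroid
    expect_lt(abs(sum((pl$point - pl$point) * pl$normal)), 1e-9)
    expect_gt(pl$n_candidates, 10)
  }
  expect_error(fit_plateau_plane(trimesh(diag(3), matrix(1:3, 1))),
               "fitting error")
})

test_that("tibial slope is a signed sagittal-plane angle", {
  K <- c(0, 0, 0); A <- c(0, 0, -380)
  expect_equal(tibial_slope(list(normal = c(0, 0, 1)), K, A), 0)
  phi <- 8
  n <- c(0, -sin(phi * pi / 180), cos(phi * pi / 180))
  expect_equal(tibial_slope(list(normal = n), K, A), phi, tolerance = 1e-9)
  # medial-lateral tilt does not change the sagittal projection angle
  n2 <- n + c(0.3, 0, 0)
  expect_equal(tibial_slope(list(normal = n2), K, A), phi, tolerance = 1e-9)
  # end-to-end: constructed slope 8 recovered through the plane fit
  lg <- generate_leg(phantom_params(slope_angle = 8, voxel_spacing = 1.5),
                     "right")
  mask <- proximal_tibia_mask(lg$volume, "right", span = 110)
  mesh <- marching_cubes(mask * 1, spacing = lg$volume$spacing,
                         origin = lg$volume$origin)
  lm <- lg$volume$landmarks$right
  ts <- tibial_slope(fit_plateau_plane(mesh), lm$KC, lm$AC)
  expect_equal(ts, 8, tolerance = 0.5)
  expect_error(tibial_slope(list(normal = c(1, 0, 0)), K,
                            c(0, 0, 0)), "degenerate")
})

test_that("isosurface extraction is watertight and metrically accurate", {
  r <- 20
  xs <- seq(-25, 25, by = 1)
  n <- length(xs)
  d2 <- outer(xs^2, outer(xs^2, xs^2, `+`), `+`)
  mask <- array(as.numeric(d2 <= r^2), c(n, n, n))
  mesh <- marching_cubes(mask, spacing = c(1, 1, 1), origin = c(-25, -25, -25))
  expect_equal(mesh_area(mesh), 4 * pi * r^2, tolerance = 0.03)
  expect_equal(euler_characteristic(mesh), 2)
  # vertices inside the dilated foreground bounding box
  expect_true(all(abs(mesh$vertices) <= r + 2))
  # a single voxel produces a small closed surface
  sv <- array(0, c(5, 5, 5)); sv[3, 3, 3] <- 1
  ms <- marching_cubes(sv)
  expect_equal(euler_characteristic(ms), 2)
  expect_error(marching_cubes(array(0, c(4, 4, 4))), "empty-mesh")
})

test_that("dice matches the counting oracle and its closed forms", {
  set.seed(22)
  A <- array(runif(16^3) > 0.5, c(16, 16, 16))
  B <- array(runif(16^3) > 0.5, c(16, 16, 16))
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(A)) {
    inter <- inter + (A[i] && B[i]); na <- na + A[i]; nb <- nb + B[i]
  }
  expect_equal(dice_score(A, B), 2 * inter / (na + nb), tolerance = 1e-12)
  expect_equal(dice_score(A, B), dice_score(B, A))
  expect_equal(dice_score(A, A), 1)
  expect_equal(dice_score(A, !A), 0)
  expect_equal(dice_score(A * 0, A * 0), 1)
  # analytic overlap of two boxes: 2*overlap/(n1+n2)
  X <- array(0, c(10, 10, 10)); Y <- array(0, c(10, 10, 10))
  X[1:6, , ] <- 1; Y[4:10, , ] <- 1
  expect_equal(dice_score(X, Y), 2 * 300 / (600 + 700))
  expect_error(dice_score(X, array(0, c(5, 5, 5))), "shape")
})

test_that("mean surface distance matches analytic offsets and is asymmetric", {
  xs <- seq(-25, 25, by = 1); n <- length(xs)
  d2 <- outer(xs^2, outer(xs^2, xs^2, `+`), `+`)
  outer_m <- marching_cubes(array(as.numeric(d2 <= 20^2), c(n, n, n)),
                            spacing = c(1, 1, 1), origin = c(-25, -25, -25))
  inner_m <- marching_cubes(array(as.numeric(d2 <= 17^2), c(n, n, n)),
                            spacing = c(1, 1, 1), origin = c(-25, -25, -25))
  expect_equal(mean_surface_distance(inner_m, outer_m), 3, tolerance = 0.02)
  expect_equal(mean_surface_distance(outer_m, outer_m), 0, tolerance = 1e-9)
  # spatially indexed query agrees exactly with the brute-force scan
  expect_equal(mean_surface_distance(inner_m, outer_m),
               mean_surface_distance(inner_m, outer_m, method = "brute"),
               tolerance = 1e-12)
  # asymmetry when extents differ
  half <- inner_m
  keep <- half$vertices[, 3] <= 0
  half$vertices[!keep, 3] <- 0
  expect_false(isTRUE(all.equal(mean_surface_distance(half, outer_m),
                                mean_surface_distance(outer_m, half))))
})

test_that("landmark errors follow the Euclidean definition", {
  truth <- list(HC = c(0, 0, 0), KC = c(1, 2, 2), AC = c(5, 5, 5))
  expect_equal(landmark_errors(truth, truth)$error, c(0, 0, 0))
  pred <- list(HC = c(3, 4, 0), KC = c(1, 2, 2), AC = c(5, 5, 5))
  expect_equal(landmark_errors(pred, truth)$error[1], 5)
  set.seed(23)
  pr <- lapply(truth, function(p) p + rnorm(3))
  le <- landmark_errors(pr, truth)
  for (i in 1:3)
    expect_equal(le$error[i],
                 sqrt(sum((pr[[i]] - truth[[i]])^2)), tolerance = 1e-12)
  expect_warning(le2 <- landmark_errors(pred[1:2], truth), "missing")
  expect_true(is.na(le2$error[3]))
})

test_that("mesh IO round-trips through STL", {
  m <- fixture("tiny_mesh", function() {
    sv <- array(0, c(6, 6, 6)); sv[3:4, 3:4, 3:4] <- 1
    marching_cubes(sv)
  })
  f <- tempfile(fileext = ".stl")
  write_stl(m, f)
  m2 <- read_stl(f)
  expect_equal(nrow(m2$faces), nrow(m$faces))
  expect_equal(mesh_area(m2), mesh_area(m), tolerance = 1e-6)
})
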