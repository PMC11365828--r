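test_that("constructed ground truth matches the deformity parameters", {
  straight <- generate_leg(phantom_params(varus_angle = 0, slope_angle = 0),
                           "right")
  expect_equal(straight$truth$MA_true, 0)
  expect_equal(straight$truth$TS_true, 0)
  lm <- straight$volume$landmarks$right
  # collinear joint centers in the frontal plane
  hk <- (lm$HC - lm$KC)[c(1, 3)]; ak <- (lm$AC - lm$KC)[c(1, 3)]
  expect_lt(abs(hk[1] * ak[2] - hk[2] * ak[1]) /
              (sqrt(sum(hk^2)) * sqrt(sum(ak^2))), 1e-12)

  varus <- generate_leg(phantom_params(varus_angle = 7), "right")
  lm <- varus$volume$landmarks$right
  hk <- (lm$HC - lm$KC)[c(1, 3)]; ak <- (lm$AC - lm$KC)[c(1, 3)]
  ang <- acos(sum(hk * ak) / sqrt(sum(hk^2) * sum(ak^2))) * 180 / pi
  expect_equal(ang, 180 - 7, tolerance = 1e-9)
})

test_that("construction/measurement consistency holds across parameters", {
  for (v in c(-12, -3, 0.5, 9, 18)) {
    lg <- generate_leg(phantom_params(varus_angle = v), "left")
    lm <- lg$volume$landmarks$left
    hk <- (lm$HC - lm$KC)[c(1, 3)]; ak <- (lm$AC - lm$KC)[c(1, 3)]
    ang <- acos(sum(hk * ak) / sqrt(sum(hk^2) * sum(ak^2))) * 180 / pi
    expect_equal(ang, 180 - abs(v), tolerance = 1e-6)
    expect_true(lm$HC[3] > lm$KC[3] && lm$KC[3] > lm$AC[3])
  }
})

test_that("parameter validation rejects out-of-range phantoms", {
  expect_error(phantom_params(varus_angle = 25))
  expect_error(phantom_params(slope_angle = -1))
  expect_error(phantom_params(bone_intensity = 0.2, soft_intensity = 0.5))
  expect_error(phantom_params(tibia_radius = -1))
})

test_that("voxelization conserves analytic primitive volume", {
  # a single cylinder voxelized at fine spacing carries pi r^2 L of voxels
  cyl <- osteoplan:::prim_cylinder(c(0, 0, 0), c(0, 0, 100), 14,
                                   "right", "tibia", 2L, 1)
  for (r in c(10, 14, 20)) {
    cyl$r <- r
    vol <- osteoplan:::voxelize_scene(list(cyl), spacing = 1)
    count <- sum(vol$labels == 2L)
    expect_equal(count * 1, pi * r^2 * 100, tolerance = 0.05)
  }
})

test_that("two-leg subjects keep the legs disjoint and symmetric", {
  sub <- fix_subject()
  right <- sub$labels %in% c(1L, 2L)
  left <- sub$labels %in% c(11L, 12L)
  expect_equal(sum(right & left), 0)
  expect_true(all(c("left", "right") %in% names(sub$landmarks)))

  # mirrored parameters give landmark X symmetry about the midline
  p <- phantom_params(varus_angle = 5)
  sym <- generate_subject(p, p, seed = 1)
  for (nm in c("HC", "KC", "AC")) {
    expect_lt(abs(sym$landmarks$left[[nm]][1] +
                    sym$landmarks$right[[nm]][1]), p$voxel_spacing)
    expect_equal(sym$landmarks$left[[nm]][3], sym$landmarks$right[[nm]][3])
  }
})

test_that("zero stance separation raises a placement error", {
  expect_error(generate_subject(phantom_params(), phantom_params(),
                                stance_separation = 0),
               "overlap")
})

test_that("subjects are bit-identical under a fixed seed", {
  p1 <- phantom_params(varus_angle = 3)
  a <- generate_subject(p1, p1, seed = 5)
  b <- generate_subject(p1, p1, seed = 5)
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$labels, b$labels)
})

test_that("cohort draws are recorded and reproducible", {
  co <- generate_cohort(4, phantom_params(voxel_spacing = 8), seed = 21)
  expect_length(co$cases, 4)
  expect_equal(nrow(co$manifest), 4)
  expect_true(all(co$manifest$varus_angle_left >= 2 &
                    co$manifest$varus_angle_left <= 12))
  co2 <- generate_cohort(4, phantom_params(voxel_spacing = 8), seed = 21)
  expect_identical(co$manifest, co2$manifest)
  co3 <- generate_cohort(4, phantom_params(voxel_spacing = 8), seed = 22)
  expect_false(identical(co$manifest$varus_angle_left,
                         co3$manifest$varus_angle_left))
  # single-case cohort equals generate_subject with the drawn parameters
  co1 <- generate_cohort(1, phantom_params(voxel_spacing = 8), seed = 21)
  expect_identical(co1$cases[[1]]$intensity, co$cases[[1]]$intensity)
})

test_that("proximal tibia mask is tibia-only and knee-local", {
  sub <- fix_subject()
  m <- proximal_tibia_mask(sub, "right", span = 120)
  expect_true(all(sub$labels[m] == 2L))
  K <- sub$landmarks$right$KC
  dims <- dim(m)
  idx <- which(m, arr.ind = TRUE)
  pts <- sweep(sweep(idx - 1, 2, sub$spacing, `*`), 2, sub$origin, `+`)
  expect_true(all(sqrt(rowSums(sweep(pts, 2, K)^2)) <= 120 + 1e-9))
})
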