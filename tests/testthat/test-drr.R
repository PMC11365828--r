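test_that("parallel projection integrates path length exactly", {
  # homogeneous box: interior pixels see the full box thickness
  box <- osteoplan:::prim_slab(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                               c(0, 0, 1), 60, 60, 60, "right", "soft",
                               0L, 1)
  vol <- osteoplan:::voxelize_scene(list(box), spacing = 2)
  g <- projection_geometry("frontal", detector_size = c(64, 64),
                           pixel_spacing = 2, center = c(0, 0), step = 2)
  rad <- project(vol, g, normalize = FALSE)
  c1 <- rad$pixels[32, 32]; c2 <- rad$pixels[30, 34]
  expect_gt(c1, 0)
  expect_lt(abs(c1 - c2), 1e-12)
  # linearity before normalization
  vol2 <- vol; vol2$intensity <- vol$intensity * 0.3
  r2 <- project(vol2, g, normalize = FALSE)
  expect_equal(r2$pixels, 0.3 * rad$pixels, tolerance = 1e-10)
})

test_that("empty volumes project to all-zero images", {
  box <- osteoplan:::prim_sphere(c(0, 0, 0), 10, "right", "soft", 0L, 1)
  vol <- osteoplan:::voxelize_scene(list(box), spacing = 2)
  vol$intensity[] <- 0
  g <- projection_geometry("frontal", detector_size = c(16, 16),
                           pixel_spacing = 4, center = c(0, 0))
  expect_true(all(project(vol, g)$pixels == 0))
})

test_that("fan projection localizes a bright voxel where project_point says", {
  vol <- osteoplan:::voxelize_scene(
    list(osteoplan:::prim_sphere(c(30, -20, 40), 6, "right", "soft", 0L, 1)),
    spacing = 2, margin = 30)
  vol$intensity[] <- 0
  vol$intensity[11, 9, 13] <- 1
  ctr <- vol$origin + c(10, 8, 12) * vol$spacing
  g <- projection_geometry("frontal", "fan", detector_size = c(128, 128),
                           pixel_spacing = 1, center = c(30, 40), step = 0.5)
  rad <- project(vol, g)
  pk <- which(rad$pixels == max(rad$pixels), arr.ind = TRUE)[1, ]
  uv <- project_point(ctr, g)
  expect_lt(abs((pk[2] - 1) - uv["u"]), 1.1)
  expect_lt(abs((pk[1] - 1) - uv["v"]), 1.1)
})

test_that("project_point obeys the biplanar geometry", {
  g <- fix_geoms()
  # central-axis point maps to the detector center
  uv <- project_point(c(0, -50, 10), g$f)
  expect_equal(unname(uv["u"]), (g$f$nu - 1) / 2)
  # moving-emitter property: Z does not change u (fan mode)
  gf <- projection_geometry("frontal", "fan")
  u1 <- project_point(c(55, 30, 0), gf)["u"]
  u2 <- project_point(c(55, 30, 333), gf)["u"]
  expect_equal(u1, u2)
  # fan u matches an independent ray/plane intersection oracle
  set.seed(3)
  for (i in 1:20) {
    p <- c(runif(1, -150, 150), runif(1, -80, 80), runif(1, -200, 200))
    expect_equal(unname(project_point(p, gf)["u"]), oracle_fan_u(p, gf),
                 tolerance = 1e-9)
  }
  # shared vertical axis: equal v in both views
  for (i in 1:10) {
    p <- c(runif(1, -100, 100), runif(1, -60, 60), runif(1, -150, 150))
    expect_equal(project_point(p, g$f)["v"], project_point(p, g$s)["v"],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(project_point(c(0, 2000, 0), gf), "behind")
})

test_that("masked projection matches the single-bone volume", {
  sub <- fix_subject()
  g <- fix_geoms()$f
  masked <- project(sub, g, mask = 2L, normalize = FALSE)
  only <- sub
  only$intensity <- sub$intensity * (sub$labels == 2L)
  direct <- project(only, g, normalize = FALSE)
  expect_equal(masked$pixels, direct$pixels)
})

test_that("right-leg augmentation draws stay in the stated ranges", {
  sub <- fix_coarse_subject()
  set.seed(99)
  shifts <- numeric(200); rots <- numeric(200)
  for (i in 1:200) {
    av <- augment_right_leg(sub)
    shifts[i] <- av$augmentation$shift
    rots[i] <- av$augmentation$rotation
  }
  expect_true(all(shifts >= 40 & shifts <= 60))
  expect_true(all(abs(rots) >= 10 & abs(rots) <= 20))
  expect_true(any(rots > 0) && any(rots < 0))
})

test_that("augmentation moves only the right leg and records itself", {
  sub <- fix_subject()
  g <- fix_geoms()
  av <- augment_right_leg(sub, shift = 45, rotation = 0)
  expect_equal(av$landmarks$right$AC[2] - sub$landmarks$right$AC[2], 45)
  for (nm in c("HC", "KC", "AC")) {
    expect_equal(av$landmarks$left[[nm]], sub$landmarks$left[[nm]])
    expect_equal(project_point(av$landmarks$left[[nm]], g$f),
                 project_point(sub$landmarks$left[[nm]], g$f),
                 tolerance = 1e-12)
  }
  av0 <- augment_right_leg(sub, shift = 0, rotation = 0)
  expect_identical(av0$intensity, sub$intensity)
  expect_identical(av0$labels, sub$labels)
})

test_that("contrast enhancement follows the sigmoid transform", {
  expect_equal(contrast_enhance(0.45), 0.5)
  xs <- seq(0, 1, length.out = 1000)
  fx <- contrast_enhance(xs)
  expect_true(all(diff(fx) > 0))
  expect_equal(contrast_enhance(0), 1 / (1 + exp(0.45 / 0.12)),
               tolerance = 1e-12)
  expect_equal(contrast_enhance(1), 1 / (1 + exp(-(1 - 0.45) / 0.12)),
               tolerance = 1e-12)
})

test_that("studies carry separated targets, landmarks and silhouettes", {
  st <- fix_study()
  sub <- fix_subject()
  g <- fix_geoms()
  # two disjoint leg silhouettes in the frontal image
  cols <- which(apply(st$I_fron$pixels > 0.25, 2, any))
  expect_true(any(diff(cols) > 5))
  # single-leg sagittal support is inside the full sagittal support
  raw_r <- project(osteoplan:::side_volume(sub, "right"), g$s,
                   normalize = FALSE)
  raw_full <- project(sub, g$s, normalize = FALSE)
  expect_true(all(raw_full$pixels[raw_r$pixels > 0] > 0))
  # the projected right knee lands inside the right tibia silhouette
  sil <- project(sub, g$f, mask = 2L)
  kc <- st$landmarks2d$frontal$right$KC
  expect_gt(sil$pixels[round(kc["v"]) + 1, round(kc["u"]) + 1], 0)
  # frontal carries 6 landmarks, each sagittal side 3
  expect_length(unlist(st$landmarks2d$frontal, recursive = FALSE), 6)
  expect_length(st$landmarks2d$sagittal$right, 3)
})

test_that("heatmaps are unit-peak Gaussians with exact argmax", {
  set.seed(5)
  for (i in 1:10) {
    lm <- c(u = runif(1, 2, 29), v = runif(1, 2, 29))
    hm <- make_heatmaps(list(p = lm), sigma = 3, shape = c(32, 32))
    expect_equal(max(hm), 1)
    pk <- which(hm[, , 1] == 1, arr.ind = TRUE)
    expect_equal(unname(pk[1, ]), unname(c(round(lm["v"]) + 1,
                                           round(lm["u"]) + 1)))
  }
  hm <- make_heatmaps(list(p = c(u = 10, v = 12)), sigma = 4,
                      shape = c(32, 32))
  expect_equal(hm[13, 11 + 4, 1], exp(-0.5), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(make_heatmaps(list(p = c(5, 5)), sigma = 0, shape = c(8, 8)),
               "sigma")
})

test_that("dataset split is patient-level with the stated arithmetic", {
  ids <- sprintf("P%02d", 1:10)
  sp <- dataset_split(ids, seed = 4)
  expect_length(sp$test, 1)
  expect_length(sp$val, 2)
  expect_length(sp$train, 7)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_error(dataset_split(c("a", "b"), 1), "split error")
  sp175 <- dataset_split(sprintf("P%03d", 1:175), seed = 1)
  expect_length(sp175$test, 18)
  expect_length(sp175$val, 31)
  expect_length(sp175$train, 126)
})

test_that("build_dataset produces n_aug studies per patient, one partition each", {
  co <- generate_cohort(4, phantom_params(voxel_spacing = 8), seed = 31)
  g32 <- function(v) projection_geometry(v, detector_size = c(32, 32),
                                         pixel_spacing = 14)
  ds <- build_dataset(co, n_aug = 2, seed = 32,
                      geom_frontal = g32("frontal"),
                      geom_sagittal = g32("sagittal"))
  expect_length(ds$studies, 8)
  pids <- unique(vapply(ds$studies, function(s) s$patient, ""))
  for (p in pids)
    expect_equal(sum(vapply(list(ds$split$train, ds$split$val, ds$split$test),
                            function(x) p %in% x, TRUE)), 1)
  expect_error(build_dataset(co$cases[1:2], n_aug = 1, seed = 1,
                             geom_frontal = g32("frontal"),
                             geom_sagittal = g32("sagittal")),
               "split error")
})
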