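gt_case <- function() fixture("gt_case", function() {
  st <- fix_study()
  ground_truth_case(st, "right")
})

test_that("zero opening angle is the identity correction", {
  case <- gt_case()
  pre <- measure_deformity(case$landmarks, case$mesh, "right")
  plan <- osteotomy_plan(c(case$landmarks$KC[1] + 8,
                           case$landmarks$KC[3] - 25, 0, 0,
                           0, 0, case$landmarks$KC[1] - 30,
                           case$landmarks$KC[2], case$landmarks$KC[3] - 40,
                           0, 0, 0), side = "right")
  sim <- simulate_correction(case$landmarks, case$mesh, plan)
  expect_equal(sim$achieved$MA, pre$MA, tolerance = 1e-9)
  expect_equal(sim$landmarks$AC, case$landmarks$AC)
  expect_equal(sim$mesh$vertices, case$mesh$vertices)
})

test_that("axis orientation decouples frontal and sagittal corrections", {
  case <- gt_case()
  pre <- measure_deformity(case$landmarks, case$mesh, "right")
  # hinge at the knee's frontal position: the knee-ankle line rotates by
  # exactly the opening angle
  base <- c(case$landmarks$KC[1], case$landmarks$KC[3], 0, 0,
            6, 0, case$landmarks$KC[1] - 30, case$landmarks$KC[2],
            case$landmarks$KC[3] - 40, 0, 0, 0)
  # pure anterior-posterior axis: frontal-plane rotation only
  simY <- simulate_correction(case$landmarks, case$mesh,
                              osteotomy_plan(base, "right"))
  expect_equal(abs(simY$achieved$MA - pre$MA), 6, tolerance = 0.1)
  expect_equal(simY$achieved$TS, pre$TS, tolerance = 0.1)
  # opening reduces varus (the medial wedge straightens the leg)
  expect_lt(simY$achieved$MA, pre$MA)
  # pure medial-lateral axis: sagittal-plane rotation only
  baseX <- base; baseX[3] <- 90
  simX <- simulate_correction(case$landmarks, case$mesh,
                              osteotomy_plan(baseX, "right"))
  expect_equal(abs(simX$achieved$TS - pre$TS), 6, tolerance = 0.1)
  expect_equal(simX$achieved$MA, pre$MA, tolerance = 0.1)
})

test_that("the moved fragment is transformed rigidly", {
  case <- gt_case()
  plan <- osteotomy_plan(c(case$landmarks$KC[1] + 8,
                           case$landmarks$KC[3] - 25, 0, 0, 9, 5,
                           rep(0, 6)), side = "right")
  sim <- simulate_correction(case$landmarks, case$mesh, plan)
  idx <- which(sim$moved)
  expect_gt(length(idx), 10)
  pick <- idx[round(seq(1, length(idx), length.out = 12))]
  d0 <- as.matrix(dist(case$mesh$vertices[pick, ]))
  d1 <- as.matrix(dist(sim$mesh$vertices[pick, ]))
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("fitness reflects targets and plate placement", {
  case <- gt_case()
  targets <- planning_targets(MA = 0, TS = 5)
  K <- case$landmarks$KC
  x <- c(K[1] + 8, K[3] - 25, 0, 0, 7, 0,
         K[1] - 28, K[2], K[3] - 45, 0, 0, 0)
  f0 <- plan_fitness(osteotomy_plan(x, "right"), case, targets)
  expect_true(all(is.finite(f0)))
  expect_true(all(f0 >= 0))
  # moving the plate 5 mm further from the bone raises the gap by ~5
  x5 <- x; x5[7] <- x5[7] - 5
  f5 <- plan_fitness(osteotomy_plan(x5, "right"), case, targets)
  expect_equal(f5["plate_gap"] - f0["plate_gap"], 5, tolerance = 0.8,
               ignore_attr = TRUE)
  # a plan with the hinge far outside the bone is infeasible
  xbad <- x; xbad[1] <- K[1] + 200
  expect_true(all(is.infinite(
    plan_fitness(osteotomy_plan(xbad, "right"), case, targets))))
  # over-opening beyond the exact plan increases the MA deviation
  xov <- x; xov[5] <- x[5] + 4
  fov <- plan_fitness(osteotomy_plan(xov, "right"), case, targets)
  expect_gt(fov["dMA"], f0["dMA"])
})

test_that("constraint rules report individually and honor thresholds", {
  case <- gt_case()
  K <- case$landmarks$KC
  slab <- abs(case$mesh$vertices[, 3] - (K[3] - 40)) <= 6
  med_x <- min(case$mesh$vertices[slab, 1])
  good <- osteotomy_plan(c(K[1], K[3] - 25, 0, 0, 7, 0,
                           med_x - 2, K[2], K[3] - 40, 0, 0, 0), "right")
  rep1 <- check_constraints(good, case)
  expect_equal(nrow(rep1), 3)
  expect_true(attr(rep1, "feasible"))
  # a cut through the plateau violates the depth rule
  high <- good; high$par["axis_si"] <- K[3] + 2
  rep2 <- check_constraints(high, case)
  expect_false(rep2$pass[rep2$rule == "plane_below_plateau"])
  # raising d_min flips a boundary case
  depth <- rep1$value[rep1$rule == "plane_below_plateau"]
  rep3 <- check_constraints(good, case,
                            rules = list(h_min = 10, d_min = depth + 1,
                                         plate_max_gap = 10))
  expect_false(rep3$pass[rep3$rule == "plane_below_plateau"])
})

test_that("plan comparison reports the headline offsets", {
  x <- c(10, -40, 0, 0, 8, 3, -30, 0, -45, 0, 0, 0)
  a <- osteotomy_plan(x, "right", "caseA")
  expect_true(all(unlist(compare_plans(a, a)[1:8]) == 0))
  xb <- x; xb[1] <- x[1] + 3
  b <- osteotomy_plan(xb, "right", "caseA")
  cp <- compare_plans(a, b)
  expect_equal(cp$axis_offset, 3)
  expect_equal(cp$axis_offset_ml, 3)
  expect_equal(cp$axis_offset_si, 0)
  expect_false(cp$frame_mismatch)
  # plane normals tilted about Z: frontal projection angle matches 2D oracle
  xc <- x; xc[3] <- 10  # azimuth rotates the axis, tilting the plane normal
  cpc <- compare_plans(a, osteotomy_plan(xc, "right", "caseA"))
  na <- osteoplan:::plan_plane_normal(osteotomy_plan(x, "right")$par)
  nc <- osteoplan:::plan_plane_normal(osteotomy_plan(xc, "right")$par)
  ang2d <- function(u, v) acos(sum(u * v) /
                                 sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  expect_equal(cpc$plane_normal_frontal, ang2d(na[c(1, 3)], nc[c(1, 3)]),
               tolerance = 1e-9)
  mis <- compare_plans(a, osteotomy_plan(x, "right", "caseB"))
  expect_true(mis$frame_mismatch)
})

test_that("the genetic search returns a deterministic non-dominated front", {
  case <- gt_case()
  targets <- planning_targets(MA = 0, TS = 5)
  res <- optimize_plan(case, targets, side = "right",
                       population = 20, generations = 8, seed = 3)
  F <- as.matrix(res$pareto[, c("dMA", "dTS", "plate_gap")])
  for (i in seq_len(nrow(F))) for (j in seq_len(nrow(F))) {
    if (i == j) next
    expect_false(all(F[i, ] <= F[j, ]) && any(F[i, ] < F[j, ]))
  }
  res2 <- optimize_plan(case, targets, side = "right",
                        population = 20, generations = 8, seed = 3)
  expect_equal(res$selected$par, res2$selected$par)
  expect_lt(res$selected_fitness[1], 3)  # already closes in at tiny budgets
})
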