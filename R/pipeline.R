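# End-to-end orchestration: presets, network training over a dataset,
# evaluation tables, the separation ablation harness, and a resumable
# run_pipeline() with a manifest.

#' Pipeline configuration presets
#'
#' `desk`: a small CPU-friendly configuration (10 patients, 128 px images,
#' 32^3 reconstruction cubes, few epochs) that exercises every stage in
#' minutes. `full`: the reference protocol scale (175 patients, 3
#' augmentations, 512 px images, 128^3 cubes, epochs 20/20/30) kept as
#' configuration.
#'
#' @param preset `"desk"` or `"full"`
#' @param seed global seed; all per-stage seeds derive from it
#' @param out_dir run directory for artifacts
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(preset = c("desk", "full"), seed = 1L,
                            out_dir = tempfile("osteoplan_run_")) {
  preset <- match.arg(preset)
  desk <- preset == "desk"
  cfg <- list(
    preset = preset, seed = as.integer(seed), out_dir = out_dir,
    phantom = list(n_patients = if (desk) 10L else 175L,
                   voxel_spacing = if (desk) 3.5 else 1,
                   stance_separation = 190),
    dataset = list(n_aug = 3L,
                   detector_px = if (desk) 128L else 512L,
                   pixel_spacing = if (desk) 3.5 else 1),
    nets = list(base_channels = if (desk) c(separation = 8L, landmarks = 8L,
                                            reconstruction = 6L)
                                else c(separation = 32L, landmarks = 32L,
                                       reconstruction = 32L),
                epochs = if (desk) c(separation = 8L, landmarks = 14L,
                                     landmarks_sagittal = 8L,
                                     reconstruction = 3L)
                         else c(separation = 20L, landmarks = 20L,
                                landmarks_sagittal = 20L,
                                reconstruction = 30L),
                batch_size = if (desk) c(separation = 2L, landmarks = 1L,
                                         reconstruction = 1L)
                             else c(separation = 16L, landmarks = 1L,
                                    reconstruction = 1L),
                learning_rate = if (desk) c(separation = 1.5e-3,
                                            landmarks = 2e-3,
                                            reconstruction = 1e-3)
                                else c(separation = 1e-3, landmarks = 1e-4,
                                       reconstruction = 5e-5),
                heatmap_sigma = 5),
    planner = list(population = if (desk) 60L else 100L,
                   generations = if (desk) 40L else 100L,
                   target_MA = 0, target_TS = 5))
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' The file may specify `preset`, `seed`, `out_dir` and any nested
#' overrides of the preset's blocks (`phantom`, `dataset`, `nets`,
#' `planner`).
#'
#' @param path YAML file
#' @return a [pipeline_config()]
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config(y$preset %||% "desk", seed = y$seed %||% 1L,
                         out_dir = y$out_dir %||% tempfile("osteoplan_run_"))
  for (block in intersect(names(y), c("phantom", "dataset", "nets", "planner")))
    for (k in names(y[[block]]))
      cfg[[block]][[k]] <- y[[block]][[k]]
  cfg
}

stage_seed <- function(cfg, stage) {
  (cfg$seed * 97L + match(stage, c("phantom", "dataset", "separation",
                                   "landmarks", "reconstruction",
                                   "evaluate", "plan")) * 1009L) %% 2147483647L
}

#' Train all networks of the pipeline on a dataset
#'
#' @param dataset result of [build_dataset()]
#' @param cfg a [pipeline_config()]
#' @param ablation also train the no-separation reconstruction variant
#' @param verbose print epoch losses
#' @return list of trained models (`separation`, `landmark_frontal`,
#'   `landmark_sagittal`, `reconstruction`, optionally
#'   `reconstruction_ablation`)
#' @export
train_pipeline_models <- function(dataset, cfg = pipeline_config(),
                                  ablation = FALSE, verbose = FALSE) {
  tr <- studies_in(dataset, "train"); va <- studies_in(dataset, "val")
  nc <- cfg$nets
  S <- cfg$dataset$detector_px
  models <- list()
  bc <- function(w) if (length(nc$base_channels) > 1) nc$base_channels[[w]]
    else nc$base_channels
  sep_cfg <- network_config("separation", input_size = S,
                            base_channels = bc("separation"),
                            epochs = nc$epochs[["separation"]],
                            batch_size = nc$batch_size[["separation"]],
                            learning_rate = nc$learning_rate[["separation"]],
                            seed = stage_seed(cfg, "separation"))
  models$separation <- train_network(
    build_separation_model(sep_cfg),
    separation_samples(tr), separation_samples(va),
    seed = stage_seed(cfg, "separation"), verbose = verbose)
  lm_cfg <- network_config("landmarks", input_size = S, in_channels = 3L,
                           base_channels = bc("landmarks"),
                           epochs = nc$epochs[["landmarks"]],
                           learning_rate = nc$learning_rate[["landmarks"]],
                           seed = stage_seed(cfg, "landmarks"))
  models$landmark_frontal <- train_network(
    build_landmark_model(lm_cfg, 6L),
    landmark_samples_frontal(tr, nc$heatmap_sigma),
    landmark_samples_frontal(va, nc$heatmap_sigma),
    seed = stage_seed(cfg, "landmarks"), verbose = verbose)
  models$landmark_sagittal <- train_network(
    build_landmark_model(lm_cfg, 3L),
    landmark_samples_sagittal(tr, nc$heatmap_sigma),
    landmark_samples_sagittal(va, nc$heatmap_sigma),
    epochs = nc$epochs[["landmarks_sagittal"]] %||% nc$epochs[["landmarks"]],
    seed = stage_seed(cfg, "landmarks") + 1L, verbose = verbose)
  rc_cfg <- network_config("reconstruction", input_size = S,
                           base_channels = bc("reconstruction"),
                           epochs = nc$epochs[["reconstruction"]],
                           learning_rate = nc$learning_rate[["reconstruction"]],
                           seed = stage_seed(cfg, "reconstruction"))
  models$reconstruction <- train_network(
    build_reconstruction_model(rc_cfg),
    recon_samples(tr, sagittal = "separated"),
    recon_samples(va, sagittal = "separated"),
    seed = stage_seed(cfg, "reconstruction"), verbose = verbose)
  if (ablation) {
    models$reconstruction_ablation <- train_network(
      build_reconstruction_model(rc_cfg),
      recon_samples(tr, sagittal = "full"),
      recon_samples(va, sagittal = "full"),
      seed = stage_seed(cfg, "reconstruction"), verbose = verbose)
  }
  models
}

#' Per-case reconstruction Dice on a set of studies
#'
#' @param model reconstruction model
#' @param studies list of studies
#' @param sagittal `"separated"` or `"full"` inputs
#' @param sides legs to score
#' @return data.frame with case, side, dice
#' @export
evaluate_reconstruction <- function(model, studies, sagittal = "separated",
                                    sides = c("right", "left")) {
  rows <- list()
  for (st in studies) for (side in sides) {
    ri <- make_recon_inputs(st, side, sagittal = sagittal)
    yh <- predict_model(model, list(frontal = ri$frontal,
                                    sagittal = ri$sagittal))
    n <- attr(yh, "n")
    pred <- array(yh[, 2] > 0.5, c(n, n, n)) * 1
    rows[[length(rows) + 1L]] <-
      data.frame(case = st$case_id, side = side,
                 dice = dice_score(pred, ri$target * 1))
  }
  do.call(rbind, rows)
}

#' Per-study 2D landmark localization errors (px)
#'
#' Runs the frontal (and, on the ground-truth separated images, the
#' sagittal) landmark networks and reports the Euclidean pixel error per
#' landmark.
#'
#' @param models list with `landmark_frontal` and `landmark_sagittal`
#' @param studies list of studies
#' @return data.frame with case, view, side, landmark, error
#' @export
evaluate_landmarks <- function(models, studies) {
  rows <- list()
  for (st in studies) {
    hmf <- predict_model(models$landmark_frontal, lm_input(st$I_fron$pixels))
    for (side in c("right", "left")) {
      off <- if (side == "right") 0 else 3
      for (i in 1:3) {
        p <- extract_landmark(hmf[, , off + i])
        tr <- st$landmarks2d$frontal[[side]][[lm_names[i]]]
        rows[[length(rows) + 1L]] <-
          data.frame(case = st$case_id, view = "frontal", side = side,
                     landmark = lm_names[i],
                     error = sqrt(sum((p - tr)^2)))
      }
      img <- if (side == "right") st$I_sag_R else st$I_sag_L
      hms <- predict_model(models$landmark_sagittal, lm_input(img$pixels))
      for (i in 1:3) {
        p <- extract_landmark(hms[, , i])
        tr <- st$landmarks2d$sagittal[[side]][[lm_names[i]]]
        rows[[length(rows) + 1L]] <-
          data.frame(case = st$case_id, view = "sagittal", side = side,
                     landmark = lm_names[i],
                     error = sqrt(sum((p - tr)^2)))
      }
    }
  }
  do.call(rbind, rows)
}

#' Relative improvement in percent
#'
#' `(full - ablated) / ablated * 100`, the statistic used to summarize the
#' separation ablation.
#'
#' @param full,ablated metric values (e.g. mean Dice with and without
#'   separation)
#' @return percent improvement
#' @export
relative_improvement <- function(full, ablated) (full - ablated) / ablated * 100

#' Separation ablation table
#'
#' Scores the reconstruction network trained with prior separation against
#' the variant trained on the unseparated sagittal, on the same studies,
#' and reports mean Dice per side with the relative improvement.
#'
#' @param model_sep,model_abl the two reconstruction models
#' @param studies evaluation studies
#' @return data.frame with side, dice_separated, dice_ablation,
#'   improvement_pct
#' @export
ablation_table <- function(model_sep, model_abl, studies) {
  ds <- evaluate_reconstruction(model_sep, studies, "separated")
  da <- evaluate_reconstruction(model_abl, studies, "full")
  out <- lapply(c("right", "left"), function(s) {
    fs <- mean(ds$dice[ds$side == s]); fa <- mean(da$dice[da$side == s])
    data.frame(side = s, dice_separated = fs, dice_ablation = fa,
               improvement_pct = relative_improvement(fs, fa))
  })
  do.call(rbind, out)
}

write_manifest <- function(path, manifest) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
}

artifact_digest <- function(path) unname(tools::md5sum(path))

run_stage <- function(cfg, name, deps, fn, force = FALSE) {
  path <- file.path(cfg$out_dir, paste0(name, ".rds"))
  if (file.exists(path) && !force) {
    return(list(value = readRDS(path), path = path, computed = FALSE))
  }
  t0 <- proc.time()[3]
  value <- fn()
  saveRDS(value, path)
  list(value = value, path = path, computed = TRUE,
       seconds = unname(proc.time()[3] - t0))
}

#' Run the full pipeline
#'
#' Executes phantom generation, dataset simulation, network training,
#' evaluation (including the separation ablation) and planning in
#' dependency order. Each stage persists its artifact under the run
#' directory and is skipped when the artifact already exists, so a run can
#' resume from any completed stage. A manifest with the configuration,
#' per-stage seeds, digests and timing is written at the run root.
#'
#' @param cfg a [pipeline_config()]
#' @param force_stages character vector of stage names to recompute
#' @param verbose print progress
#' @return list with all stage results and the manifest (invisibly the run
#'   directory is populated)
#' @export
run_pipeline <- function(cfg = pipeline_config(), force_stages = character(),
                         verbose = FALSE) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  stages$phantom <- run_stage(cfg, "phantom", NULL, function() {
    generate_cohort(cfg$phantom$n_patients,
                    phantom_params(voxel_spacing = cfg$phantom$voxel_spacing),
                    seed = stage_seed(cfg, "phantom"),
                    stance_separation = cfg$phantom$stance_separation)
  }, force = "phantom" %in% force_stages)
  stages$dataset <- run_stage(cfg, "dataset", "phantom", function() {
    gf <- projection_geometry("frontal", detector_size =
                                rep(cfg$dataset$detector_px, 2),
                              pixel_spacing = cfg$dataset$pixel_spacing)
    gs <- projection_geometry("sagittal", detector_size =
                                rep(cfg$dataset$detector_px, 2),
                              pixel_spacing = cfg$dataset$pixel_spacing)
    build_dataset(stages$phantom$value, n_aug = cfg$dataset$n_aug,
                  seed = stage_seed(cfg, "dataset"),
                  geom_frontal = gf, geom_sagittal = gs)
  }, force = "dataset" %in% force_stages)
  stages$models <- run_stage(cfg, "models", "dataset", function() {
    train_pipeline_models(stages$dataset$value, cfg, ablation = TRUE,
                          verbose = verbose)
  }, force = "models" %in% force_stages)
  stages$evaluation <- run_stage(cfg, "evaluation", "models", function() {
    ds <- stages$dataset$value; mo <- stages$models$value
    te <- studies_in(ds, "test")
    list(dice = evaluate_reconstruction(mo$reconstruction, te, "separated"),
         landmarks = evaluate_landmarks(mo, te),
         ablation = ablation_table(mo$reconstruction,
                                   mo$reconstruction_ablation, te))
  }, force = "evaluation" %in% force_stages)
  stages$plan <- run_stage(cfg, "plan", "evaluation", function() {
    ds <- stages$dataset$value
    te <- studies_in(ds, "test")
    st <- te[[1]]
    case <- ground_truth_case(st, "right")
    optimize_plan(case, planning_targets(cfg$planner$target_MA,
                                         cfg$planner$target_TS),
                  side = "right",
                  population = cfg$planner$population,
                  generations = cfg$planner$generations,
                  seed = stage_seed(cfg, "plan"))
  }, force = "plan" %in% force_stages)
  manifest <- list(
    config = unclass(cfg),
    seeds = stats::setNames(
      lapply(c("phantom", "dataset", "separation", "landmarks",
               "reconstruction", "evaluate", "plan"),
             function(s) stage_seed(cfg, s)),
      c("phantom", "dataset", "separation", "landmarks", "reconstruction",
        "evaluate", "plan")),
    stages = lapply(stages, function(s)
      list(path = basename(s$path), digest = artifact_digest(s$path),
           computed = s$computed, seconds = s$seconds %||% NA)),
    version = as.character(utils::packageVersion("osteoplan")))
  write_manifest(file.path(cfg$out_dir, "manifest.json"), manifest)
  invisible(c(stages, list(manifest = manifest, out_dir = cfg$out_dir)))
}

#' Ground-truth planning case from a study
#'
#' Builds the proximal-tibia mesh from the analytically sampled target grid
#' and pairs it with the ground-truth 3D landmarks of the requested side.
#'
#' @param study a `biplanar_study` with its volume attached
#' @param side leg side
#' @return list with `landmarks`, `mesh`, `case_id`
#' @export
ground_truth_case <- function(study, side = "right") {
  ri <- make_recon_inputs(study, side)
  lv <- recon_label_volume(ri$target, ri$grid)
  mesh <- marching_cubes(lv)
  list(landmarks = study$landmarks3d[[side]], mesh = mesh,
       case_id = study$case_id)
}

#' Evaluation report of a pipeline run
#'
#' Summarizes the evaluation artifacts as mean +/- SD tables: per-side
#' reconstruction Dice, per-view landmark errors, and the separation
#' ablation with its relative Dice improvement.
#'
#' @param run result of [run_pipeline()]
#' @return list of data.frames (`dice`, `landmarks`, `ablation`,
#'   `plan_fitness`); missing artifacts are reported as absent
#' @export
report <- function(run) {
  ev <- run$evaluation$value
  if (is.null(ev)) return(list(absent = "evaluation"))
  dice <- stats::aggregate(dice ~ side, ev$dice,
                           function(x) c(mean = mean(x), sd = stats::sd(x)))
  lms <- stats::aggregate(error ~ view + side, ev$landmarks,
                          function(x) c(mean = mean(x), sd = stats::sd(x)))
  out <- list(dice = do.call(data.frame, dice),
              landmarks = do.call(data.frame, lms),
              ablation = ev$ablation)
  if (!is.null(run$plan$value))
    out$plan_fitness <- data.frame(
      dMA = run$plan$value$selected_fitness[1],
      dTS = run$plan$value$selected_fitness[2],
      plate_gap = run$plan$value$selected_fitness[3])
  out
}

# ---- standard-format IO -----------------------------------------------------

#' Write an annotated volume's grids as NIfTI
#'
#' @param vol an `annotated_volume`
#' @param path_intensity,path_labels output `.nii.gz` paths (labels
#'   optional)
#' @export
write_volume_nifti <- function(vol, path_intensity, path_labels = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI output")
  img <- RNifti::asNifti(vol$intensity, pixdim = vol$spacing)
  RNifti::writeNifti(img, path_intensity)
  if (!is.null(path_labels))
    RNifti::writeNifti(RNifti::asNifti(vol$labels + 0, pixdim = vol$spacing),
                       path_labels)
  invisible(path_intensity)
}

#' Write a radiograph as 16-bit PNG with a JSON sidecar
#'
#' @param rad a `radiograph`
#' @param path output `.png`; the sidecar is `path` + `.json`
#' @export
write_radiograph <- function(rad, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required for radiograph output")
  png::writePNG(rad$pixels, path)
  g <- rad$geom
  jsonlite::write_json(list(view = rad$view, spacing = rad$spacing,
                            detector = c(g$nu, g$nv),
                            center = c(g$cu, g$cv), mode = g$mode,
                            norm = rad$norm),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a landmark set as JSON
#' @param landmarks per-side list of `HC`, `KC`, `AC` points
#' @param path output file
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(lapply(landmarks, function(s) lapply(s, as.numeric)),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
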