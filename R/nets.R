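# Dataset adapters between biplanar studies and the three networks, and the
# full-study inference path.

lm_names <- c("HC", "KC", "AC")

# landmark-network input: the image plus coordinate ramp channels
lm_input <- function(img) c(list(img), coord_channels(dim(img)))

#' Training samples for the separation network
#'
#' Input: the two-leg sagittal image; targets: the contrast-enhanced
#' single-leg sagittal images (right and left decoder).
#'
#' @param studies list of `biplanar_study`
#' @return list of samples for [train_network()]
#' @export
separation_samples <- function(studies) {
  lapply(studies, function(st) {
    list(x = st$I_sag$pixels,
         y = list(R = st$I_sag_R$pixels, L = st$I_sag_L$pixels))
  })
}

#' Training samples for the frontal landmark network (6 channels)
#'
#' @param studies list of `biplanar_study`
#' @param sigma heatmap spread (px)
#' @return list of samples; channel order right HC,KC,AC then left HC,KC,AC
#' @export
landmark_samples_frontal <- function(studies, sigma = 5) {
  lapply(studies, function(st) {
    lms <- c(stats::setNames(st$landmarks2d$frontal$right,
                             paste0("right.", lm_names)),
             stats::setNames(st$landmarks2d$frontal$left,
                             paste0("left.", lm_names)))
    list(x = lm_input(st$I_fron$pixels),
         y = make_heatmaps(lms, sigma, dim(st$I_fron$pixels)))
  })
}

#' Training samples for the sagittal landmark network (3 channels)
#'
#' Two samples per study: each separated single-leg sagittal with its three
#' joint-center heatmaps.
#'
#' @param studies list of `biplanar_study`
#' @param sigma heatmap spread (px)
#' @return list of samples
#' @export
landmark_samples_sagittal <- function(studies, sigma = 5) {
  out <- list()
  for (st in studies) {
    for (side in c("right", "left")) {
      img <- if (side == "right") st$I_sag_R else st$I_sag_L
      lms <- stats::setNames(st$landmarks2d$sagittal[[side]], lm_names)
      out[[length(out) + 1L]] <-
        list(x = lm_input(img$pixels),
             y = make_heatmaps(lms, sigma, dim(img$pixels)))
    }
  }
  out
}

#' Training samples for the reconstruction network
#'
#' One sample per study and side: the knee-centered frontal and sagittal
#' crops (upsampled to the network input size) and the one-hot
#' background/tibia target on the fusion grid. `sagittal = "full"` builds
#' the ablation condition (no prior separation).
#'
#' @param studies list of `biplanar_study`
#' @param sides legs to include
#' @param sagittal `"separated"` or `"full"`
#' @param ... passed to [make_recon_inputs()]
#' @return list of samples; each keeps its `grid` and `side`
#' @export
recon_samples <- function(studies, sides = c("right", "left"),
                          sagittal = "separated", ...) {
  out <- list()
  for (st in studies) for (side in sides) {
    ri <- make_recon_inputs(st, side, sagittal = sagittal, ...)
    t <- as.numeric(ri$target)
    out[[length(out) + 1L]] <-
      list(x = list(frontal = ri$frontal, sagittal = ri$sagittal),
           y = cbind(1 - t, t), grid = ri$grid, side = side,
           case_id = st$case_id)
  }
  out
}

extract_landmark_set <- function(hm, names) {
  out <- lapply(seq_along(names), function(i) extract_landmark(hm[, , i]))
  stats::setNames(out, names)
}

#' Run the full inference pipeline on one study
#'
#' Separation (network, oracle single-leg targets, or none), heatmap
#' landmark localization on the frontal and the separated sagittal images,
#' triangulation of the 2D landmarks to 3D, and per-leg 2D-3D
#' reconstruction from the knee-centered crops. The two legs are
#' reconstructed independently.
#'
#' @param models list with elements `separation`, `landmark_frontal`,
#'   `landmark_sagittal`, `reconstruction` (any may be NULL to skip)
#' @param study a `biplanar_study`
#' @param separation_mode `"network"`, `"oracle"` (ground-truth separated
#'   targets) or `"none"` (both-leg sagittal; the ablation condition)
#' @param use_true_landmarks center the reconstruction crops on the
#'   ground-truth knee position instead of the detected one
#' @param sides legs to process
#' @return list with `separated`, `landmarks2d`, `landmarks3d`, `recon`
#'   (per side: softmax array in (v, x, y) order, binary prediction, target,
#'   dice, grid), and `dice` (named per side)
#' @export
predict_study <- function(models, study,
                          separation_mode = c("network", "oracle", "none"),
                          use_true_landmarks = FALSE,
                          sides = c("right", "left")) {
  separation_mode <- match.arg(separation_mode)
  sep <- switch(separation_mode,
    network = {
      if (is.null(models$separation)) stop("pipeline error: missing separation model")
      predict_model(models$separation, study$I_sag$pixels)
    },
    oracle = list(R = study$I_sag_R$pixels, L = study$I_sag_L$pixels),
    none = NULL)
  lm2d <- list(frontal = list(), sagittal = list())
  if (!is.null(models$landmark_frontal)) {
    hmf <- predict_model(models$landmark_frontal, lm_input(study$I_fron$pixels))
    lm2d$frontal <- list(
      right = extract_landmark_set(hmf[, , 1:3, drop = FALSE], lm_names),
      left = extract_landmark_set(hmf[, , 4:6, drop = FALSE], lm_names))
  }
  if (!is.null(models$landmark_sagittal) && !is.null(sep)) {
    for (side in sides) {
      img <- if (side == "right") sep$R else sep$L
      hms <- predict_model(models$landmark_sagittal, lm_input(img))
      lm2d$sagittal[[side]] <- extract_landmark_set(hms, lm_names)
    }
  }
  # 3D landmarks by triangulation
  lm3d <- list()
  gf <- study$I_fron$geom; gs <- study$I_sag$geom
  for (side in sides) {
    if (is.null(lm2d$frontal[[side]]) || is.null(lm2d$sagittal[[side]])) next
    lm3d[[side]] <- lapply(stats::setNames(lm_names, lm_names), function(nm)
      triangulate_landmark(lm2d$frontal[[side]][[nm]],
                           lm2d$sagittal[[side]][[nm]], gf, gs)$point)
  }
  recon <- list(); dice <- c()
  if (!is.null(models$reconstruction)) {
    for (side in sides) {
      knee2d <- NULL
      if (!use_true_landmarks &&
          !is.null(lm2d$frontal[[side]]) && !is.null(lm2d$sagittal[[side]]) &&
          !anyNA(lm2d$frontal[[side]]$KC) && !anyNA(lm2d$sagittal[[side]]$KC))
        knee2d <- list(frontal = lm2d$frontal[[side]]$KC,
                       sagittal = lm2d$sagittal[[side]]$KC)
      sag_img <- if (is.null(sep)) NULL
        else if (side == "right") sep$R else sep$L
      ri <- make_recon_inputs(study, side,
                              sagittal = if (is.null(sep)) "full" else "separated",
                              sag_image = sag_img, knee2d = knee2d)
      yh <- predict_model(models$reconstruction,
                          list(frontal = ri$frontal, sagittal = ri$sagittal))
      n <- attr(yh, "n")
      pred <- array(yh[, 2] > 0.5, c(n, n, n))
      rec <- list(prob = array(yh[, 2], c(n, n, n)), pred = pred,
                  target = ri$target, grid = ri$grid)
      if (!is.null(ri$target)) {
        rec$dice <- dice_score(pred * 1, ri$target * 1)
        dice[side] <- rec$dice
      }
      recon[[side]] <- rec
    }
  }
  list(separated = sep, landmarks2d = lm2d, landmarks3d = lm3d,
       recon = recon, dice = dice, separation_mode = separation_mode,
       case_id = study$case_id)
}
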