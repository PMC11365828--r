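# Base-graphics visualization helpers.

#' Display a radiograph
#'
#' @param x a `radiograph`
#' @param main plot title
#' @param ... passed to [graphics::image()]
#' @export
plot.radiograph <- function(x, main = x$view, ...) {
  px <- x$pixels
  graphics::image(t(px[nrow(px):1, , drop = FALSE]),
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  asp = nrow(px) / ncol(px), main = main, ...)
  invisible(x)
}

#' Overlay predicted heatmap peaks on an image
#'
#' @param img image matrix (rows = v, cols = u)
#' @param heatmaps `nv x nu x C` heatmap array
#' @param truth optional named list of `c(u, v)` ground-truth positions
#' @export
plot_landmarks <- function(img, heatmaps, truth = NULL) {
  nv <- nrow(img); nu <- ncol(img)
  graphics::image(t(img[nv:1, , drop = FALSE]),
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  asp = nv / nu)
  for (i in seq_len(dim(heatmaps)[3])) {
    p <- extract_landmark(heatmaps[, , i])
    if (anyNA(p)) next
    graphics::points(p["u"] / (nu - 1), 1 - p["v"] / (nv - 1),
                     col = "red", pch = 3, cex = 1.2)
  }
  if (!is.null(truth))
    for (t in truth)
      graphics::points(t["u"] / (nu - 1), 1 - t["v"] / (nv - 1),
                       col = "green", pch = 1, cex = 1.2)
  invisible(NULL)
}

#' Plot training loss curves
#'
#' @param model a trained `osteo_model` (with a `history`)
#' @param ... passed to [graphics::matplot()]
#' @export
plot_history <- function(model, ...) {
  h <- model$history
  graphics::matplot(h$epoch, cbind(h$train, h$val), type = "l", lty = 1,
                    xlab = "epoch", ylab = "loss",
                    col = c("black", "red"), ...)
  graphics::legend("topright", c("train", "val"), lty = 1,
                   col = c("black", "red"), bty = "n")
  invisible(h)
}
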