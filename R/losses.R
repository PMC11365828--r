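# Training losses for the three networks. Image gradients for the gradient
# correlation use central differences (zero rows/columns at the borders).

grad_x <- function(img) {
  g <- img * 0
  n <- ncol(img)
  if (n >= 3) g[, 2:(n - 1)] <- (img[, 3:n] - img[, 1:(n - 2)]) / 2
  g
}
grad_y <- function(img) {
  g <- img * 0
  n <- nrow(img)
  if (n >= 3) g[2:(n - 1), ] <- (img[3:n, ] - img[1:(n - 2), ]) / 2
  g
}
# adjoint of the central-difference operators
grad_x_adj <- function(g) {
  d <- g * 0
  n <- ncol(g)
  if (n >= 3) {
    d[, 3:n] <- d[, 3:n] + g[, 2:(n - 1)] / 2
    d[, 1:(n - 2)] <- d[, 1:(n - 2)] - g[, 2:(n - 1)] / 2
  }
  d
}
grad_y_adj <- function(g) {
  d <- g * 0
  n <- nrow(g)
  if (n >= 3) {
    d[3:n, ] <- d[3:n, ] + g[2:(n - 1), ] / 2
    d[1:(n - 2), ] <- d[1:(n - 2), ] - g[2:(n - 1), ] / 2
  }
  d
}

ncc <- function(a, b) {
  ac <- a - mean(a); bc <- b - mean(b)
  na <- sqrt(sum(ac^2)); nb <- sqrt(sum(bc^2))
  if (na == 0 || nb == 0) return(NA_real_)  # degenerate; caller decides
  sum(ac * bc) / (na * nb)
}

#' Gradient correlation between two images
#'
#' Mean of the normalized cross-correlations of the horizontal and vertical
#' central-difference gradient images of `y` and `yhat`; the gradient-image
#' means are subtracted inside each correlation. The result lies in
#' `[-1, 1]` and equals 1 when the images agree (or differ by a positive
#' affine map). A constant input has zero-variance gradients; the
#' correlation is then defined as 0 with a warning.
#'
#' @param y,yhat numeric matrices of equal shape
#' @return scalar in `[-1, 1]`
#' @export
gradient_correlation <- function(y, yhat) {
  stopifnot(all(dim(y) == dim(yhat)))
  cx <- ncc(grad_x(y), grad_x(yhat))
  cy <- ncc(grad_y(y), grad_y(yhat))
  if (anyNA(c(cx, cy))) {
    warning("zero-variance gradient image; correlation set to 0")
    if (is.na(cx)) cx <- 0
    if (is.na(cy)) cy <- 0
  }
  0.5 * (cx + cy)
}

# d gradient_correlation / d yhat
gc_grad <- function(y, yhat) {
  d <- yhat * 0
  for (ax in c("x", "y")) {
    G <- if (ax == "x") grad_x else grad_y
    Gt <- if (ax == "x") grad_x_adj else grad_y_adj
    l1 <- G(y); l2 <- G(yhat)
    l1c <- l1 - mean(l1); l2c <- l2 - mean(l2)
    n1 <- sqrt(sum(l1c^2)); n2 <- sqrt(sum(l2c^2))
    if (n1 == 0 || n2 == 0) next
    r <- sum(l1c * l2c) / (n1 * n2)
    g <- l1c / (n1 * n2) - r * l2c / n2^2
    g <- g - mean(g)
    d <- d + 0.5 * Gt(g)
  }
  d
}

#' Separation-network loss
#'
#' `L = (MSE + (1 - GC)) / 2`: mean squared error plus one minus the
#' gradient correlation, so the loss decreases to 0 as the prediction
#' approaches the target. The correlation enters as a dissimilarity because
#' it is a similarity score whose purpose is sharpening the predicted leg
#' outlines.
#'
#' @param y,yhat numeric matrices of equal shape
#' @return non-negative scalar
#' @export
separation_loss <- function(y, yhat) {
  stopifnot(all(dim(y) == dim(yhat)))
  mse <- mean((y - yhat)^2)
  0.5 * (mse + (1 - gradient_correlation(y, yhat)))
}

# d separation_loss / d yhat
separation_loss_grad <- function(y, yhat) {
  (yhat - y) / length(y) - 0.5 * gc_grad(y, yhat)
}

#' Binary cross-entropy loss
#'
#' `-(1/N) sum(y log yhat + (1 - y) log(1 - yhat))` with predictions clipped
#' to `[eps, 1 - eps]`.
#'
#' @param y,yhat numeric arrays of equal shape, values in `[0, 1]`
#' @param eps clipping constant
#' @return non-negative scalar
#' @export
bce_loss <- function(y, yhat, eps = 1e-7) {
  stopifnot(length(y) == length(yhat))
  p <- pmin(pmax(yhat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Dice plus cross-entropy loss for multi-class volumes
#'
#' `sum_c (1 - 2 sum(y yhat) / (sum y + sum yhat))` over classes, plus the
#' mean cross-entropy `-(1/N) sum_i sum_c y log yhat`. `yhat` must be a
#' per-voxel softmax (rows summing to 1).
#'
#' @param y one-hot matrix (voxels x classes)
#' @param yhat softmax matrix (voxels x classes)
#' @param eps clipping constant for the log terms
#' @return non-negative scalar
#' @export
dice_ce_loss <- function(y, yhat, eps = 1e-7) {
  y <- as.matrix(y); yhat <- as.matrix(yhat)
  stopifnot(all(dim(y) == dim(yhat)))
  if (max(abs(rowSums(yhat) - 1)) > 1e-6)
    stop("contract violation: yhat rows must sum to 1 (softmax output)")
  dice <- 0
  for (c in seq_len(ncol(y))) {
    s <- sum(y[, c]) + sum(yhat[, c])
    dice <- dice + (1 - if (s > 0) 2 * sum(y[, c] * yhat[, c]) / s else 1)
  }
  p <- pmin(pmax(yhat, eps), 1 - eps)
  ce <- -sum(y * log(p)) / nrow(y)
  dice + ce
}

# gradient of dice_ce_loss w.r.t. the pre-softmax logits
dice_ce_grad_logits <- function(y, yhat, eps = 1e-7) {
  n <- nrow(y)
  g <- yhat * 0
  for (c in seq_len(ncol(y))) {
    s <- sum(y[, c]) + sum(yhat[, c])
    if (s > 0) {
      inter <- sum(y[, c] * yhat[, c])
      g[, c] <- g[, c] - 2 * (y[, c] * s - inter) / s^2
    }
  }
  g <- g + (-(y / pmin(pmax(yhat, eps), 1 - eps))) / n
  # chain through softmax: dz = yhat * (g - sum(g * yhat))
  yhat * (g - rowSums(g * yhat))
}
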