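# Small convolutional-network core: 3x3(x3) same-padding convolutions via
# im2col (native kernels) + BLAS matrix products, 2x max pooling, nearest
# upsampling, ReLU, He-normal init, Adam. Feature maps are (npix, channels)
# matrices with pixels column-major over the spatial dims (first dim = image
# row / v, fastest). Backward passes are hand-written for the three fixed
# U-net topologies.

im2colN <- function(X, dims) {
  if (length(dims) == 2) im2col2_cpp(X, dims[1], dims[2])
  else im2col3_cpp(X, dims[1], dims[2], dims[3])
}
col2imN <- function(dcol, dims, C) {
  if (length(dims) == 2) col2im2_cpp(dcol, dims[1], dims[2], C)
  else col2im3_cpp(dcol, dims[1], dims[2], dims[3], C)
}

conv_fwd <- function(X, dims, W, b) {
  if (length(dims) == 3)
    conv3_fwd_cpp(X, dims[1], dims[2], dims[3], W, b)
  else sweep(im2colN(X, dims) %*% W, 2, b, "+")
}
conv_bwd <- function(dZ, X, dims, W) {
  if (length(dims) == 3) {
    r <- conv3_bwd_cpp(dZ, X, dims[1], dims[2], dims[3], W)
    return(list(dW = r$dW, db = drop(r$db), dX = r$dX))
  }
  col <- im2colN(X, dims)
  list(dW = crossprod(col, dZ), db = colSums(dZ),
       dX = col2imN(dZ %*% t(W), dims, ncol(X)))
}

sigmoid <- function(z) 1 / (1 + exp(-z))
softmax_rows <- function(z) {
  e <- exp(z - apply(z, 1, max))
  e / rowSums(e)
}

# double conv + ReLU block
dc_fwd <- function(X, dims, p, pre) {
  z1 <- conv_fwd(X, dims, p[[paste0(pre, ".W1")]], p[[paste0(pre, ".b1")]])
  a1 <- pmax(z1, 0)
  z2 <- conv_fwd(a1, dims, p[[paste0(pre, ".W2")]], p[[paste0(pre, ".b2")]])
  a2 <- pmax(z2, 0)
  list(X = X, a1 = a1, m1 = z1 > 0, m2 = z2 > 0, a2 = a2)
}
dc_bwd <- function(dA2, cache, dims, p, pre, gr) {
  dz2 <- dA2 * cache$m2
  c2 <- conv_bwd(dz2, cache$a1, dims, p[[paste0(pre, ".W2")]])
  gr <- gacc(gr, paste0(pre, ".W2"), c2$dW)
  gr <- gacc(gr, paste0(pre, ".b2"), c2$db)
  dz1 <- c2$dX * cache$m1
  c1 <- conv_bwd(dz1, cache$X, dims, p[[paste0(pre, ".W1")]])
  gr <- gacc(gr, paste0(pre, ".W1"), c1$dW)
  gr <- gacc(gr, paste0(pre, ".b1"), c1$db)
  list(gr = gr, dX = c1$dX)
}
gacc <- function(gr, name, val) {
  gr[[name]] <- if (is.null(gr[[name]])) val else gr[[name]] + val
  gr
}

he_conv <- function(k_cin, cout) {
  matrix(rnorm(k_cin * cout, 0, sqrt(2 / k_cin)), k_cin, cout)
}
mk_dc <- function(pre, k, cin, cout) {
  out <- list()
  out[[paste0(pre, ".W1")]] <- he_conv(k * cin, cout)
  out[[paste0(pre, ".b1")]] <- numeric(cout)
  out[[paste0(pre, ".W2")]] <- he_conv(k * cout, cout)
  out[[paste0(pre, ".b2")]] <- numeric(cout)
  out
}

#' Network configuration
#'
#' Shared hyperparameters of the three networks: 3x3(x3) kernels, pool size
#' 2, ReLU, same padding, He-normal initialization, Adam. Per-network
#' defaults follow the reference protocol: learning rate 0.001 / 0.0001 /
#' 0.00005, epochs 20 / 20 / 30 and batch size 16 / 1 / 1 for the
#' separation, landmark and reconstruction networks; the desk preset
#' overrides these with fewer epochs and a larger learning rate suited to
#' small synthetic cohorts.
#'
#' @param which network kind
#' @param input_size spatial edge of the (square) input in px; must be
#'   divisible by 8
#' @param base_channels channel width at the top level (doubles per level)
#' @param in_channels input channels
#' @param out_channels output channels (separation: per decoder; landmarks:
#'   number of heatmaps; reconstruction: classes)
#' @param learning_rate,epochs,batch_size training hyperparameters; `NULL`
#'   picks the per-network default
#' @param final_activation `"sigmoid"` or `"softmax"`; `NULL` picks the
#'   per-network default
#' @param seed RNG seed for weight initialization
#' @return object of class `network_config`
#' @export
network_config <- function(which = c("separation", "landmarks",
                                     "reconstruction"),
                           input_size = 128, base_channels = 8,
                           in_channels = 1, out_channels = NULL,
                           learning_rate = NULL, epochs = NULL,
                           batch_size = NULL, final_activation = NULL,
                           seed = 1L) {
  which <- match.arg(which)
  idx <- match(which, c("separation", "landmarks", "reconstruction"))
  if (input_size %% 8 != 0)
    stop("config error: input_size must be divisible by 8")
  structure(list(
    which = which, input_size = as.integer(input_size),
    base_channels = as.integer(base_channels),
    in_channels = as.integer(in_channels),
    out_channels = as.integer(out_channels %||% c(1, 3, 2)[idx]),
    kernel_size = 3L, pool_size = 2L, activation = "relu",
    padding = "same", weight_init = "he_normal", optimizer = "adam",
    learning_rate = learning_rate %||% c(0.001, 0.0001, 0.00005)[idx],
    epochs = as.integer(epochs %||% c(20, 20, 30)[idx]),
    batch_size = as.integer(batch_size %||% c(16, 1, 1)[idx]),
    final_activation = final_activation %||%
      c("sigmoid", "sigmoid", "softmax")[idx],
    seed = as.integer(seed)), class = "network_config")
}

#' Build the leg-separation network
#'
#' A 2D U-net with one encoding path and two separate decoding paths (right
#' and left leg), each with skip connections and a sigmoid output image.
#'
#' @param cfg a [network_config()] with `which = "separation"`
#' @return model object
#' @export
build_separation_model <- function(cfg) {
  stopifnot(cfg$which == "separation")
  unet2d_build(cfg, decoders = c("dR", "dL"))
}

#' Build the landmark localization network
#'
#' A 2D U-net emitting `n_channels` heatmaps in `[0, 1]` (sigmoid).
#'
#' @param cfg a [network_config()] with `which = "landmarks"`
#' @param n_channels heatmap channels (3 per leg; 6 for the two-leg frontal)
#' @return model object
#' @export
build_landmark_model <- function(cfg, n_channels = 3) {
  stopifnot(cfg$which == "landmarks", n_channels %in% c(3L, 6L))
  cfg$out_channels <- as.integer(n_channels)
  unet2d_build(cfg, decoders = "d")
}

unet2d_build <- function(cfg, decoders) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  c0 <- cfg$base_channels
  p <- c(mk_dc("e1", 9, cfg$in_channels, c0),
         mk_dc("e2", 9, c0, 2 * c0),
         mk_dc("bt", 9, 2 * c0, 4 * c0))
  for (d in decoders) {
    p <- c(p, mk_dc(paste0(d, ".d2"), 9, 6 * c0, 2 * c0),
           mk_dc(paste0(d, ".d1"), 9, 3 * c0, c0))
    p[[paste0(d, ".out.W")]] <- he_conv(9 * c0, cfg$out_channels)
    p[[paste0(d, ".out.b")]] <- numeric(cfg$out_channels)
  }
  structure(list(cfg = cfg, params = p, decoders = decoders),
            class = "osteo_model")
}

#' @export
print.osteo_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat("<osteo_model> ", x$cfg$which, ", ", np, " parameters, input ",
      x$cfg$input_size, " px\n", sep = "")
  invisible(x)
}

#' Number of parameters per model component
#' @param model an `osteo_model`
#' @return named integer vector (total and per decoder where applicable)
#' @export
model_param_counts <- function(model) {
  n <- vapply(model$params, length, 0L)
  out <- c(total = sum(n))
  for (d in model$decoders %||% character())
    out[d] <- sum(n[startsWith(names(n), paste0(d, "."))])
  out
}

unet2d_fwd <- function(model, x) {
  cfg <- model$cfg; p <- model$params
  S <- as.integer(sqrt(nrow(x)))
  d1 <- c(S, S); d2 <- d1 %/% 2L; d3 <- d1 %/% 4L
  e1 <- dc_fwd(x, d1, p, "e1")
  p1 <- maxpool_cpp(e1$a2, d1)
  e2 <- dc_fwd(p1$y, d2, p, "e2")
  p2 <- maxpool_cpp(e2$a2, d2)
  bt <- dc_fwd(p2$y, d3, p, "bt")
  outs <- list(); dec <- list()
  for (d in model$decoders) {
    u2 <- upsample_cpp(bt$a2, d3)
    cat2 <- cbind(u2, e2$a2)
    dd2 <- dc_fwd(cat2, d2, p, paste0(d, ".d2"))
    u1 <- upsample_cpp(dd2$a2, d2)
    cat1 <- cbind(u1, e1$a2)
    dd1 <- dc_fwd(cat1, d1, p, paste0(d, ".d1"))
    z <- conv_fwd(dd1$a2, d1, p[[paste0(d, ".out.W")]],
                  p[[paste0(d, ".out.b")]])
    outs[[d]] <- sigmoid(z)
    dec[[d]] <- list(dd2 = dd2, dd1 = dd1)
  }
  list(outs = outs,
       cache = list(e1 = e1, p1 = p1, e2 = e2, p2 = p2, bt = bt, dec = dec,
                    d1 = d1, d2 = d2, d3 = d3))
}

unet2d_bwd <- function(model, cache, dZs) {
  p <- model$params; gr <- list()
  d1 <- cache$d1; d2 <- cache$d2; d3 <- cache$d3
  c0 <- model$cfg$base_channels
  de1 <- 0; de2 <- 0; dbt <- 0
  for (d in model$decoders) {
    dz <- dZs[[d]]
    dd1 <- cache$dec[[d]]$dd1; dd2 <- cache$dec[[d]]$dd2
    cb <- conv_bwd(dz, dd1$a2, d1, p[[paste0(d, ".out.W")]])
    gr <- gacc(gr, paste0(d, ".out.W"), cb$dW)
    gr <- gacc(gr, paste0(d, ".out.b"), cb$db)
    r1 <- dc_bwd(cb$dX, dd1, d1, p, paste0(d, ".d1"), gr); gr <- r1$gr
    du1 <- r1$dX[, seq_len(2 * c0), drop = FALSE]
    de1 <- de1 + r1$dX[, -seq_len(2 * c0), drop = FALSE]
    dA2 <- upsample_back_cpp(du1, d2)
    r2 <- dc_bwd(dA2, dd2, d2, p, paste0(d, ".d2"), gr); gr <- r2$gr
    du2 <- r2$dX[, seq_len(4 * c0), drop = FALSE]
    de2 <- de2 + r2$dX[, -seq_len(4 * c0), drop = FALSE]
    dbt <- dbt + upsample_back_cpp(du2, d3)
  }
  rb <- dc_bwd(dbt, cache$bt, d3, p, "bt", gr); gr <- rb$gr
  de2 <- de2 + maxpool_back_cpp(rb$dX, cache$p2$idx, prod(d2))
  r2 <- dc_bwd(de2, cache$e2, d2, p, "e2", gr); gr <- r2$gr
  de1 <- de1 + maxpool_back_cpp(r2$dX, cache$p1$idx, prod(d1))
  r1 <- dc_bwd(de1, cache$e1, d1, p, "e1", gr); gr <- r1$gr
  gr
}

#' Build the 2D-3D reconstruction network
#'
#' Two separate 2D branches (frontal and sagittal) for the first two levels;
#' each branch's `S/4 x S/4` feature map is replicated `S/4` times along the
#' missing axis, the two volumes are averaged per voxel into one fused 3D
#' feature map, and the remaining encoder and the full decoder run in 3D
#' with skip connections at the fused levels (none at the two 2D levels).
#' Softmax over background/tibia.
#'
#' @param cfg a [network_config()] with `which = "reconstruction"`
#' @return model object
#' @export
build_reconstruction_model <- function(cfg) {
  stopifnot(cfg$which == "reconstruction")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  c0 <- cfg$base_channels
  p <- c(mk_dc("bf.e1", 9, 1, c0), mk_dc("bf.e2", 9, c0, 2 * c0),
         mk_dc("bs.e1", 9, 1, c0), mk_dc("bs.e2", 9, c0, 2 * c0),
         mk_dc("e3", 27, 2 * c0, 2 * c0),
         mk_dc("bt", 27, 2 * c0, 4 * c0),
         mk_dc("d3", 27, 6 * c0, 2 * c0))
  p[["out.W"]] <- he_conv(27 * 2 * c0, cfg$out_channels)
  p[["out.b"]] <- numeric(cfg$out_channels)
  structure(list(cfg = cfg, params = p), class = "osteo_model")
}

# replication index vectors for the fusion cube
fusion_idx <- function(n) {
  v <- rep(seq_len(n), times = n * n)
  xi <- rep(rep(seq_len(n), each = n), times = n)
  yi <- rep(seq_len(n), each = n * n)
  list(i_f = v + n * (xi - 1L), i_s = v + n * (yi - 1L))
}

recon_branch_fwd <- function(p, x, S, pre) {
  d1 <- c(S, S); d2 <- d1 %/% 2L
  e1 <- dc_fwd(x, d1, p, paste0(pre, ".e1"))
  p1 <- maxpool_cpp(e1$a2, d1)
  e2 <- dc_fwd(p1$y, d2, p, paste0(pre, ".e2"))
  p2 <- maxpool_cpp(e2$a2, d2)
  list(e1 = e1, p1 = p1, e2 = e2, p2 = p2, M = p2$y, d1 = d1, d2 = d2)
}
recon_branch_bwd <- function(p, cache, dM, pre, gr) {
  de2 <- maxpool_back_cpp(dM, cache$p2$idx, prod(cache$d2))
  r2 <- dc_bwd(de2, cache$e2, cache$d2, p, paste0(pre, ".e2"), gr); gr <- r2$gr
  de1 <- maxpool_back_cpp(r2$dX, cache$p1$idx, prod(cache$d1))
  r1 <- dc_bwd(de1, cache$e1, cache$d1, p, paste0(pre, ".e1"), gr); gr <- r1$gr
  gr
}

recon_fwd <- function(model, xf, xs) {
  p <- model$params
  S <- as.integer(sqrt(nrow(xf)))
  n <- S %/% 4L
  bf <- recon_branch_fwd(p, xf, S, "bf")
  bs <- recon_branch_fwd(p, xs, S, "bs")
  fi <- fusion_idx(n)
  f0 <- (bf$M[fi$i_f, , drop = FALSE] + bs$M[fi$i_s, , drop = FALSE]) / 2
  dv <- c(n, n, n); dh <- dv %/% 2L
  e3 <- dc_fwd(f0, dv, p, "e3")
  p3 <- maxpool_cpp(e3$a2, dv)
  bt <- dc_fwd(p3$y, dh, p, "bt")
  u <- upsample_cpp(bt$a2, dh)
  cat3 <- cbind(u, e3$a2)
  d3 <- dc_fwd(cat3, dv, p, "d3")
  z <- conv_fwd(d3$a2, dv, p[["out.W"]], p[["out.b"]])
  yhat <- softmax_rows(z)
  list(yhat = yhat,
       cache = list(bf = bf, bs = bs, fi = fi, e3 = e3, p3 = p3, bt = bt,
                    d3 = d3, dv = dv, dh = dh, n = n))
}

recon_bwd <- function(model, cache, dZ) {
  p <- model$params; gr <- list()
  c0 <- model$cfg$base_channels
  dv <- cache$dv; dh <- cache$dh
  cb <- conv_bwd(dZ, cache$d3$a2, dv, p[["out.W"]])
  gr <- gacc(gr, "out.W", cb$dW); gr <- gacc(gr, "out.b", cb$db)
  r3 <- dc_bwd(cb$dX, cache$d3, dv, p, "d3", gr); gr <- r3$gr
  du <- r3$dX[, seq_len(4 * c0), drop = FALSE]
  de3 <- r3$dX[, -seq_len(4 * c0), drop = FALSE]
  dbt <- upsample_back_cpp(du, dh)
  rb <- dc_bwd(dbt, cache$bt, dh, p, "bt", gr); gr <- rb$gr
  de3 <- de3 + maxpool_back_cpp(rb$dX, cache$p3$idx, prod(dv))
  re <- dc_bwd(de3, cache$e3, dv, p, "e3", gr); gr <- re$gr
  df0 <- re$dX
  dMf <- rowsum(df0 / 2, cache$fi$i_f)
  dMs <- rowsum(df0 / 2, cache$fi$i_s)
  gr <- recon_branch_bwd(p, cache$bf, dMf, "bf", gr)
  gr <- recon_branch_bwd(p, cache$bs, dMs, "bs", gr)
  gr
}

# inputs may be a single image matrix or a list of channel matrices
x_to_mat <- function(x) {
  if (is.list(x)) do.call(cbind, lapply(x, as.numeric))
  else matrix(as.numeric(x), ncol = 1)
}
x_shape <- function(x) if (is.list(x)) dim(x[[1]]) else dim(x)

#' Normalized coordinate ramp channels for an image shape
#'
#' Provides absolute-position information (horizontal and vertical ramps in
#' `[0, 1]`) to the landmark networks, which must assign otherwise
#' identical-looking anatomy to side-specific output channels.
#'
#' @param shape `c(nv, nu)`
#' @return list of two matrices (`u` ramp, `v` ramp)
#' @export
coord_channels <- function(shape) {
  nv <- shape[1]; nu <- shape[2]
  list(u = matrix(rep((0:(nu - 1)) / (nu - 1), each = nv), nv, nu),
       v = matrix(rep((0:(nv - 1)) / (nv - 1), times = nu), nv, nu))
}

# forward pass + loss + logit gradients for one training sample
model_sample_pass <- function(model, sample, with_grad = TRUE) {
  which <- model$cfg$which
  if (which == "separation") {
    x <- x_to_mat(sample$x)
    fw <- unet2d_fwd(model, x)
    shp <- dim(sample$y$R)
    yhR <- matrix(fw$outs$dR, shp[1], shp[2])
    yhL <- matrix(fw$outs$dL, shp[1], shp[2])
    loss <- 0.5 * (separation_loss(sample$y$R, yhR) +
                   separation_loss(sample$y$L, yhL))
    if (!with_grad) return(list(loss = loss, outs = fw$outs))
    dzR <- 0.5 * separation_loss_grad(sample$y$R, yhR) * yhR * (1 - yhR)
    dzL <- 0.5 * separation_loss_grad(sample$y$L, yhL) * yhL * (1 - yhL)
    gr <- unet2d_bwd(model, fw$cache,
                     list(dR = matrix(dzR, ncol = 1),
                          dL = matrix(dzL, ncol = 1)))
    return(list(loss = loss, gr = gr))
  }
  if (which == "landmarks") {
    x <- x_to_mat(sample$x)
    fw <- unet2d_fwd(model, x)
    C <- dim(sample$y)[3]
    ym <- matrix(sample$y, ncol = C)
    yh <- fw$outs$d
    loss <- bce_loss(ym, yh)
    if (!with_grad) return(list(loss = loss, outs = fw$outs))
    dz <- (yh - ym) / length(ym)
    gr <- unet2d_bwd(model, fw$cache, list(d = dz))
    return(list(loss = loss, gr = gr))
  }
  # reconstruction
  xf <- matrix(as.numeric(sample$x$frontal), ncol = 1)
  xs <- matrix(as.numeric(sample$x$sagittal), ncol = 1)
  fw <- recon_fwd(model, xf, xs)
  loss <- dice_ce_loss(sample$y, fw$yhat)
  if (!with_grad) return(list(loss = loss, yhat = fw$yhat))
  dz <- dice_ce_grad_logits(sample$y, fw$yhat)
  list(loss = loss, gr = recon_bwd(model, fw$cache, dz))
}

#' Train a network
#'
#' Adam with the configuration's learning rate, epoch count and batch size;
#' batch gradients are averaged. Monitors the validation loss and returns
#' the model at its best-validation epoch, with the full loss history.
#'
#' @param model an `osteo_model`
#' @param samples list of training samples (network-specific `x`/`y` pairs)
#' @param val_samples optional validation samples
#' @param epochs,learning_rate,batch_size optional overrides
#' @param seed RNG seed for shuffling
#' @param verbose print per-epoch losses
#' @return the trained model with a `history` data.frame attached
#' @export
train_network <- function(model, samples, val_samples = NULL,
                          epochs = NULL, learning_rate = NULL,
                          batch_size = NULL, seed = 1L, verbose = FALSE) {
  if (length(samples) == 0) stop("data error: empty training split")
  cfg <- model$cfg
  epochs <- epochs %||% cfg$epochs
  lr <- learning_rate %||% cfg$learning_rate
  bs <- batch_size %||% cfg$batch_size
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  opt <- list(m = lapply(model$params, function(x) x * 0),
              v = lapply(model$params, function(x) x * 0), t = 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  best <- list(val = Inf, params = model$params)
  for (ep in seq_len(epochs)) {
    ord <- sample(seq_along(samples))
    tr_loss <- 0
    i <- 1
    while (i <= length(ord)) {
      idx <- ord[i:min(i + bs - 1, length(ord))]
      gr <- NULL; bl <- 0
      for (j in idx) {
        r <- model_sample_pass(model, samples[[j]], with_grad = TRUE)
        bl <- bl + r$loss
        gr <- if (is.null(gr)) r$gr else {
          for (nm in names(r$gr)) gr[[nm]] <- gr[[nm]] + r$gr[[nm]]
          gr
        }
      }
      tr_loss <- tr_loss + bl
      nb <- length(idx)
      opt$t <- opt$t + 1
      corr <- sqrt(1 - b2^opt$t) / (1 - b1^opt$t)
      for (nm in names(gr)) {
        g <- gr[[nm]] / nb
        opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
        opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
        model$params[[nm]] <- model$params[[nm]] -
          lr * corr * opt$m[[nm]] / (sqrt(opt$v[[nm]]) + eps)
      }
      i <- i + bs
    }
    tr_loss <- tr_loss / length(samples)
    vl <- NA_real_
    if (!is.null(val_samples) && length(val_samples)) {
      vl <- mean(vapply(val_samples, function(s)
        model_sample_pass(model, s, with_grad = FALSE)$loss, 0))
      if (vl < best$val) { best$val <- vl; best$params <- model$params }
    }
    hist <- rbind(hist, data.frame(epoch = ep, train = tr_loss, val = vl))
    if (verbose)
      message(sprintf("[%s] epoch %d train %.5f val %.5f",
                      cfg$which, ep, tr_loss, vl))
  }
  if (is.finite(best$val)) model$params <- best$params
  model$history <- hist
  model
}

#' Run a model forward on one input
#'
#' @param model trained `osteo_model`
#' @param x input: image matrix (separation/landmarks) or
#'   `list(frontal =, sagittal =)` image matrices (reconstruction)
#' @return separation: list of two image matrices (`R`, `L`); landmarks:
#'   `nv x nu x C` heatmap array; reconstruction: `n^3 x classes` softmax
#'   matrix plus attached cube edge `n`
#' @export
predict_model <- function(model, x) {
  if (model$cfg$which == "reconstruction") {
    fw <- recon_fwd(model, matrix(as.numeric(x$frontal), ncol = 1),
                    matrix(as.numeric(x$sagittal), ncol = 1))
    return(structure(fw$yhat, n = fw$cache$n))
  }
  fw <- unet2d_fwd(model, x_to_mat(x))
  shp <- x_shape(x)
  if (model$cfg$which == "separation") {
    return(list(R = matrix(fw$outs$dR, shp[1], shp[2]),
                L = matrix(fw$outs$dL, shp[1], shp[2])))
  }
  array(fw$outs$d, c(shp[1], shp[2], model$cfg$out_channels))
}

#' Decode a landmark position from a heatmap channel
#'
#' Argmax refined by center of mass over a 7x7 window; ties broken toward
#' the lowest (v, then u). An all-zero channel returns `c(NA, NA)`.
#'
#' @param channel `nv x nu` heatmap matrix
#' @return `c(u, v)` continuous 0-based pixel coordinates, or NAs
#' @export
extract_landmark <- function(channel) {
  if (all(channel == 0)) return(c(u = NA_real_, v = NA_real_))
  mx <- max(channel)
  hits <- which(channel == mx, arr.ind = TRUE) # (row = v+1, col = u+1)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  v0 <- hits[1, 1]; u0 <- hits[1, 2]
  nv <- nrow(channel); nu <- ncol(channel)
  vr <- max(1, v0 - 3):min(nv, v0 + 3)
  ur <- max(1, u0 - 3):min(nu, u0 + 3)
  w <- channel[vr, ur, drop = FALSE]
  sw <- sum(w)
  if (sw == 0) return(c(u = u0 - 1, v = v0 - 1))
  uu <- sum(w * matrix(rep(ur - 1, each = length(vr)), length(vr))) / sw
  vv <- sum(w * matrix(rep(vr - 1, times = length(ur)), length(vr))) / sw
  c(u = uu, v = vv)
}
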