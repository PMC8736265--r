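#' Encoder configuration
#'
#' @param backbone `"toy"` (a reduced stack of 3x3 convolution + 2x2
#'   max-pool blocks, suitable for desk-scale experiments) or `"vgg16"`
#'   (the 16-layer shape: five 3x3 convolution blocks with channel widths
#'   64-64 / 128-128 / 256x3 / 512x3 / 512x3, each followed by 2x2 max
#'   pooling, then two 4096-wide fully connected ReLU layers; the
#'   classification softmax is removed and the 1x4096 penultimate vector is
#'   the global image descriptor).
#' @param d_out Width of the pooled global feature vector (the t = -1
#'   injection); must match the decoder embedding width. Default 256.
#' @param d_attn Width of the per-location features handed to attention.
#'   Default 256.
#' @param dropout_p Dropout probability on the penultimate vector before
#'   the dense head, active only in training mode. Default 0.5.
#' @param channels Integer vector of per-block output channels for the toy
#'   backbone. Default `c(8, 16, 16)`.
#' @param weights_path Optional RDS file with pre-computed backbone weights
#'   (same structure as [build_backbone()] produces); `NULL` uses seeded
#'   random weights.
#' @return List of class `cxr_encoder_config`.
#' @export
encoder_config <- function(backbone = c("toy", "vgg16"), d_out = 256L,
                           d_attn = 256L, dropout_p = 0.5,
                           channels = c(8L, 16L, 16L), weights_path = NULL) {
  backbone <- match.arg(backbone)
  if (!(dropout_p >= 0 && dropout_p < 1)) stop("dropout_p must be in [0, 1)")
  structure(list(backbone = backbone, d_out = as.integer(d_out),
                 d_attn = as.integer(d_attn), dropout_p = dropout_p,
                 channels = as.integer(channels),
                 weights_path = weights_path),
            class = "cxr_encoder_config")
}

# 3x3 "same" convolution via im2col. x: H x W x C array; w: (9*C) x K
# matrix with rows ordered (c fastest, then dj, then di); b: length-K bias.
conv3_same <- function(x, w, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  cols <- matrix(0, H * W, 9L * C)
  k <- 0L
  for (di in 0:2) for (dj in 0:2) {
    sl <- xp[di + seq_len(H), dj + seq_len(W), , drop = FALSE]
    cols[, k + seq_len(C)] <- sl
    k <- k + C
  }
  out <- cols %*% w
  out <- sweep(out, 2L, b, "+")
  array(out, c(H, W, ncol(w)))
}

relu <- function(x) { x[x < 0] <- 0; x }

# 2x2 max pooling, stride 2; odd trailing row/column is dropped.
maxpool2 <- function(x) {
  d <- dim(x); H <- d[1] - d[1] %% 2L; W <- d[2] - d[2] %% 2L
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  pmax(x[i1, j1, , drop = FALSE], x[i2, j1, , drop = FALSE],
       x[i1, j2, , drop = FALSE], x[i2, j2, , drop = FALSE])
}

vgg16_channels <- list(c(64L, 64L), c(128L, 128L), c(256L, 256L, 256L),
                       c(512L, 512L, 512L), c(512L, 512L, 512L))

#' Build a convolutional feature-extraction backbone
#'
#' Weights are drawn once from a seeded scaled-normal initialisation (or
#' loaded from `config$weights_path`) and then held fixed: the backbone is
#' a frozen feature extractor, while the dense projection head
#' ([project_features()]) carries the trainable image-side parameters.
#'
#' @param config A `cxr_encoder_config`.
#' @param seed Integer seed for weight initialisation. Default 1.
#' @return An object of class `cxr_backbone` with the convolution stack,
#'   block structure and expected input channel count.
#' @export
build_backbone <- function(config, seed = 1L) {
  if (!inherits(config, "cxr_encoder_config")) stop("unknown backbone config")
  if (!is.null(config$weights_path)) {
    bb <- readRDS(config$weights_path)
    if (!inherits(bb, "cxr_backbone")) stop("weights_path is not a cxr_backbone")
    return(bb)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  he <- function(fan_in, fan_out)
    matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
  if (config$backbone == "toy") {
    blocks <- as.list(config$channels)
    in_ch <- 1L
    fc <- NULL
  } else {
    blocks <- vgg16_channels
    in_ch <- 3L
  }
  conv <- list()
  c_in <- in_ch
  for (bi in seq_along(blocks)) {
    for (c_out in blocks[[bi]]) {
      conv[[length(conv) + 1L]] <- list(
        w = he(9L * c_in, c_out), b = numeric(c_out), block = bi)
      c_in <- c_out
    }
  }
  fc <- NULL
  if (config$backbone == "vgg16") {
    # 224x224 input -> 7x7x512 after five poolings; two 4096-wide FC layers
    fc <- list(list(w = he(7L * 7L * 512L, 4096L), b = numeric(4096L)),
               list(w = he(4096L, 4096L), b = numeric(4096L)))
  }
  structure(list(name = config$backbone, conv = conv,
                 n_blocks = length(blocks), in_ch = in_ch, fc = fc),
            class = "cxr_backbone")
}

#' @export
print.cxr_backbone <- function(x, ...) {
  cat("<cxr_backbone> '", x$name, "': ", length(x$conv),
      " conv layers in ", x$n_blocks, " blocks", sep = "")
  if (!is.null(x$fc)) cat(", 2 FC layers (4096)")
  cat("\n")
  invisible(x)
}

#' Run the backbone on one image
#'
#' @param backbone A `cxr_backbone`.
#' @param image H x W, H x W x 1 or H x W x 3 array in [0, 1]. Grayscale
#'   input is replicated to 3 channels for the "vgg16" backbone.
#' @return List with `spatial` (Hf x Wf x C array, the last convolutional
#'   block's output), `penultimate` (numeric vector: the 1x4096 FC output
#'   for "vgg16", the flattened spatial map for "toy") and `grid_dim`
#'   c(Hf, Wf).
#' @export
backbone_forward <- function(backbone, image) {
  if (length(dim(image)) == 2L) image <- array(image, c(dim(image), 1L))
  if (any(!is.finite(image))) stop("non-finite pixels in input image")
  if (dim(image)[3] == 1L && backbone$in_ch == 3L)
    image <- array(rep(image, 3L), c(dim(image)[1:2], 3L))
  if (dim(image)[3] != backbone$in_ch)
    stop("image has ", dim(image)[3], " channels; backbone expects ", backbone$in_ch)
  min_side <- 2L^backbone$n_blocks
  if (min(dim(image)[1:2]) < min_side)
    stop("image smaller than the backbone's downsampling budget (needs >= ",
         min_side, " px per side)")
  x <- image
  cur_block <- 1L
  for (ly in backbone$conv) {
    if (ly$block > cur_block) { x <- maxpool2(x); cur_block <- ly$block }
    x <- relu(conv3_same(x, ly$w, ly$b))
  }
  x <- maxpool2(x)
  pen <- as.vector(x)
  if (!is.null(backbone$fc)) {
    for (fcl in backbone$fc)
      pen <- relu(as.vector(pen %*% fcl$w) + fcl$b)
  }
  list(spatial = x, penultimate = pen, grid_dim = dim(x)[1:2])
}

#' Trainable projection-head parameters
#'
#' @param p_raw Penultimate vector width of the backbone.
#' @param c_raw Channel count of the backbone's spatial map.
#' @param d_out Pooled output width.
#' @param d_attn Location feature width.
#' @param seed Integer seed.
#' @return List with `Wp`, `bp` (pooled dense head) and `Wl`, `bl`
#'   (per-location linear projection).
#' @export
projection_params <- function(p_raw, c_raw, d_out, d_attn, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  list(Wp = glorot(p_raw, d_out), bp = numeric(d_out),
       Wl = glorot(c_raw, d_attn), bl = numeric(d_attn))
}

#' Project raw backbone features to the decoder's feature grid
#'
#' The pooled global vector is ReLU(dense(dropout(penultimate))); the n
#' spatial locations are a per-location linear projection of the last
#' convolutional map. Dropout (inverted scaling, so expectations match
#' evaluation mode) is active only when `training = TRUE`; in evaluation
#' mode the output is deterministic.
#'
#' @param penultimate Numeric vector (backbone penultimate output).
#' @param spatial Hf x Wf x C array or n x C matrix of raw location
#'   features.
#' @param proj Projection parameters from [projection_params()].
#' @param dropout_p Dropout probability in [0, 1).
#' @param training Logical; enables dropout.
#' @return List of class `cxr_features`: `locations` (n x d_attn matrix),
#'   `pooled` (length d_out), `grid_dim`.
#' @export
project_features <- function(penultimate, spatial, proj, dropout_p = 0,
                             training = FALSE) {
  if (any(!is.finite(penultimate))) stop("non-finite penultimate features")
  if (!(dropout_p >= 0 && dropout_p < 1)) stop("dropout_p must be in [0, 1)")
  grid_dim <- NULL
  if (length(dim(spatial)) == 3L) {
    d <- dim(spatial)
    grid_dim <- d[1:2]
    spatial <- matrix(spatial, d[1] * d[2], d[3])
  }
  if (any(!is.finite(spatial))) stop("non-finite spatial features")
  pen <- as.numeric(penultimate)
  if (training && dropout_p > 0) {
    keep <- stats::runif(length(pen)) >= dropout_p
    pen <- pen * keep / (1 - dropout_p)
  }
  pooled <- relu(as.vector(pen %*% proj$Wp) + proj$bp)
  locations <- sweep(spatial %*% proj$Wl, 2L, proj$bl, "+")
  structure(list(locations = locations, pooled = pooled, grid_dim = grid_dim),
            class = "cxr_features")
}

#' Read an image file into a [0, 1] array
#'
#' PNG via the png package; JPEG via EBImage when available.
#'
#' @param path Image path.
#' @return H x W (grayscale) or H x W x C numeric array in [0, 1].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else if (grepl("\\.jpe?g$", path, ignore.case = TRUE)) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("JPEG input requires the EBImage package")
    img <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(img)) >= 2L) img <- aperm(img, c(2L, 1L, seq_along(dim(img))[-(1:2)]))
  } else stop("unsupported image format: ", path)
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]  # drop alpha
  img
}

#' Encode an image end to end
#'
#' @param image Path or pixel array.
#' @param backbone A `cxr_backbone`.
#' @param proj Projection parameters.
#' @param dropout_p,training Passed to [project_features()].
#' @return A `cxr_features` list.
#' @export
encode_image <- function(image, backbone, proj, dropout_p = 0, training = FALSE) {
  if (is.character(image)) image <- read_image(image)
  raw <- backbone_forward(backbone, image)
  feats <- project_features(raw$penultimate, raw$spatial, proj,
                            dropout_p = dropout_p, training = training)
  feats$grid_dim <- raw$grid_dim
  feats
}
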