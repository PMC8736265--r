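#' Additive (Bahdanau) attention parameters
#'
#' Creates the three arrays of the additive attention scorer
#' e_j = v' tanh(U h_j + W s): `U` (d x a) acts on location features,
#' `W` (s x a) on the decoder query state, and `v` (length a) collapses the
#' tanh layer to a scalar energy per location.
#'
#' @param d Location feature width.
#' @param s Decoder state width.
#' @param a Attention (scorer hidden) width.
#' @param seed Optional integer seed for Glorot-uniform initialisation.
#' @return List with matrices `U`, `W` and vector `v`.
#' @export
attention_params <- function(d, s, a, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
  }
  list(U = glorot(d, a), W = glorot(s, a), v = as.vector(glorot(a, 1L)))
}

#' Attention energies for one decoding step
#'
#' Computes e_j = v' tanh(h_j U + s W) for each of the n image locations;
#' the query `s_prev` is the decoder's previous hidden/output state.
#'
#' @param h n x d matrix of location features (one row per image location).
#' @param s_prev Length-s decoder state vector (the query).
#' @param params List with `U` (d x a), `W` (s x a), `v` (length a), as from
#'   [attention_params()].
#' @return Numeric vector of n unnormalised energies.
#' @export
attention_score <- function(h, s_prev, params) {
  h <- as.matrix(h)
  if (ncol(h) != nrow(params$U))
    stop("location width ", ncol(h), " does not match U (", nrow(params$U), " rows)")
  if (length(s_prev) != nrow(params$W))
    stop("state width ", length(s_prev), " does not match W (", nrow(params$W), " rows)")
  q <- as.vector(s_prev %*% params$W)                # 1 x a
  th <- tanh(sweep(h %*% params$U, 2L, q, "+"))      # n x a
  as.vector(th %*% params$v)
}

#' Normalise attention energies to simplex weights
#'
#' Softmax with max-subtraction for numerical stability; invariant to adding
#' a constant to all energies. The result is non-negative and sums to one —
#' the constraint the context vector construction requires.
#'
#' @param energies Numeric vector of finite energies (length >= 1).
#' @return Weight vector alpha on the probability simplex.
#' @export
attention_normalise <- function(energies) {
  if (length(energies) == 0L) stop("cannot normalise an empty energy vector")
  if (any(!is.finite(energies))) stop("non-finite attention energies")
  z <- exp(energies - max(energies))
  z / sum(z)
}

#' Attention context vector
#'
#' The convex combination C_t = sum_j alpha_j h_j of location features:
#' the "glimpse" of the image handed to the decoder at this step.
#'
#' @param alpha Simplex weight vector of length n.
#' @param h n x d matrix of location features.
#' @return Numeric vector of length d.
#' @export
attention_context <- function(alpha, h) {
  h <- as.matrix(h)
  if (length(alpha) != nrow(h))
    stop("length(alpha) = ", length(alpha), " but h has ", nrow(h), " rows")
  as.vector(crossprod(h, alpha))
}

#' Score, normalise and pool in one call
#'
#' @inheritParams attention_score
#' @return List of class `cxr_attention` with `energies`, `weights`
#'   (simplex) and `context` (length-d vector).
#' @export
attend <- function(h, s_prev, params) {
  e <- attention_score(h, s_prev, params)
  a <- attention_normalise(e)
  structure(list(energies = e, weights = a, context = attention_context(a, h)),
            class = "cxr_attention")
}

# Glorot/Xavier uniform initialiser, used across all dense parameter arrays.
glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Render attention weights as a heat-map overlay PNG
#'
#' Upsamples the n = hf x wf attention weights to the image grid (nearest
#' neighbour) and writes an RGB PNG in which the red channel carries the
#' normalised attention mass over the grayscale image.
#'
#' @param alpha Length-n attention weight vector.
#' @param grid_dim Integer c(hf, wf) with hf * wf = n (feature-map layout,
#'   row-major over image rows).
#' @param image H x W (or H x W x C) array in [0, 1].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
attention_heatmap <- function(alpha, grid_dim, image, path) {
  hf <- grid_dim[1]; wf <- grid_dim[2]
  stopifnot(length(alpha) == hf * wf)
  if (length(dim(image)) == 3L) image <- image[, , 1]
  H <- nrow(image); W <- ncol(image)
  amap <- matrix(alpha, hf, wf)
  amap <- amap / max(amap)
  up <- amap[pmin(hf, ceiling(seq_len(H) / (H / hf))),
             pmin(wf, ceiling(seq_len(W) / (W / wf))), drop = FALSE]
  out <- array(0, c(H, W, 3))
  out[, , 1] <- pmin(1, 0.5 * image + 0.5 * up)
  out[, , 2] <- 0.5 * image
  out[, , 3] <- 0.5 * image
  png::writePNG(out, path)
  invisible(path)
}
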