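# Internal network core: flat parameter set, batched teacher-forced forward
# pass with caches, and backpropagation through time. The exported module
# surfaces (lstm_step, decode_step, attend, project_features, ...) are the
# single-instance views of the same equations; training runs through the
# batched code below, and tests pin the two routes together.

# Flat trainable parameter list. Row 1 of emb is the pad row, held at zero.
init_theta <- function(V, p_raw, c_raw, embed_width, ctx_width, attn_width,
                       hidden_width, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  E <- embed_width; D <- ctx_width; A <- attn_width; H <- hidden_width
  emb <- glorot(V + 1L, E)
  emb[1L, ] <- 0
  theta <- list(
    Wp = glorot(p_raw, E), bp = numeric(E),
    Wl = glorot(c_raw, D), bl = numeric(D),
    emb = emb,
    Ua = glorot(D, A), Wa = glorot(H, A), va = as.vector(glorot(A, 1L)),
    W_ix = glorot(E + D, H), W_im = glorot(H, H),
    W_fx = glorot(E + D, H), W_fm = glorot(H, H),
    W_ox = glorot(E + D, H), W_om = glorot(H, H),
    W_cx = glorot(E + D, H), W_cm = glorot(H, H),
    b_i = numeric(H), b_f = numeric(H), b_o = numeric(H), b_c = numeric(H),
    Wv = glorot(H, V), bv = numeric(V))
  theta
}

model_cfg <- function(V, embed_width, ctx_width, attn_width, hidden_width,
                      use_attention = TRUE, output_tanh = FALSE,
                      dropout_p = 0.5) {
  list(V = as.integer(V), E = as.integer(embed_width),
       D = as.integer(ctx_width), A = as.integer(attn_width),
       H = as.integer(hidden_width), use_attention = isTRUE(use_attention),
       output_tanh = isTRUE(output_tanh), dropout_p = dropout_p)
}

# Nested decoder-parameter view of the flat set (for decode_step etc.).
theta_to_decoder <- function(theta, cfg) {
  structure(list(
    emb = theta$emb,
    attn = list(U = theta$Ua, W = theta$Wa, v = theta$va),
    lstm = structure(theta[c("W_ix", "W_im", "W_fx", "W_fm", "W_ox", "W_om",
                             "W_cx", "W_cm", "b_i", "b_f", "b_o", "b_c")],
                     class = "cxr_lstm_params"),
    head = list(W = theta$Wv, b = theta$bv),
    V = cfg$V, use_attention = cfg$use_attention,
    output_tanh = cfg$output_tanh),
    class = "cxr_decoder_params")
}

theta_to_proj <- function(theta) theta[c("Wp", "bp", "Wl", "bl")]

decoder_to_theta <- function(params) {
  c(list(emb = params$emb, Ua = params$attn$U, Wa = params$attn$W,
         va = params$attn$v, Wv = params$head$W, bv = params$head$b),
    unclass(params$lstm)[c("W_ix", "W_im", "W_fx", "W_fm", "W_ox", "W_om",
                           "W_cx", "W_cm", "b_i", "b_f", "b_o", "b_c")])
}

sigmoid_m <- function(x) 1 / (1 + exp(-x))

row_softmax <- function(x) {
  x <- x - apply(x, 1L, max)
  z <- exp(x)
  z / rowSums(z)
}

# Batched unroll from projected features.
# Q0: B x E pooled vectors; Lmat: (B*n) x D stacked location features
# (rows grouped by sequence); S: B x T padded token-id matrix.
# Returns nll (sum over tokens), n_tok, n_correct, per-sequence prob
# matrices (want_probs) and caches for the backward pass (want_cache).
core_forward <- function(theta, cfg, Q0, Lmat, n_loc, S,
                         training = FALSE, want_cache = FALSE,
                         want_probs = FALSE) {
  B <- nrow(S); Tlen <- ncol(S)
  E <- cfg$E; D <- cfg$D; H <- cfg$H; V <- cfg$V
  use_att <- cfg$use_attention && !is.null(Lmat)
  p_drop <- if (training) cfg$dropout_p else 0
  gidx <- rep(seq_len(B), each = n_loc)
  LU <- if (use_att) Lmat %*% theta$Ua else NULL

  seq_len_b <- rowSums(S != 0L)
  Tm1 <- max(seq_len_b) - 1L

  # t = -1: pooled image vector in the embedding slot, zero context
  x_init <- cbind(Q0, matrix(0, B, D))
  st <- lstm_forward_m(x_init, matrix(0, B, H), matrix(0, B, H), theta, cfg)
  cache_init <- if (want_cache) c(st, list(x = x_init)) else NULL
  Cc <- st$c; Mm <- st$m

  nll <- 0; n_tok <- 0L; n_correct <- 0L
  steps <- if (want_cache) vector("list", Tm1) else NULL
  probs <- if (want_probs) lapply(seq_len(B), function(b)
    matrix(0, max(seq_len_b[b] - 1L, 0L), V)) else NULL

  for (t in seq_len(Tm1)) {
    tok <- S[, t]
    Et <- theta$emb[tok + 1L, , drop = FALSE]
    Me <- NULL
    if (p_drop > 0) {
      Me <- matrix((stats::runif(B * E) >= p_drop) / (1 - p_drop), B, E)
      Et <- Et * Me
    }
    if (use_att) {
      Qa <- Mm %*% theta$Wa
      Tpre <- LU + Qa[gidx, , drop = FALSE]
      Th <- tanh(Tpre)
      e_flat <- as.vector(Th %*% theta$va)
      emat <- matrix(e_flat, n_loc, B)
      emat <- sweep(emat, 2L, apply(emat, 2L, max))
      z <- exp(emat)
      alpha <- sweep(z, 2L, colSums(z), "/")
      ctx <- rowsum(Lmat * as.vector(alpha), gidx)
    } else {
      Th <- NULL; alpha <- NULL
      ctx <- matrix(0, B, D)
    }
    x_t <- cbind(Et, ctx)
    M_prev <- Mm; C_prev <- Cc
    st <- lstm_forward_m(x_t, C_prev, M_prev, theta, cfg)
    Cc <- st$c; Mm <- st$m
    logits <- Mm %*% theta$Wv
    logits <- sweep(logits, 2L, theta$bv, "+")
    P <- row_softmax(logits)

    tgt <- S[, t + 1L]
    mask <- tgt != 0L
    if (any(mask)) {
      rows <- which(mask)
      pc <- P[cbind(rows, tgt[rows])]
      nll <- nll - sum(log(pmax(pc, 1e-12)))
      pred <- max.col(P[rows, , drop = FALSE], ties.method = "first")
      n_correct <- n_correct + sum(pred == tgt[rows])
      n_tok <- n_tok + length(rows)
    }
    if (want_probs) for (b in seq_len(B)) {
      if (t <= seq_len_b[b] - 1L) probs[[b]][t, ] <- P[b, ]
    }
    if (want_cache)
      steps[[t]] <- list(tok = tok, Me = Me, Th = Th, alpha = alpha,
                         x = x_t, i = st$i, f = st$f, o = st$o, g = st$g,
                         C = Cc, C_prev = C_prev, M_prev = M_prev,
                         P = P, tgt = tgt, mask = mask)
  }
  list(nll = nll, n_tok = n_tok, n_correct = n_correct,
       loss = nll / B, probs = probs,
       cache = if (want_cache) list(init = cache_init, steps = steps,
                                    Tm1 = Tm1, gidx = gidx, LU = LU) else NULL)
}

lstm_forward_m <- function(x, C_prev, M_prev, theta, cfg) {
  zi <- x %*% theta$W_ix + M_prev %*% theta$W_im
  zf <- x %*% theta$W_fx + M_prev %*% theta$W_fm
  zo <- x %*% theta$W_ox + M_prev %*% theta$W_om
  zg <- x %*% theta$W_cx + M_prev %*% theta$W_cm
  i <- sigmoid_m(sweep(zi, 2L, theta$b_i, "+"))
  f <- sigmoid_m(sweep(zf, 2L, theta$b_f, "+"))
  o <- sigmoid_m(sweep(zo, 2L, theta$b_o, "+"))
  g <- tanh(sweep(zg, 2L, theta$b_c, "+"))
  Cc <- f * C_prev + i * g
  Mm <- if (cfg$output_tanh) o * tanh(Cc) else o * Cc
  list(c = Cc, m = Mm, i = i, f = f, o = o, g = g)
}

zero_like <- function(theta) lapply(theta, function(p) p * 0)

# Backward pass through the unrolled batch. Returns gradients of the mean
# per-sequence summed NLL with respect to every flat parameter, plus the
# gradients into the projected features (dLmat, dQ0) for the projection
# head.
core_backward <- function(theta, cfg, Lmat, n_loc, fwd) {
  cache <- fwd$cache
  stopifnot(!is.null(cache))
  steps <- cache$steps; Tm1 <- cache$Tm1; gidx <- cache$gidx
  B <- length(steps[[1]]$tok)
  D <- cfg$D; E <- cfg$E
  use_att <- cfg$use_attention && !is.null(steps[[Tm1]]$alpha)
  g <- zero_like(theta)
  dLmat <- if (!is.null(Lmat)) Lmat * 0 else NULL
  dC_next <- matrix(0, B, cfg$H)
  dM_next <- matrix(0, B, cfg$H)

  for (t in rev(seq_len(Tm1))) {
    sc <- steps[[t]]
    # vocabulary head
    dlog <- sc$P
    rows <- which(sc$mask)
    dlog[cbind(rows, sc$tgt[rows])] <- dlog[cbind(rows, sc$tgt[rows])] - 1
    if (length(rows) < B) dlog[!sc$mask, ] <- 0
    dlog <- dlog / B
    Mm <- if (cfg$output_tanh) sc$o * tanh(sc$C) else sc$o * sc$C
    g$Wv <- g$Wv + crossprod(Mm, dlog)
    g$bv <- g$bv + colSums(dlog)
    dM <- dlog %*% t(theta$Wv) + dM_next

    bk <- lstm_backward_m(dM, dC_next, sc, theta, cfg, g)
    g <- bk$g
    dC_next <- bk$dC_prev
    dM_prev <- bk$dM_prev
    dx <- bk$dx

    dEt <- dx[, seq_len(E), drop = FALSE]
    dctx <- dx[, E + seq_len(D), drop = FALSE]

    if (!is.null(sc$Me)) dEt <- dEt * sc$Me
    gr <- rowsum(dEt, sc$tok)
    ids <- as.integer(rownames(gr)) + 1L
    g$emb[ids, ] <- g$emb[ids, , drop = FALSE] + gr

    if (use_att) {
      alpha_flat <- as.vector(sc$alpha)
      dctx_rep <- dctx[gidx, , drop = FALSE]
      dalpha <- rowSums(Lmat * dctx_rep)                    # (B*n)
      dLmat <- dLmat + alpha_flat * dctx_rep
      amat <- sc$alpha
      damat <- matrix(dalpha, n_loc, B)
      s <- colSums(amat * damat)
      dE_sc <- amat * sweep(damat, 2L, s)                   # n x B
      dE_flat <- as.vector(dE_sc)
      dTh <- outer(dE_flat, theta$va)                       # (B*n) x A
      g$va <- g$va + as.vector(crossprod(sc$Th, dE_flat))
      dTpre <- dTh * (1 - sc$Th^2)
      g$Ua <- g$Ua + crossprod(Lmat, dTpre)
      dLmat <- dLmat + dTpre %*% t(theta$Ua)
      dQa <- rowsum(dTpre, gidx)
      g$Wa <- g$Wa + crossprod(sc$M_prev, dQa)
      dM_prev <- dM_prev + dQa %*% t(theta$Wa)
    }
    dM_next <- dM_prev
  }

  # t = -1 image-injection step
  ic <- cache$init
  bk <- lstm_backward_m(dM_next, dC_next, ic, theta, cfg, g,
                        C_prev = matrix(0, B, cfg$H),
                        M_prev = matrix(0, B, cfg$H))
  g <- bk$g
  dQ0 <- bk$dx[, seq_len(E), drop = FALSE]
  g$emb[1L, ] <- 0
  list(g = g, dLmat = dLmat, dQ0 = dQ0)
}

lstm_backward_m <- function(dM, dC_in, sc, theta, cfg, g,
                            C_prev = NULL, M_prev = NULL) {
  if (is.null(C_prev)) C_prev <- sc$C_prev
  if (is.null(M_prev)) M_prev <- sc$M_prev
  Cc <- sc$c %||% sc$C
  if (cfg$output_tanh) {
    tc <- tanh(Cc)
    dO <- dM * tc
    dC <- dM * sc$o * (1 - tc^2) + dC_in
  } else {
    dO <- dM * Cc
    dC <- dM * sc$o + dC_in
  }
  dI <- dC * sc$g
  dG <- dC * sc$i
  dF <- dC * C_prev
  dC_prev <- dC * sc$f
  dZi <- dI * sc$i * (1 - sc$i)
  dZf <- dF * sc$f * (1 - sc$f)
  dZo <- dO * sc$o * (1 - sc$o)
  dZg <- dG * (1 - sc$g^2)
  x <- sc$x
  g$W_ix <- g$W_ix + crossprod(x, dZi)
  g$W_fx <- g$W_fx + crossprod(x, dZf)
  g$W_ox <- g$W_ox + crossprod(x, dZo)
  g$W_cx <- g$W_cx + crossprod(x, dZg)
  g$W_im <- g$W_im + crossprod(M_prev, dZi)
  g$W_fm <- g$W_fm + crossprod(M_prev, dZf)
  g$W_om <- g$W_om + crossprod(M_prev, dZo)
  g$W_cm <- g$W_cm + crossprod(M_prev, dZg)
  g$b_i <- g$b_i + colSums(dZi)
  g$b_f <- g$b_f + colSums(dZf)
  g$b_o <- g$b_o + colSums(dZo)
  g$b_c <- g$b_c + colSums(dZg)
  dx <- dZi %*% t(theta$W_ix) + dZf %*% t(theta$W_fx) +
    dZo %*% t(theta$W_ox) + dZg %*% t(theta$W_cx)
  dM_prev <- dZi %*% t(theta$W_im) + dZf %*% t(theta$W_fm) +
    dZo %*% t(theta$W_om) + dZg %*% t(theta$W_cm)
  list(g = g, dx = dx, dM_prev = dM_prev, dC_prev = dC_prev)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Projection stage + core, from raw (frozen-backbone) features.
# pen_raw: B x Praw; Sraw: (B*n) x Craw.
forward_batch <- function(theta, cfg, pen_raw, Sraw, n_loc, S,
                          training = FALSE, want_cache = FALSE,
                          want_probs = FALSE) {
  B <- nrow(S)
  p_drop <- if (training) cfg$dropout_p else 0
  pen_d <- pen_raw
  Mp <- NULL
  if (p_drop > 0) {
    Mp <- matrix((stats::runif(length(pen_raw)) >= p_drop) / (1 - p_drop),
                 nrow(pen_raw), ncol(pen_raw))
    pen_d <- pen_raw * Mp
  }
  Zp <- sweep(pen_d %*% theta$Wp, 2L, theta$bp, "+")
  Q0 <- relu(Zp)
  Lmat <- if (cfg$use_attention)
    sweep(Sraw %*% theta$Wl, 2L, theta$bl, "+") else NULL
  fwd <- core_forward(theta, cfg, Q0, Lmat, n_loc, S,
                      training = training, want_cache = want_cache,
                      want_probs = want_probs)
  fwd$proj_cache <- if (want_cache) list(pen_d = pen_d, Zp = Zp,
                                         Lmat = Lmat) else NULL
  fwd
}

backward_batch <- function(theta, cfg, Sraw, n_loc, fwd) {
  pc <- fwd$proj_cache
  bk <- core_backward(theta, cfg, pc$Lmat, n_loc, fwd)
  g <- bk$g
  dZp <- bk$dQ0 * (pc$Zp > 0)
  g$Wp <- g$Wp + crossprod(pc$pen_d, dZp)
  g$bp <- g$bp + colSums(dZp)
  if (!is.null(bk$dLmat)) {
    g$Wl <- g$Wl + crossprod(Sraw, bk$dLmat)
    g$bl <- g$bl + colSums(bk$dLmat)
  }
  g
}
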