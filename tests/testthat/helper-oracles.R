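# Independent reference implementations used as oracles. These are written
# deliberately as plain scalar loops / string tables, separate from the
# package's vectorised code paths.

# LSTM gate equations, one unit at a time, explicit sums.
oracle_lstm_step <- function(x, c_prev, m_prev, p, output_tanh = FALSE) {
  H <- length(c_prev)
  sig <- function(z) 1 / (1 + exp(-z))
  c_t <- m_t <- numeric(H)
  for (u in seq_len(H)) {
    zi <- p$b_i[u]; zf <- p$b_f[u]; zo <- p$b_o[u]; zg <- p$b_c[u]
    for (k in seq_along(x)) {
      zi <- zi + x[k] * p$W_ix[k, u]
      zf <- zf + x[k] * p$W_fx[k, u]
      zo <- zo + x[k] * p$W_ox[k, u]
      zg <- zg + x[k] * p$W_cx[k, u]
    }
    for (k in seq_len(H)) {
      zi <- zi + m_prev[k] * p$W_im[k, u]
      zf <- zf + m_prev[k] * p$W_fm[k, u]
      zo <- zo + m_prev[k] * p$W_om[k, u]
      zg <- zg + m_prev[k] * p$W_cm[k, u]
    }
    i <- sig(zi); f <- sig(zf); o <- sig(zo)
    c_t[u] <- f * c_prev[u] + i * tanh(zg)
    m_t[u] <- if (output_tanh) o * tanh(c_t[u]) else o * c_t[u]
  }
  list(c = c_t, m = m_t)
}

# Additive attention: energies, softmax weights, context; scalar loops.
oracle_attention <- function(h, s, U, W, v) {
  n <- nrow(h); d <- ncol(h); a <- length(v)
  e <- numeric(n)
  for (j in seq_len(n)) {
    acc <- 0
    for (ai in seq_len(a)) {
      z <- 0
      for (di in seq_len(d)) z <- z + U[di, ai] * h[j, di]
      for (k in seq_along(s)) z <- z + W[k, ai] * s[k]
      acc <- acc + v[ai] * tanh(z)
    }
    e[j] <- acc
  }
  w <- exp(e - max(e)); w <- w / sum(w)
  ctx <- numeric(d)
  for (j in seq_len(n)) for (di in seq_len(d))
    ctx[di] <- ctx[di] + w[j] * h[j, di]
  list(energies = e, weights = w, context = ctx)
}

oracle_softmax <- function(z) { ez <- exp(z - max(z)); ez / sum(ez) }

# Plain BLEU via pasted n-gram string tables; returns the four cumulative
# scores. Independent of the package's counting code.
oracle_bleu <- function(cand, refs, w3 = c(0.33, 0.33, 0.33)) {
  grams <- function(toks, n) {
    if (length(toks) < n) return(character(0))
    sapply(seq_len(length(toks) - n + 1L),
           function(i) paste(toks[i:(i + n - 1L)], collapse = " "))
  }
  p <- numeric(4)
  for (n in 1:4) {
    cg <- grams(cand, n)
    if (length(cg) == 0L) { p[n] <- 0; next }
    ct <- table(cg)
    clipped <- 0
    for (g in names(ct)) {
      mx <- 0
      for (r in refs) {
        rt <- table(grams(r, n))
        cnt <- if (g %in% names(rt)) rt[[g]] else 0
        if (cnt > mx) mx <- cnt
      }
      clipped <- clipped + min(ct[[g]], mx)
    }
    p[n] <- clipped / length(cg)
  }
  rl <- sapply(refs, length)
  r <- rl[order(abs(rl - length(cand)), rl)][1]
  bp <- if (length(cand) > r) 1 else exp(1 - r / length(cand))
  wsets <- list(c(1, 0, 0, 0), c(0.5, 0.5, 0, 0), c(w3, 0), rep(0.25, 4))
  sapply(wsets, function(w) {
    act <- which(w > 0)
    if (any(p[act] == 0)) return(0)
    bp * exp(sum(w[act] * log(p[act])))
  })
}

# Exhaustive search over all token sequences up to max_len - 1 words
# (terminating early at the end token, id 2), scored through decode_step.
oracle_enumerate <- function(features, params, max_len) {
  best <- list(logprob = -Inf, ids = integer(0))
  rec <- function(prev, state, ids, lp, depth) {
    st <- decode_step(prev, state, features, params)
    lpv <- log(pmax(st$p_next, 1e-300))
    for (v in seq_len(params$V)) {
      lp2 <- lp + lpv[v]
      if (v == 2L) {
        if (lp2 > best$logprob) best <<- list(logprob = lp2, ids = ids)
      } else if (depth < max_len - 1L) {
        rec(v, st$state, c(ids, v), lp2, depth + 1L)
      } else {
        if (lp2 > best$logprob) best <<- list(logprob = lp2, ids = c(ids, v))
      }
    }
  }
  st0 <- init_state(features, params)
  rec(1L, st0, integer(0), 0, 1L)
  best
}

# Random small decoder + feature fixtures.
make_features <- function(n, d, e, seed = 1) {
  set.seed(seed)
  structure(list(locations = matrix(rnorm(n * d), n, d),
                 pooled = rnorm(e), grid_dim = NULL),
            class = "cxr_features")
}

make_decoder <- function(V = 3L, E = 4L, D = 3L, A = 3L, H = 4L, seed = 1,
                         use_attention = TRUE) {
  decoder_params(V, embed_width = E, ctx_width = D, attn_width = A,
                 hidden_width = H, seed = seed, use_attention = use_attention)
}
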