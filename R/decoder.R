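#' LSTM gate parameters
#'
#' Eight weight matrices (input/forget/output/candidate gates, each with an
#' input-to-hidden and a hidden-to-hidden matrix) plus four bias vectors
#' initialised to zero. The decoder input width is embedding width plus
#' attention context width, because the context vector is concatenated with
#' the previous word's embedding at every step.
#'
#' @param input_width Width of the step input x_t.
#' @param hidden_width Width of the cell memory c and output m.
#' @param seed Optional integer seed for Glorot-uniform initialisation.
#' @return List of class `cxr_lstm_params`.
#' @export
lstm_params <- function(input_width, hidden_width, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
  }
  g <- function() glorot(input_width, hidden_width)
  r <- function() glorot(hidden_width, hidden_width)
  structure(list(
    W_ix = g(), W_im = r(), W_fx = g(), W_fm = r(),
    W_ox = g(), W_om = r(), W_cx = g(), W_cm = r(),
    b_i = numeric(hidden_width), b_f = numeric(hidden_width),
    b_o = numeric(hidden_width), b_c = numeric(hidden_width)),
    class = "cxr_lstm_params")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

zero_state <- function(hidden_width) {
  list(c = numeric(hidden_width), m = numeric(hidden_width))
}

#' One LSTM cell update
#'
#' Applies the gate equations: the sigmoid input, forget and output gates
#' each see the step input and the previous output
#' (i = sigma(W_ix x + W_im m + b_i), similarly f and o); the cell memory is
#' c_t = f * c_{t-1} + i * tanh(W_cx x + W_cm m + b_c); and the emitted
#' output is m_t = o * c_t (optionally m_t = o * tanh(c_t) when
#' `output_tanh` is set — the convention this model follows by default
#' applies the output gate to the raw cell value).
#'
#' @param x Step input vector.
#' @param state List with `c` (cell memory) and `m` (previous output),
#'   e.g. from `list(c = 0s, m = 0s)`.
#' @param params `cxr_lstm_params` (biases optional; missing biases are 0).
#' @param output_tanh Logical; squash the cell with tanh before the output
#'   gate. Default `FALSE`.
#' @return New state list with `c` and `m`, plus gate activations `i`, `f`,
#'   `o` for inspection.
#' @export
lstm_step <- function(x, state, params, output_tanh = FALSE) {
  x <- as.numeric(x)
  if (length(x) != nrow(params$W_ix))
    stop("input width ", length(x), " does not match W_ix (", nrow(params$W_ix), " rows)")
  H <- ncol(params$W_ix)
  if (length(state$c) != H || length(state$m) != H)
    stop("state width does not match hidden width ", H)
  if (any(!is.finite(state$c)) || any(!is.finite(state$m)))
    stop("non-finite decoder state")
  b <- function(nm) if (is.null(params[[nm]])) 0 else params[[nm]]
  m0 <- state$m
  i <- sigmoid(as.vector(x %*% params$W_ix + m0 %*% params$W_im) + b("b_i"))
  f <- sigmoid(as.vector(x %*% params$W_fx + m0 %*% params$W_fm) + b("b_f"))
  o <- sigmoid(as.vector(x %*% params$W_ox + m0 %*% params$W_om) + b("b_o"))
  g <- tanh(as.vector(x %*% params$W_cx + m0 %*% params$W_cm) + b("b_c"))
  c_t <- f * state$c + i * g
  m_t <- if (output_tanh) o * tanh(c_t) else o * c_t
  list(c = c_t, m = m_t, i = i, f = f, o = o)
}

#' Initialise the decoder state from image features
#'
#' The pooled image vector is injected once, as the step input at t = -1,
#' before any word is processed: one LSTM update from the all-zero state
#' with the pooled vector in the embedding slot and the context slot
#' zero-filled (there is no query state yet, so attention is bypassed). No
#' token is emitted for this step.
#'
#' @param features Feature grid list with `pooled` (and `locations`).
#' @param params Full decoder parameter list (see [decoder_params()]).
#' @return A `DecoderState` list with `c` and `m`.
#' @export
init_state <- function(features, params) {
  d_ctx <- nrow(params$attn$U)
  x <- c(as.numeric(features$pooled), numeric(d_ctx))
  st <- lstm_step(x, zero_state(ncol(params$lstm$W_ix)), params$lstm,
                  output_tanh = isTRUE(params$output_tanh))
  list(c = st$c, m = st$m)
}

#' Full decoder parameter set
#'
#' Embedding table, attention scorer, LSTM gates, and the affine vocabulary
#' head. Row 1 of the embedding matrix belongs to the pad id 0 and is held
#' at zero; token id k uses row k + 1.
#'
#' @param V Vocabulary size.
#' @param embed_width Word embedding width (also the pooled image vector
#'   width, since image and words are projected to the same space).
#' @param ctx_width Attention context width (location feature width d).
#' @param attn_width Attention scorer hidden width.
#' @param hidden_width LSTM hidden width.
#' @param seed Integer seed.
#' @param use_attention Logical; `FALSE` zeroes the context vector at every
#'   step (the attention-ablated variant).
#' @param output_tanh Passed to [lstm_step()].
#' @return List of class `cxr_decoder_params`.
#' @export
decoder_params <- function(V, embed_width = 64L, ctx_width = 32L,
                           attn_width = 32L, hidden_width = 96L,
                           seed = 1L, use_attention = TRUE,
                           output_tanh = FALSE) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  emb <- glorot(V + 1L, embed_width)
  emb[1L, ] <- 0
  structure(list(
    emb = emb,
    attn = list(U = glorot(ctx_width, attn_width),
                W = glorot(hidden_width, attn_width),
                v = as.vector(glorot(attn_width, 1L))),
    lstm = lstm_params(embed_width + ctx_width, hidden_width),
    head = list(W = glorot(hidden_width, V), b = numeric(V)),
    V = as.integer(V),
    use_attention = isTRUE(use_attention),
    output_tanh = isTRUE(output_tanh)),
    class = "cxr_decoder_params")
}

#' One decoding step: embed, attend, recur, predict
#'
#' Embeds the previous token, computes additive attention over the image
#' locations with the previous output m as query, concatenates embedding
#' and context as the LSTM input, updates the state, and maps the new
#' output through the affine vocabulary head and softmax.
#'
#' @param prev_token_id Integer id of the previous token (1..V).
#' @param state `DecoderState` list with `c`, `m`.
#' @param features Feature grid list with `locations` (n x d) and `pooled`.
#' @param params `cxr_decoder_params`.
#' @return List of class `cxr_step`: `p_next` (length-V probability
#'   vector), `state`, `attention` (a `cxr_attention`, or `NULL` when
#'   attention is disabled).
#' @export
decode_step <- function(prev_token_id, state, features, params) {
  V <- params$V
  if (!is.numeric(prev_token_id) || length(prev_token_id) != 1L ||
      is.na(prev_token_id) || prev_token_id < 1 || prev_token_id > V)
    stop("invalid token id: ", prev_token_id)
  e_t <- params$emb[as.integer(prev_token_id) + 1L, ]
  if (params$use_attention) {
    att <- attend(features$locations, state$m, params$attn)
    ctx <- att$context
  } else {
    att <- NULL
    ctx <- numeric(nrow(params$attn$U))
  }
  st <- lstm_step(c(e_t, ctx), state, params$lstm,
                  output_tanh = params$output_tanh)
  logits <- as.vector(st$m %*% params$head$W) + params$head$b
  structure(list(p_next = softmax(logits),
                 state = list(c = st$c, m = st$m),
                 attention = att),
            class = "cxr_step")
}
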