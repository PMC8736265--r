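#' Greedy (argmax) report generation
#'
#' Starting from the image injection at t = -1 and the start token, emits
#' at each step the highest-probability token (ties broken by lowest token
#' id) until the end token appears or `max_len - 1` words have been
#' produced, in which case the output is flagged as truncated. With
#' `stochastic = TRUE` the next token is drawn from the predicted
#' distribution instead of the argmax.
#'
#' @param features A `cxr_features` for the image (see [encode_image()]).
#' @param params A `cxr_decoder_params`.
#' @param max_len Maximum sequence length (>= 2); at most `max_len - 1`
#'   words are emitted.
#' @param vocab Optional `cxr_vocab`; when given, word strings and the
#'   report text are included in the result.
#' @param stochastic Sample instead of argmax. Default `FALSE`.
#' @return List of class `cxr_generation`: `token_ids` (emitted words,
#'   without start/end), `logprob` (summed log-probability, including the
#'   end token when reached), `attention` (list of per-step weight
#'   vectors), `truncated`, and — with a vocabulary — `tokens`, `report`.
#' @export
greedy_sample <- function(features, params, max_len = 24L, vocab = NULL,
                          stochastic = FALSE) {
  stopifnot(max_len >= 2L)
  end_id <- 2L
  state <- init_state(features, params)
  prev <- 1L  # startseq
  ids <- integer(0)
  att <- list()
  logprob <- 0
  truncated <- FALSE
  repeat {
    step <- decode_step(prev, state, features, params)
    state <- step$state
    nxt <- if (stochastic) {
      sample.int(params$V, 1L, prob = step$p_next)
    } else which.max(step$p_next)
    logprob <- logprob + log(max(step$p_next[nxt], 1e-300))
    if (!is.null(step$attention)) att[[length(att) + 1L]] <- step$attention$weights
    if (nxt == end_id) break
    ids <- c(ids, nxt)
    prev <- nxt
    if (length(ids) >= max_len - 1L) { truncated <- TRUE; break }
  }
  out <- list(token_ids = ids, logprob = logprob, attention = att,
              truncated = truncated)
  if (!is.null(vocab)) {
    out$tokens <- vocab$tokens[ids]
    out$report <- paste(out$tokens, collapse = " ")
  }
  structure(out, class = "cxr_generation")
}

#' @export
print.cxr_generation <- function(x, ...) {
  txt <- if (!is.null(x$report)) x$report else paste(x$token_ids, collapse = " ")
  cat("<cxr_generation> \"", txt, "\"  (logprob ",
      sprintf("%.4f", x$logprob),
      if (x$truncated) ", truncated" else "", ")\n", sep = "")
  invisible(x)
}

#' Beam-search report generation
#'
#' Length-wise beam search over summed log-probabilities: at every step
#' each live hypothesis is extended by every vocabulary token, the best
#' `k` continuations survive, and hypotheses that emit the end token
#' retire into the candidate pool. `k = 1` reproduces [greedy_sample()]
#' exactly (same lowest-id tie-break). By default scores are raw summed
#' log-probabilities; `length_norm = TRUE` divides by the emitted length
#' when ranking the final pool.
#'
#' @inheritParams greedy_sample
#' @param k Beam width (>= 1).
#' @param length_norm Normalise final scores by length. Default `FALSE`.
#' @return A `cxr_generation` (the best sequence found).
#' @export
beam_search <- function(features, params, k = 3L, max_len = 24L,
                        vocab = NULL, length_norm = FALSE) {
  if (k < 1L) stop("beam width k must be >= 1")
  stopifnot(max_len >= 2L)
  end_id <- 2L
  state0 <- init_state(features, params)
  live <- list(list(ids = integer(0), prev = 1L, logprob = 0,
                    state = state0, att = list()))
  pool <- list()
  for (step_no in seq_len(max_len - 1L)) {
    cand <- list()
    for (hyp in live) {
      st <- decode_step(hyp$prev, hyp$state, features, params)
      lp <- log(pmax(st$p_next, 1e-300))
      aw <- if (!is.null(st$attention)) st$attention$weights else NULL
      for (v in seq_len(params$V)) {
        cand[[length(cand) + 1L]] <- list(
          ids = hyp$ids, prev = v, logprob = hyp$logprob + lp[v],
          state = st$state,
          att = if (is.null(aw)) hyp$att else c(hyp$att, list(aw)),
          tok = v)
      }
    }
    scores <- vapply(cand, `[[`, 0, "logprob")
    toks <- vapply(cand, `[[`, 0L, "tok")
    ord <- order(-scores, toks)
    keep <- ord[seq_len(min(k, length(ord)))]
    live <- list()
    for (ci in keep) {
      h <- cand[[ci]]
      if (h$tok == end_id) {
        h$truncated <- FALSE
        pool[[length(pool) + 1L]] <- h
      } else {
        h$ids <- c(h$ids, h$tok)
        live[[length(live) + 1L]] <- h
      }
    }
    if (length(live) == 0L) break
  }
  for (h in live) {
    h$truncated <- TRUE
    pool[[length(pool) + 1L]] <- h
  }
  final_score <- vapply(pool, function(h) {
    s <- h$logprob
    if (length_norm) s <- s / max(length(h$ids) + 1L, 1L)
    s
  }, 0)
  best <- pool[[order(-final_score)[1]]]
  out <- list(token_ids = best$ids, logprob = best$logprob,
              attention = best$att, truncated = best$truncated)
  if (!is.null(vocab)) {
    out$tokens <- vocab$tokens[best$ids]
    out$report <- paste(out$tokens, collapse = " ")
  }
  structure(out, class = "cxr_generation")
}

#' Log-probability of a fixed token sequence under the model
#'
#' Re-scores an emitted word sequence through [decode_step()]: the summed
#' log-probability of each word given its predecessors, plus the end-token
#' term unless `truncated`. Generation is self-consistent with this score.
#'
#' @param token_ids Integer word ids (without start/end sentinels).
#' @param features,params As in [greedy_sample()].
#' @param truncated If `TRUE`, the end-token probability is not added.
#' @return Numeric scalar log-probability.
#' @export
score_sequence <- function(token_ids, features, params, truncated = FALSE) {
  state <- init_state(features, params)
  prev <- 1L
  lp <- 0
  for (id in token_ids) {
    st <- decode_step(prev, state, features, params)
    lp <- lp + log(max(st$p_next[id], 1e-300))
    state <- st$state
    prev <- id
  }
  if (!truncated) {
    st <- decode_step(prev, state, features, params)
    lp <- lp + log(max(st$p_next[2L], 1e-300))
  }
  lp
}
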