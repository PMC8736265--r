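#' BLEU weight vectors
#'
#' Cumulative weights for BLEU-1..4 as conventionally printed:
#' (1,0,0,0), (0.5,0.5,0,0), (0.33,0.33,0.33,0), (0.25,0.25,0.25,0.25).
#' `exact_thirds = TRUE` replaces the printed 0.33 entries with exact 1/3.
#'
#' @param exact_thirds Logical, default `FALSE`.
#' @return List of four weight vectors.
#' @export
bleu_weights <- function(exact_thirds = FALSE) {
  w3 <- if (exact_thirds) rep(1 / 3, 3) else rep(0.33, 3)
  list(bleu1 = c(1, 0, 0, 0),
       bleu2 = c(0.5, 0.5, 0, 0),
       bleu3 = c(w3, 0),
       bleu4 = rep(0.25, 4))
}

# n-gram count table for one token vector: named integer vector.
ngram_counts <- function(tokens, n) {
  L <- length(tokens)
  if (L < n) return(integer(0))
  grams <- tokens
  if (n > 1L) {
    grams <- vapply(seq_len(L - n + 1L), function(i)
      paste(tokens[i:(i + n - 1L)], collapse = "\r"), "")
  }
  c(table(grams))
}

# Clipped n-gram matches and candidate total for one candidate against refs.
clipped_matches <- function(cand_tokens, ref_token_lists, n) {
  cc <- ngram_counts(cand_tokens, n)
  total <- sum(cc)
  if (total == 0L) return(c(match = 0, total = 0))
  maxref <- integer(length(cc))
  names(maxref) <- names(cc)
  for (ref in ref_token_lists) {
    rc <- ngram_counts(ref, n)
    shared <- intersect(names(cc), names(rc))
    if (length(shared))
      maxref[shared] <- pmax(maxref[shared], rc[shared])
  }
  c(match = sum(pmin(cc, maxref)), total = total)
}

# Closest-length reference; ties go to the shorter reference.
effective_ref_length <- function(c_len, ref_lens) {
  d <- abs(ref_lens - c_len)
  ref_lens[order(d, ref_lens)][1]
}

bleu_from_stats <- function(match, total, c_len, r_len, weights, smooth_eps) {
  p <- ifelse(total > 0, match / total, 0)
  bp <- min(1, exp(1 - r_len / max(c_len, 1)))
  score_one <- function(w) {
    act <- which(w > 0)
    pw <- p[act]
    if (any(pw == 0)) {
      if (smooth_eps <= 0) return(0)
      pw[pw == 0] <- smooth_eps
    }
    bp * exp(sum(w[act] * log(pw)))
  }
  ws <- weights
  structure(list(bleu1 = score_one(ws$bleu1), bleu2 = score_one(ws$bleu2),
                 bleu3 = score_one(ws$bleu3), bleu4 = score_one(ws$bleu4),
                 precisions = p, brevity_penalty = bp,
                 candidate_length = c_len, reference_length = r_len,
                 weights = ws),
            class = "cxr_bleu")
}

#' @export
print.cxr_bleu <- function(x, ...) {
  cat(sprintf("BLEU-1 %.4f  BLEU-2 %.4f  BLEU-3 %.4f  BLEU-4 %.4f  (BP %.4f)\n",
              x$bleu1, x$bleu2, x$bleu3, x$bleu4, x$brevity_penalty))
  invisible(x)
}

#' Sentence-level BLEU-1..4
#'
#' Modified (clipped) n-gram precisions p_n up to order 4, combined with
#' cumulative weights as BP * exp(sum w_n log p_n), where the brevity
#' penalty is BP = min(1, exp(1 - r/c)) and r is the closest-length
#' reference. With no smoothing (the default) a zero precision at any
#' weighted order gives score 0.
#'
#' @param candidate Character vector of tokens, or a single string that is
#'   split on whitespace.
#' @param references A token vector, a list of token vectors, or a
#'   character vector of reference strings.
#' @param weights Weight list from [bleu_weights()].
#' @param smooth_eps Replace zero precisions by this epsilon (0 disables
#'   smoothing; useful because short clinical sentences often have no
#'   matching 4-gram at all). Default 0.
#' @return Object of class `cxr_bleu` with `bleu1..bleu4`, per-order
#'   `precisions`, `brevity_penalty` and lengths.
#' @export
bleu <- function(candidate, references, weights = bleu_weights(),
                 smooth_eps = 0) {
  candidate <- as_tokens(candidate)
  references <- as_token_list(references)
  if (length(references) == 0L) stop("at least one reference is required")
  if (length(candidate) == 0L) {
    warning("empty candidate: all BLEU scores are 0")
    return(bleu_from_stats(rep(0, 4), rep(0, 4), 0,
                           effective_ref_length(0, lengths(references)),
                           weights, smooth_eps))
  }
  st <- vapply(1:4, function(n) clipped_matches(candidate, references, n),
               c(match = 0, total = 0))
  r_len <- effective_ref_length(length(candidate), lengths(references))
  bleu_from_stats(st["match", ], st["total", ], length(candidate), r_len,
                  weights, smooth_eps)
}

as_tokens <- function(x) {
  if (length(x) == 1L && is.character(x) && grepl("[[:space:]]", x))
    x <- strsplit(x, "[[:space:]]+")[[1]]
  x <- as.character(x)
  x[nzchar(x)]
}

as_token_list <- function(refs) {
  if (is.list(refs)) return(lapply(refs, as_tokens))
  if (is.character(refs) && length(refs) > 1L && !any(grepl("[[:space:]]", refs)))
    return(list(as_tokens(refs)))  # a single tokenised reference
  lapply(as.character(refs), as_tokens)
}

#' Corpus-level BLEU-1..4
#'
#' Pools clipped n-gram match counts, candidate totals and effective
#' reference lengths over all candidate/reference pairs before computing
#' precisions and the brevity penalty (the standard corpus aggregation).
#' A single pair reduces exactly to [bleu()].
#'
#' @param candidates List (or character vector) of candidates.
#' @param references List of reference sets, one per candidate; each set as
#'   in [bleu()].
#' @param weights,smooth_eps As in [bleu()].
#' @return Object of class `cxr_bleu`.
#' @export
corpus_bleu <- function(candidates, references, weights = bleu_weights(),
                        smooth_eps = 0) {
  if (is.character(candidates)) candidates <- as.list(candidates)
  stopifnot(length(candidates) >= 1L, length(candidates) == length(references))
  match <- total <- rep(0, 4)
  c_len <- r_len <- 0
  for (i in seq_along(candidates)) {
    cand <- as_tokens(candidates[[i]])
    refs <- as_token_list(references[[i]])
    if (length(cand) == 0L) {
      r_len <- r_len + effective_ref_length(0, lengths(refs))
      next
    }
    for (n in 1:4) {
      st <- clipped_matches(cand, refs, n)
      match[n] <- match[n] + st["match"]
      total[n] <- total[n] + st["total"]
    }
    c_len <- c_len + length(cand)
    r_len <- r_len + effective_ref_length(length(cand), lengths(refs))
  }
  bleu_from_stats(match, total, c_len, r_len, weights, smooth_eps)
}

#' Label a sentence as describing normality or an abnormality
#'
#' A preprocessed sentence is labelled `"normal"` when it contains any of
#' the normality keywords (defaults: "no", "normal", "clear", "stable"),
#' and `"abnormal"` otherwise (including the empty sentence).
#'
#' @param sentence Token vector or whitespace-separated string.
#' @param keywords Character vector of normality keywords.
#' @return `"normal"` or `"abnormal"`.
#' @export
label_normality <- function(sentence,
                            keywords = c("no", "normal", "clear", "stable")) {
  toks <- as_tokens(sentence)
  if (length(toks) > 0L && any(toks %in% keywords)) "normal" else "abnormal"
}
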