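#' Fit a chest-X-ray report generator
#'
#' Trains the full encoder-attention-decoder pipeline on an image/report
#' corpus by teacher forcing: findings are preprocessed into short
#' reports, encoded against a corpus vocabulary, and an LSTM decoder
#' learns to predict each token from the image (injected once at t = -1
#' as a pooled feature vector) and all preceding tokens, with an additive
#' attention context vector over spatial image locations concatenated to
#' every word embedding. The objective is the summed negative
#' log-likelihood of the reference tokens, minimised with Adam; the
#' returned parameters are those of the epoch with minimum validation
#' loss.
#'
#' The convolutional backbone is a frozen, seeded feature extractor; the
#' trainable image-side parameters are the dense projection head mapping
#' its penultimate vector and spatial map into the decoder's feature
#' space.
#'
#' @param manifest Manifest path or data.frame (see [read_manifest()]).
#' @param image_dir Directory image paths are relative to (defaults to
#'   the manifest's directory).
#' @param split Optional list with integer `train` and `test` record
#'   indices; by default an 80/20 image-level split drawn with
#'   `control$seed`.
#' @param encoder An [encoder_config()]. The default is a desk-scale
#'   profile (toy backbone, 48-wide pooled vector, 32-wide location
#'   features) sized for the bundled synthetic corpus; pass
#'   `encoder_config("vgg16", d_out = 256, d_attn = 256)` for the
#'   full-scale shape.
#' @param hidden_width LSTM hidden width. Default 64.
#' @param attn_width Attention scorer width. Default 32.
#' @param l_max Padded sequence length including sentinels. Default 24
#'   (22 words + startseq/endseq).
#' @param max_words Maximum words per report chunk. Default 22.
#' @param use_attention `FALSE` trains the attention-ablated variant
#'   (zero context vector at every step).
#' @param control A [train_control()].
#' @param backbone_seed Seed for the frozen backbone weights. Defaults to
#'   `control$seed`.
#' @return An object of class `cxrgen` with components `theta` (named
#'   parameter arrays), `vocab`, `trace` (per-epoch losses/accuracies),
#'   `best_epoch`, `split`, and the configuration needed to regenerate
#'   the backbone.
#' @seealso [predict.cxrgen()], [evaluate_reports()], [save_checkpoint()]
#' @export
cxrgen <- function(manifest, image_dir = NULL, split = NULL,
                   encoder = encoder_config("toy", d_out = 48L,
                                            d_attn = 32L),
                   hidden_width = 64L, attn_width = 32L, l_max = 24L,
                   max_words = 22L, use_attention = TRUE,
                   control = train_control(batch_size = 16L),
                   backbone_seed = control$seed) {
  cl <- match.call()
  corpus <- prepare_corpus(manifest, l_max = l_max, max_words = max_words,
                           base_dir = image_dir)
  n_rec <- nrow(corpus$records)
  if (is.null(split)) {
    imgs <- unique(corpus$records$image)
    plan <- split_corpus(length(imgs), fraction = 0.8,
                         seed = control$seed)[[1]]
    rec_img <- match(corpus$records$image, imgs)
    split <- list(train = which(rec_img %in% plan$train),
                  test = which(rec_img %in% plan$test))
  }
  stopifnot(length(intersect(split$train, split$test)) == 0L,
            all(c(split$train, split$test) %in% seq_len(n_rec)))

  backbone <- build_backbone(encoder, seed = backbone_seed)
  feats <- precompute_features(corpus$records$image, backbone)
  cfg <- model_cfg(vocab_size(corpus$vocab), encoder$d_out, encoder$d_attn,
                   attn_width, hidden_width, use_attention = use_attention,
                   output_tanh = FALSE, dropout_p = control$dropout_p)
  fit <- cxr_train(corpus, feats, split$train, split$test, cfg, control)

  structure(list(theta = fit$theta, cfg = cfg, vocab = corpus$vocab,
                 l_max = corpus$l_max, encoder = encoder,
                 backbone = backbone, backbone_seed = backbone_seed,
                 trace = fit$trace, best_epoch = fit$best_epoch,
                 best_val_loss = fit$best_val_loss, split = split,
                 records = corpus$records, grid_dim = feats$grid_dim,
                 control = control, call = cl),
            class = "cxrgen")
}

# Nested decoder-parameter view of a fitted model.
model_decoder <- function(model) theta_to_decoder(model$theta, model$cfg)

# Deterministic (evaluation-mode) features for one image.
model_features <- function(model, image) {
  encode_image(image, model$backbone, theta_to_proj(model$theta))
}

#' @export
print.cxrgen <- function(x, ...) {
  cat("Chest-X-ray report generator (", x$encoder$backbone, " backbone, ",
      if (x$cfg$use_attention) "with" else "no", " attention)\n", sep = "")
  cat("  vocabulary: ", x$cfg$V, " tokens;  l_max: ", x$l_max, "\n", sep = "")
  cat("  records: ", length(x$split$train), " train / ",
      length(x$split$test), " held out\n", sep = "")
  cat(sprintf("  selected epoch %d of %d (min validation loss %.4f)\n",
              x$best_epoch, nrow(x$trace), x$best_val_loss))
  invisible(x)
}

#' @export
summary.cxrgen <- function(object, ...) {
  n_par <- sum(vapply(object$theta, length, 0L))
  structure(list(model = object, n_par = n_par,
                 trace = object$trace), class = "summary.cxrgen")
}

#' @export
print.summary.cxrgen <- function(x, ...) {
  print(x$model)
  cat("  trainable parameters: ", format(x$n_par, big.mark = ","), "\n", sep = "")
  cat("\nTraining trace (last rows):\n")
  print(utils::tail(x$trace, 5L), row.names = FALSE)
  invisible(x)
}

#' @export
coef.cxrgen <- function(object, ...) object$theta

#' @export
logLik.cxrgen <- function(object, ...) {
  n_val <- length(object$split$test)
  structure(-object$best_val_loss * n_val,
            df = sum(vapply(object$theta, length, 0L)),
            nobs = n_val, class = "logLik")
}

#' Training and validation curves of a fitted report generator
#'
#' @param x A `cxrgen` model.
#' @param which `"loss"` or `"accuracy"`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.cxrgen <- function(x, which = c("loss", "accuracy"), ...) {
  which <- match.arg(which)
  tr <- x$trace
  cols <- if (which == "loss") c("train_loss", "val_loss")
          else c("train_acc", "val_acc")
  graphics::matplot(tr$epoch, tr[, cols], type = "b", pch = c(1, 16),
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = which, ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", legend = c("training", "validation"),
                   col = c("grey40", "firebrick"), pch = c(1, 16), bty = "n")
  invisible(x)
}

#' Generate reports for new images
#'
#' @param object A fitted `cxrgen` model.
#' @param newdata Image paths (character), a manifest-like data.frame
#'   with an `image` column, or missing, in which case the model's
#'   held-out split is used.
#' @param method `"greedy"` (argmax sampling, the default) or `"beam"`.
#' @param k Beam width for `method = "beam"`. Default 3.
#' @param max_len Maximum generated sequence length. Defaults to the
#'   model's `l_max`.
#' @param stochastic Draw tokens from the predicted distribution instead
#'   of the argmax (greedy method only).
#' @param attention Also return per-token attention weight vectors.
#' @param ... Unused.
#' @return A data.frame with columns `image`, `report`, `logprob`,
#'   `truncated`; with `attention = TRUE`, the full `cxr_generation`
#'   objects are attached as the `generations` attribute.
#' @export
predict.cxrgen <- function(object, newdata = NULL,
                           method = c("greedy", "beam"), k = 3L,
                           max_len = object$l_max, stochastic = FALSE,
                           attention = FALSE, ...) {
  method <- match.arg(method)
  if (is.null(newdata))
    newdata <- unique(object$records$image[object$split$test])
  if (is.data.frame(newdata)) newdata <- newdata$image
  params <- model_decoder(object)
  gens <- lapply(newdata, function(img) {
    f <- model_features(object, img)
    if (method == "beam")
      beam_search(f, params, k = k, max_len = max_len, vocab = object$vocab)
    else
      greedy_sample(f, params, max_len = max_len, vocab = object$vocab,
                    stochastic = stochastic)
  })
  out <- data.frame(
    image = as.character(newdata),
    report = vapply(gens, `[[`, "", "report"),
    logprob = vapply(gens, `[[`, 0, "logprob"),
    truncated = vapply(gens, `[[`, FALSE, "truncated"),
    stringsAsFactors = FALSE)
  if (attention) attr(out, "generations") <- gens
  out
}

#' Stochastic report simulation
#'
#' Draws `nsim` reports per image from the model's predictive
#' distribution (ancestral sampling through the decoder).
#'
#' @param object A fitted `cxrgen` model.
#' @param nsim Number of draws per image. Default 1.
#' @param seed Optional RNG seed.
#' @param newdata As in [predict.cxrgen()].
#' @param ... Unused.
#' @return A data.frame with `image`, `sim` (draw index) and `report`.
#' @export
simulate.cxrgen <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  res <- do.call(rbind, lapply(seq_len(nsim), function(s) {
    p <- predict(object, newdata = newdata, stochastic = TRUE)
    cbind(p[, "image", drop = FALSE], sim = s, report = p$report)
  }))
  rownames(res) <- NULL
  res
}

#' BLEU evaluation of generated reports against reference findings
#'
#' Generates a report for each image (greedy by default), preprocesses
#' the reference findings into chunks (a long findings text yields
#' several references per image), and computes per-image and
#' corpus-level BLEU-1..4.
#'
#' @param model A fitted `cxrgen` model.
#' @param manifest Reference manifest (path or data.frame). Defaults to
#'   the model's held-out records.
#' @param image_dir Base directory for manifest image paths.
#' @param predictions Optional precomputed data.frame with `image` and
#'   `report` columns; skips generation.
#' @param smooth_eps Passed to [bleu()]/[corpus_bleu()].
#' @param ... Passed to [predict.cxrgen()].
#' @return List with `per_image` (data.frame of per-image BLEU-1..4) and
#'   `corpus` (a `cxr_bleu`).
#' @export
evaluate_reports <- function(model, manifest = NULL, image_dir = NULL,
                             predictions = NULL, smooth_eps = 0, ...) {
  if (is.null(manifest)) {
    recs <- model$records[model$split$test, , drop = FALSE]
    refs_by_img <- split(recs$text, recs$image)
  } else {
    if (is.character(manifest)) {
      if (is.null(image_dir)) image_dir <- dirname(manifest)
      manifest <- read_manifest(manifest)
    }
    if (is.null(image_dir)) image_dir <- "."
    imgs <- file.path(image_dir, manifest$image)
    refs_by_img <- lapply(seq_len(nrow(manifest)), function(i)
      preprocess_report(manifest$findings[i]))
    names(refs_by_img) <- imgs
    refs_by_img <- tapply(unlist(refs_by_img, use.names = FALSE),
                          rep(imgs, lengths(refs_by_img)), c,
                          simplify = FALSE)
  }
  images <- names(refs_by_img)
  if (is.null(predictions))
    predictions <- predict(model, newdata = images, ...)
  pr <- predictions$report[match(images, predictions$image)]
  refs <- lapply(refs_by_img, function(r) lapply(r, as_tokens))
  per <- do.call(rbind, lapply(seq_along(images), function(i) {
    b <- bleu(pr[i], refs[[i]], smooth_eps = smooth_eps)
    data.frame(image = images[i], report = pr[i], bleu1 = b$bleu1,
               bleu2 = b$bleu2, bleu3 = b$bleu3, bleu4 = b$bleu4,
               stringsAsFactors = FALSE)
  }))
  corpus <- corpus_bleu(as.list(pr), refs, smooth_eps = smooth_eps)
  list(per_image = per, corpus = corpus)
}
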