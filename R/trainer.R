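#' Negative log-likelihood of a target sequence
#'
#' The sequence loss is the sum over timesteps of -log p_t(correct token),
#' i.e. sparse categorical cross-entropy with sum reduction over the
#' sequence. Pad positions (target id 0) are excluded. A predicted
#' probability of zero for the correct token is clamped at 1e-12 and
#' reported via a message.
#'
#' For a list of sequences the per-sequence sums are averaged (mean over
#' the batch), matching the training objective.
#'
#' @param p_series A (T-1) x V matrix of per-step distributions over the
#'   vocabulary (row t predicts the token at position t+1), or a list of
#'   such matrices.
#' @param target_ids Integer vector of target ids (positions 2..T of the
#'   padded sequence, or already trimmed), or a list of such vectors.
#' @return Numeric scalar loss.
#' @export
sequence_loss <- function(p_series, target_ids) {
  if (is.list(p_series) && !is.matrix(p_series)) {
    stopifnot(is.list(target_ids), length(p_series) == length(target_ids))
    return(mean(mapply(sequence_loss, p_series, target_ids)))
  }
  p_series <- as.matrix(p_series)
  target_ids <- as.integer(target_ids)
  if (length(target_ids) > nrow(p_series))
    target_ids <- target_ids[seq_len(nrow(p_series))]
  keep <- which(target_ids != 0L)
  if (length(keep) == 0L) return(0)
  pc <- p_series[cbind(keep, target_ids[keep])]
  if (any(pc < 1e-12)) {
    message("sequence_loss: ", sum(pc < 1e-12),
            " probability value(s) clamped at 1e-12")
    pc <- pmax(pc, 1e-12)
  }
  -sum(log(pc))
}

#' Teacher-forced per-step distributions for a batch
#'
#' Runs the decoder over padded ground-truth sequences: the true token at
#' position t is the input when predicting position t+1 (no sampling), and
#' the image is injected once at t = -1 through [init_state()]. Processing
#' is batched; the result is identical to stepping each sequence on its
#' own.
#'
#' @param features A `cxr_features` or a list of them, one per sequence.
#' @param ids Integer matrix (one padded row per sequence) or a single id
#'   vector.
#' @param params A `cxr_decoder_params` (see [decoder_params()]).
#' @return List of (len-1) x V probability matrices, one per sequence,
#'   where len is the sequence's non-pad length; pad positions contribute
#'   no rows beyond len-1.
#' @export
teacher_forcing_batch <- function(features, ids, params) {
  if (inherits(features, "cxr_features")) features <- list(features)
  if (!is.matrix(ids)) ids <- matrix(ids, nrow = 1L)
  stopifnot(length(features) == nrow(ids))
  theta <- decoder_to_theta(params)
  cfg <- model_cfg(params$V, ncol(params$emb), nrow(params$attn$U),
                   ncol(params$attn$U), ncol(params$lstm$W_ix),
                   use_attention = params$use_attention,
                   output_tanh = params$output_tanh, dropout_p = 0)
  n_loc <- nrow(features[[1]]$locations)
  Q0 <- do.call(rbind, lapply(features, function(f) as.numeric(f$pooled)))
  Lmat <- do.call(rbind, lapply(features, function(f) as.matrix(f$locations)))
  fwd <- core_forward(theta, cfg, Q0, Lmat, n_loc, ids,
                      training = FALSE, want_probs = TRUE)
  fwd$probs
}

#' Training control parameters
#'
#' @param learning_rate Adam step size. Default 0.001.
#' @param batch_size Minibatch size. Default 64.
#' @param max_epochs Maximum number of epochs. Default 30.
#' @param dropout_p Dropout probability (encoder penultimate vector and
#'   word embeddings). Default 0.5.
#' @param seed Integer seed governing parameter initialisation, data
#'   order and dropout masks. Default 1.
#' @param optimizer Only `"adam"` is implemented.
#' @param beta1,beta2,eps Adam moment decies and stabiliser. Defaults 0.9,
#'   0.999, 1e-8.
#' @param clip Global gradient-norm clip. Default 5.
#' @param patience Stop after this many epochs without a new validation
#'   minimum; `Inf` trains for `max_epochs`. Default `Inf`.
#' @param checkpoint_dir Optional directory; when set, a checkpoint is
#'   written after every epoch.
#' @param verbose Print a line per epoch. Default `FALSE`.
#' @return List of class `cxr_train_control`.
#' @export
train_control <- function(learning_rate = 0.001, batch_size = 64L,
                          max_epochs = 30L, dropout_p = 0.5, seed = 1L,
                          optimizer = "adam", beta1 = 0.9, beta2 = 0.999,
                          eps = 1e-8, clip = 5, patience = Inf,
                          checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1L)
  if (!identical(optimizer, "adam")) stop("only the 'adam' optimizer is implemented")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), dropout_p = dropout_p,
                 seed = as.integer(seed), optimizer = optimizer,
                 beta1 = beta1, beta2 = beta2, eps = eps, clip = clip,
                 patience = patience, checkpoint_dir = checkpoint_dir,
                 verbose = isTRUE(verbose)),
            class = "cxr_train_control")
}

adam_init <- function(theta) list(m = zero_like(theta), v = zero_like(theta), t = 0L)

adam_update <- function(theta, g, st, ctrl) {
  st$t <- st$t + 1L
  c1 <- 1 - ctrl$beta1^st$t
  c2 <- 1 - ctrl$beta2^st$t
  for (nm in names(theta)) {
    st$m[[nm]] <- ctrl$beta1 * st$m[[nm]] + (1 - ctrl$beta1) * g[[nm]]
    st$v[[nm]] <- ctrl$beta2 * st$v[[nm]] + (1 - ctrl$beta2) * g[[nm]]^2
    theta[[nm]] <- theta[[nm]] - ctrl$learning_rate *
      (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + ctrl$eps)
  }
  list(theta = theta, st = st)
}

clip_global_norm <- function(g, clip) {
  gn <- sqrt(sum(vapply(g, function(x) sum(x^2), 0)))
  if (is.finite(gn) && gn > clip) g <- lapply(g, function(x) x * (clip / gn))
  g
}

# Precompute frozen backbone features for a set of images.
# Returns pen_raw (N x Praw), Sraw ((N*n) x Craw), n_loc, grid_dim.
precompute_features <- function(image_paths, backbone) {
  uniq <- unique(image_paths)
  pen_list <- vector("list", length(uniq))
  sp_list <- vector("list", length(uniq))
  grid_dim <- NULL
  for (i in seq_along(uniq)) {
    raw <- backbone_forward(backbone, read_image(uniq[i]))
    pen_list[[i]] <- raw$penultimate
    d <- dim(raw$spatial)
    sp_list[[i]] <- matrix(raw$spatial, d[1] * d[2], d[3])
    grid_dim <- d[1:2]
  }
  n_loc <- nrow(sp_list[[1]])
  idx <- match(image_paths, uniq)
  list(pen_raw = do.call(rbind, pen_list), Sraw_list = sp_list,
       img_index = idx, n_loc = n_loc, grid_dim = grid_dim)
}

# Assemble the raw-feature matrices for a batch of record indices.
batch_raw <- function(feats, rec_img) {
  pen <- feats$pen_raw[rec_img, , drop = FALSE]
  Sraw <- do.call(rbind, feats$Sraw_list[rec_img])
  list(pen = pen, Sraw = Sraw)
}

# Core training loop over encoded records. Returns the best checkpoint by
# validation loss plus the full epoch trace.
cxr_train <- function(corpus, feats, train_idx, val_idx, cfg, ctrl) {
  S_all <- corpus$ids
  img_of_rec <- feats$img_index
  set.seed(ctrl$seed)
  theta <- init_theta(cfg$V, ncol(feats$pen_raw), ncol(feats$Sraw_list[[1]]),
                      cfg$E, cfg$D, cfg$A, cfg$H,
                      seed = ctrl$seed)
  opt <- adam_init(theta)
  trace <- data.frame(epoch = integer(), train_loss = double(),
                      val_loss = double(), train_acc = double(),
                      val_acc = double())
  best <- list(val_loss = Inf, epoch = NA_integer_, theta = NULL)

  eval_split <- function(idx) {
    nll <- 0; ntok <- 0L; ncor <- 0L
    for (start in seq(1L, length(idx), by = ctrl$batch_size)) {
      bi <- idx[start:min(start + ctrl$batch_size - 1L, length(idx))]
      br <- batch_raw(feats, img_of_rec[bi])
      fwd <- forward_batch(theta, cfg, br$pen, br$Sraw, feats$n_loc,
                           S_all[bi, , drop = FALSE], training = FALSE)
      nll <- nll + fwd$nll; ntok <- ntok + fwd$n_tok
      ncor <- ncor + fwd$n_correct
    }
    c(loss = nll / length(idx), acc = ncor / max(ntok, 1L))
  }

  for (epoch in seq_len(ctrl$max_epochs)) {
    ord <- sample(train_idx)
    ep_nll <- 0; ep_tok <- 0L; ep_cor <- 0L; ep_seq <- 0L
    batch_no <- 0L
    for (start in seq(1L, length(ord), by = ctrl$batch_size)) {
      batch_no <- batch_no + 1L
      bi <- ord[start:min(start + ctrl$batch_size - 1L, length(ord))]
      br <- batch_raw(feats, img_of_rec[bi])
      fwd <- forward_batch(theta, cfg, br$pen, br$Sraw, feats$n_loc,
                           S_all[bi, , drop = FALSE], training = TRUE,
                           want_cache = TRUE)
      if (!is.finite(fwd$loss))
        stop("training diverged: non-finite loss at epoch ", epoch,
             ", batch ", batch_no)
      g <- backward_batch(theta, cfg, br$Sraw, feats$n_loc, fwd)
      g <- clip_global_norm(g, ctrl$clip)
      upd <- adam_update(theta, g, opt, ctrl)
      theta <- upd$theta; opt <- upd$st
      ep_nll <- ep_nll + fwd$nll; ep_tok <- ep_tok + fwd$n_tok
      ep_cor <- ep_cor + fwd$n_correct; ep_seq <- ep_seq + length(bi)
    }
    val <- eval_split(val_idx)
    tr_loss <- ep_nll / ep_seq
    trace <- rbind(trace, data.frame(
      epoch = epoch, train_loss = tr_loss, val_loss = unname(val["loss"]),
      train_acc = ep_cor / max(ep_tok, 1L), val_acc = unname(val["acc"])))
    if (!is.null(ctrl$checkpoint_dir)) {
      dir.create(ctrl$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(list(theta = theta, cfg = cfg, epoch = epoch),
              file.path(ctrl$checkpoint_dir, sprintf("epoch_%03d.rds", epoch)))
    }
    if (val["loss"] < best$val_loss) {
      best <- list(val_loss = unname(val["loss"]), epoch = epoch,
                   theta = theta)
    }
    if (ctrl$verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f/%.3f",
                      epoch, tr_loss, val["loss"],
                      ep_cor / max(ep_tok, 1L), val["acc"]))
    if (epoch - best$epoch >= ctrl$patience) break
  }
  list(theta = best$theta, best_epoch = best$epoch,
       best_val_loss = best$val_loss, trace = trace, final_theta = theta)
}

#' Save a model checkpoint
#'
#' Writes the named parameter arrays together with shape metadata, the
#' configuration and the vocabulary, so a loader can validate consistency.
#'
#' @param model A fitted `cxrgen` model.
#' @param path Output RDS path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "cxrgen"))
  obj <- list(theta = model$theta, cfg = model$cfg,
              shapes = lapply(model$theta, function(p) dim(p) %||% length(p)),
              vocab = model$vocab, l_max = model$l_max,
              encoder = model$encoder, backbone_seed = model$backbone_seed,
              trace = model$trace, best_epoch = model$best_epoch,
              grid_dim = model$grid_dim)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path RDS path.
#' @return A `cxrgen` model object (backbone weights are regenerated from
#'   the stored seed unless a weights file is configured).
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  for (nm in names(obj$shapes)) {
    have <- dim(obj$theta[[nm]]) %||% length(obj$theta[[nm]])
    if (!identical(have, obj$shapes[[nm]]))
      stop("checkpoint shape mismatch for parameter '", nm, "'")
  }
  backbone <- build_backbone(obj$encoder, seed = obj$backbone_seed)
  structure(list(theta = obj$theta, cfg = obj$cfg, vocab = obj$vocab,
                 l_max = obj$l_max, encoder = obj$encoder,
                 backbone = backbone, backbone_seed = obj$backbone_seed,
                 trace = obj$trace, best_epoch = obj$best_epoch,
                 grid_dim = obj$grid_dim, call = NULL),
            class = "cxrgen")
}
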