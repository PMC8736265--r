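test_that("sequence_loss equals closed forms and excludes padding", {
  # uniform over V=4 at 3 target positions: 3 * ln 4
  p <- matrix(0.25, 3, 4)
  expect_equal(sequence_loss(p, c(2, 3, 1)), 3 * log(4), tolerance = 1e-12)
  # certain predictions: zero loss
  p1 <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(sequence_loss(p1, c(1, 2)), 0)
  # (0.5, 0.25) on the correct ids: ln 8
  p2 <- rbind(c(0.5, 0.5), c(0.75, 0.25))
  expect_equal(sequence_loss(p2, c(1, 2)), log(8), tolerance = 1e-12)
  # pad targets (id 0) contribute nothing
  p3 <- matrix(0.25, 4, 4)
  expect_equal(sequence_loss(p3, c(2, 3, 0, 0)), 2 * log(4), tolerance = 1e-12)
  # zero probability on the correct token is clamped and reported
  p4 <- rbind(c(0, 1))
  expect_message(l4 <- sequence_loss(p4, 1L), "clamped")
  expect_equal(l4, -log(1e-12))
  # list input averages per-sequence sums
  expect_equal(sequence_loss(list(p, p3), list(c(2, 3, 1), c(2, 3, 0, 0))),
               mean(c(3 * log(4), 2 * log(4))), tolerance = 1e-12)
})

test_that("teacher forcing emits one distribution per transition, pads excluded", {
  par <- make_decoder(V = 5, seed = 3)
  f <- make_features(4, 3, 4, seed = 1)
  ids <- c(1L, 3L, 4L, 2L, 0L, 0L)  # start, w, w, end, pad, pad
  ps <- teacher_forcing_batch(f, ids, par)
  expect_length(ps, 1L)
  expect_equal(nrow(ps[[1]]), 3L)   # k = 4 non-pad tokens -> k - 1 rows
  expect_equal(rowSums(ps[[1]]), rep(1, 3), tolerance = 1e-6)
  # the all-pad tail adds no loss terms
  expect_equal(sequence_loss(ps[[1]], ids[-1]),
               sequence_loss(ps[[1]], c(3L, 4L, 2L)))
})

test_that("batch and single-sequence teacher forcing agree at fixed weights", {
  par <- make_decoder(V = 6, E = 5, D = 3, A = 3, H = 4, seed = 10)
  feats <- lapply(1:3, function(i) make_features(4, 3, 5, seed = i))
  ids <- rbind(c(1L, 3L, 5L, 2L, 0L),
               c(1L, 6L, 2L, 0L, 0L),
               c(1L, 4L, 4L, 3L, 2L))
  batch <- teacher_forcing_batch(feats, ids, par)
  for (b in 1:3) {
    single <- teacher_forcing_batch(feats[[b]], ids[b, , drop = FALSE], par)
    expect_equal(batch[[b]], single[[1]], tolerance = 1e-10)
  }
  # and the resulting losses match a direct per-token oracle sum
  for (b in 1:3) {
    tgt <- ids[b, -1]
    direct <- 0
    kk <- sum(ids[b, ] != 0L) - 1L
    for (t in seq_len(kk)) direct <- direct - log(batch[[b]][t, tgt[t]])
    expect_equal(sequence_loss(batch[[b]], tgt), direct, tolerance = 1e-8)
  }
})

test_that("analytic gradients match finite differences on a tiny model", {
  set.seed(42)
  V <- 6L; E <- 4L; D <- 3L; A <- 3L; H <- 5L; n <- 4L; B <- 3L
  cfg <- cxrgen:::model_cfg(V, E, D, A, H, dropout_p = 0)
  theta <- cxrgen:::init_theta(V, 7L, 2L, E, D, A, H, seed = 7)
  pen <- matrix(rnorm(B * 7), B, 7)
  Sraw <- matrix(rnorm(B * n * 2), B * n, 2)
  S <- rbind(c(1, 3, 4, 5, 2, 0), c(1, 6, 2, 0, 0, 0), c(1, 4, 4, 3, 6, 2))
  fwd <- cxrgen:::forward_batch(theta, cfg, pen, Sraw, n, S,
                                training = TRUE, want_cache = TRUE)
  g <- cxrgen:::backward_batch(theta, cfg, Sraw, n, fwd)
  loss_at <- function(th) cxrgen:::forward_batch(th, cfg, pen, Sraw, n, S)$loss
  eps <- 1e-6
  for (nm in names(theta)) {
    idx <- sample(length(theta[[nm]]), min(3, length(theta[[nm]])))
    for (i in idx) {
      tp <- theta; tp[[nm]][i] <- tp[[nm]][i] + eps
      tm <- theta; tm[[nm]][i] <- tm[[nm]][i] - eps
      num <- (loss_at(tp) - loss_at(tm)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm))
    }
  }
})

test_that("a single pair is memorised within 200 steps and reproduced verbatim", {
  dir <- file.path(tempdir(), "cxrgen-memorise")
  # both images carry every finding, so they share one 20-word caption and
  # the held-out record tracks the memorisation of the training pair
  mf <- generate_synth_corpus(
    synth_spec(n_images = 2L, p_finding = 1, seed = 6L), dir)
  m <- cxrgen(mf, split = list(train = 1L, test = 2L),
              control = train_control(batch_size = 1L, max_epochs = 200L,
                                      dropout_p = 0, seed = 3L))
  expect_lt(min(m$trace$train_loss), 0.05)
  # greedy decoding of the training image returns its training caption
  pred <- predict(m, newdata = m$records$image[1])
  expect_equal(pred$report, m$records$text[1])
})

test_that("training is seed-deterministic and selects the validation-loss argmin", {
  mf <- fixture_small_corpus()
  ctrl <- train_control(batch_size = 8L, max_epochs = 4L, seed = 11L)
  m1 <- cxrgen(mf, control = ctrl)
  m2 <- cxrgen(mf, control = ctrl)
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$split, m2$split)
  expect_equal(m1$best_epoch, which.min(m1$trace$val_loss))
  # a different seed gives a different trajectory
  m3 <- cxrgen(mf, control = train_control(batch_size = 8L, max_epochs = 4L,
                                           seed = 12L))
  expect_false(identical(m1$trace, m3$trace))
})

test_that("checkpoints round-trip and validate shapes", {
  mf <- fixture_small_corpus()
  m <- cxrgen(mf, control = train_control(batch_size = 8L, max_epochs = 2L,
                                          seed = 21L))
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$theta, m$theta)
  expect_identical(m2$vocab$tokens, m$vocab$tokens)
  expect_identical(predict(m2, m$records$image[1])$report,
                   predict(m, m$records$image[1])$report)
  # corrupt a shape record -> loader refuses
  obj <- readRDS(f)
  obj$shapes$Wv <- c(1L, 1L)
  f2 <- tempfile(fileext = ".rds")
  saveRDS(obj, f2)
  expect_error(load_checkpoint(f2), "shape mismatch")
})
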