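test_that("toy backbone halves the grid per block and flattens a penultimate", {
  cfgx <- encoder_config("toy", channels = c(4L, 6L))
  bb <- build_backbone(cfgx, seed = 3)
  img <- matrix(runif(32 * 32), 32, 32)
  out <- backbone_forward(bb, img)
  expect_equal(dim(out$spatial), c(8, 8, 6))   # two 2x poolings
  expect_equal(length(out$penultimate), 8 * 8 * 6)
  expect_equal(out$grid_dim, c(8L, 8L))

  # constant-zero weights give all-zero features
  bbz <- bb
  for (i in seq_along(bbz$conv)) bbz$conv[[i]]$w <- bbz$conv[[i]]$w * 0
  outz <- backbone_forward(bbz, img)
  expect_true(all(outz$spatial == 0))

  expect_error(backbone_forward(bb, matrix(runif(4), 2, 2)),
               "downsampling budget")
  expect_error(encoder_config("resnet"), "arg")
})

test_that("vgg16-shaped backbone yields 7x7x512 spatial map and 1x4096 penultimate", {
  bb <- build_backbone(encoder_config("vgg16"), seed = 1)
  img <- array(runif(224 * 224), c(224, 224, 1))  # grayscale replicated to 3
  out <- backbone_forward(bb, img)
  expect_equal(dim(out$spatial), c(7, 7, 512))
  expect_length(out$penultimate, 4096L)
  expect_true(all(is.finite(out$penultimate)))
})

test_that("projection head: ReLU, widths, dropout semantics", {
  # identity dense on a vector with negatives: negatives zeroed
  proj <- list(Wp = diag(4), bp = rep(0, 4), Wl = diag(2), bl = rep(0, 2))
  sp <- matrix(rnorm(6 * 2), 6, 2)
  fg <- project_features(c(-1, 2, -3, 4), sp, proj)
  expect_equal(fg$pooled, c(0, 2, 0, 4))
  expect_equal(fg$locations, sp)  # identity linear projection

  # evaluation mode is deterministic regardless of dropout_p
  proj2 <- projection_params(10, 3, 5, 4, seed = 2)
  pen <- rnorm(10); sp2 <- matrix(rnorm(12 * 3), 12, 3)
  a <- project_features(pen, sp2, proj2, dropout_p = 0.5, training = FALSE)
  b <- project_features(pen, sp2, proj2, dropout_p = 0.5, training = FALSE)
  expect_identical(a, b)
  expect_equal(length(a$pooled), 5L)
  expect_equal(dim(a$locations), c(12L, 4L))
})

test_that("training-mode dropout zeroes about the configured fraction", {
  proj <- list(Wp = diag(10000), bp = rep(0, 10000),
               Wl = diag(1), bl = 0)
  pen <- rep(1, 10000)
  set.seed(42)
  fg <- project_features(pen, matrix(1, 1, 1), proj, dropout_p = 0.5,
                         training = TRUE)
  zeroed <- sum(fg$pooled == 0)
  # binomial(10^4, 0.5): mean 5000, sd 50; allow 4 sigma
  expect_gt(zeroed, 5000 - 200)
  expect_lt(zeroed, 5000 + 200)
  # surviving units are inverse-scaled to preserve the expectation
  expect_equal(unique(fg$pooled[fg$pooled > 0]), 2)
})

test_that("pooled output scales linearly with the dense weights on the positive cone", {
  proj <- projection_params(8, 2, 4, 3, seed = 5)
  pen <- rnorm(8); sp <- matrix(rnorm(4 * 2), 4, 2)
  base <- project_features(pen, sp, proj)
  projk <- proj
  projk$Wp <- proj$Wp * 3; projk$bp <- proj$bp * 3
  expect_equal(project_features(pen, sp, projk)$pooled, base$pooled * 3,
               tolerance = 1e-12)
})

test_that("encode_image reads PNGs and produces finite features", {
  dir <- tempfile(); dir.create(dir)
  img <- matrix(runif(64 * 64), 64, 64)
  png::writePNG(img, file.path(dir, "x.png"))
  cfgx <- encoder_config("toy", d_out = 8L, d_attn = 4L)
  bb <- build_backbone(cfgx, seed = 1)
  proj <- projection_params(8 * 8 * 16, 16, 8, 4, seed = 1)
  f <- encode_image(file.path(dir, "x.png"), bb, proj)
  expect_s3_class(f, "cxr_features")
  expect_length(f$pooled, 8L)
  expect_equal(dim(f$locations), c(64L, 4L))
  expect_true(all(is.finite(f$locations)))
  expect_equal(f$grid_dim, c(8L, 8L))
  # repeated evaluation-mode calls are bitwise identical
  expect_identical(f, encode_image(file.path(dir, "x.png"), bb, proj))
})
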