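test_that("lstm_step matches closed-form gate values", {
  # all-zero weights: every gate is sigmoid(0) = 0.5, candidate tanh(0) = 0
  p <- lstm_params(2, 1, seed = 1)
  for (nm in names(p)) p[[nm]] <- p[[nm]] * 0
  st <- lstm_step(c(1, 1), list(c = 1, m = 0), p)
  expect_equal(st$i, 0.5)
  expect_equal(st$f, 0.5)
  expect_equal(st$o, 0.5)
  expect_equal(st$c, 0.5)   # f * c_prev = 0.5 * 1
  expect_equal(st$m, 0.25)  # o * c_t

  # zero input, zero state: cell write is killed by tanh(0)
  p2 <- lstm_params(3, 2, seed = 4)
  st2 <- lstm_step(rep(0, 3), list(c = numeric(2), m = numeric(2)), p2)
  expect_equal(st2$c, c(0, 0))
  expect_equal(st2$m, c(0, 0))
})

test_that("lstm_step agrees with the scalar-loop oracle to 1e-10", {
  set.seed(5)
  for (i in 1:30) {
    H <- sample(1:4, 1); xw <- sample(1:5, 1)
    p <- lstm_params(xw, H, seed = 100 + i)
    x <- rnorm(xw); cp <- rnorm(H); mp <- rnorm(H)
    got <- lstm_step(x, list(c = cp, m = mp), p)
    ora <- oracle_lstm_step(x, cp, mp, p)
    expect_equal(got$c, ora$c, tolerance = 1e-10)
    expect_equal(got$m, ora$m, tolerance = 1e-10)
    # and with the optional tanh on the cell output
    got_t <- lstm_step(x, list(c = cp, m = mp), p, output_tanh = TRUE)
    ora_t <- oracle_lstm_step(x, cp, mp, p, output_tanh = TRUE)
    expect_equal(got_t$m, ora_t$m, tolerance = 1e-10)
  }
})

test_that("gate activations stay in (0,1) and the cell growth is bounded", {
  set.seed(9)
  for (i in 1:25) {
    H <- sample(1:4, 1)
    p <- lstm_params(3, H, seed = i)
    cp <- rnorm(H, sd = 2)
    st <- lstm_step(rnorm(3, sd = 3), list(c = cp, m = rnorm(H)), p)
    expect_true(all(st$i > 0 & st$i < 1))
    expect_true(all(st$f > 0 & st$f < 1))
    expect_true(all(st$o > 0 & st$o < 1))
    expect_true(all(abs(st$c) <= abs(cp) + 1))
  }
  expect_error(lstm_step(c(1, 2), list(c = 1, m = 1),
                         lstm_params(3, 1, seed = 1)), "width")
  expect_error(lstm_step(rep(1, 3), list(c = NaN, m = 0),
                         lstm_params(3, 1, seed = 1)), "non-finite")
})

test_that("decode_step produces a probability vector and composes the oracles", {
  feats <- make_features(n = 1, d = 3, e = 4, seed = 2)
  par <- make_decoder(V = 3, E = 4, D = 3, A = 3, H = 4, seed = 6)
  st0 <- init_state(feats, par)
  out <- decode_step(1L, st0, feats, par)
  expect_equal(sum(out$p_next), 1, tolerance = 1e-6)
  expect_true(all(out$p_next >= 0))

  # independent composition: attention oracle -> scalar LSTM oracle -> softmax
  att <- oracle_attention(feats$locations, st0$m, par$attn$U, par$attn$W,
                          par$attn$v)
  x <- c(par$emb[2L, ], att$context)
  lst <- oracle_lstm_step(x, st0$c, st0$m, par$lstm)
  p_ref <- oracle_softmax(as.vector(lst$m %*% par$head$W) + par$head$b)
  expect_equal(out$p_next, p_ref, tolerance = 1e-10)
  expect_equal(out$state$m, lst$m, tolerance = 1e-10)

  # zero vocabulary head gives the uniform distribution
  par0 <- par
  par0$head$W <- par0$head$W * 0
  par0$head$b <- par0$head$b * 0
  expect_equal(decode_step(2L, st0, feats, par0)$p_next, rep(1 / 3, 3))
  expect_error(decode_step(9L, st0, feats, par), "invalid token id")
})

test_that("image injection at t = -1 is deterministic and image-sensitive", {
  par <- make_decoder(seed = 8)
  fa <- make_features(4, 3, 4, seed = 1)
  fb <- make_features(4, 3, 4, seed = 2)
  expect_identical(init_state(fa, par), init_state(fa, par))
  expect_false(isTRUE(all.equal(init_state(fa, par)$m, init_state(fb, par)$m)))

  # zero pooled vector and zero weights: tanh(0) kills the write
  parz <- par
  for (nm in names(parz$lstm)) parz$lstm[[nm]] <- parz$lstm[[nm]] * 0
  fz <- fa; fz$pooled <- rep(0, 4)
  st <- init_state(fz, parz)
  expect_equal(st$c, rep(0, 4))
  expect_equal(st$m, rep(0, 4))
})

test_that("p_next is a probability vector across many random models", {
  set.seed(77)
  for (i in 1:40) {
    V <- sample(2:6, 1)
    par <- make_decoder(V = V, seed = 1000 + i)
    feats <- make_features(sample(1:5, 1), 3, 4, seed = i)
    st <- init_state(feats, par)
    prev <- sample(V, 1)
    out <- decode_step(prev, st, feats, par)
    expect_equal(sum(out$p_next), 1, tolerance = 1e-6)
    expect_true(all(out$p_next >= 0))
    expect_equal(sum(out$attention$weights), 1, tolerance = 1e-6)
  }
})
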