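# LSTM and CNN feature extractors and the node-feature assembly.

zero_lstm_weights <- function(n = 3) {
  w0 <- matrix(0, n, n + 1)
  list(W_f = w0, W_i = w0, W_C = w0, W_o = w0,
       b_f = numeric(n), b_i = numeric(n), b_C = numeric(n),
       b_o = numeric(n))
}

test_that("lstm_step reproduces the gate equations in closed form", {
  n <- 3
  st <- list(h = numeric(n), C = numeric(n))
  out <- lstm_step(st, 0.7, zero_lstm_weights(n))
  # all-zero weights: f = i = o = 1/2, candidate = 0, so C and h stay 0
  expect_identical(out$C, numeric(n))
  expect_identical(out$h, numeric(n))
  # saturated forget gate preserves the cell state
  w <- zero_lstm_weights(n)
  w$b_f <- rep(10, n)
  st2 <- list(h = numeric(n), C = c(1, -2, 0.5))
  out2 <- lstm_step(st2, 0.3, w)
  expect_equal(out2$C, st2$C, tolerance = 1e-4)
  # hidden state bounded by the output nonlinearity
  set.seed(2)
  w3 <- lapply(zero_lstm_weights(n), function(x) x + rnorm(length(x), sd = 2))
  out3 <- lstm_step(list(h = rnorm(n), C = rnorm(n)), 1.5, w3)
  expect_true(all(abs(out3$h) < 1))
  expect_error(lstm_step(list(h = numeric(2), C = numeric(2)), 1,
                         zero_lstm_weights(3)), "W_f")
})

test_that("compiled LSTM agrees with the plain-R recurrence", {
  set.seed(11)
  segs <- c(lapply(1:3, function(i) tone_segment(10, 1L, i)),
            lapply(4:6, function(i) noise_segment(0L, i)))
  cfg <- extractor_config(hidden = 8, epochs = 1, seed = 2)
  model <- train_time_extractor(segs, cfg)
  h <- model$hidden
  w <- list(W_f = model$W[1:h, , drop = FALSE],
            W_i = model$W[(h + 1):(2 * h), , drop = FALSE],
            W_C = model$W[(2 * h + 1):(3 * h), , drop = FALSE],
            W_o = model$W[(3 * h + 1):(4 * h), , drop = FALSE],
            b_f = model$b[1:h], b_i = model$b[(h + 1):(2 * h)],
            b_C = model$b[(2 * h + 1):(3 * h)],
            b_o = model$b[(3 * h + 1):(4 * h)])
  x <- pcohnet:::standardize_channels(segs[[1]]$data)[1, ]
  st <- list(h = numeric(h), C = numeric(h))
  for (t in seq_along(x)) st <- lstm_step(st, x[t], w)
  r <- pmax(as.numeric(model$Wfc %*% st$h) + as.numeric(model$bfc), 0)
  scores_r <- as.numeric(model$Wout %*% r) + as.numeric(model$bout)
  scores_cpp <- as.numeric(time_features(segs[[1]], model)[1, ])
  expect_equal(scores_cpp, scores_r, tolerance = 1e-10)
})

test_that("time extractor learns a separable toy problem deterministically", {
  segs <- c(lapply(1:10, function(i) tone_segment(10, 1L, i)),
            lapply(11:20, function(i) noise_segment(0L, i)))
  cfg <- extractor_config(hidden = 32, epochs = 10, seed = 7)
  model <- train_time_extractor(segs, cfg)
  # training accuracy evaluated with dropout off
  preds <- vapply(segs, function(s) {
    f <- time_features(s, model)
    as.integer(mean(f[, 2] - f[, 1]) > 0)
  }, integer(1))
  labs <- vapply(segs, function(s) s$label, integer(1))
  expect_gt(mean(preds == labs), 0.9)
  # per-class mean logit difference has opposite sign
  d1 <- mean(vapply(segs[1:10], function(s) {
    f <- time_features(s, model); mean(f[, 2] - f[, 1]) }, numeric(1)))
  d0 <- mean(vapply(segs[11:20], function(s) {
    f <- time_features(s, model); mean(f[, 2] - f[, 1]) }, numeric(1)))
  expect_gt(d1, d0)
  # seeded rerun reproduces the loss trajectory and weights exactly
  model2 <- train_time_extractor(segs, cfg)
  expect_identical(model$loss, model2$loss)
  expect_identical(model$W, model2$W)
  expect_error(train_time_extractor(segs[1:10], cfg), "both classes")
})

test_that("time features are deterministic and channel-consistent", {
  segs <- c(lapply(1:3, function(i) tone_segment(10, 1L, i)),
            lapply(4:6, function(i) noise_segment(0L, i)))
  model <- train_time_extractor(segs, extractor_config(hidden = 8,
                                                       epochs = 1, seed = 3))
  f1 <- time_features(segs[[1]], model)
  expect_identical(dim(f1), c(19L, 2L))
  expect_true(all(is.finite(f1)))
  expect_identical(f1, time_features(segs[[1]], model))
  # duplicated channels give identical feature rows
  d <- segs[[1]]$data
  d[5, ] <- d[3, ]
  f2 <- time_features(eeg_segment(d, label = 1L), model)
  expect_equal(f2[5, ], f2[3, ], ignore_attr = TRUE)
})

test_that("spectrum matrix is the 640-point DFT magnitude", {
  z <- spectrum_matrix(matrix(0, 19, 640))
  expect_true(all(z == 0))
  t0 <- (0:639) / 128
  d <- matrix(rep(sin(2 * pi * 10 * t0), 19), 19, byrow = TRUE)
  sp <- spectrum_matrix(d)
  expect_identical(dim(sp), c(19L, 640L))
  # 10 Hz is DFT bin 50 (0-based); conjugate mirror at 640 - 50
  expect_equal(which.max(sp[1, 1:320]), 51L)
  expect_equal(sp[1, 51], 320, tolerance = 1)
  expect_equal(sp[1, 591], 320, tolerance = 1)
  # Parseval
  m <- random_segment(3)
  expect_equal(sum(spectrum_matrix(m)^2) / 640, sum(m^2),
               tolerance = 1e-6)
})

test_that("frequency extractor separates tones and is seeded", {
  train <- c(lapply(1:10, function(i) tone_segment(10, 1L, i)),
             lapply(11:20, function(i) tone_segment(30, 0L, i)))
  test <- c(lapply(21:25, function(i) tone_segment(10, 1L, i)),
            lapply(26:30, function(i) tone_segment(30, 0L, i)))
  cfg <- extractor_config(epochs = 10, seed = 4)
  model <- train_freq_extractor(train, cfg)
  preds <- vapply(test, function(s) {
    f <- freq_features(s, model)
    as.integer(mean(f[, 2] - f[, 1]) > 0)
  }, integer(1))
  labs <- vapply(test, function(s) s$label, integer(1))
  expect_gt(mean(preds == labs), 0.95)
  model2 <- train_freq_extractor(train, cfg)
  expect_identical(model$W1, model2$W1)
  expect_identical(model$loss, model2$loss)
  expect_error(train_freq_extractor(train[1:10], cfg), "both classes")
})

test_that("label-shuffled extractors stay near chance on held-out data", {
  train <- c(lapply(1:12, function(i) tone_segment(10, 1L, i)),
             lapply(13:24, function(i) tone_segment(30, 0L, i)))
  # labels balanced within each tone class: zero label-spectrum association
  shuffled <- rep(c(1L, 0L), 12)
  for (i in seq_along(train)) train[[i]]$label <- shuffled[i]
  test <- c(lapply(31:40, function(i) tone_segment(10, 1L, i)),
            lapply(41:50, function(i) tone_segment(30, 0L, i)))
  model <- train_freq_extractor(train, extractor_config(epochs = 5,
                                                        seed = 12))
  preds <- vapply(test, function(s) {
    f <- freq_features(s, model)
    as.integer(mean(f[, 2] - f[, 1]) > 0)
  }, integer(1))
  labs <- vapply(test, function(s) s$label, integer(1))
  # 99% binomial band around 1/2 for n = 20
  expect_true(abs(mean(preds == labs) - 0.5) <= 2.576 * sqrt(0.25 / 20))
})

test_that("extractor checkpoints round-trip through versioned files", {
  segs <- c(lapply(1:3, function(i) tone_segment(10, 1L, i)),
            lapply(4:6, function(i) noise_segment(0L, i)))
  model <- train_time_extractor(segs, extractor_config(hidden = 8,
                                                       epochs = 1, seed = 3))
  path <- withr::local_tempfile(fileext = ".rds")
  save_extractor(model, path)
  back <- load_extractor(path)
  expect_identical(time_features(segs[[1]], back),
                   time_features(segs[[1]], model))
  saveRDS(list(format = "other"), path)
  expect_error(load_extractor(path), "not an extractor checkpoint")
  expect_error(save_extractor(list(), path), "trained extractor")
})

test_that("node-feature concatenation keeps column blocks", {
  tmat <- matrix(1:38, 19, 2)
  fmat <- matrix(101:138, 19, 2)
  x <- concat_features(tmat, fmat)
  expect_identical(dim(x), c(19L, 4L))
  expect_identical(x[, 1:2], tmat)
  expect_identical(x[, 3:4], fmat)
  expect_true(all(concat_features(matrix(0, 19, 2),
                                  matrix(0, 19, 2)) == 0))
  expect_error(concat_features(matrix(0, 18, 2), fmat), "19 x 2")
})
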