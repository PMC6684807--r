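# Conv-LSTM construction, forward contracts, gradient correctness, training
# and inference schemes.

tiny_spec <- function() model_spec(n_filters = 3, n_bands = 6, kernel_frames = 3,
                                   lstm_hidden = 4, n_classes = 3)

random_input <- function(B, bands, T_f, seed) {
  set.seed(seed)
  array(rnorm(B * bands * T_f), dim = c(B, 1, bands, T_f))
}

test_that("model building is deterministic and validates the kernel band extent", {
  m1 <- build_model(model_spec(n_filters = 8, lstm_hidden = 8), seed = 4)
  m2 <- build_model(model_spec(n_filters = 8, lstm_hidden = 8), seed = 4)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(model_spec(n_filters = 8, lstm_hidden = 8), seed = 5)
  expect_false(identical(m1$params, m3$params))

  # mismatched band extent is rejected at the input
  X <- random_input(1, 100, 10, 1)
  expect_error(infer_many_to_many(m1, structure(list(values = X),
                                                class = "spectrogram_batch"),
                                  seed = 1),
               "band")
  expect_error(model_spec(kernel_frames = 4), "odd")
})

test_that("same-padding keeps the frame count and every softmax row is normalized", {
  m <- build_model(model_spec(n_filters = 8, lstm_hidden = 8), seed = 1)
  b <- structure(list(values = random_input(2, 200, 116, 2)),
                 class = "spectrogram_batch")
  fps <- infer_many_to_many(m, b, seed = 3)
  expect_length(fps, 2)
  for (fp in fps) {
    expect_identical(nrow(fp), 116L)                # (116 + 2*3 - 7) + 1
    expect_identical(colnames(fp), ieeg_classes())
    expect_equal(rowSums(fp), rep(1, 116), tolerance = 1e-6)
    expect_true(all(fp >= 0))
  }
  # valid padding drops kernel-1 frames
  mv <- build_model(model_spec(n_filters = 8, lstm_hidden = 8,
                               padding = "valid"), seed = 1)
  expect_identical(nrow(infer_many_to_many(mv, b, seed = 3)[[1]]), 110L)
})

test_that("LSTM state initialization honors its range, seed, and degenerate case", {
  m <- build_model(tiny_spec(), seed = 1)
  st0 <- init_lstm_state(m, 3, range = c(0, 0))
  expect_true(all(st0$h0 == 0) && all(st0$c0 == 0))
  s1 <- init_lstm_state(m, 3, seed = 8)
  s2 <- init_lstm_state(m, 3, seed = 8)
  expect_identical(s1, s2)
  expect_true(all(abs(s1$h0) <= 0.1))
})

test_that("analytic gradients match central finite differences", {
  m <- build_model(tiny_spec(), seed = 5)
  X <- random_input(2, 6, 5, 42)
  y <- c(1L, 3L)
  st <- init_lstm_state(m, 2, seed = 9)
  bw <- ieegnet:::conv_lstm_backward(m, X, y, st$h0, st$c0)
  loss_at <- function(mm) ieegnet:::conv_lstm_backward(mm, X, y, st$h0, st$c0)$loss
  eps <- 1e-5
  set.seed(6)
  for (nm in names(m$params)) {
    idx <- sample(length(m$params[[nm]]), min(length(m$params[[nm]]), 8))
    for (i in idx) {
      up <- m; up$params[[nm]][i] <- up$params[[nm]][i] + eps
      dn <- m; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      ana <- bw$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("zero learning rate leaves parameters unchanged over an epoch", {
  ds <- toy_dataset(c(3, 3, 3), seed = 71)
  b <- preprocess_dataset(ds)
  m <- build_model(model_spec(n_filters = 4, lstm_hidden = 4), seed = 2)
  before <- m$params
  m <- train_many_to_one(m, b, train_spec(learning_rate = 0, epochs = 1, seed = 3))
  expect_equal(m$params, before, tolerance = 1e-15)
})

test_that("training rejects unlabeled and single-class batches", {
  ds <- toy_dataset(c(4, 0, 0), seed = 72)
  b <- preprocess_dataset(ds)
  m <- build_model(model_spec(n_filters = 4, lstm_hidden = 4), seed = 2)
  expect_error(train_many_to_one(m, b, train_spec(epochs = 1)), "single class")
  b$labels <- NULL
  expect_error(train_many_to_one(m, b, train_spec(epochs = 1)), "label")
})

test_that("a toy separable set is learned to high accuracy with a decreasing loss", {
  ds <- generate_dataset(synthetic_spec(n_per_class = c(20, 20, 20), seed = 11))
  b <- preprocess_dataset(ds)
  m <- build_model(model_spec(n_filters = 32, lstm_hidden = 16), seed = 1)
  m <- train_many_to_one(m, b, train_spec(epochs = 15, seed = 2))
  expect_gte(utils::tail(m$history$acc, 1), 0.95)
  # epoch-mean loss decreases over every 5-epoch window
  sm <- stats::filter(m$history$loss, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) < 0))
})

test_that("training is deterministic given seed and data order", {
  ds <- toy_dataset(c(3, 3, 3), seed = 73)
  b <- preprocess_dataset(ds)
  run <- function() {
    m <- build_model(model_spec(n_filters = 4, lstm_hidden = 4), seed = 2)
    train_many_to_one(m, b, train_spec(epochs = 2, seed = 5))
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("an untrained symmetric model emits near-uniform mean probabilities", {
  m <- build_model(model_spec(n_filters = 8, lstm_hidden = 8), seed = 3)
  b <- structure(list(values = random_input(30, 200, 30, 5)),
                 class = "spectrogram_batch")
  fps <- infer_many_to_many(m, b, seed = 6)
  mean_p <- colMeans(do.call(rbind, fps))
  expect_true(all(abs(mean_p - 1 / 3) < 0.15))
})

test_that("inference is causal up to the convolution's 3-frame lookahead", {
  m <- build_model(model_spec(n_filters = 8, lstm_hidden = 8), seed = 7)
  X <- random_input(1, 200, 60, 8)
  st <- init_lstm_state(m, 1, seed = 9)
  full <- infer_many_to_many(m, structure(list(values = X),
                                          class = "spectrogram_batch"),
                             state = st)[[1]]
  k <- 40
  Xk <- X[, , , 1:k, drop = FALSE]
  pre <- infer_many_to_many(m, structure(list(values = Xk),
                                         class = "spectrogram_batch"),
                            state = st)[[1]]
  # frames 1..k-3 of the truncated run depend on no frame beyond k
  look <- (m$spec$kernel_frames - 1) %/% 2
  expect_identical(pre[1:(k - look), ], full[1:(k - look), ])
  # the padded tail frames differ in general (they see the zero padding)
  expect_false(identical(pre, full[1:k, ]))
})

test_that("checkpoints round-trip with their JSON sidecar", {
  m <- build_model(tiny_spec(), seed = 1)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_model(path)
  expect_identical(back$params, m$params)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(side$spec$n_filters, 3L)
})
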