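test_that("feature widths double per level up to the bottleneck", {
  expect_equal(feature_widths(net_config(depth = 7, base_features = 16)),
               c(16, 32, 64, 128, 256, 512, 1024))
  expect_equal(max(feature_widths(net_config(depth = 4, base_features = 8))),
               64)
})

test_that("parameter count matches the hand-derived formula", {
  # conv params: (k^2 * c_in + 1) * c_out; encoder blocks (two convs),
  # decoder blocks (concat input then two convs), 1x1 output conv
  formula_params <- function(depth, base) {
    ch <- base * 2^(0:(depth - 1))
    total <- 0
    for (i in seq_len(depth)) {
      cin <- if (i == 1) 1 else ch[i - 1]
      total <- total + (9 * cin + 1) * ch[i] + (9 * ch[i] + 1) * ch[i]
    }
    for (i in seq_len(depth - 1)) {   # decoder level i (finest = 1)
      total <- total + (9 * (ch[i + 1] + ch[i]) + 1) * ch[i] +
        (9 * ch[i] + 1) * ch[i]
    }
    total + (base + 1) * 1
  }
  for (cfg in list(c(3, 4), c(4, 8))) {
    m <- build_network(net_config(depth = cfg[1], base_features = cfg[2]))
    expect_equal(n_parameters(m), formula_params(cfg[1], cfg[2]))
  }
})

test_that("forward pass preserves the input shape and is deterministic", {
  cf <- net_config(depth = 3, base_features = 4, seed = 5)
  m <- build_network(cf, c(24, 16))
  x <- array(rnorm(24 * 16 * 2), c(24, 16, 2))
  y1 <- cpp_unet_forward(m$weights, x, cf$depth, cf$base_features)
  y2 <- cpp_unet_forward(m$weights, x, cf$depth, cf$base_features)
  expect_equal(dim(y1), dim(x))
  expect_identical(y1, y2)
  # untrained model (zero-initialized output head) predicts ~zero
  expect_equal(max(abs(y1)), 0)
  # same seed gives identical initialization
  m2 <- build_network(cf, c(24, 16))
  expect_identical(m$weights, m2$weights)
})

test_that("incompatible input sizes are rejected with the required padding", {
  expect_error(build_network(net_config(depth = 4, base_features = 8),
                             input_dim = c(60, 60)),
               "divisible.*pad to 64 x 64")
})

test_that("train/test split sizes, determinism and leak-freedom", {
  sp <- split_dataset(1890, 0.8, seed = 1)
  expect_length(sp$train, 1512)
  expect_length(sp$test, 378)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:1890)

  expect_equal(lengths(split_dataset(10, 0.8, seed = 2)),
               c(train = 8L, test = 2L))
  expect_identical(split_dataset(100, 0.8, seed = 3),
                   split_dataset(100, 0.8, seed = 3))
  expect_error(split_dataset(0, 0.8), "empty")

  # phantom-held-out mode keeps all pairs of a mouse on one side
  specs <- make_dataset(4, 10, 20, seed = 5)
  sp <- split_dataset(specs, 0.8, seed = 5, by_phantom = TRUE)
  pid <- vapply(specs, function(s) paste(s$kind, s$phantom_id), "")
  for (g in unique(pid[seq_len(40)])) {
    idx <- which(pid == g)
    expect_true(all(idx %in% sp$train) || all(idx %in% sp$test))
  }
})

test_that("a zero learning rate leaves the weights untouched", {
  cf <- net_config(depth = 3, base_features = 4, lr = 0, epochs = 3,
                   batch_size = 4, seed = 7)
  m <- build_network(cf)
  x <- array(runif(16 * 16 * 8), c(16, 16, 8))
  y <- array(runif(16 * 16 * 8), c(16, 16, 8))
  m2 <- train_network(m, x, y, 1:6, 7:8)
  for (i in seq_along(m$weights)) {
    expect_equal(m2$weights[[i]]$W, m$weights[[i]]$W, tolerance = 1e-12)
  }
  expect_equal(diff(range(m2$history$train_mae)), 0, tolerance = 1e-7)
})

test_that("training learns an identity mapping at tiny scale", {
  cf <- net_config(depth = 3, base_features = 4, lr = 1e-3, epochs = 50,
                   batch_size = 8, seed = 11)
  m0 <- build_network(cf, c(32, 32))
  set.seed(20)
  x <- array(0, c(32, 32, 24))
  for (i in 1:24) {  # smooth blobby images, roughly line-integral scale
    cx <- runif(1, 10, 22); cy <- runif(1, 10, 22); r <- runif(1, 4, 10)
    g <- outer((1:32 - cx)^2, (1:32 - cy)^2, `+`)
    x[, , i] <- pmax(0, 1 - g / r^2)
  }
  untrained <- cpp_unet_forward(m0$weights, x[, , 21:24], 3, 4)
  mae0 <- mean(abs(untrained - x[, , 21:24]))
  m <- train_network(m0, x, x, 1:20, 21:24)
  mae1 <- min(m$history$val_mae)
  expect_lt(mae1, mae0 / 10)
  # history bookkeeping
  expect_equal(nrow(m$history), cf$epochs)
  expect_true(all(c("data_hash", "best_epoch") %in% names(m$provenance)))
})

test_that("prediction is a pure function with padding support", {
  cf <- net_config(depth = 3, base_features = 4, seed = 3)
  m <- build_network(cf)
  cyl <- fix_cylinder()
  geom <- cbct_geometry(npix = c(50, 46), pitch = c(2.5, 2.5), angles = 90)
  pp <- project_poly(cyl, geom)
  before <- pp$images
  pred <- predict_mono(m, pp)
  expect_identical(pp$images, before)
  expect_equal(dim(pred$images), dim(pp$images))  # padded then cropped
  expect_equal(pred$kind, "predicted-mono")
  expect_identical(predict_mono(m, pp)$images, pred$images)

  pm <- project_mono(cyl, geom)
  expect_warning(predict_mono(m, pm), "kind")
})

test_that("checkpoints round trip with history and provenance", {
  cf <- net_config(depth = 3, base_features = 4, epochs = 2, batch_size = 4,
                   lr = 1e-4, seed = 1)
  m <- build_network(cf)
  x <- array(runif(16 * 16 * 6), c(16, 16, 6))
  m <- train_network(m, x, x, 1:4, 5:6)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "ckpt.rds")
  write_checkpoint(m, f)
  expect_true(file.exists(paste0(f, ".history.csv")))
  m2 <- read_checkpoint(f)
  expect_identical(m2$weights, m$weights)
  expect_equal(m2$history, m$history)
})
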