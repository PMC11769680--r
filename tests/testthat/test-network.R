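test_that("the canonical shape contract holds for a fresh model", {
  m <- build_model(width = 4, fc_width = 8, rng_seed = 1)
  out <- predict_patch(m, array(rnorm(63 * 63 * 7), c(63, 63, 7)))
  expect_equal(dim(out), c(3, 3, 6))
  ## the proximity branch is channel 1, pseudomarkers are channels 2-6
  maps <- predict_tile(m, array(rnorm(70 * 70 * 7), c(70, 70, 7)))
  expect_equal(dim(maps$proximity), c(70, 70))
  expect_equal(names(maps$phenotype), phenotyping_markers())
  expect_error(predict_tile(m, array(0, c(50, 50, 7))), "receptive field")
})

test_that("percentile normalization maps the 3rd/99.8th percentiles to 0/1", {
  ramp <- matrix(seq(0, 100, length.out = 1000), 40, 25)
  n <- normalize_tile(array(ramp, c(40, 25, 1)))
  q <- quantile(ramp, c(0.03, 0.998), names = FALSE)
  expect_equal(max(abs((ramp - q[1]) / (q[2] - q[1] + 1e-12) - n[, , 1])), 0)
  expect_equal(sum(n[, , 1] <= 0), sum(ramp <= q[1]))
  ## value at the upper percentile maps to ~1
  expect_equal(n[, , 1][which.min(abs(ramp - q[2]))], 1, tolerance = 1e-4)

  const <- array(5, c(30, 30, 1))
  expect_warning(nc <- normalize_tile(const), "constant")
  expect_true(all(nc == 0) && !any(is.na(nc)))
})

test_that("augmentation transforms input and label jointly, intensities input only", {
  input <- array(rnorm(63 * 63 * 7), c(63, 63, 7))
  label <- array(rnorm(3 * 3 * 6), c(3, 3, 6))
  ## identity settings leave both untouched
  a <- augment_patch(input, label, noise_sd = 0, rot = 0, flip = FALSE,
                     s1 = 1, s2 = 0)
  expect_equal(a$input, input)
  expect_equal(a$label, label)
  ## double horizontal flip is the identity
  f1 <- augment_patch(input, label, noise_sd = 0, rot = 0, flip = TRUE,
                      s1 = 1, s2 = 0)
  f2 <- augment_patch(f1$input, f1$label, noise_sd = 0, rot = 0,
                      flip = TRUE, s1 = 1, s2 = 0)
  expect_equal(f2$input, input)
  expect_equal(f2$label, label)
  ## intensity ops never touch the label
  b <- augment_patch(input, label, noise_sd = 0.3, rot = 0, flip = FALSE,
                     s1 = 1.7, s2 = -0.1)
  expect_equal(b$label, label)
  expect_false(isTRUE(all.equal(b$input, input)))
  ## four rotations return to the identity
  r <- list(input = input, label = label)
  for (i in 1:4)
    r <- augment_patch(r$input, r$label, noise_sd = 0, rot = 1,
                       flip = FALSE, s1 = 1, s2 = 0)
  expect_equal(r$input, input)
  expect_equal(r$label, label)
})

## Small synthetic regression task: labels are smooth functionals of the
## input, so a few epochs must reduce the training loss.
make_toy_patches <- function(n, seed = 1) {
  set.seed(seed)
  x <- array(rnorm(63 * 63 * 7 * n), c(63, 63, 7, n))
  y <- array(0, c(3, 3, 6, n))
  for (i in seq_len(n)) {
    y[, , 1, i] <- 2 * mean(x[25:39, 25:39, 1, i])
    for (m in 1:5)
      y[, , 1 + m, i] <- pmin(pmax(mean(x[29:35, 29:35, m + 1, i]) + 0.5,
                                   0), 1)
  }
  list(input = x, label = y)
}

test_that("training reduces the weighted loss and records both branches", {
  p <- make_toy_patches(200)
  m <- build_model(width = 4, fc_width = 8, rng_seed = 1)
  cfg <- train_config(epochs = 5, batch_size = 32, dropout = 0,
                      input_noise_sd = 0, augment = FALSE, rng_seed = 2)
  m2 <- train_model(m, p, cfg)
  h <- m2$history
  expect_equal(dim(h), c(5L, 3L))
  expect_lt(h[5, "loss"], h[1, "loss"])
  ## the loss decomposition uses the 1/20 branch weights
  expect_equal(h[, "loss"],
               1 * h[, "mse_proximity"] + 20 * h[, "mse_phenotype"])
  ## determinism under a fixed seed
  m3 <- train_model(m, p, cfg)
  expect_equal(m3$history, m2$history)
  expect_equal(m3$params$conv1_W, m2$params$conv1_W)
})

test_that("a single patch can be overfit to near-zero loss", {
  p <- make_toy_patches(1, seed = 3)
  m <- build_model(width = 8, fc_width = 16, rng_seed = 4)
  cfg <- train_config(epochs = 500, batch_size = 1, dropout = 0,
                      input_noise_sd = 0, augment = FALSE, rng_seed = 5)
  m2 <- train_model(m, p, cfg)
  expect_lt(m2$history[500, "loss"], 1e-3)
})

test_that("dense tile prediction equals per-patch prediction (translation covariance)", {
  m <- build_model(width = 4, fc_width = 8, rng_seed = 6)
  set.seed(7)
  img <- array(rnorm(90 * 90 * 7), c(90, 90, 7))
  maps <- predict_tile(m, img)
  for (px in c(45, 50)) {
    patch <- img[(px - 31 + 1):(px + 31 + 1), (px - 31 + 1):(px + 31 + 1), ]
    out <- predict_patch(m, patch)
    expect_equal(maps$proximity[px + 1, px + 1], out[2, 2, 1],
                 tolerance = 1e-10)
    expect_equal(maps$phenotype$CD3[px + 1, px + 1], out[2, 2, 2],
                 tolerance = 1e-10)
  }
  ## the mean aggregation is a 3x3 box filter of the dense map
  mm <- predict_tile(m, img, aggregate = "mean")
  expect_equal(mm$proximity[50, 50], mean(maps$proximity[49:51, 49:51]),
               tolerance = 1e-10)
})

test_that("patch pooling and subsampling preserve shapes", {
  p1 <- make_toy_patches(10, seed = 8)
  p2 <- make_toy_patches(6, seed = 9)
  both <- combine_patches(p1, p2)
  expect_equal(dim(both$input)[4], 16)
  expect_equal(both$input[, , , 12], p2$input[, , , 2])
  sub <- subsample_patches(both, 5, rng_seed = 1)
  expect_equal(dim(sub$input)[4], 5)
  expect_equal(dim(sub$label)[4], 5)
})
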