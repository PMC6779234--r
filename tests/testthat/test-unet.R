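tiny_spec <- function() unet_spec(c(16L, 16L, 4L), c(2L, 3L, 3L, 2L))

test_that("patch shape must be divisible by the pooling factors", {
  expect_error(unet_spec(c(60, 64, 16)), "axis 1")
  expect_error(unet_spec(c(64, 64, 14)), "axis 3")
  expect_silent(unet_spec(c(64, 64, 16)))
})

test_that("default architecture parameter count is near the design total", {
  m <- build_model(unet_spec(), seed = 1)
  expect_gte(n_parameters(m), 104000)
  expect_lte(n_parameters(m), 156000)
})

test_that("forward pass preserves shape and initialization is seeded", {
  m1 <- build_model(tiny_spec(), seed = 5)
  m2 <- build_model(tiny_spec(), seed = 5)
  m3 <- build_model(tiny_spec(), seed = 6)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params$enc[[1]]$W, m3$params$enc[[1]]$W))
  set.seed(1)
  x <- array(rnorm(16 * 16 * 4 * 2), c(1, 16, 16, 4, 2))
  out <- zteac:::unet_forward(m1, x)$out
  expect_identical(dim(out), c(1L, 16L, 16L, 4L, 2L))
})

test_that("analytic gradients match finite differences", {
  m <- build_model(tiny_spec(), seed = 5)
  set.seed(9)
  x <- array(rnorm(16 * 16 * 4), c(1, 16, 16, 4, 1))
  tgt <- array(rnorm(16 * 16 * 4), c(1, 16, 16, 4, 1))
  fw <- zteac:::unet_forward(m, x, train = TRUE)
  g <- zteac:::unet_backward(m, fw$cache, 2 * (fw$out - tgt) / length(tgt))
  th <- zteac:::flatten_params(m$params)
  gv <- zteac:::flatten_params(g)
  set.seed(11)
  idx <- sample(length(th), 12)
  eps <- 1e-5
  loss_at <- function(v) {
    mm <- m; mm$params <- zteac:::unflatten_params(m$params, v)
    mean((zteac:::unet_forward(mm, x, train = TRUE)$out - tgt)^2)
  }
  for (i in idx) {
    tp <- th; tp[i] <- tp[i] + eps
    tm <- th; tm[i] <- tm[i] - eps
    num <- (loss_at(tp) - loss_at(tm)) / (2 * eps)
    expect_lt(abs(num - gv[i]) / max(abs(num) + abs(gv[i]), 1e-8), 1e-4)
  }
})

test_that("patch sampling is seeded, in bounds and standardized", {
  b <- fixture("small_ph", function()
    phantom_cohort(1, seed = 77, grid_shape = c(48L, 48L, 24L),
                   spacing_mm = 4.8)[[1]])
  sp <- unet_spec(c(16L, 16L, 8L), c(2L, 2L, 2L, 2L))
  p1 <- sample_patches(b$zte, b$ct, 10, sp, seed = 4)
  p2 <- sample_patches(b$zte, b$ct, 10, sp, seed = 4)
  expect_identical(p1$origins, p2$origins)
  expect_false(identical(
    p1$origins, sample_patches(b$zte, b$ct, 10, sp, seed = 5)$origins))
  # brute-force bounds check on a bigger draw
  p3 <- sample_patches(b$zte, b$ct, 500, sp, seed = 6)
  d <- dim(b$zte$data)
  for (ax in 1:3) {
    expect_true(all(p3$origins[, ax] >= 1))
    expect_true(all(p3$origins[, ax] + sp$patch_shape[ax] - 1 <= d[ax]))
  }
  # every patch intersects the head mask
  mask <- zteac:::head_mask(b$zte$data)
  hits <- vapply(seq_len(500), function(k) {
    o <- p3$origins[k, ]
    any(mask[o[1]:(o[1] + 15), o[2]:(o[2] + 15), o[3]:(o[3] + 7)])
  }, TRUE)
  expect_true(all(hits))
  # constant volume cannot be standardized
  cv <- volume(array(1, d), 4.8, "zte")
  expect_error(sample_patches(cv, b$ct, 5, sp), "threshold|zero")
})

test_that("zero training iterations leave the model untouched", {
  m <- build_model(tiny_spec(), seed = 2)
  ps <- structure(list(inputs = array(rnorm(16 * 16 * 4 * 3),
                                      c(16, 16, 4, 3)),
                       targets = array(0, c(16, 16, 4, 3)),
                       origins = matrix(1L, 3, 3),
                       mean = 0, sd = 1,
                       patch_shape = c(16L, 16L, 4L)),
                  class = "patch_set")
  out <- train(m, ps, train_config(iterations = 0))
  expect_identical(out$model$params, m$params)
  expect_identical(out$loss, numeric(0))
})

test_that("training reduces the loss on a small identity task", {
  set.seed(21)
  n <- 32
  inputs <- array(rnorm(16 * 16 * 4 * n), c(16, 16, 4, n))
  ps <- structure(list(inputs = inputs, targets = inputs * 1000,
                       origins = matrix(1L, n, 3), mean = 0, sd = 1,
                       patch_shape = c(16L, 16L, 4L)),
                  class = "patch_set")
  m <- build_model(tiny_spec(), seed = 3)
  fit <- train(m, ps, train_config(iterations = 200, batch_size = 4,
                                   learning_rate = 3e-3, seed = 5))
  expect_length(fit$loss, 200)
  sm <- stats::filter(fit$loss, rep(1 / 50, 50), sides = 1)
  expect_lt(tail(stats::na.omit(sm), 1), mean(fit$loss[1:50]))
  # determinism of the whole training loop
  fit2 <- train(m, ps, train_config(iterations = 200, batch_size = 4,
                                    learning_rate = 3e-3, seed = 5))
  expect_identical(fit$loss, fit2$loss)
})

test_that("prediction is deterministic and covers every voxel", {
  b <- fixture("small_ph", function()
    phantom_cohort(1, seed = 77, grid_shape = c(48L, 48L, 24L),
                   spacing_mm = 4.8)[[1]])
  sp <- unet_spec(c(16L, 16L, 8L), c(2L, 2L, 2L, 2L))
  m <- build_model(sp, seed = 8)
  v1 <- predict_volume(m, b$zte, 0.5)
  v2 <- predict_volume(m, b$zte, 0.5)
  expect_identical(v1$data, v2$data)
  expect_error(predict_volume(m, b$zte, 1), "overlap_fraction")
  small <- volume(array(1, c(8, 8, 4)), 4.8, "zte")
  expect_error(predict_volume(m, small, 0), "smaller than the patch")
})

test_that("window coverage matches a brute-force placement enumeration", {
  sp <- unet_spec(c(16L, 16L, 8L), c(2L, 2L, 2L, 2L))
  m <- build_model(sp, seed = 1)
  for (ov in c(0, 0.5, 0.75)) {
    cov <- prediction_coverage(m, c(48L, 40L, 24L), ov)
    # oracle: enumerate all window origins directly
    oracle <- array(0L, c(48, 40, 24))
    p <- sp$patch_shape
    stride <- pmax(1L, as.integer(floor(p * (1 - ov))))
    for (ax_starts in list(NULL)) {
      sx <- unique(c(seq(1L, 48L - p[1] + 1L, stride[1]), 48L - p[1] + 1L))
      sy <- unique(c(seq(1L, 40L - p[2] + 1L, stride[2]), 40L - p[2] + 1L))
      sz <- unique(c(seq(1L, 24L - p[3] + 1L, stride[3]), 24L - p[3] + 1L))
      for (a in sx) for (b2 in sy) for (c2 in sz)
        oracle[a:(a + p[1] - 1), b2:(b2 + p[2] - 1), c2:(c2 + p[3] - 1)] <-
          oracle[a:(a + p[1] - 1), b2:(b2 + p[2] - 1), c2:(c2 + p[3] - 1)] + 1L
    }
    expect_identical(cov, oracle)
    expect_true(all(cov >= 1))
  }
  # zero overlap on an exactly tiled volume: every voxel predicted once
  cov0 <- prediction_coverage(m, c(32L, 32L, 16L), 0)
  expect_true(all(cov0 == 1L))
})
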