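test_that("SE gates follow the sigmoid exactly", {
  # zero excitation parameters: every gate is sigmoid(0) = 0.5
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  gp0 <- list(sW1 = matrix(0, 3, 1), sb1 = 0, sW2 = matrix(0, 1, 3),
              sb2 = numeric(3))
  expect_equal(unname(se_recalibrate(x, gp0)), 0.5 * x, ignore_attr = TRUE)
  # gates lie in (0, 1): output never exceeds the input in magnitude
  set.seed(3)
  gp <- list(sW1 = matrix(rnorm(3), 3, 1), sb1 = rnorm(1),
             sW2 = matrix(rnorm(3), 1, 3), sb2 = rnorm(3))
  y <- se_recalibrate(x, gp)
  expect_true(all(abs(y) <= abs(x)))
  gates <- attr(y, "gates")
  expect_true(all(gates > 0 & gates < 1))
  # hand-set parameters giving pre-sigmoid activation 2
  x1 <- array(1, c(4, 4, 1))
  gp2 <- list(sW1 = matrix(0, 1, 1), sb1 = 1, sW2 = matrix(2, 1, 1), sb2 = 0)
  y1 <- se_recalibrate(x1, gp2)
  expect_equal(as.numeric(y1), rep(1 / (1 + exp(-2)), 16))
})

test_that("network geometry: pooling arithmetic and the 80 -> 1 reduction", {
  cfg <- sercnet_config()
  dims <- sercnet_dims(cfg)
  expect_equal(dims$spatial_in, c(80, 40, 20, 10, 5, 2))
  expect_equal(dims$spatial_out, c(40, 20, 10, 5, 2, 1))
  expect_equal(attr(dims, "flat_dim"), 1 * 1 * dims$out_channels[6])
  # a seventh block would pool a 1-pixel map: build-time error
  expect_error(sercnet_config(n_blocks = 7, channels_per_block = rep(8, 7)),
               "n_blocks")
  expect_error(sercnet_config(merge = "add", init_channels = 4,
                              channels_per_block = c(4, 8), n_blocks = 2),
               "channels_per_block")
  expect_error(sercnet_config(channels_per_block = c(8, 8)),
               "channels_per_block")
})

test_that("a block halves the spatial size and zero weights give zero output", {
  cfg <- tiny_cfg(input_size = 16)
  m <- build_model(cfg)
  bp <- sercnet_block_params(m, 1)
  x <- array(rnorm(16 * 16 * 4 * 2), c(16, 16, 4, 2))
  y <- dense_residual_block(x, bp)
  expect_identical(dim(y), c(8L, 8L, 8L, 2L))       # concat: 4 + 4 channels
  bp0 <- lapply(bp, function(p) p * 0)
  x0 <- array(0, c(16, 16, 4, 1))
  expect_equal(dense_residual_block(x0, bp0), array(0, c(8, 8, 8, 1)))
})

test_that("forcing unit gates recovers the plain residual block", {
  cfg <- tiny_cfg(input_size = 16)
  m <- build_model(cfg)
  bp <- sercnet_block_params(m, 1)
  set.seed(9)
  x <- array(rnorm(16 * 16 * 4 * 3), c(16, 16, 4, 3))
  gated_off <- dense_residual_block(x, bp, se_gates = 1)
  # plain residual block assembled from the primitive pieces
  cb <- function(x, W, b, g, be) {
    z <- uwbfall:::conv2d_fw_cpp(x, W, b)
    uwbfall:::.relu(uwbfall:::.bn_fw(z, g, be)$y)
  }
  c1 <- cb(x, bp$W1, bp$b1, bp$g1, bp$be1)
  c2 <- cb(c1, bp$W2, bp$b2, bp$g2, bp$be2)
  plain <- uwbfall:::maxpool2_fw_cpp(uwbfall:::.concat_ch(x, c1 + c2))$y
  expect_equal(gated_off, plain)
})

test_that("build reports parameter counts and produces finite logits", {
  cfg <- sercnet_config(n_classes = 10, input_size = 32, init_channels = 4,
                        n_blocks = 2, channels_per_block = c(4, 6), seed = 1)
  m <- build_model(cfg)
  expect_gt(m$n_params, 0)
  expect_true(all(grepl("^(conv0|b1|b2|dense)\\.", names(m$params))))
  expect_equal(sum(vapply(m$params, length, 0L)), m$n_params)
  logits <- predict(m, array(0, c(32, 32, 1, 3)))
  expect_identical(dim(logits), c(3L, 10L))
  expect_true(all(is.finite(logits)))
  # identical seed, identical init
  expect_identical(build_model(cfg)$params, m$params)
  expect_error(predict(m, array(0, c(16, 16, 1, 2))), "input error")
})

test_that("analytic gradients match finite differences", {
  cfg <- sercnet_config(n_classes = 3, input_size = 8, init_channels = 2,
                        n_blocks = 1, channels_per_block = 3,
                        se_reduction = 2, seed = 7)
  m <- build_model(cfg)
  P <- m$params
  set.seed(42)
  x <- array(rnorm(8 * 8 * 1 * 4), c(8, 8, 1, 4))
  y <- c(0L, 1L, 2L, 1L)
  fw <- uwbfall:::.net_fw(P, cfg, x, keep = TRUE)
  sm <- uwbfall:::.softmax_ce(fw$logits, y)
  G <- uwbfall:::.net_bw(P, cfg, fw, sm$dlogits)
  lossfn <- function(P) {
    f <- uwbfall:::.net_fw(P, cfg, x)
    uwbfall:::.softmax_ce(f$logits, y)$loss
  }
  eps <- 1e-6
  for (nm in names(P)) {
    idx <- sample(length(P[[nm]]), min(3, length(P[[nm]])))
    for (i in idx) {
      Pp <- P; Pp[[nm]][i] <- Pp[[nm]][i] + eps
      Pm <- P; Pm[[nm]][i] <- Pm[[nm]][i] - eps
      num <- (lossfn(Pp) - lossfn(Pm)) / (2 * eps)
      ana <- G[[nm]][i]
      if (abs(num) + abs(ana) > 1e-7)
        expect_lt(abs(num - ana) / (abs(num) + abs(ana)), 1e-5)
    }
  }
})

test_that("training solves a linearly separable toy problem", {
  ts <- toy_blob_set(15, seed = 1)
  vs <- toy_blob_set(5, seed = 2)
  cfg <- tiny_cfg(epochs = 15)
  m <- train(build_model(cfg), ts, vs)
  h <- m$history
  expect_equal(nrow(h), 15L)
  expect_true(all(is.finite(h$train_loss)))
  expect_equal(h$train_acc[15], 1.0)
  # loss is non-increasing after warm-up, allowing 5 % spikes
  late <- h$train_loss[5:15]
  expect_true(all(diff(late) <= 0.05 * late[-length(late)]))
})

test_that("training is deterministic and a zero step size changes nothing", {
  ts <- toy_blob_set(8, seed = 3)
  vs <- toy_blob_set(4, seed = 4)
  cfg <- tiny_cfg(epochs = 4)
  m1 <- train(build_model(cfg), ts, vs)
  m2 <- train(build_model(cfg), ts, vs)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  cfg0 <- tiny_cfg(epochs = 4, learning_rate = 0)
  m0 <- build_model(cfg0)
  t0 <- train(m0, ts, vs)
  expect_identical(t0$params, m0$params)      # weights untouched
  # and the validation accuracy equals the untrained model's
  acc <- function(mm) mean(max.col(predict(mm, vs), ties.method = "first") -
                             1L == vs$y)
  expect_identical(acc(t0), acc(m0))
  expect_true(all(t0$history$val_acc == acc(m0)))
  expect_error(train(m0, list(x = ts$x, y = integer(0)), vs), "data error")
})

test_that("prediction is a pure batch map: duplicates and permutations", {
  cfg <- tiny_cfg()
  m <- build_model(cfg)
  set.seed(5)
  x <- array(runif(16 * 16 * 1 * 6), c(16, 16, 1, 6))
  L <- predict(m, x)
  expect_identical(dim(L), c(6L, 2L))
  xdup <- x
  xdup[, , , 6] <- x[, , , 1]
  Ld <- predict(m, xdup)
  expect_equal(Ld[6, ], Ld[1, ])
  perm <- c(4, 2, 6, 1, 3, 5)
  Lp <- predict(m, x[, , , perm, drop = FALSE])
  expect_equal(Lp, L[perm, ], tolerance = 1e-10)
})
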