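test_that("softmax is a shift-invariant map onto the simplex", {
  expect_equal(softmax_probs(rep(0, 10)), rep(0.1, 10))
  expect_equal(softmax_probs(c(1, 0)),
               c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)))
  z <- c(2.3, -1.1, 0.4, 7)
  # invariant up to rounding of z + 100 itself
  expect_equal(softmax_probs(z), softmax_probs(z + 100), tolerance = 1e-12)
  zd <- c(2.25, -1.5, 0.5, 7)  # dyadic values: the shift is exact in binary
  expect_identical(softmax_probs(zd), softmax_probs(zd + 128))
  set.seed(1)
  for (i in 1:20) {
    z <- rnorm(sample(2:12, 1), sd = 50)
    s <- softmax_probs(z)
    expect_equal(sum(s), 1)
    expect_true(all(s >= 0 & s <= 1))
  }
  expect_error(softmax_probs(numeric(0)), "empty")
  expect_error(softmax_probs(c(1, NA)), "finite")
})

test_that("confidence extracts smax/imax with lowest-index tie-breaking", {
  u <- confidence(rep(0.1, 10))
  expect_equal(u$smax, 0.1)
  expect_equal(u$imax, 0L)
  v <- confidence(c(0.05, 0.9, 0.05))
  expect_equal(v$smax, 0.9)
  expect_equal(v$imax, 1L)
  set.seed(2)
  for (i in 1:25) {
    s <- softmax_probs(rnorm(sample(2:10, 1)))
    expect_gte(confidence(s)$smax, 1 / length(s))
  }
})

test_that("classifier_output derives a consistent record", {
  o <- classifier_output(c(3, 1, 0, 0))
  expect_equal(sum(o$probs), 1)
  expect_equal(o$imax, 0L)
  expect_equal(o$smax, max(o$probs))
  expect_gte(o$smax, 0.25)
})

test_that("decision fusion: majority wins, else highest confidence", {
  out <- function(pred, smax, K = 10) {
    z <- rep(0, K)
    z[pred + 1] <- log(smax * (K - 1) / (1 - smax))  # softmax gives smax
    classifier_output(z)
  }
  a <- out(3, 0.8); b <- out(3, 0.6); c3 <- out(7, 0.9)
  expect_equal(as.integer(decision_fuse(list(a, b, c3))), 3L)
  expect_equal(attr(decision_fuse(list(a, b, c3)), "rule"), "majority")
  d <- decision_fuse(list(out(1, 0.5), out(2, 0.9), out(3, 0.7)))
  expect_equal(as.integer(d), 2L)
  expect_equal(attr(d, "rule"), "confidence")
  expect_equal(as.integer(decision_fuse(list(out(4, .5), out(4, .6), out(4, .7)))),
               4L)
  # smax tie with all-different predictions: lowest map index wins
  tie <- decision_fuse(list(out(5, 0.6), out(6, 0.6), out(7, 0.6)))
  expect_equal(as.integer(tie), 5L)
  expect_error(decision_fuse(list(a, b)), "input error")
  expect_error(decision_fuse(list(a, b, classifier_output(c(1, 2)))),
               "input error")
})

test_that("confidence normalization is a scale-invariant simplex map", {
  expect_equal(normalize_confidences(c(0.5, 0.5, 0.5)), rep(1 / 3, 3))
  expect_equal(normalize_confidences(c(0.9, 0.6, 0.3)), c(0.5, 1 / 3, 1 / 6))
  x <- c(0.9, 0.6, 0.3)
  expect_equal(normalize_confidences(0.5 * x), normalize_confidences(x))
  expect_equal(sum(normalize_confidences(c(0.2, 0.9, 0.4))), 1)
  expect_error(normalize_confidences(c(0.5, 0.5)), "input error")
  expect_error(normalize_confidences(c(0, 0.5, 0.5)), "input error")
})

test_that("adaptive weighted fusion reproduces the hand-worked example", {
  out <- function(pred, smax, K = 10) {
    z <- rep(0, K)
    z[pred + 1] <- log(smax * (K - 1) / (1 - smax))
    classifier_output(z)
  }
  n <- c(0.94, 0.94, 0.96)
  outs <- list(out(2, 0.99), out(8, 0.6), out(8, 0.6))
  fs <- adaptive_weighted_fuse(n, outs)
  # independent hand evaluation: m = smax / sum(smax); w = n * m
  m <- c(0.99, 0.6, 0.6) / sum(c(0.99, 0.6, 0.6))
  expect_equal(fs$m, m, tolerance = 1e-9)
  expect_equal(unname(fs$w_prime["2"]), 0.94 * m[1], tolerance = 1e-9)
  expect_equal(unname(fs$w_prime["8"]), (0.94 + 0.96) * m[2], tolerance = 1e-9)
  # the two agreeing lower-confidence maps override the single confident one
  expect_equal(fs$fused_class, 8L)
  # unanimity: any positive accuracies give the common class
  u <- list(out(5, 0.5), out(5, 0.9), out(5, 0.4))
  expect_equal(adaptive_weighted_fuse(c(0.2, 0.9, 0.5), u)$fused_class, 5L)
  # equal accuracies reduce to the all-different confidence rule
  dif <- list(out(1, 0.5), out(2, 0.9), out(3, 0.7))
  expect_equal(adaptive_weighted_fuse(c(1, 1, 1), dif)$fused_class,
               as.integer(decision_fuse(dif)))
  expect_error(adaptive_weighted_fuse(c(0.9, 0.8), outs), "input error")
})

test_that("adaptive fusion agrees with brute force on 1000 random triples", {
  set.seed(7)
  agree <- TRUE
  unanimity_ok <- TRUE
  for (i in 1:1000) {
    K <- sample(2:10, 1)
    outs <- lapply(1:3, function(j) random_output(K))
    n <- runif(3, 0.05, 1)
    fused <- adaptive_weighted_fuse(n, outs)$fused_class
    agree <- agree && identical(as.integer(fused), brute_force_fuse(n, outs))
    preds <- vapply(outs, `[[`, 0L, "imax")
    if (length(unique(preds)) == 1) {
      unanimity_ok <- unanimity_ok &&
        fused == preds[1] &&
        as.integer(decision_fuse(outs)) == preds[1]
    }
  }
  expect_true(agree)
  expect_true(unanimity_ok)
})

test_that("raising a map's validation accuracy never flips away its class", {
  set.seed(8)
  for (rep in 1:200) {
    K <- sample(3:10, 1)
    outs <- lapply(1:3, function(j) random_output(K))
    n <- runif(3, 0.05, 0.95)
    for (i in 1:3) {
      fused <- adaptive_weighted_fuse(n, outs)$fused_class
      if (fused == outs[[i]]$imax) {
        n2 <- n
        n2[i] <- runif(1, n[i], 1)
        expect_equal(adaptive_weighted_fuse(n2, outs)$fused_class, fused)
      }
    }
  }
})

test_that("jointly permuting maps and accuracies leaves the decision fixed", {
  set.seed(9)
  for (rep in 1:200) {
    K <- sample(2:10, 1)
    outs <- lapply(1:3, function(j) random_output(K))
    n <- runif(3, 0.05, 1)
    fs <- adaptive_weighted_fuse(n, outs)
    wp <- sort(fs$w_prime, decreasing = TRUE)
    if (length(wp) > 1 && wp[1] - wp[2] < 1e-12) next  # skip tie configs
    perm <- sample(3)
    expect_equal(adaptive_weighted_fuse(n[perm], outs[perm])$fused_class,
                 fs$fused_class)
  }
})

test_that("per-class accuracy matrices weight each map by its own class", {
  out <- function(pred, smax, K = 4) {
    z <- rep(0, K)
    z[pred + 1] <- log(smax * (K - 1) / (1 - smax))
    classifier_output(z)
  }
  outs <- list(out(0, 0.7), out(1, 0.7), out(2, 0.7))
  nm <- matrix(0.5, 3, 4)
  nm[1, 1] <- 0.9   # map 1 is excellent on its predicted class 0
  fs <- adaptive_weighted_fuse(nm, outs)
  expect_equal(fs$fused_class, 0L)
  # constant rows reduce to the scalar form
  nm2 <- matrix(rep(c(0.3, 0.6, 0.9), 4), 3, 4)
  expect_equal(adaptive_weighted_fuse(nm2, outs)$fused_class,
               adaptive_weighted_fuse(c(0.3, 0.6, 0.9), outs)$fused_class)
})
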