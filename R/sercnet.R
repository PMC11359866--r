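#' SE-RCNet configuration
#'
#' Architecture and training hyper-parameters of the squeeze-and-excitation
#' residual concatenate network: an initial 3x3 convolution + ReLU, then
#' `n_blocks` dense residual blocks (two conv-BN-ReLU paths summed, SE
#' channel recalibration, merge with the block input, 2x2 max-pool), a
#' flatten layer and a dense softmax head.
#'
#' With the default six blocks an 80x80 input is pooled
#' 80 -> 40 -> 20 -> 10 -> 5 -> 2 -> 1 (floor at each stage).
#'
#' @param n_classes Number of output classes (default 10).
#' @param input_size Input image side length (default 80).
#' @param input_channels Input channels (default 1; use 3 for colormapped
#'   renderings).
#' @param init_channels Filters of the initial convolution.
#' @param n_blocks Number of dense residual blocks (default 6).
#' @param channels_per_block Integer vector of per-block filter counts;
#'   recycled to length `n_blocks` if scalar.
#' @param merge `"concat"` (dense connection: block input concatenated with
#'   the SE-recalibrated residual sum; default) or `"add"` (additive merge,
#'   which requires the block input and block channel counts to match).
#' @param se_reduction SE bottleneck reduction ratio r; the hidden width is
#'   `max(1, floor(C / r))`.
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param seed Integer seed controlling initialization and shuffling.
#' @return An object of class `sercnet_config`.
#' @export
sercnet_config <- function(n_classes = 10, input_size = 80,
                           input_channels = 1, init_channels = 16,
                           n_blocks = 6,
                           channels_per_block = c(16, 32, 48, 64, 80, 96),
                           merge = c("concat", "add"), se_reduction = 4,
                           epochs = 100, batch_size = 32,
                           learning_rate = 1e-3, seed = 0) {
  merge <- match.arg(merge)
  if (n_blocks < 1) stop("invalid `n_blocks`: must be >= 1")
  if (length(channels_per_block) == 1)
    channels_per_block <- rep(channels_per_block, n_blocks)
  if (length(channels_per_block) != n_blocks)
    stop("invalid `channels_per_block`: need one entry per block (",
         n_blocks, ")")
  if (any(channels_per_block < 1)) stop("invalid `channels_per_block`")
  if (se_reduction < 1) stop("invalid `se_reduction`: must be >= 1")
  if (input_size < 2) stop("invalid `input_size`")
  if (input_channels < 1) stop("invalid `input_channels`")
  if (n_classes < 2) stop("invalid `n_classes`")
  if (epochs < 0) stop("invalid `epochs`")
  if (batch_size < 1) stop("invalid `batch_size`")
  if (learning_rate < 0) stop("invalid `learning_rate`")
  cfg <- structure(
    list(n_classes = as.integer(n_classes),
         input_size = as.integer(input_size),
         input_channels = as.integer(input_channels),
         init_channels = as.integer(init_channels),
         n_blocks = as.integer(n_blocks),
         channels_per_block = as.integer(channels_per_block),
         merge = merge, se_reduction = as.integer(se_reduction),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, seed = as.integer(seed)),
    class = "sercnet_config")
  sercnet_dims(cfg)  # validates the spatial reduction
  cfg
}

#' Layer geometry of an SE-RCNet configuration
#'
#' Tracks spatial size and channel count through the blocks; errors at build
#' time if any block would pool a feature map smaller than 2 pixels.
#'
#' @param cfg A [sercnet_config].
#' @return A data.frame with one row per block (`block`, `in_channels`,
#'   `block_channels`, `out_channels`, `spatial_in`, `spatial_out`) and an
#'   attribute `flat_dim`, the flatten width feeding the dense head.
#' @export
sercnet_dims <- function(cfg) {
  s <- cfg$input_size
  cin <- cfg$init_channels
  rows <- vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    ch <- cfg$channels_per_block[b]
    if (s < 2)
      stop("invalid `n_blocks`/`input_size`: spatial size ", s,
           " before pooling in block ", b)
    if (cfg$merge == "add" && cin != ch)
      stop("invalid `channels_per_block`: additive merge in block ", b,
           " needs input channels (", cin, ") to equal block channels (",
           ch, ")")
    cout <- if (cfg$merge == "concat") cin + ch else ch
    sout <- s %/% 2L
    rows[[b]] <- data.frame(block = b, in_channels = cin,
                            block_channels = ch, out_channels = cout,
                            spatial_in = s, spatial_out = sout)
    cin <- cout
    s <- sout
  }
  out <- do.call(rbind, rows)
  attr(out, "flat_dim") <- s * s * cin
  out
}

.he_mat <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)

#' Build an (untrained) SE-RCNet model
#'
#' Initializes all parameters from the configuration seed (He-normal
#' convolution and dense weights, unit batch-norm gains, zero biases) and
#' reports the total parameter count.
#'
#' @param cfg A [sercnet_config].
#' @return An object of class `sercnet_model` with elements `cfg`, `params`
#'   (flat named list of weight arrays), `n_params` and `history` (empty
#'   until trained).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "sercnet_config"))
  dims <- sercnet_dims(cfg)
  k <- 3L
  params <- with_seed(cfg$seed, {
    P <- list()
    P[["conv0.W"]] <- .he_mat(k * k * cfg$input_channels, cfg$init_channels,
                              k * k * cfg$input_channels)
    P[["conv0.b"]] <- numeric(cfg$init_channels)
    for (b in seq_len(cfg$n_blocks)) {
      cin <- dims$in_channels[b]
      ch <- dims$block_channels[b]
      hid <- max(1L, ch %/% cfg$se_reduction)
      pre <- sprintf("b%d.", b)
      P[[paste0(pre, "W1")]] <- .he_mat(k * k * cin, ch, k * k * cin)
      P[[paste0(pre, "b1")]] <- numeric(ch)
      P[[paste0(pre, "g1")]] <- rep(1, ch)
      P[[paste0(pre, "be1")]] <- numeric(ch)
      P[[paste0(pre, "W2")]] <- .he_mat(k * k * ch, ch, k * k * ch)
      P[[paste0(pre, "b2")]] <- numeric(ch)
      P[[paste0(pre, "g2")]] <- rep(1, ch)
      P[[paste0(pre, "be2")]] <- numeric(ch)
      P[[paste0(pre, "sW1")]] <- .he_mat(ch, hid, ch)
      P[[paste0(pre, "sb1")]] <- numeric(hid)
      P[[paste0(pre, "sW2")]] <- .he_mat(hid, ch, hid)
      P[[paste0(pre, "sb2")]] <- numeric(ch)
    }
    D <- attr(dims, "flat_dim")
    P[["dense.W"]] <- .he_mat(D, cfg$n_classes, D)
    P[["dense.b"]] <- numeric(cfg$n_classes)
    P
  })
  structure(list(cfg = cfg, params = params,
                 n_params = sum(vapply(params, length, 0L)),
                 history = NULL),
            class = "sercnet_model")
}

#' @export
print.sercnet_model <- function(x, ...) {
  cat(sprintf("<sercnet_model> %d blocks, %s merge, %d classes, %d parameters%s\n",
              x$cfg$n_blocks, x$cfg$merge, x$cfg$n_classes, x$n_params,
              if (is.null(x$history)) " (untrained)" else ""))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; best val accuracy %.3f (epoch %d)\n",
                nrow(x$history), max(x$history$val_acc),
                which.max(x$history$val_acc)))
  }
  invisible(x)
}

# ---- low-level forward/backward pieces ------------------------------------

.relu <- function(x) { y <- pmax(x, 0); dim(y) <- dim(x); y }
.sigmoid <- function(x) 1 / (1 + exp(-x))

# per-(channel, sample) spatial means/sums of a [H,W,C,N] array -> [C, N]
.ch_means <- function(x) {
  d <- dim(x)
  matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}
.ch_sums <- function(x) {
  d <- dim(x)
  matrix(colSums(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}
# broadcast a [C, N] matrix (or length-C vector) over the spatial dims
.bcast_cn <- function(m, d) array(rep(m, each = d[1] * d[2]), d)
.bcast_c <- function(v, d) array(rep(v, each = d[1] * d[2]), d)

# batch normalization over (H, W, N) per channel, batch statistics
.bn_fw <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
  mu <- colMeans(xm)
  va <- pmax(colMeans(xm * xm) - mu^2, 0)
  inv <- 1 / sqrt(va + eps)
  xhat <- (x - .bcast_c(mu, d)) * .bcast_c(inv, d)
  y <- .bcast_c(gamma, d) * xhat + .bcast_c(beta, d)
  list(y = y, xhat = xhat, inv = inv, gamma = gamma)
}

.bn_bw <- function(dy, cache) {
  d <- dim(dy)
  C <- d[3]
  M <- d[1] * d[2] * d[4]
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = C)
  xhm <- matrix(aperm(cache$xhat, c(1, 2, 4, 3)), ncol = C)
  dgamma <- colSums(dym * xhm)
  dbeta <- colSums(dym)
  g <- cache$gamma
  s1 <- dbeta * g            # colSums of dxhat
  s2 <- dgamma * g           # colSums of dxhat * xhat
  dx <- .bcast_c(g * cache$inv, d) * dy -
    .bcast_c(cache$inv * s1 / M, d) -
    cache$xhat * .bcast_c(cache$inv * s2 / M, d)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# squeeze-and-excite forward on [H,W,C,N]; returns gated features and cache
.se_fw <- function(s, sW1, sb1, sW2, sb2) {
  d <- dim(s)
  zv <- .ch_means(s)                        # C x N
  upre <- crossprod(sW1, zv) + sb1          # hid x N
  u <- pmax(upre, 0)
  v <- crossprod(sW2, u) + sb2              # C x N
  g <- .sigmoid(v)
  list(y = s * .bcast_cn(g, d), zv = zv, upre = upre, u = u, g = g)
}

.se_bw <- function(dy, s, cache, sW1, sW2) {
  d <- dim(s)
  g <- cache$g
  ds <- dy * .bcast_cn(g, d)
  dg <- .ch_sums(dy * s)
  dv <- dg * g * (1 - g)
  dsb2 <- rowSums(dv)
  dsW2 <- cache$u %*% t(dv)
  du <- (sW2 %*% dv) * (cache$upre > 0)
  dsb1 <- rowSums(du)
  dsW1 <- cache$zv %*% t(du)
  dzv <- sW1 %*% du
  ds <- ds + .bcast_cn(dzv, d) / (d[1] * d[2])
  list(ds = ds, dsW1 = dsW1, dsb1 = dsb1, dsW2 = dsW2, dsb2 = dsb2)
}

.concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# forward through one dense residual block; cache everything if training
.block_fw <- function(h, bp, merge, se_gates = NULL, keep = FALSE) {
  z1 <- conv2d_fw_cpp(h, bp$W1, bp$b1)
  bn1 <- .bn_fw(z1, bp$g1, bp$be1)
  c1 <- .relu(bn1$y)
  z2 <- conv2d_fw_cpp(c1, bp$W2, bp$b2)
  bn2 <- .bn_fw(z2, bp$g2, bp$be2)
  c2 <- .relu(bn2$y)
  s <- c1 + c2
  if (is.null(se_gates)) {
    se <- .se_fw(s, bp$sW1, bp$sb1, bp$sW2, bp$sb2)
    yse <- se$y
  } else {
    se <- NULL
    yse <- s * .bcast_cn(matrix(se_gates, dim(s)[3], dim(s)[4]), dim(s))
  }
  merged <- if (merge == "concat") .concat_ch(h, yse) else h + yse
  mp <- maxpool2_fw_cpp(merged)
  out <- list(y = mp$y)
  if (keep)
    out <- c(out, list(h = h, bn1 = bn1, c1 = c1, bn2 = bn2, c2 = c2,
                       s = s, se = se, idx = mp$idx,
                       msize = dim(merged)[1:2]))
  out
}

.block_bw <- function(dp, cache, bp, merge) {
  d_h <- dim(cache$h)
  dm <- maxpool2_bw_cpp(cache$idx, dp, cache$msize[1], cache$msize[2])
  if (merge == "concat") {
    cin <- d_h[3]
    dh_direct <- dm[, , seq_len(cin), , drop = FALSE]
    dyse <- dm[, , cin + seq_len(dim(dm)[3] - cin), , drop = FALSE]
  } else {
    dh_direct <- dm
    dyse <- dm
  }
  se <- .se_bw(dyse, cache$s, cache$se, bp$sW1, bp$sW2)
  ds <- se$ds
  dbn2 <- ds * (cache$c2 > 0)
  bn2 <- .bn_bw(dbn2, cache$bn2)
  cv2 <- conv2d_bw_cpp(cache$c1, bp$W2, bn2$dx)
  dc1 <- ds + cv2$dx
  dbn1 <- dc1 * (cache$c1 > 0)
  bn1 <- .bn_bw(dbn1, cache$bn1)
  cv1 <- conv2d_bw_cpp(cache$h, bp$W1, bn1$dx)
  dh <- dh_direct + cv1$dx
  list(dh = dh,
       grads = list(W1 = cv1$dW, b1 = cv1$db, g1 = bn1$dgamma,
                    be1 = bn1$dbeta, W2 = cv2$dW, b2 = cv2$db,
                    g2 = bn2$dgamma, be2 = bn2$dbeta,
                    sW1 = se$dsW1, sb1 = se$dsb1,
                    sW2 = se$dsW2, sb2 = se$dsb2))
}

.block_par <- function(P, b) {
  pre <- sprintf("b%d.", b)
  fields <- c("W1", "b1", "g1", "be1", "W2", "b2", "g2", "be2",
              "sW1", "sb1", "sW2", "sb2")
  stats::setNames(lapply(fields, function(f) P[[paste0(pre, f)]]), fields)
}

# full network forward; returns logits [K, N] (+ caches when training)
.net_fw <- function(P, cfg, x, keep = FALSE) {
  z0 <- conv2d_fw_cpp(x, P[["conv0.W"]], P[["conv0.b"]])
  a0 <- .relu(z0)
  h <- a0
  caches <- if (keep) vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    res <- .block_fw(h, .block_par(P, b), cfg$merge, keep = keep)
    if (keep) caches[[b]] <- res
    h <- res$y
  }
  dh <- dim(h)
  fm <- matrix(h, dh[1] * dh[2] * dh[3], dh[4])
  logits <- crossprod(P[["dense.W"]], fm) + P[["dense.b"]]
  out <- list(logits = logits)
  if (keep) out <- c(out, list(x = x, z0 = z0, a0 = a0, caches = caches,
                               fm = fm, hdim = dh))
  out
}

.net_bw <- function(P, cfg, fwd, dlogits) {
  G <- list()
  G[["dense.W"]] <- fwd$fm %*% t(dlogits)
  G[["dense.b"]] <- rowSums(dlogits)
  dfm <- P[["dense.W"]] %*% dlogits
  dh <- array(dfm, fwd$hdim)
  for (b in rev(seq_len(cfg$n_blocks))) {
    bb <- .block_bw(dh, fwd$caches[[b]], .block_par(P, b), cfg$merge)
    dh <- bb$dh
    for (f in names(bb$grads)) G[[sprintf("b%d.%s", b, f)]] <- bb$grads[[f]]
  }
  da0 <- dh * (fwd$z0 > 0)
  cv0 <- conv2d_bw_cpp(fwd$x, P[["conv0.W"]], da0)
  G[["conv0.W"]] <- cv0$dW
  G[["conv0.b"]] <- cv0$db
  G
}

# softmax cross-entropy over logits [K, N]; y is 0-based labels
.softmax_ce <- function(logits, y) {
  K <- nrow(logits); N <- ncol(logits)
  Z <- sweep(logits, 2, apply(logits, 2, max))
  E <- exp(Z)
  Pm <- sweep(E, 2, colSums(E), "/")
  iy <- cbind(y + 1L, seq_len(N))
  loss <- -mean(log(pmax(Pm[iy], 1e-300)))
  dlog <- Pm
  dlog[iy] <- dlog[iy] - 1
  list(loss = loss, dlogits = dlog / N, probs = Pm)
}

# ---- exported layer operations (testable building blocks) ------------------

#' Squeeze-and-excite channel recalibration
#'
#' Squeeze: per-channel spatial mean. Excite: linear map to `C/r` units,
#' ReLU, linear map back to `C`, sigmoid, giving per-channel gates in (0, 1)
#' that rescale the input channels.
#'
#' @param features `[H, W, C]` or `[H, W, C, N]` numeric array.
#' @param gate_params List with `sW1` (`C x hid`), `sb1`, `sW2` (`hid x C`),
#'   `sb2` excitation parameters.
#' @return Array of the same shape with each channel multiplied by its gate;
#'   the gates are attached as attribute `"gates"` (`C x N`).
#' @examples
#' x <- array(1, c(4, 4, 2))
#' gp <- list(sW1 = matrix(0, 2, 1), sb1 = 0, sW2 = matrix(0, 1, 2),
#'            sb2 = c(0, 0))
#' y <- se_recalibrate(x, gp)   # all gates sigmoid(0) = 0.5
#' @export
se_recalibrate <- function(features, gate_params) {
  x <- features
  squeeze3 <- FALSE
  if (length(dim(x)) == 3) { dim(x) <- c(dim(x), 1L); squeeze3 <- TRUE }
  stopifnot(length(dim(x)) == 4)
  se <- .se_fw(x, gate_params$sW1, gate_params$sb1,
               gate_params$sW2, gate_params$sb2)
  y <- se$y
  if (squeeze3) dim(y) <- dim(y)[1:3]
  attr(y, "gates") <- se$g
  y
}

#' Dense residual block forward pass
#'
#' One SE-RCNet block: conv-BN-ReLU, conv-BN-ReLU, element-wise sum of the
#' two paths, SE recalibration, merge with the block input (channel
#' concatenation by default), then 2x2 max-pooling.
#'
#' @param features `[H, W, C]` or `[H, W, C, N]` array.
#' @param block_params Flat list with fields `W1, b1, g1, be1, W2, b2, g2,
#'   be2, sW1, sb1, sW2, sb2` (see [sercnet_block_params()]).
#' @param merge `"concat"` or `"add"`.
#' @param se_gates Optional fixed gate value(s) overriding the SE module
#'   (e.g. `1` to disable recalibration and recover the plain residual
#'   block).
#' @return The pooled block output array.
#' @export
dense_residual_block <- function(features, block_params,
                                 merge = c("concat", "add"),
                                 se_gates = NULL) {
  merge <- match.arg(merge)
  x <- features
  squeeze3 <- FALSE
  if (length(dim(x)) == 3) { dim(x) <- c(dim(x), 1L); squeeze3 <- TRUE }
  res <- .block_fw(x, block_params, merge, se_gates = se_gates)
  y <- res$y
  if (squeeze3) dim(y) <- dim(y)[1:3]
  y
}

#' Extract the parameters of one block of a model
#'
#' @param model A [build_model()] result.
#' @param b Block index (1-based).
#' @return Flat named list of the block's twelve parameter arrays.
#' @export
sercnet_block_params <- function(model, b) {
  stopifnot(inherits(model, "sercnet_model"))
  if (b < 1 || b > model$cfg$n_blocks) stop("no block ", b)
  .block_par(model$params, b)
}

# ---- datasets --------------------------------------------------------------

#' Stack radar images into a training array
#'
#' Collects a list of [radar_image]s (or plain matrices) into the
#' `[H, W, channels, N]` array + label vector format consumed by [train()]
#' and [predict.sercnet_model()].
#'
#' @param images List of [radar_image]s or numeric matrices.
#' @param labels Optional integer class labels (0-based); taken from the
#'   images when omitted.
#' @return List with `x` (4-d array) and `y` (integer labels or NULL).
#' @export
image_stack <- function(images, labels = NULL) {
  stopifnot(is.list(images), length(images) >= 1)
  mats <- lapply(images, function(im)
    if (inherits(im, "radar_image")) im$pixels else im)
  d1 <- dim(mats[[1]])
  x <- array(unlist(mats, use.names = FALSE), c(d1[1], d1[2], 1L, length(mats)))
  if (is.null(labels)) {
    labs <- lapply(images, function(im)
      if (inherits(im, "radar_image") && !is.null(im$label)) im$label else NA_integer_)
    labels <- unlist(labs)
    if (all(is.na(labels))) labels <- NULL
  }
  if (!is.null(labels)) labels <- as.integer(labels)
  list(x = x, y = labels)
}

.as_batch <- function(newdata, cfg) {
  x <- if (is.list(newdata) && !is.null(newdata$x)) newdata$x else newdata
  if (is.list(x) && !is.array(x)) x <- image_stack(x)$x
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x)[1:2], 1L, dim(x)[3])
  if (length(dim(x)) != 4)
    stop("input error: expected [H, W, C, N] image array")
  d <- dim(x)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size ||
      d[3] != cfg$input_channels)
    stop("input error: image shape ", d[1], "x", d[2], "x", d[3],
         " does not match the configured ", cfg$input_size, "x",
         cfg$input_size, "x", cfg$input_channels)
  x
}

# ---- training --------------------------------------------------------------

.adam_step <- function(P, G, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(P)) {
    g <- G[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    P[[nm]] <- P[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(P = P, state = state)
}

#' Train an SE-RCNet model
#'
#' Minimizes categorical cross-entropy with Adam. Shuffling and
#' initialization derive from the configuration seed, so equal seeds give
#' identical histories. The weights achieving the best validation accuracy
#' (earliest epoch on ties) are returned.
#'
#' @param model An untrained (or previously trained) [build_model()] result.
#' @param train_set,val_set Lists with `x` (`[H, W, C, N]` array) and `y`
#'   (0-based integer labels), e.g. from [image_stack()].
#' @param cfg Optional [sercnet_config] whose *training* fields (`epochs`,
#'   `batch_size`, `learning_rate`, `seed`) override the model's; the
#'   architecture always comes from the model.
#' @return The model with trained `params` and a `history` data.frame
#'   (epoch, train_loss, train_acc, val_loss, val_acc).
#' @export
train <- function(model, train_set, val_set, cfg = model$cfg) {
  stopifnot(inherits(model, "sercnet_model"))
  mcfg <- model$cfg
  xt <- .as_batch(train_set, mcfg)
  xv <- .as_batch(val_set, mcfg)
  yt <- as.integer(train_set$y)
  yv <- as.integer(val_set$y)
  if (length(yt) == 0 || length(yv) == 0)
    stop("data error: empty train or validation split")
  if (length(yt) != dim(xt)[4] || length(yv) != dim(xv)[4])
    stop("data error: label count does not match image count")
  if (any(yt < 0 | yt >= mcfg$n_classes) || any(yv < 0 | yv >= mcfg$n_classes))
    stop("data error: labels must lie in 0..n_classes-1")
  epochs <- cfg$epochs
  bs <- cfg$batch_size
  lr <- cfg$learning_rate
  P <- model$params
  state <- list(t = 0, m = lapply(P, function(p) p * 0),
                v = lapply(P, function(p) p * 0))
  N <- length(yt)
  hist <- vector("list", epochs)
  best <- list(acc = -Inf, params = P)
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      tl <- 0; tc <- 0
      for (s0 in seq(1, N, by = bs)) {
        ix <- ord[s0:min(s0 + bs - 1, N)]
        xb <- xt[, , , ix, drop = FALSE]
        yb <- yt[ix]
        fwd <- .net_fw(P, mcfg, xb, keep = TRUE)
        sm <- .softmax_ce(fwd$logits, yb)
        G <- .net_bw(P, mcfg, fwd, sm$dlogits)
        upd <- .adam_step(P, G, state, lr)
        P <- upd$P; state <- upd$state
        tl <- tl + sm$loss * length(ix)
        tc <- tc + sum(max.col(t(fwd$logits), ties.method = "first") - 1L == yb)
      }
      vf <- .net_fw(P, mcfg, xv)
      vs <- .softmax_ce(vf$logits, yv)
      vacc <- mean(max.col(t(vf$logits), ties.method = "first") - 1L == yv)
      hist[[ep]] <- data.frame(epoch = ep, train_loss = tl / N,
                               train_acc = tc / N, val_loss = vs$loss,
                               val_acc = vacc)
      if (vacc > best$acc) best <- list(acc = vacc, params = P)
    }
  })
  model$params <- if (epochs > 0) best$params else P
  model$history <- if (epochs > 0) do.call(rbind, hist) else
    data.frame(epoch = integer(), train_loss = numeric(),
               train_acc = numeric(), val_loss = numeric(),
               val_acc = numeric())
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict logits for a batch of radar images
#'
#' Returns raw class scores (logits); convert to probabilities and
#' confidences with [softmax_probs()] / [classifier_output()].
#'
#' @param object A [sercnet_model].
#' @param newdata `[H, W, C, N]` array, list with `x`, list of
#'   [radar_image]s, or a single image matrix.
#' @param ... Unused.
#' @return Numeric matrix `[N, n_classes]` of logits (one row per sample).
#' @export
predict.sercnet_model <- function(object, newdata, ...) {
  x <- .as_batch(newdata, object$cfg)
  t(.net_fw(object$params, object$cfg, x)$logits)
}
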