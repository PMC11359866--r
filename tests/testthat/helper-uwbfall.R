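# Shared fixtures: a small radar geometry that keeps simulations cheap while
# leaving enough pulses for the default 128-point STFT window, and toy image
# datasets for classifier tests.

small_params <- function(duration = 1, n_range_bins = 64, max_range = 5)
  radar_params(duration = duration, n_range_bins = n_range_bins,
               max_range = max_range)

# a clutter-free, noise-free recording of a custom trajectory
clean_recording <- function(range_fn, params, label = NULL) {
  pr <- motion_profile(range_fn, class_id = if (is.null(label)) NA else label)
  synthesize_pulses(pr, params, clutter_amp = 0, noise_sigma = 0, rng_seed = 1)
}

# two linearly separable classes: a bright blob on the left vs on the right
toy_blob_set <- function(n_per_class, size = 16, seed = 1, jitter = 0.05) {
  imgs <- list()
  labels <- integer(0)
  set.seed(seed)
  for (cl in 0:1) {
    for (i in seq_len(n_per_class)) {
      m <- matrix(abs(rnorm(size * size, 0, jitter)), size, size)
      rows <- (size %/% 2 - 2):(size %/% 2 + 2)
      cols <- if (cl == 0) 2:6 else (size - 5):(size - 1)
      m[rows, cols] <- m[rows, cols] + 1
      imgs[[length(imgs) + 1]] <- pmin(m, 1)
      labels <- c(labels, cl)
    }
  }
  list(x = image_stack(imgs)$x, y = as.integer(labels))
}

tiny_cfg <- function(...) {
  defaults <- list(n_classes = 2, input_size = 16, init_channels = 4,
                   n_blocks = 1, channels_per_block = 4, se_reduction = 2,
                   epochs = 15, batch_size = 8, learning_rate = 5e-3,
                   seed = 42)
  args <- utils::modifyList(defaults, list(...))
  do.call(sercnet_config, args)
}

# random classifier_output over K classes with seeded logits
random_output <- function(K) classifier_output(rnorm(K, sd = 2))

# independent brute-force adaptive fusion: materialize w' over all K classes
brute_force_fuse <- function(n, outputs) {
  K <- length(outputs[[1]]$probs)
  smax <- sapply(outputs, function(o) o$smax)
  m <- smax / sum(smax)
  w <- n * m
  wp <- numeric(K)
  for (i in 1:3) {
    cls <- outputs[[i]]$imax + 1
    wp[cls] <- wp[cls] + w[i]
  }
  best <- which(wp == max(wp))[1]   # lowest index on ties
  best - 1L
}

# independent one-vs-rest metric computation from first principles
brute_force_metrics <- function(cm) {
  K <- nrow(cm)
  prec <- rec <- f1 <- numeric(K)
  for (k in seq_len(K)) {
    tp <- cm[k, k]
    fp <- sum(cm[-k, k])
    fn <- sum(cm[k, -k])
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec[k] + rec[k] > 0)
      2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  list(accuracy = sum(diag(cm)) / sum(cm), precision = mean(prec),
       recall = mean(rec), f1 = mean(f1))
}
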