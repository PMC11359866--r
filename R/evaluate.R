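#' Stratified 6:2:2 train/validation/test split
#'
#' Randomly partitions sample indices into training, validation and test
#' sets in a 6:2:2 ratio, stratified by class: within each class
#' `floor(0.6 n)` samples go to training, `floor(0.2 n)` to validation and
#' the remainder to test. Deterministic given `seed`.
#'
#' @param labels Vector of class labels (one per sample).
#' @param seed Integer seed.
#' @return An object of class `split_plan`: list with integer index vectors
#'   `train`, `val`, `test` and the `seed`.
#' @examples
#' sp <- split_622(rep(0:9, each = 10), seed = 1)
#' lengths(sp[c("train", "val", "test")])  # 60 / 20 / 20
#' @export
split_622 <- function(labels, seed = 0) {
  labels <- as.vector(labels)
  cnt <- table(labels)
  small <- names(cnt)[cnt < 5]
  if (length(small) > 0)
    stop("data error: class(es) ", paste(small, collapse = ", "),
         " have fewer than 5 samples")
  idx <- with_seed(seed, {
    tr <- va <- te <- integer(0)
    for (cl in names(cnt)) {
      ix <- sample(which(labels == cl))
      n <- length(ix)
      n_tr <- floor(0.6 * n)
      n_va <- floor(0.2 * n)
      tr <- c(tr, ix[seq_len(n_tr)])
      va <- c(va, ix[n_tr + seq_len(n_va)])
      te <- c(te, ix[-seq_len(n_tr + n_va)])
    }
    list(train = tr, val = va, test = te)
  })
  structure(c(idx, list(seed = seed)), class = "split_plan")
}

#' Stratified k-fold cross-validation plan
#'
#' Deals each class's shuffled samples round-robin into k folds, so every
#' sample is held out exactly once and folds are class-balanced within
#' rounding.
#'
#' @param labels Vector of class labels.
#' @param k Number of folds (default 5, must be >= 2).
#' @param seed Integer seed.
#' @return List of k `split_plan`-like lists, each with `train` and `test`
#'   index vectors; the fold assignment vector is attached as attribute
#'   `"fold"`.
#' @export
kfold <- function(labels, k = 5, seed = 0) {
  if (k < 2) stop("parameter error: `k` must be >= 2")
  labels <- as.vector(labels)
  cnt <- table(labels)
  small <- names(cnt)[cnt < k]
  if (length(small) > 0)
    stop("data error: class(es) ", paste(small, collapse = ", "),
         " have fewer than k = ", k, " samples")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(cnt)) {
      ix <- sample(which(labels == cl))
      fold[ix] <- rep_len(seq_len(k), length(ix))
    }
  })
  plans <- lapply(seq_len(k), function(f)
    structure(list(train = which(fold != f), test = which(fold == f),
                   seed = seed),
              class = "split_plan"))
  attr(plans, "fold") <- fold
  plans
}

#' Confusion matrix
#'
#' Counts matrix with rows = true class, columns = predicted class, over
#' classes `0..K-1`.
#'
#' @param true_labels,predicted_labels Equal-length integer vectors with
#'   values in `0..K-1`.
#' @param K Number of classes.
#' @return A `K x K` integer matrix of class `confusion_matrix` (dimnames
#'   are the class ids).
#' @export
confusion <- function(true_labels, predicted_labels, K) {
  if (length(true_labels) != length(predicted_labels))
    stop("input error: label vectors differ in length")
  lv <- 0:(K - 1)
  if (any(!true_labels %in% lv) || any(!predicted_labels %in% lv))
    stop("input error: labels outside 0..", K - 1)
  cm <- table(factor(true_labels, levels = lv),
              factor(predicted_labels, levels = lv))
  cm <- matrix(as.integer(cm), K, K, dimnames = list(true = lv, predicted = lv))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (rows = true, cols = predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is the trace over the total. Per-class precision
#' `TP / (TP + FP)`, recall `TP / (TP + FN)` and
#' `F1 = 2 * precision * recall / (precision + recall)` are computed
#' one-vs-rest; a class never predicted gets precision 0, and F1 is 0 when
#' precision + recall is 0. The headline precision/recall/F1 are macro
#' averages (unweighted class means) by default; `average = "micro"` pools
#' the per-class counts instead (for single-label classification micro
#' precision = recall = F1 = accuracy).
#'
#' @param cm A [confusion()] matrix (any square count matrix works).
#' @param average `"macro"` (default) or `"micro"`.
#' @return An object of class `metrics_report`: list with `accuracy`,
#'   `precision`, `recall`, `f1`, `average` and a `per_class` data.frame.
#' @export
metrics <- function(cm, average = c("macro", "micro")) {
  average <- match.arg(average)
  cm <- unclass(cm)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || length(cm) == 0)
    stop("input error: `cm` must be a non-empty square matrix")
  total <- sum(cm)
  if (total <= 0) stop("input error: empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  per_class <- data.frame(class = colnames(cm) %||% as.character(seq_len(nrow(cm)) - 1),
                          precision = as.numeric(prec),
                          recall = as.numeric(rec), f1 = as.numeric(f1),
                          support = as.numeric(rowSums(cm)))
  if (average == "macro") {
    P <- mean(prec); R <- mean(rec); F1 <- mean(f1)
  } else {
    P <- sum(tp) / (sum(tp) + sum(fp))
    R <- sum(tp) / (sum(tp) + sum(fn))
    F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  }
  structure(list(accuracy = sum(tp) / total, precision = P, recall = R,
                 f1 = F1, average = average, per_class = per_class),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat(sprintf("<metrics_report> (%s-averaged)\n", x$average))
  cat(sprintf("  accuracy %.*f  precision %.*f  recall %.*f  F1 %.*f\n",
              digits, x$accuracy, digits, x$precision, digits, x$recall,
              digits, x$f1))
  invisible(x)
}

#' Experiment configuration
#'
#' Settings for the end-to-end driver [run_experiment()]: dataset scale,
#' radar and STFT parameters, classifier configuration and the optional
#' deliberate degradation of one map kind (extra pixel noise, used to study
#' how fusion copes with an unreliable map).
#'
#' @param per_class Recordings per class.
#' @param params A [radar_params].
#' @param net A [sercnet_config].
#' @param stft An [stft_config].
#' @param clutter_amp,noise_sigma Echo simulator settings.
#' @param degrade_kind One of `"none"`, `"range_time"`, `"time_doppler"`,
#'   `"range_doppler"`: map kind to corrupt with additive Gaussian pixel
#'   noise (clamped back to \[0, 1\]).
#' @param degrade_sigma Standard deviation of the degradation noise.
#' @param seed Master seed; all stage seeds derive from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(per_class = 30, params = radar_params(),
                              net = sercnet_config(), stft = stft_config(),
                              clutter_amp = 1, noise_sigma = 0.05,
                              degrade_kind = c("none", "range_time",
                                               "time_doppler", "range_doppler"),
                              degrade_sigma = 0.3, seed = 0) {
  degrade_kind <- match.arg(degrade_kind)
  stopifnot(inherits(params, "radar_params"), inherits(net, "sercnet_config"),
            inherits(stft, "stft_config"), per_class >= 5)
  structure(list(per_class = as.integer(per_class), params = params,
                 net = net, stft = stft, clutter_amp = clutter_amp,
                 noise_sigma = noise_sigma, degrade_kind = degrade_kind,
                 degrade_sigma = degrade_sigma, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Simulate a dataset of preprocessed radar images
#'
#' Streams the echo simulator into the preprocessing chain one recording at
#' a time (pulse matrices are not retained), yielding the three image
#' stacks for a balanced `10 * per_class` dataset.
#'
#' @param params A [radar_params].
#' @param per_class Recordings per class.
#' @param rng_seed Master seed.
#' @param clutter_amp,noise_sigma Echo simulator settings.
#' @param stft An [stft_config].
#' @param size Image side length.
#' @return List with `labels` (integer vector) and one `[size, size, 1, N]`
#'   array per map kind (`range_time`, `time_doppler`, `range_doppler`).
#' @export
simulate_images <- function(params, per_class, rng_seed = 0, clutter_amp = 1,
                            noise_sigma = 0.05, stft = stft_config(),
                            size = 80) {
  per_class <- as.integer(per_class)
  n <- 10L * per_class
  seeds <- with_seed(rng_seed, matrix(sample.int(.Machine$integer.max, 2L * n),
                                      nrow = 2L))
  kinds <- c("range_time", "time_doppler", "range_doppler")
  arrs <- lapply(kinds, function(k) array(0, c(size, size, 1L, n)))
  names(arrs) <- kinds
  labels <- integer(n)
  k <- 0L
  for (cid in 0:9) {
    for (r in seq_len(per_class)) {
      k <- k + 1L
      pr <- make_profile(cid, params, rng_seed = seeds[1L, k])
      pm <- synthesize_pulses(pr, params, clutter_amp = clutter_amp,
                              noise_sigma = noise_sigma,
                              rng_seed = seeds[2L, k])
      ims <- radar_images(pm, stft, size = size)
      for (kind in kinds) arrs[[kind]][, , 1L, k] <- ims[[kind]]$pixels
      labels[k] <- cid
    }
  }
  c(list(labels = labels), arrs)
}

.subset_x <- function(x, ix) x[, , , ix, drop = FALSE]

.degrade_images <- function(x, sigma, seed) {
  if (sigma <= 0) return(x)
  noisy <- x + with_seed(seed, array(rnorm(length(x), 0, sigma), dim(x)))
  array(pmin(pmax(noisy, 0), 1), dim(x))
}

#' End-to-end fall-classification experiment
#'
#' Runs the full protocol at the configured scale: simulate a balanced
#' dataset, preprocess into the three map kinds, split 6:2:2 (stratified),
#' train one SE-RCNet per map kind, measure each map's validation accuracy
#' `n`, then classify the test set and fuse the three per-sample outputs
#' with both decision-level fusion and adaptive weighted fusion. The report
#' tabulates accuracy/precision/recall/F1 per map and per fusion method,
#' plus improvement rows (fused minus best single map) in both absolute
#' percentage points and relative percent.
#'
#' @param config An [experiment_config].
#' @return An object of class `experiment_report`: list with `table`
#'   (data.frame of metrics), `val_accuracy` (n vector), `confusion`
#'   (per-method confusion matrices), `history` (per-map training
#'   histories), `config_summary` and `seed`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  kinds <- c("time_doppler", "range_time", "range_doppler")
  stage_seeds <- with_seed(config$seed, sample.int(.Machine$integer.max, 8))

  ds <- tryCatch(
    simulate_images(config$params, config$per_class,
                    rng_seed = stage_seeds[1],
                    clutter_amp = config$clutter_amp,
                    noise_sigma = config$noise_sigma, stft = config$stft,
                    size = config$net$input_size),
    error = function(e) stop("simulate stage: ", conditionMessage(e)))
  if (config$degrade_kind != "none")
    ds[[config$degrade_kind]] <- .degrade_images(ds[[config$degrade_kind]],
                                                 config$degrade_sigma,
                                                 stage_seeds[2])
  sp <- tryCatch(split_622(ds$labels, seed = stage_seeds[3]),
                 error = function(e) stop("split stage: ", conditionMessage(e)))

  models <- list()
  val_acc <- numeric(length(kinds))
  names(val_acc) <- kinds
  test_logits <- list()
  for (i in seq_along(kinds)) {
    kind <- kinds[i]
    cfg_i <- config$net
    cfg_i$seed <- as.integer((config$net$seed + stage_seeds[4] + i) %%
                               .Machine$integer.max)
    mdl <- tryCatch({
      m <- build_model(cfg_i)
      train(m,
            list(x = .subset_x(ds[[kind]], sp$train), y = ds$labels[sp$train]),
            list(x = .subset_x(ds[[kind]], sp$val), y = ds$labels[sp$val]))
    }, error = function(e) stop("train stage (", kind, "): ",
                                conditionMessage(e)))
    models[[kind]] <- mdl
    vl <- predict(mdl, .subset_x(ds[[kind]], sp$val))
    val_acc[i] <- mean(max.col(vl, ties.method = "first") - 1L ==
                         ds$labels[sp$val])
    test_logits[[kind]] <- predict(mdl, .subset_x(ds[[kind]], sp$test))
  }

  y_test <- ds$labels[sp$test]
  n_test <- length(y_test)
  K <- config$net$n_classes
  pred_single <- lapply(test_logits, function(L)
    max.col(L, ties.method = "first") - 1L)
  pred_decision <- integer(n_test)
  pred_adaptive <- integer(n_test)
  for (s in seq_len(n_test)) {
    outs <- lapply(kinds, function(kind)
      classifier_output(test_logits[[kind]][s, ]))
    pred_decision[s] <- as.integer(decision_fuse(outs))
    pred_adaptive[s] <- as.integer(
      adaptive_weighted_fuse(unname(val_acc), outs)$fused_class)
  }

  cms <- c(lapply(pred_single, function(p) confusion(y_test, p, K)),
           list(decision_fusion = confusion(y_test, pred_decision, K),
                adaptive_weighted_fusion = confusion(y_test, pred_adaptive, K)))
  mts <- lapply(cms, metrics)
  row_of <- function(name, m)
    data.frame(method = name, accuracy = m$accuracy, precision = m$precision,
               recall = m$recall, f1 = m$f1)
  tab <- do.call(rbind, c(
    lapply(seq_along(kinds), function(i)
      row_of(paste0(kinds[i], " (before fusion)"), mts[[i]])),
    list(row_of("adaptive_weighted_fusion", mts$adaptive_weighted_fusion),
         row_of("decision_fusion", mts$decision_fusion))))

  single <- tab[seq_along(kinds), c("accuracy", "precision", "recall", "f1")]
  best_single <- apply(single, 2, max)
  imp_rows <- do.call(rbind, lapply(
    c("adaptive_weighted_fusion", "decision_fusion"), function(meth) {
      fused <- unlist(tab[tab$method == meth,
                          c("accuracy", "precision", "recall", "f1")])
      rbind(data.frame(method = paste0("improvement_points (", meth, ")"),
                       accuracy = 100 * (fused[1] - best_single[1]),
                       precision = 100 * (fused[2] - best_single[2]),
                       recall = 100 * (fused[3] - best_single[3]),
                       f1 = 100 * (fused[4] - best_single[4])),
            data.frame(method = paste0("improvement_relative_pct (", meth, ")"),
                       accuracy = 100 * (fused[1] / best_single[1] - 1),
                       precision = 100 * (fused[2] / best_single[2] - 1),
                       recall = 100 * (fused[3] / best_single[3] - 1),
                       f1 = 100 * (fused[4] / best_single[4] - 1)))
    }))
  tab <- rbind(tab, imp_rows)
  rownames(tab) <- NULL

  structure(list(table = tab, val_accuracy = val_acc, confusion = cms,
                 history = lapply(models, `[[`, "history"),
                 predictions = list(test_labels = y_test,
                                    single = pred_single,
                                    decision = pred_decision,
                                    adaptive = pred_adaptive),
                 config_summary = list(per_class = config$per_class,
                                       degrade_kind = config$degrade_kind,
                                       degrade_sigma = config$degrade_sigma,
                                       epochs = config$net$epochs),
                 seed = config$seed),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, digits = 4, ...) {
  cat("<experiment_report>  (seed", x$seed, ")\n")
  cat("validation accuracy n =",
      paste(sprintf("%s %.3f", names(x$val_accuracy), x$val_accuracy),
            collapse = ", "), "\n\n")
  tab <- x$table
  tab[, -1] <- round(tab[, -1], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write an experiment report to disk
#'
#' Saves the metrics table and configuration as JSON and every confusion
#' matrix as CSV.
#'
#' @param report An [run_experiment()] report.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(table = report$table, val_accuracy = as.list(report$val_accuracy),
         config = report$config_summary, seed = report$seed),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  for (nm in names(report$confusion))
    utils::write.csv(unclass(report$confusion[[nm]]),
                     file.path(dir, paste0("confusion_", nm, ".csv")))
  invisible(dir)
}
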