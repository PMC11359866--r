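#' Softmax probabilities from logits
#'
#' Converts a logits vector z into the probability simplex via
#' `s_i = exp(z_i) / sum_j exp(z_j)`, computed shift-invariantly (the
#' maximum is subtracted first), so `softmax_probs(z) == softmax_probs(z + c)`
#' for any constant c.
#'
#' @param z Finite numeric vector of class scores.
#' @return Numeric vector of the same length summing to 1.
#' @examples
#' softmax_probs(c(1, 0))   # ~ c(0.731, 0.269)
#' @export
softmax_probs <- function(z) {
  if (length(z) == 0) stop("input error: empty logits vector")
  if (any(!is.finite(z))) stop("input error: logits must be finite")
  e <- exp(z - max(z))
  e / sum(e)
}

#' Prediction confidence
#'
#' The confidence of a probabilistic prediction is its largest class
#' probability `smax = max(s)`; `imax` is the class attaining it (ties break
#' to the lowest class index).
#'
#' @param s Probability vector (non-negative, summing to 1).
#' @param classes Class labels corresponding to the entries of `s`;
#'   defaults to 0-based indices `0..K-1`.
#' @return List with `smax` and `imax` (the class label).
#' @export
confidence <- function(s, classes = seq_along(s) - 1L) {
  stopifnot(length(s) >= 1, length(classes) == length(s))
  if (any(s < 0) || abs(sum(s) - 1) > 1e-6)
    stop("input error: `s` must be a probability vector")
  i <- which.max(s)   # which.max takes the first (lowest index) on ties
  list(smax = s[[i]], imax = classes[[i]])
}

#' Classifier output record
#'
#' Bundles one sample's logits with the derived softmax probabilities,
#' confidence `smax` and predicted class `imax`.
#'
#' @param logits Finite numeric vector of class scores.
#' @param classes Class labels; default 0-based indices.
#' @return An object of class `classifier_output` with fields `logits`,
#'   `probs`, `smax`, `imax`, `classes`.
#' @export
classifier_output <- function(logits, classes = seq_along(logits) - 1L) {
  s <- softmax_probs(logits)
  cf <- confidence(s, classes)
  structure(list(logits = logits, probs = s, smax = cf$smax, imax = cf$imax,
                 classes = classes),
            class = "classifier_output")
}

#' @export
print.classifier_output <- function(x, ...) {
  cat(sprintf("<classifier_output> K = %d, predicted class %s (confidence %.3f)\n",
              length(x$probs), format(x$imax), x$smax))
  invisible(x)
}

.check_triple <- function(outputs) {
  if (length(outputs) != 3 ||
      !all(vapply(outputs, inherits, TRUE, "classifier_output")))
    stop("input error: need a list of exactly 3 classifier_output records")
  K <- vapply(outputs, function(o) length(o$probs), 0L)
  if (length(unique(K)) != 1)
    stop("input error: the three outputs disagree on the number of classes")
  cls <- lapply(outputs, `[[`, "classes")
  if (!all(vapply(cls[-1], identical, TRUE, cls[[1]])))
    stop("input error: the three outputs disagree on the class labels")
  invisible(outputs)
}

#' Decision-level fusion of three radar-map classifiers
#'
#' Majority-with-confidence rule: if two or more maps predict the same
#' class, that class is the result; if all three disagree, the prediction
#' with the highest confidence `smax` wins (ties break to the lowest map
#' index).
#'
#' @param outputs List of 3 [classifier_output] records over the same
#'   classes.
#' @return The fused class label, with the decisive rule (`"majority"` or
#'   `"confidence"`) attached as attribute `"rule"`.
#' @export
decision_fuse <- function(outputs) {
  .check_triple(outputs)
  preds <- unname(vapply(outputs, `[[`, outputs[[1]]$imax[1], "imax"))
  tab <- table(preds)
  if (max(tab) >= 2) {
    win <- names(tab)[tab == max(tab)][1]
    cls <- preds[[match(win, as.character(preds))]]
    return(structure(cls, rule = "majority"))
  }
  smax <- vapply(outputs, `[[`, 0, "smax")
  structure(preds[[which.max(smax)]], rule = "confidence")
}

#' Normalize per-map confidences
#'
#' Sum-normalizes the three maps' `smax` values for one sample into the
#' probability vector `m = smax / sum(smax)` (components in (0, 1], summing
#' to 1); invariant to a common positive rescaling.
#'
#' @param smax_triple Numeric vector of 3 confidences in (0, 1].
#' @return Numeric vector `m` of length 3.
#' @export
normalize_confidences <- function(smax_triple) {
  if (length(smax_triple) != 3) stop("input error: need exactly 3 confidences")
  if (any(!is.finite(smax_triple)) || any(smax_triple <= 0) ||
      any(smax_triple > 1))
    stop("input error: confidences must lie in (0, 1]")
  smax_triple / sum(smax_triple)
}

#' Adaptive weighted fusion
#'
#' Weights each map's per-sample confidence by that map's validation
#' accuracy: with per-map validation accuracies `n = [n1, n2, n3]` and the
#' sample's normalized confidences `m = [m1, m2, m3]`, the adjusted weights
#' are the Hadamard product `w = n o m`. The weights of maps predicting the
#' same class are summed into the per-class score vector `w'`, and the fused
#' class is `argmax(w')` (ties break to the lowest class index). Classes
#' predicted by no map score 0.
#'
#' When all three validation accuracies are equal the ordering of `w`
#' reduces to the ordering of the confidences, so the all-different branch
#' coincides with [decision_fuse()].
#'
#' @param n Numeric vector of 3 per-map validation accuracies in \[0, 1\]
#'   (scalar per map), or a `3 x K` matrix of per-class validation
#'   accuracies (then map i is weighted by its accuracy on its own predicted
#'   class).
#' @param outputs List of 3 [classifier_output] records.
#' @return An object of class `fusion_score`: list with `m`, `w`, `w_prime`
#'   (named per-class scores) and `fused_class`.
#' @export
adaptive_weighted_fuse <- function(n, outputs) {
  .check_triple(outputs)
  classes <- outputs[[1]]$classes
  K <- length(classes)
  per_class <- is.matrix(n)
  if (per_class) {
    if (nrow(n) != 3 || ncol(n) != K)
      stop("input error: per-class `n` must be a 3 x K matrix")
    if (any(!is.finite(n)) || any(n < 0) || any(n > 1))
      stop("input error: accuracies must lie in [0, 1]")
  } else {
    if (length(n) != 3)
      stop("input error: `n` must have one accuracy per map (3)")
    if (any(!is.finite(n)) || any(n < 0) || any(n > 1))
      stop("input error: accuracies must lie in [0, 1]")
  }
  m <- normalize_confidences(vapply(outputs, `[[`, 0, "smax"))
  preds <- vapply(outputs, `[[`, outputs[[1]]$imax[1], "imax")
  pred_pos <- match(preds, classes)
  ni <- if (per_class) n[cbind(1:3, pred_pos)] else n
  w <- ni * m
  w_prime <- numeric(K)
  names(w_prime) <- as.character(classes)
  for (i in 1:3) w_prime[pred_pos[i]] <- w_prime[pred_pos[i]] + w[i]
  fused <- classes[[which.max(w_prime)]]
  structure(list(m = m, w = w, w_prime = w_prime, fused_class = fused),
            class = "fusion_score")
}

#' @export
print.fusion_score <- function(x, ...) {
  cat(sprintf("<fusion_score> fused class %s\n", format(x$fused_class)))
  cat("  w =", format(round(x$w, 4)), "\n")
  nz <- x$w_prime[x$w_prime > 0]
  cat("  w':", paste(sprintf("%s=%.4f", names(nz), nz), collapse = "  "), "\n")
  invisible(x)
}
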