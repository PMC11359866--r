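#' Moving-target-indication three-pulse canceller
#'
#' Applies the second-difference MTI filter `y(n) = x(n+1) - 2 x(n) + x(n-1)`
#' independently per range bin along slow time, suppressing echoes of
#' stationary targets (constants and linear slow-time ramps are annihilated
#' exactly). The output has two fewer pulses; its slow-time grid refers to
#' the retained (interior) pulse indices.
#'
#' The slow-time magnitude response of the canceller at frequency f is
#' `4 sin^2(pi f / prf)`: zero at DC, maximal at the Doppler Nyquist limit.
#'
#' @param pulses A [pulse_matrix] with at least 3 pulses.
#' @return A [pulse_matrix] with `n_pulses - 2` columns; params and label
#'   are preserved.
#' @export
mti_filter <- function(pulses) {
  stopifnot(inherits(pulses, "pulse_matrix"))
  X <- pulses$samples
  n <- ncol(X)
  if (n < 3) stop("MTI three-pulse canceller needs at least 3 pulses, got ", n)
  Y <- X[, 3:n, drop = FALSE] - 2 * X[, 2:(n - 1), drop = FALSE] +
    X[, 1:(n - 2), drop = FALSE]
  out <- pulses
  out$samples <- Y
  out
}

# Analytic signal along slow time (per range bin) via the FFT half-spectrum
# method. The FFT length is zero-padded to the next 5-smooth integer and the
# result truncated, keeping the transform fast for awkward pulse counts.
.analytic_signal <- function(X) {
  n <- ncol(X)
  if (n < 2) return(X + 0i)
  nfft <- next_fast_len(n)
  Xp <- if (nfft > n) cbind(X, matrix(0, nrow(X), nfft - n)) else X
  Fc <- stats::mvfft(t(Xp))                  # fft of each range bin's series
  h <- numeric(nfft)
  h[1] <- 1
  if (nfft %% 2 == 0) {
    h[nfft / 2 + 1] <- 1
    if (nfft > 2) h[2:(nfft / 2)] <- 2
  } else {
    h[2:((nfft + 1) / 2)] <- 2
  }
  A <- t(stats::mvfft(Fc * h, inverse = TRUE)) / nfft
  A[, seq_len(n), drop = FALSE]
}

#' Analytic signal of a pulse matrix
#'
#' Converts a real pulse matrix into its complex analytic signal along slow
#' time (Hilbert transform per range bin). Complex input is returned as is.
#'
#' @param pulses A [pulse_matrix].
#' @return A [pulse_matrix] with complex samples.
#' @export
analytic_signal <- function(pulses) {
  stopifnot(inherits(pulses, "pulse_matrix"))
  if (is.complex(pulses$samples)) return(pulses)
  out <- pulses
  out$samples <- .analytic_signal(pulses$samples)
  out
}

#' Radar map container
#'
#' A 2-D non-negative magnitude map with physical axis coordinates. Three
#' kinds are produced by the pipeline: `range_time` (range m x time s),
#' `time_doppler` (Doppler Hz x time s) and `range_doppler`
#' (range m x Doppler Hz). Doppler axes are zero-centred and span
#' \[-prf/2, +prf/2\].
#'
#' @param values Non-negative numeric matrix.
#' @param kind One of `"range_time"`, `"time_doppler"`, `"range_doppler"`.
#' @param axis0 Physical coordinates of the rows.
#' @param axis1 Physical coordinates of the columns.
#' @param params The [radar_params] the map derives from.
#' @param label Optional class id.
#' @return An object of class `radar_map`.
#' @export
radar_map <- function(values, kind, axis0, axis1, params, label = NULL) {
  kind <- match.arg(kind, c("range_time", "time_doppler", "range_doppler"))
  stopifnot(is.matrix(values), inherits(params, "radar_params"))
  if (any(values < 0) || any(!is.finite(values)))
    stop("radar_map values must be finite and non-negative")
  if (length(axis0) != nrow(values) || length(axis1) != ncol(values))
    stop("axis lengths must match the value grid")
  structure(list(values = values, kind = kind, axis0 = axis0, axis1 = axis1,
                 params = params, label = label),
            class = "radar_map")
}

#' @export
print.radar_map <- function(x, ...) {
  cat(sprintf("<radar_map:%s> %d x %d%s\n", x$kind, nrow(x$values),
              ncol(x$values),
              if (is.null(x$label)) "" else paste0(", class ", x$label)))
  invisible(x)
}

#' Range-time map via the Hilbert envelope
#'
#' Forms the analytic signal along slow time per range bin and returns its
#' magnitude as a `range_time` map (range in metres by slow time in
#' seconds). Normally applied after [mti_filter()], so the envelope traces
#' the moving scatterer only.
#'
#' @param pulses A [pulse_matrix] (real, or already analytic).
#' @return A [radar_map] of kind `range_time`.
#' @export
analytic_envelope <- function(pulses) {
  stopifnot(inherits(pulses, "pulse_matrix"))
  if (length(pulses$samples) == 0) stop("empty pulse matrix")
  A <- if (is.complex(pulses$samples)) pulses$samples
       else .analytic_signal(pulses$samples)
  p <- pulses$params
  radar_map(Mod(A), "range_time",
            axis0 = range_axis(p),
            axis1 = (seq_len(ncol(A)) - 1) / p$prf,
            params = p, label = pulses$label)
}

#' STFT configuration
#'
#' Window length, overlap and taper of the short-time Fourier transform used
#' for the time-Doppler map. Defaults are a 128-point window with 110 points
#' of overlap (hop 18).
#'
#' @param window_length Window length in slow-time samples.
#' @param overlap Overlap in samples; `0 <= overlap < window_length`.
#' @param window_shape `"hamming"` (default) or `"rect"`.
#' @return An object of class `stft_config`.
#' @export
stft_config <- function(window_length = 128, overlap = 110,
                        window_shape = c("hamming", "rect")) {
  window_shape <- match.arg(window_shape)
  window_length <- as.integer(window_length)
  overlap <- as.integer(overlap)
  if (window_length < 2) stop("`window_length` must be >= 2")
  if (overlap < 0 || overlap >= window_length)
    stop("need 0 <= overlap < window_length")
  structure(list(window_length = window_length, overlap = overlap,
                 window_shape = window_shape),
            class = "stft_config")
}

# zero-centred frequency ordering for an n-point FFT
.fftshift_index <- function(n) c((floor(n / 2) + 1):n, 1:floor(n / 2))
.fftshift_freqs <- function(n, fs) (seq_len(n) - 1 - floor(n / 2)) * fs / n

#' Time-Doppler map via the short-time Fourier transform
#'
#' Coherently sums the analytic signal across range bins into a single
#' complex slow-time series, then computes its magnitude STFT (default
#' 128-point window, 110-point overlap, Hamming taper). The frequency axis
#' is zero-centred and spans +/- prf/2.
#'
#' @param pulses A [pulse_matrix]; apply [mti_filter()] first so stationary
#'   clutter does not dominate the DC column.
#' @param cfg An [stft_config].
#' @return A [radar_map] of kind `time_doppler` (Doppler Hz x time s).
#' @export
time_doppler <- function(pulses, cfg = stft_config()) {
  stopifnot(inherits(pulses, "pulse_matrix"), inherits(cfg, "stft_config"))
  A <- if (is.complex(pulses$samples)) pulses$samples
       else .analytic_signal(pulses$samples)
  s <- colSums(A)
  np <- length(s)
  wl <- cfg$window_length
  if (np < wl)
    stop("signal has ", np, " pulses, shorter than the ", wl, "-point window")
  hop <- wl - cfg$overlap
  nf <- (np - wl) %/% hop + 1L
  win <- if (cfg$window_shape == "hamming") as.numeric(signal::hamming(wl))
         else rep(1, wl)
  starts <- (seq_len(nf) - 1L) * hop
  segs <- vapply(starts, function(s0) s[(s0 + 1):(s0 + wl)] * win,
                 complex(wl))
  S <- Mod(stats::mvfft(segs))
  p <- pulses$params
  sh <- .fftshift_index(wl)
  radar_map(S[sh, , drop = FALSE], "time_doppler",
            axis0 = .fftshift_freqs(wl, p$prf),
            axis1 = (starts + (wl - 1) / 2) / p$prf,
            params = p, label = pulses$label)
}

#' Range-Doppler map via the slow-time FFT
#'
#' Magnitude FFT along slow time independently per range bin of the analytic
#' signal (real input is converted first). The Doppler axis is zero-centred;
#' the FFT length is zero-padded to the next 5-smooth integer, which
#' interpolates the Doppler grid without altering peak locations.
#'
#' @param x A [pulse_matrix] (real or analytic) or a `range_time`
#'   [radar_map] (in which case the FFT is taken over its envelope values).
#' @return A [radar_map] of kind `range_doppler` (range m x Doppler Hz).
#' @export
range_doppler <- function(x) {
  if (inherits(x, "radar_map")) {
    if (x$kind != "range_time")
      stop("range_doppler expects a range_time map or a pulse_matrix")
    A <- x$values
    p <- x$params
    label <- x$label
  } else if (inherits(x, "pulse_matrix")) {
    A <- if (is.complex(x$samples)) x$samples else .analytic_signal(x$samples)
    p <- x$params
    label <- x$label
  } else stop("range_doppler expects a range_time map or a pulse_matrix")
  if (ncol(A) < 2) stop("need at least 2 slow-time samples")
  n <- ncol(A)
  nfft <- next_fast_len(n)
  Ap <- if (nfft > n) cbind(A, matrix(0, nrow(A), nfft - n)) else A
  Fm <- Mod(t(stats::mvfft(t(Ap))))
  sh <- .fftshift_index(nfft)
  radar_map(Fm[, sh, drop = FALSE], "range_doppler",
            axis0 = range_axis(p),
            axis1 = .fftshift_freqs(nfft, p$prf),
            params = p, label = label)
}

#' Radar image (classifier input)
#'
#' A fixed-size single-channel image with pixel values in \[0, 1\], obtained
#' from a [radar_map] by log compression and bilinear resampling.
#'
#' @param pixels Numeric `size x size` matrix in \[0, 1\].
#' @param kind Map kind the image derives from.
#' @param label Optional class id.
#' @return An object of class `radar_image`.
#' @export
radar_image <- function(pixels, kind, label = NULL) {
  stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels))
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("radar_image pixels must lie in [0, 1]")
  structure(list(pixels = pixels, kind = kind, label = label),
            class = "radar_image")
}

#' Convert a radar map to a normalized classifier image
#'
#' Log-compresses the magnitudes (20 log10 relative to the map maximum,
#' floored at -60 dB), min-max normalizes to \[0, 1\] and bilinearly
#' resamples to `size x size`. The dB step makes the image invariant to any
#' positive rescaling of the input map. An all-zero (or constant) map yields
#' an all-zero image rather than an error.
#'
#' @param map A [radar_map].
#' @param size Output side length in pixels (default 80).
#' @return A [radar_image]; kind and label are propagated.
#' @export
to_image <- function(map, size = 80) {
  stopifnot(inherits(map, "radar_map"))
  v <- map$values
  if (length(v) == 0) stop("empty map")
  mx <- max(v)
  if (mx <= 0 || min(v) == mx) {
    px <- matrix(0, size, size)
    return(radar_image(px, map$kind, map$label))
  }
  db <- 20 * log10(pmax(v / mx, 1e-300))
  db <- pmax(db, -60)
  rng <- range(db)
  px <- if (diff(rng) == 0) matrix(0, nrow(db), ncol(db))
        else (db - rng[1]) / diff(rng)
  if (nrow(px) != size || ncol(px) != size) {
    px <- EBImage::resize(px, w = size, h = size, filter = "bilinear")
    px <- matrix(pmin(pmax(as.numeric(px), 0), 1), size, size)
  }
  radar_image(px, map$kind, map$label)
}

#' @export
print.radar_image <- function(x, ...) {
  cat(sprintf("<radar_image:%s> %d x %d%s\n", x$kind, nrow(x$pixels),
              ncol(x$pixels),
              if (is.null(x$label)) "" else paste0(", class ", x$label)))
  invisible(x)
}

#' Full three-map preprocessing of a recording
#'
#' Applies the canonical chain MTI -> analytic signal -> the three maps ->
#' normalized images: `range_time` (Hilbert envelope), `time_doppler`
#' (STFT of the range-summed analytic signal) and `range_doppler`
#' (slow-time FFT per range bin).
#'
#' @param pulses A raw [pulse_matrix].
#' @param cfg An [stft_config] for the time-Doppler map.
#' @param size Image side length (default 80).
#' @return Named list of three [radar_image]s
#'   (`range_time`, `time_doppler`, `range_doppler`).
#' @export
radar_images <- function(pulses, cfg = stft_config(), size = 80) {
  f <- mti_filter(pulses)
  a <- analytic_signal(f)
  list(range_time = to_image(analytic_envelope(a), size),
       time_doppler = to_image(time_doppler(a, cfg), size),
       range_doppler = to_image(range_doppler(a), size))
}
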