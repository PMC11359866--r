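#' Action classes of the fall-recognition task
#'
#' Ten action types: five daily activities and five fall variants. Class ids
#' are integers 0..9:
#'
#' | id | behaviour |
#' |----|-----------|
#' | 0 | Sitting down |
#' | 1 | Falling while sitting/standing |
#' | 2 | Bending to pick something up |
#' | 3 | Falling sideways to the radar |
#' | 4 | Standing up |
#' | 5 | Falling backwards to the radar |
#' | 6 | Walking towards the radar |
#' | 7 | Walking away from the radar |
#' | 8 | Falling towards the radar at 45 degrees to the right |
#' | 9 | Falling towards the radar at 45 degrees to the left |
#'
#' @return Named character vector of length 10 (names are the class ids).
#' @export
action_classes <- function() {
  c(`0` = "Sitting down",
    `1` = "Falling while sitting/standing",
    `2` = "Bending to pick something up",
    `3` = "Falling sideways to the radar",
    `4` = "Standing up",
    `5` = "Falling backwards to the radar",
    `6` = "Walking towards the radar",
    `7` = "Walking away from the radar",
    `8` = "Falling towards the radar at 45 deg right",
    `9` = "Falling towards the radar at 45 deg left")
}

.fall_classes <- c(1L, 3L, 5L, 8L, 9L)
.walk_classes <- c(6L, 7L)
.transient_classes <- c(0L, 2L, 4L)

#' Construct a motion profile
#'
#' A motion profile describes a single human-scale scatterer: its radial
#' range trajectory `R(t)` (metres, as a vectorized function of slow time in
#' seconds) and a dimensionless radar-cross-section envelope `a(t)`. Use
#' [make_profile()] for the seeded per-class generators; this raw constructor
#' is for custom trajectories (e.g. constant-velocity calibration targets).
#'
#' @param range_trajectory Function of a time vector returning ranges (m).
#' @param rcs_envelope Function of a time vector returning amplitudes;
#'   defaults to unit amplitude.
#' @param class_id Optional class label 0..9 (NA for unlabeled).
#' @return An object of class `motion_profile`.
#' @examples
#' # 1 m/s constant-velocity target starting at 1.2 m
#' pr <- motion_profile(function(t) 1.2 + 1.0 * t)
#' @export
motion_profile <- function(range_trajectory,
                           rcs_envelope = function(t) rep(1, length(t)),
                           class_id = NA_integer_) {
  stopifnot(is.function(range_trajectory), is.function(rcs_envelope))
  structure(list(class_id = class_id,
                 range_trajectory = range_trajectory,
                 rcs_envelope = rcs_envelope),
            class = "motion_profile")
}

# raised-cosine displacement segment: 0 before t0, d after t0+dur, smooth
# in between; peak velocity d*pi/(2*dur) at the segment midpoint.
.seg_smooth <- function(t, t0, dur, d) {
  s <- pmin(pmax((t - t0) / dur, 0), 1)
  d * (1 - cos(pi * s)) / 2
}

# out-and-back displacement (bending): returns to the start, peak |v| = d*pi/dur
.seg_outback <- function(t, t0, dur, d) {
  s <- pmin(pmax((t - t0) / dur, 0), 1)
  d * sin(pi * s)
}

# decaying post-impact oscillation (body settling after a fall)
.seg_settle <- function(t, t_imp, amp, freq, tau = 0.5) {
  u <- pmax(t - t_imp, 0)
  ifelse(t > t_imp, amp * exp(-u / tau) * sin(2 * pi * freq * u), 0)
}

#' Seeded per-class motion profile generator
#'
#' Draws a randomized trajectory from the kinematic family of one of the ten
#' action classes (see [action_classes()]). The families are piecewise
#' smooth constant-acceleration-style segments:
#'
#' * falls (classes 1, 3, 5, 8, 9): a short raised-cosine displacement burst
#'   of 0.7-1.2 m with peak radial speed in the 1.5-3 m/s band, followed by a
#'   small decaying settle oscillation (the subject lies still afterwards).
#'   Backwards falls (5) move away from the radar, the 45-degree falls (8, 9)
#'   move towards it; sideways falls (3) and sit/stand falls (1) have random
#'   radial sign, and class 1 is preceded by a slow sit/stand transient.
#' * walking (6 towards, 7 away): strictly monotone range with a sustained
#'   speed near 0.8 m/s (the span the default 5 m scene allows over 5 s)
#'   modulated by a 10-15 % gait oscillation peaking near 1 m/s.
#' * sit/stand/bend (0, 4, 2): low-speed transients (< 0.8 m/s peak) of
#'   0.15-0.35 m; bending returns to the starting range.
#'
#' All timings, amplitudes and start ranges are drawn from seeded uniform
#' distributions, so equal seeds give bit-identical profiles.
#'
#' @param class_id Integer 0..9.
#' @param params A [radar_params] object; trajectories are kept inside
#'   `(0, max_range)` and below the unambiguous radial speed.
#' @param rng_seed Integer seed.
#' @return A [motion_profile] with the drawn trajectory.
#' @examples
#' p <- radar_params()
#' pr <- make_profile(7, p, rng_seed = 1)  # walking away: R(t) increasing
#' t <- slow_time_axis(p)
#' all(diff(pr$range_trajectory(t)) > 0)
#' @export
make_profile <- function(class_id, params, rng_seed = 0) {
  if (!is.numeric(class_id) || length(class_id) != 1 ||
      is.na(class_id) || class_id != round(class_id) ||
      class_id < 0 || class_id > 9)
    stop("unknown class_id: ", format(class_id), " (must be an integer 0..9)")
  class_id <- as.integer(class_id)
  stopifnot(inherits(params, "radar_params"))
  dur_rec <- params$duration

  pr <- with_seed(rng_seed, {
    if (class_id %in% .transient_classes) {
      R0 <- runif(1, 1.8, 3.2)
      t0 <- runif(1, 0.15, 0.5) * dur_rec
      if (class_id == 2L) {           # bend: out-and-back
        d <- sample(c(-1, 1), 1) * runif(1, 0.15, 0.30)
        dur <- runif(1, 1.2, 2.0)
        rfun <- function(t) R0 + .seg_outback(t, t0, dur, d)
      } else {                        # sit (away) / stand (toward)
        d <- if (class_id == 0L) runif(1, 0.15, 0.35) else -runif(1, 0.15, 0.35)
        dur <- runif(1, 1.0, 1.6)
        rfun <- function(t) R0 + .seg_smooth(t, t0, dur, d)
      }
      afun <- local({a0 <- runif(1, 0.8, 1.2); function(t) rep(a0, length(t))})
    } else if (class_id %in% .walk_classes) {
      fg <- runif(1, 1.4, 2.0)        # gait cadence, Hz
      ph <- runif(1, 0, 2 * pi)
      depth <- runif(1, 0.10, 0.15)
      sgn <- if (class_id == 6L) -1 else 1
      R0 <- if (class_id == 6L) runif(1, 4.1, 4.6) else runif(1, 0.4, 0.8)
      # cap the walking speed so the subject stays inside the scene
      margin <- runif(1, 0.35, 0.5)
      span <- if (class_id == 6L) R0 - margin else params$max_range - margin - R0
      if (span <= 0) stop("scene too small for a walking trajectory")
      vbar <- min(runif(1, 0.72, 0.85), span / dur_rec)
      # integral of vbar*(1 + depth*sin(2*pi*fg*t + ph)); v(t) > 0 always
      disp <- function(t)
        vbar * (t - depth / (2 * pi * fg) * (cos(2 * pi * fg * t + ph) - cos(ph)))
      rfun <- function(t) R0 + sgn * disp(t)
      afun <- local({
        a0 <- runif(1, 0.8, 1.2)
        function(t) a0 * (1 + 0.1 * sin(2 * pi * fg * t + ph))
      })
    } else {                          # falls
      vpk <- switch(as.character(class_id),
                    `1` = runif(1, 1.7, 2.8),
                    `3` = runif(1, 1.6, 2.2),
                    `5` = runif(1, 1.8, 2.8),
                    runif(1, 1.7, 2.5))          # 8, 9
      d <- if (class_id == 3L) runif(1, 0.7, 0.9) else runif(1, 0.8, 1.2)
      dur <- pi * d / (2 * vpk)
      sgn <- switch(as.character(class_id),
                    `5` = 1, `8` = -1, `9` = -1, sample(c(-1, 1), 1))
      R0 <- if (sgn < 0) runif(1, 2.2, 3.4) else runif(1, 2.0, 3.2)
      t0 <- runif(1, 0.2, 0.55) * dur_rec
      # subtle post-impact settle; mirrored 45-degree falls differ only in it
      fs <- switch(as.character(class_id),
                   `8` = runif(1, 0.8, 1.1), `9` = runif(1, 1.3, 1.7),
                   runif(1, 0.9, 1.5))
      pre_d <- if (class_id == 1L) sgn * runif(1, 0.10, 0.20) else 0
      pre_dur <- runif(1, 0.6, 1.0)
      a0 <- runif(1, 0.8, 1.2)
      rfun <- function(t)
        R0 + pre_d * .seg_smooth(t, t0 - pre_dur, pre_dur, 1) +
          sgn * d * (.seg_smooth(t, t0, dur, 1)) +
          .seg_settle(t, t0 + dur, 0.03, fs)
      afun <- function(t) a0 * (1 + 0.3 * .seg_smooth(t, t0, dur, 1))
    }
    motion_profile(rfun, afun, class_id)
  })

  # contract checks against the acquisition geometry
  tg <- seq(0, dur_rec, length.out = max(64L, n_pulses(params)))
  R <- pr$range_trajectory(tg)
  if (any(!is.finite(R)) || any(R <= 0) || any(R >= params$max_range))
    stop("trajectory for class ", class_id, " leaves (0, max_range)")
  v <- diff(R) / diff(tg)
  if (max(abs(v)) >= max_unambiguous_speed(params))
    stop("trajectory radial speed exceeds the unambiguous limit")
  pr
}

#' Raw pulse matrix
#'
#' A real-valued fast-time x slow-time grid of radar echo amplitudes:
#' axis 0 (rows) is fast time / range, axis 1 (columns) is slow time / pulse
#' index. Constructed by [synthesize_pulses()] or [mti_filter()].
#'
#' @param samples Numeric (or complex, for analytic signals) matrix with
#'   `params$n_range_bins` rows.
#' @param params A [radar_params] object.
#' @param label Optional class id 0..9.
#' @return An object of class `pulse_matrix`.
#' @export
pulse_matrix <- function(samples, params, label = NULL) {
  stopifnot(is.matrix(samples), inherits(params, "radar_params"))
  if (nrow(samples) != params$n_range_bins)
    stop("samples must have n_range_bins = ", params$n_range_bins, " rows")
  if (!all(is.finite(if (is.complex(samples)) Mod(samples) else samples)))
    stop("pulse matrix contains non-finite values")
  if (!is.null(label)) label <- as.integer(label)
  structure(list(samples = samples, params = params, label = label),
            class = "pulse_matrix")
}

#' @export
print.pulse_matrix <- function(x, ...) {
  cat(sprintf("<pulse_matrix> %d range bins x %d pulses%s%s\n",
              nrow(x$samples), ncol(x$samples),
              if (is.complex(x$samples)) " (analytic)" else "",
              if (is.null(x$label)) "" else paste0(", class ", x$label)))
  invisible(x)
}

#' Synthesize UWB radar echoes for a motion profile
#'
#' Point-scatterer echo model: for each pulse at slow time t the scatterer at
#' range R(t) contributes a Gaussian fast-time envelope of width c/(2B)
#' (the radar's physical range resolution) centred on R(t), scaled by the
#' RCS envelope and modulated by the two-way carrier phase term
#' `cos(4 pi fc R(t) / c)` so that the Doppler shift 2 v fc / c appears after
#' analytic-signal conversion and slow-time spectral analysis. A time-constant
#' clutter column (a static scatterer at `clutter_range`) and i.i.d. Gaussian
#' noise are added. Deterministic given `rng_seed`.
#'
#' @param profile A [motion_profile].
#' @param params A [radar_params].
#' @param clutter_amp Amplitude of the static clutter scatterer (>= 0).
#' @param noise_sigma Standard deviation of the additive Gaussian noise (>= 0).
#' @param rng_seed Integer seed for the noise draw.
#' @param clutter_range Range of the static clutter scatterer, metres.
#' @return A [pulse_matrix] labeled with the profile's class id.
#' @examples
#' p <- radar_params(duration = 1)
#' pm <- synthesize_pulses(motion_profile(function(t) rep(2, length(t))), p,
#'                         clutter_amp = 0, noise_sigma = 0)
#' @export
synthesize_pulses <- function(profile, params, clutter_amp = 1,
                              noise_sigma = 0.05, rng_seed = 0,
                              clutter_range = 1.2) {
  stopifnot(inherits(profile, "motion_profile"), inherits(params, "radar_params"))
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  if (clutter_amp < 0) stop("`clutter_amp` must be >= 0")
  t <- slow_time_axis(params)
  R <- profile$range_trajectory(t)
  if (any(!is.finite(R)) || any(R <= 0) || any(R >= params$max_range))
    stop("trajectory leaves [0, max_range]: range-domain error")
  a <- profile$rcs_envelope(t)
  rb <- range_axis(params)
  sigma_r <- .c0 / (2 * params$bandwidth)       # physical range resolution
  np <- n_pulses(params)
  nb <- params$n_range_bins
  # [nb x np] Gaussian envelopes centred on R(t)
  E <- exp(-0.5 * (outer(rb, R, "-") / sigma_r)^2)
  mod <- a * cos(4 * pi * params$fc * R / .c0)  # two-way carrier phase
  X <- E * rep(mod, each = nb)
  if (clutter_amp > 0)
    X <- X + clutter_amp * exp(-0.5 * ((rb - clutter_range) / sigma_r)^2)
  if (noise_sigma > 0)
    X <- X + with_seed(rng_seed,
                       matrix(rnorm(nb * np, 0, noise_sigma), nb, np))
  label <- if (is.na(profile$class_id)) NULL else profile$class_id
  pulse_matrix(X, params, label)
}

#' Generate a balanced labeled echo dataset
#'
#' Draws `per_class` recordings for each of the 10 action classes
#' (10 * per_class items in total), each with its own profile and noise
#' seeds derived reproducibly from `rng_seed`.
#'
#' @param params A [radar_params].
#' @param per_class Recordings per class (>= 1).
#' @param rng_seed Master seed; equal seeds give bit-identical datasets.
#' @param clutter_amp,noise_sigma,clutter_range Passed to
#'   [synthesize_pulses()].
#' @return An object of class `labeled_echo_set`: a list with `items` (list
#'   of [pulse_matrix]), `labels`, `seed`, `class_counts` and `params`.
#' @export
generate_dataset <- function(params, per_class, rng_seed = 0,
                             clutter_amp = 1, noise_sigma = 0.05,
                             clutter_range = 1.2) {
  stopifnot(inherits(params, "radar_params"))
  if (per_class < 1) stop("`per_class` must be >= 1")
  per_class <- as.integer(per_class)
  n <- 10L * per_class
  seeds <- with_seed(rng_seed, matrix(sample.int(.Machine$integer.max, 2L * n),
                                      nrow = 2L))
  items <- vector("list", n)
  labels <- integer(n)
  k <- 0L
  for (cid in 0:9) {
    for (r in seq_len(per_class)) {
      k <- k + 1L
      pr <- make_profile(cid, params, rng_seed = seeds[1L, k])
      items[[k]] <- synthesize_pulses(pr, params, clutter_amp = clutter_amp,
                                      noise_sigma = noise_sigma,
                                      rng_seed = seeds[2L, k],
                                      clutter_range = clutter_range)
      labels[k] <- cid
    }
  }
  counts <- as.integer(table(factor(labels, levels = 0:9)))
  names(counts) <- as.character(0:9)
  structure(list(items = items, labels = labels, seed = rng_seed,
                 class_counts = counts, params = params),
            class = "labeled_echo_set")
}

#' @export
print.labeled_echo_set <- function(x, ...) {
  cat(sprintf("<labeled_echo_set> %d recordings (seed %s)\n",
              length(x$items), format(x$seed)))
  print(x$class_counts)
  invisible(x)
}

#' Write / read a labeled echo set archive
#'
#' Serializes a [labeled_echo_set] to a single hierarchical archive (one
#' entry per recording plus label and parameter attributes) using R's native
#' serialization.
#'
#' @param set A `labeled_echo_set`.
#' @param path File path.
#' @return `write_echo_set` returns `path` invisibly; `read_echo_set`
#'   returns the restored `labeled_echo_set`.
#' @export
write_echo_set <- function(set, path) {
  stopifnot(inherits(set, "labeled_echo_set"))
  saveRDS(set, path)
  invisible(path)
}

#' @rdname write_echo_set
#' @export
read_echo_set <- function(path) {
  set <- readRDS(path)
  if (!inherits(set, "labeled_echo_set"))
    stop("file does not contain a labeled_echo_set")
  set
}
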