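#' Radar acquisition parameters
#'
#' Bundles the acquisition settings of a UWB impulse radar: pulse repetition
#' frequency (PRF, the slow-time sampling rate), carrier/centre frequency,
#' bandwidth, recording duration and the discretized range grid. Defaults
#' match a PulsOn-440-class sensor: PRF 240 Hz, centre frequency 4.3 GHz,
#' 1.7 GHz bandwidth (3.1-4.8 GHz band) and 5 s recordings.
#'
#' The simulator does not model the raw RF sampling rate; echoes live on an
#' equivalent decimated range grid (`n_range_bins` over `max_range`) whose
#' physical resolution is carried by the Gaussian pulse envelope of width
#' c/(2B) ~ 8.8 cm.
#'
#' @param prf Pulse repetition frequency in Hz. Must be positive.
#' @param fc Carrier (centre) frequency in Hz.
#' @param bandwidth Bandwidth in Hz; sets the range resolution c/(2B).
#' @param duration Recording length in seconds. `round(prf * duration)` must
#'   be at least 3 so the three-pulse canceller is applicable.
#' @param n_range_bins Number of range bins of the simulation grid.
#' @param max_range Maximum unambiguous range of the grid, metres.
#'
#' @return An object of class `radar_params`.
#' @examples
#' p <- radar_params()
#' n_pulses(p)          # 1200 pulses at 240 Hz x 5 s
#' range_resolution(p)  # grid spacing in metres
#' @export
radar_params <- function(prf = 240, fc = 4.3e9, bandwidth = 1.7e9,
                         duration = 5, n_range_bins = 256, max_range = 5) {
  stopifnot(is.numeric(prf), length(prf) == 1, is.finite(prf),
            is.numeric(fc), length(fc) == 1, is.finite(fc),
            is.numeric(bandwidth), length(bandwidth) == 1,
            is.numeric(duration), length(duration) == 1,
            is.numeric(n_range_bins), length(n_range_bins) == 1,
            is.numeric(max_range), length(max_range) == 1)
  if (prf <= 0) stop("`prf` must be positive")
  if (fc <= 0) stop("`fc` must be positive")
  if (bandwidth <= 0) stop("`bandwidth` must be positive")
  if (duration <= 0) stop("`duration` must be positive")
  np <- as.integer(round(prf * duration))
  if (np < 3)
    stop("round(prf * duration) = ", np,
         " pulses; at least 3 are needed for the three-pulse canceller")
  n_range_bins <- as.integer(n_range_bins)
  if (n_range_bins < 1) stop("`n_range_bins` must be >= 1")
  if (max_range <= 0) stop("`max_range` must be positive")
  structure(
    list(prf = prf, fc = fc, bandwidth = bandwidth, duration = duration,
         n_range_bins = n_range_bins, max_range = max_range),
    class = "radar_params")
}

#' @export
print.radar_params <- function(x, ...) {
  cat("<radar_params>\n")
  cat(sprintf("  prf: %g Hz   fc: %g GHz   bandwidth: %g GHz\n",
              x$prf, x$fc / 1e9, x$bandwidth / 1e9))
  cat(sprintf("  duration: %g s (%d pulses)   range: %d bins over %g m\n",
              x$duration, n_pulses(x), x$n_range_bins, x$max_range))
  cat(sprintf("  unambiguous Doppler: +/-%g Hz (+/-%.2f m/s radial)\n",
              x$prf / 2, max_unambiguous_speed(x)))
  invisible(x)
}

#' Derived radar quantities
#'
#' Helpers that recompute grid geometry and Doppler limits from a
#' [radar_params] object.
#'
#' @param params A [radar_params] object.
#' @return `n_pulses`: integer pulse count `round(prf * duration)`.
#'   `range_resolution`: grid spacing `max_range / n_range_bins` in metres.
#'   `range_axis`: bin-centre ranges in metres. `slow_time_axis`: pulse times
#'   in seconds. `max_unambiguous_speed`: the radial speed (m/s) mapping to
#'   the Doppler Nyquist limit prf/2.
#' @export
n_pulses <- function(params) as.integer(round(params$prf * params$duration))

#' @rdname n_pulses
#' @export
range_resolution <- function(params) params$max_range / params$n_range_bins

#' @rdname n_pulses
#' @export
range_axis <- function(params)
  (seq_len(params$n_range_bins) - 0.5) * range_resolution(params)

#' @rdname n_pulses
#' @export
slow_time_axis <- function(params) (seq_len(n_pulses(params)) - 1) / params$prf

#' @rdname n_pulses
#' @export
max_unambiguous_speed <- function(params) (params$prf / 2) * .c0 / (2 * params$fc)

#' Doppler shift of a moving scatterer
#'
#' The two-way Doppler shift `2 v fc / c` (Hz) of a scatterer with radial
#' velocity `v` (m/s, positive away from the radar) at carrier `fc`.
#'
#' @param v Radial velocity in m/s.
#' @param fc Carrier frequency in Hz.
#' @export
doppler_shift <- function(v, fc) 2 * v * fc / .c0
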