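#' Simulate a membrane-potential trace with stereotyped action potentials
#'
#' Each spike is a piecewise-linear waveform: a slow depolarizing foot
#' from baseline to the biophysical threshold (slope below any reasonable
#' dV/dt criterion), a fast upstroke from threshold to the peak
#' (`rise_slope`, above the criterion), a linear repolarization back to
#' threshold timed so the width at half-amplitude (midway between
#' threshold and peak) equals `half_width`, then a slow return to
#' baseline. This makes the downstream threshold, overshoot and
#' half-width estimators exact up to sampling.
#'
#' @param spike_times_ms spike onset times (start of the foot), ms; must
#'   be separated by more than one spike width.
#' @param duration_ms total trace duration, ms.
#' @param threshold biophysical AP threshold, mV (default -23.5).
#' @param peak spike peak (overshoot), mV (default 35.5).
#' @param half_width width at half-amplitude between threshold and peak,
#'   ms (default 19.1).
#' @param baseline resting potential, mV (default -70).
#' @param rise_slope upstroke slope, mV/ms (default 12; must exceed the
#'   detection slope criterion for threshold estimation to localize).
#' @param foot_slope sub-threshold foot slope, mV/ms (default 5).
#' @param noise_sd additive Gaussian noise, mV.
#' @param sample_interval_ms sampling interval, ms (default 0.5).
#' @param step optional data.frame (`start`, `end`, `current_pA`)
#'   annotating the injected current step; default one step spanning the
#'   whole trace at 30 pA.
#' @param cell_id identifier.
#' @param seed RNG seed; required only when `noise_sd > 0`.
#' @return A [voltage_trace].
#' @export
simulate_voltage_trace <- function(spike_times_ms, duration_ms,
                                   threshold = -23.5, peak = 35.5,
                                   half_width = 19.1, baseline = -70,
                                   rise_slope = 12, foot_slope = 5,
                                   noise_sd = 0, sample_interval_ms = 0.5,
                                   step = NULL, cell_id = "cell0001",
                                   seed = NULL) {
  if (peak <= threshold) stopf("'peak' must exceed 'threshold'")
  if (threshold <= baseline) stopf("'threshold' must exceed 'baseline'")
  check_number(half_width, "half_width", lower = .Machine$double.eps)
  if (noise_sd > 0) seed <- check_seed(seed)
  if (!is.null(seed)) set.seed(seed)

  foot <- (threshold - baseline) / foot_slope        # ms, baseline -> threshold
  rise <- (peak - threshold) / rise_slope            # ms, threshold -> peak
  fall <- 2 * half_width - rise                      # ms, peak -> threshold
  if (fall <= 0)
    stopf("'half_width' too small for the given rise_slope: the upstroke alone is wider")
  width <- 2 * foot + rise + fall                    # full spike footprint

  st <- sort(spike_times_ms)
  if (length(st) && (min(st) < 0 || max(st) + width > duration_ms))
    stopf("spike at %g ms does not fit in a %g ms trace",
          if (min(st) < 0) min(st) else max(st), duration_ms)
  if (length(st) > 1L && any(diff(st) <= width))
    stopf("spikes must be separated by more than one spike width (%.1f ms)",
          width)

  t <- seq(0, duration_ms - sample_interval_ms / 2,
           by = sample_interval_ms)
  vm <- rep(baseline, length(t))
  for (s in st) {
    knots_t <- s + c(0, foot, foot + rise, foot + rise + fall,
                     foot + rise + fall + foot)
    knots_v <- c(baseline, threshold, peak, threshold, baseline)
    inside <- t >= knots_t[1L] & t <= knots_t[5L]
    vm[inside] <- stats::approx(knots_t, knots_v, xout = t[inside])$y
  }
  if (noise_sd > 0) vm <- vm + stats::rnorm(length(t), 0, noise_sd)

  if (is.null(step))
    step <- data.frame(start = 0, end = duration_ms, current_pA = 30)
  voltage_trace(cell_id, t, vm, step)
}
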