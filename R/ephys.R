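# Mean Cm over a half-open window [a, b), clipped so it never crosses a
# pulse; errors (naming the window) if no samples fall inside.
window_mean <- function(rec, a, b, what = "window") {
  sel <- rec$time_ms >= a & rec$time_ms < b
  if (!any(sel))
    stopf("cell '%s': no Cm samples in %s [%g, %g) ms", rec$cell_id,
          what, a, b)
  mean(rec$cm_fF[sel])
}

check_protocol_match <- function(rec, protocol) {
  if (nrow(rec$pulses) != nrow(protocol$pulses))
    stopf("cell '%s': recording has %d pulses but protocol '%s' expects %d",
          rec$cell_id, nrow(rec$pulses), protocol$name,
          nrow(protocol$pulses))
}

# Landmark window after pulse k: the measurement window immediately
# following the pulse, truncated at the next pulse onset.
post_pulse_mean <- function(rec, protocol, k, what) {
  p <- rec$pulses
  a <- p$start[k] + p$duration[k]
  b <- a + protocol$window_ms
  if (k < nrow(p)) b <- min(b, p$start[k + 1L])
  window_mean(rec, a, b, what)
}

#' Capacitance landmarks of the pool-dissection train
#'
#' The reference is the average Cm over the 300-ms window before the first
#' pulse. Each landmark is the average Cm over the 300-ms window after the
#' designated pulse, minus the reference: after pulse 6 (end of the short
#' 10-ms pulses, the immediately releasable pool), after pulse 10 (end of
#' the long 100-ms pulses, the readily releasable pool), and over the
#' 300-ms window ending `total_window_s` after first-pulse onset (total
#' release). Windows never cross a pulse; Cm during depolarizations is
#' missing data, never interpolated.
#'
#' @param rec a [capacitance_recording].
#' @param protocol a [pulse_protocol] (default `pool10`).
#' @param total_window_s end of the total-release window, seconds after
#'   first-pulse onset (default 7).
#' @return list with `ref` (absolute fF), `delta_pulse6`, `delta_pulse10`
#'   and `delta_total` (fF above reference).
#' @export
landmark_deltas <- function(rec, protocol = pulse_protocol("pool10"),
                            total_window_s = 7) {
  stopifnot(inherits(rec, "capacitance_recording"))
  check_protocol_match(rec, protocol)
  np <- nrow(rec$pulses)
  n_short <- sum(rec$pulses$duration < 100)
  ref <- window_mean(rec, rec$pulses$start[1L] - protocol$window_ms,
                     rec$pulses$start[1L], "pre-train reference window")
  d6 <- post_pulse_mean(rec, protocol, n_short,
                        sprintf("window after pulse %d", n_short)) - ref
  d10 <- post_pulse_mean(rec, protocol, np,
                         sprintf("window after pulse %d", np)) - ref
  t_end <- rec$pulses$start[1L] + total_window_s * 1000
  dtot <- window_mean(rec, t_end - protocol$window_ms, t_end,
                      "total-release window") - ref
  list(ref = ref, delta_pulse6 = d6, delta_pulse10 = d10,
       delta_total = dtot)
}

#' Decompose capacitance landmarks into vesicle pools
#'
#' The immediately releasable pool (IRP) is the Cm gained over the six
#' short pulses; the readily releasable pool (RRP) is the Cm at the end of
#' the full train, either as the cumulative gain (`"cumulative"`) or with
#' the IRP subtracted (`"incremental"`, the default); total release is the
#' gain at the end of the total-release window. All three are also
#' normalized to the initial capacitance (fF/pF), the conventional
#' cell-size correction.
#'
#' @param landmarks output of [landmark_deltas()] (or a numeric vector
#'   `c(delta_pulse6, delta_pulse10, delta_total)`).
#' @param cm0 initial capacitance, pF.
#' @param convention `"incremental"` (RRP beyond the IRP, default) or
#'   `"cumulative"`.
#' @param cell_id identifier carried into the output.
#' @param qc_class optional QC class from [qc_classify()].
#' @return An object of class `pool_estimate`.
#' @export
pool_decomposition <- function(landmarks, cm0,
                               convention = c("incremental", "cumulative"),
                               cell_id = NA_character_,
                               qc_class = NA_character_) {
  convention <- match.arg(convention)
  check_number(cm0, "cm0", lower = .Machine$double.eps)
  if (is.numeric(landmarks) && length(landmarks) == 3L)
    landmarks <- list(delta_pulse6 = landmarks[1L],
                      delta_pulse10 = landmarks[2L],
                      delta_total = landmarks[3L])
  irp <- landmarks$delta_pulse6
  rrp <- if (convention == "cumulative") landmarks$delta_pulse10
         else landmarks$delta_pulse10 - irp
  total <- landmarks$delta_total
  structure(list(cell_id = cell_id, cm0_pF = cm0,
                 irp_fF = irp, rrp_fF = rrp, total_fF = total,
                 irp_fF_per_pF = irp / cm0, rrp_fF_per_pF = rrp / cm0,
                 total_fF_per_pF = total / cm0,
                 rrp_convention = convention, qc_class = qc_class),
            class = "pool_estimate")
}

#' @export
print.pool_estimate <- function(x, ...) {
  cat(sprintf("Pool estimate%s (cm0 = %.1f pF, RRP convention: %s%s)\n",
              if (is.na(x$cell_id)) "" else paste0(" for ", x$cell_id),
              x$cm0_pF, x$rrp_convention,
              if (is.na(x$qc_class)) "" else paste0(", QC: ", x$qc_class)))
  cat(sprintf("  IRP   %7.2f fF  (%6.3f fF/pF)\n", x$irp_fF,
              x$irp_fF_per_pF))
  cat(sprintf("  RRP   %7.2f fF  (%6.3f fF/pF)\n", x$rrp_fF,
              x$rrp_fF_per_pF))
  cat(sprintf("  total %7.2f fF  (%6.3f fF/pF)\n", x$total_fF,
              x$total_fF_per_pF))
  invisible(x)
}

#' Quality-control taxonomy for capacitance recordings
#'
#' Operationalizes the recording-inclusion taxonomy: *no exocytosis* — no
#' capacitance change (total gain within `k` baseline SDs of zero)
#' despite robust inward currents on at least half the pulses;
#' *spontaneous exocytosis* — Cm fluctuates well above the noise floor
#' but the fluctuations do not correlate with the pulses; *provoked
#' exocytosis* — a clear Cm increase locked to the pulses; *unstable* —
#' access-resistance/conductance instability flagged by the caller.
#'
#' The pulse-locking statistic is the rank-biserial correlation between
#' Cm increments across pulses and Cm increments across equal-length
#' pulse-free gaps tiled into the post-train window (2 x AUC - 1, where
#' AUC is the probability that a pulse-straddling increment exceeds a
#' pulse-free one).
#'
#' @param rec a [capacitance_recording] with per-pulse peak currents.
#' @param protocol a [pulse_protocol].
#' @param k noise-floor multiplier on the baseline-window SD (default 3).
#' @param current_threshold_pA minimum |peak inward current| counted as a
#'   robust current (default 20).
#' @param corr_threshold minimum pulse-locking rank correlation for
#'   provoked exocytosis (default 0.4, about two null SDs of the
#'   statistic for the 10-pulse train).
#' @param unstable caller-set instability flag (default `FALSE`).
#' @param total_window_s as in [landmark_deltas()].
#' @return one of `"provoked"`, `"no_exocytosis"`, `"spontaneous"`,
#'   `"unstable"`.
#' @export
qc_classify <- function(rec, protocol = pulse_protocol("pool10"), k = 3,
                        current_threshold_pA = 20, corr_threshold = 0.4,
                        unstable = FALSE, total_window_s = 7) {
  stopifnot(inherits(rec, "capacitance_recording"))
  if (unstable) return("unstable")
  if (!"peak_pA" %in% names(rec$pulses) || anyNA(rec$pulses$peak_pA))
    stopf("cell '%s': per-pulse peak currents are required for QC",
          rec$cell_id)
  check_protocol_match(rec, protocol)
  p <- rec$pulses
  np <- nrow(p)
  w <- protocol$window_ms

  base_sel <- rec$time_ms >= p$start[1L] - w & rec$time_ms < p$start[1L]
  if (sum(base_sel) < 2L)
    stopf("cell '%s': too few baseline samples for a noise floor",
          rec$cell_id)
  floor_fF <- k * stats::sd(rec$cm_fF[base_sel])
  robust <- mean(abs(p$peak_pA) >= current_threshold_pA) >= 0.5

  total <- window_mean(rec, p$start[np] + p$duration[np],
                       p$start[np] + p$duration[np] + w,
                       "post-train window") -
           mean(rec$cm_fF[base_sel])
  # overall Cm variability separates a genuinely flat recording from one
  # that wanders back near its starting level
  wander <- stats::sd(rec$cm_fF)
  if (abs(total) <= floor_fF && wander <= floor_fF && robust)
    return("no_exocytosis")

  # window-to-window Cm increments: across pulses (indicator 1) and across
  # equal gaps tiled into the post-train window (indicator 0)
  pre_means <- vapply(seq_len(np), function(i)
    window_mean(rec, p$start[i] - w, p$start[i],
                sprintf("window before pulse %d", i)), numeric(1))
  post_means <- vapply(seq_len(np), function(i)
    post_pulse_mean(rec, protocol, i,
                    sprintf("window after pulse %d", i)), numeric(1))
  pulse_inc <- post_means - pre_means

  t0 <- p$start[np] + p$duration[np]
  t_max <- max(rec$time_ms)
  n_ctrl <- max(2L, floor((t_max - t0) / w) - 1L)
  ctrl_inc <- vapply(seq_len(n_ctrl), function(i) {
    window_mean(rec, t0 + i * w, t0 + (i + 1) * w,
                "post-train control window") -
      window_mean(rec, t0 + (i - 1) * w, t0 + i * w,
                  "post-train control window")
  }, numeric(1))

  # rank-biserial correlation between increments and the pulse indicator
  # (2*AUC - 1): robust to the skewed increment sizes of depletion-type
  # responses, where one long pulse can dominate the released Cm
  cmp <- outer(pulse_inc, ctrl_inc, ">")
  tie <- outer(pulse_inc, ctrl_inc, "==")
  lock <- 2 * (mean(cmp) + 0.5 * mean(tie)) - 1

  if (abs(total) > floor_fF && lock >= corr_threshold &&
      mean(pulse_inc) > 0)
    return("provoked")
  if (wander > floor_fF) return("spontaneous")
  "no_exocytosis"
}

#' Capacitance change across the potentiation train
#'
#' The Cm gained between the 300-ms window before the first pulse and the
#' 300-ms window after the last pulse of the 15 x 500-ms train, in fF and
#' normalized to initial capacitance (fF/pF).
#'
#' @param rec a [capacitance_recording].
#' @param protocol a [pulse_protocol] (default `potentiation15`).
#' @return list with `delta_fF` and `delta_fF_per_pF`.
#' @export
potentiation_delta <- function(rec,
                               protocol = pulse_protocol("potentiation15")) {
  stopifnot(inherits(rec, "capacitance_recording"))
  check_protocol_match(rec, protocol)
  p <- rec$pulses
  np <- nrow(p)
  ref <- window_mean(rec, p$start[1L] - protocol$window_ms, p$start[1L],
                     "pre-train reference window")
  d <- post_pulse_mean(rec, protocol, np,
                       sprintf("window after pulse %d", np)) - ref
  list(delta_fF = d, delta_fF_per_pF = d / rec$cm0_pF)
}

#' Detect action potentials in a current step and summarize their shape
#'
#' Spikes are upward crossings of a fixed detection level within the
#' annotated step, with a refractory lockout. The detection level is
#' deliberately distinct from the biophysical AP threshold, which is
#' estimated per spike as the membrane potential where dV/dt first
#' exceeds a slope criterion on the upstroke. Overshoot is the spike
#' peak; half-width is the duration at half-amplitude between threshold
#' and peak (sub-sample, by linear interpolation).
#'
#' @param vt a [voltage_trace].
#' @param step index into `vt$steps` (default 1).
#' @param detection_mV detection level, mV (default -20).
#' @param refractory_ms lockout after each detection, ms (default 5).
#' @param slope_criterion upstroke dV/dt criterion for threshold
#'   estimation, mV/ms (default 10).
#' @return An object of class `ap_summary`: spike count, resting Vm, and
#'   per-spike `threshold`, `overshoot`, `half_width` with their means.
#' @export
detect_spikes <- function(vt, step = 1L, detection_mV = -20,
                          refractory_ms = 5, slope_criterion = 10) {
  stopifnot(inherits(vt, "voltage_trace"))
  if (step > nrow(vt$steps)) stopf("step %d not annotated", step)
  s <- vt$steps[step, ]
  sel <- vt$time_ms >= s$start & vt$time_ms < s$end
  if (!any(sel)) stopf("current step %d contains no samples", step)
  t <- vt$time_ms[sel]
  v <- vt$vm_mV[sel]

  pre <- vt$vm_mV[vt$time_ms < s$start]
  resting <- if (length(pre)) mean(pre) else v[1L]

  up <- which(v[-1L] > detection_mV & v[-length(v)] <= detection_mV)
  crossings <- integer(0)
  last_t <- -Inf
  for (i in up) {
    if (t[i + 1L] - last_t > refractory_ms) {
      crossings <- c(crossings, i + 1L)
      last_t <- t[i + 1L]
    }
  }
  n_spk <- length(crossings)

  thr <- ovs <- hw <- rep(NA_real_, n_spk)
  dv <- c(NA, diff(v) / diff(t))
  for (j in seq_len(n_spk)) {
    i0 <- crossings[j]
    i_end <- if (j < n_spk) crossings[j + 1L] - 1L else length(v)
    pk_rel <- which.max(v[i0:i_end])
    i_pk <- i0 + pk_rel - 1L
    ovs[j] <- v[i_pk]
    # threshold = Vm where this spike's upstroke dV/dt exceeds the slope
    # criterion: take the start of the last super-criterion run before
    # the peak (earlier runs belong to previous spikes; the sample at the
    # peak itself can dip below the criterion through slope blending)
    i_lo <- if (j > 1L) crossings[j - 1L] + 1L else 2L
    sup <- dv[i_lo:i_pk] >= slope_criterion
    r <- rle(sup)
    run_ends <- cumsum(r$lengths)
    last_sup <- utils::tail(which(r$values), 1L)
    i_thr <- if (length(last_sup)) {
      i_lo + (run_ends[last_sup] - r$lengths[last_sup] + 1L) - 2L
    } else i0
    thr[j] <- v[max(i_thr, 1L)]
    half <- (thr[j] + ovs[j]) / 2
    t_up <- cross_time(t, v, half, seq(i_thr, i_pk), rising = TRUE)
    i_down_end <- i_end
    t_dn <- cross_time(t, v, half, seq(i_pk, i_down_end), rising = FALSE)
    if (!is.na(t_up) && !is.na(t_dn)) hw[j] <- t_dn - t_up
  }

  structure(list(cell_id = vt$cell_id, step = step,
                 current_pA = s$current_pA, n_spikes = n_spk,
                 resting_mV = resting, threshold_mV = thr,
                 overshoot_mV = ovs, half_width_ms = hw,
                 detection_mV = detection_mV,
                 slope_criterion = slope_criterion),
            class = "ap_summary")
}

# Sub-sample crossing time of `level` along indices idx (linear
# interpolation between the bracketing samples).
cross_time <- function(t, v, level, idx, rising = TRUE) {
  vv <- v[idx]
  if (rising) {
    k <- which(vv[-1L] >= level & vv[-length(vv)] < level)
  } else {
    k <- which(vv[-1L] <= level & vv[-length(vv)] > level)
  }
  if (!length(k)) return(NA_real_)
  k <- k[1L]
  i1 <- idx[k]; i2 <- idx[k + 1L]
  if (v[i2] == v[i1]) return(t[i2])
  t[i1] + (level - v[i1]) * (t[i2] - t[i1]) / (v[i2] - v[i1])
}

#' @export
print.ap_summary <- function(x, ...) {
  cat(sprintf("%s, step %d (%g pA): %d spike(s); resting %.1f mV\n",
              x$cell_id, x$step, x$current_pA, x$n_spikes, x$resting_mV))
  if (x$n_spikes > 0)
    cat(sprintf("  threshold %.1f mV, overshoot %.1f mV, half-width %.1f ms (means)\n",
                mean(x$threshold_mV, na.rm = TRUE),
                mean(x$overshoot_mV, na.rm = TRUE),
                mean(x$half_width_ms, na.rm = TRUE)))
  invisible(x)
}
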