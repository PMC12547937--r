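#' Configuration for a synthetic imaging cohort
#'
#' Describes a perfusion-imaging experiment: a baseline epoch, a sequence
#' of test-substance epochs, and a final positive-control epoch (KCl for
#' Fura2, forskolin/IBMX for the FRET sensor). Acquisition cadence defaults
#' to one ratio sample every 2 s, the cadence of the emulated recordings.
#' Responses are multiplicative steps on the baseline ratio: a responder
#' cell's ratio is multiplied by the epoch amplitude for the duration of
#' that epoch. Noise is additive Gaussian on the ratio and drift is linear
#' in time, both applied to responders and non-responders alike.
#'
#' @param n_cells number of cells.
#' @param sample_interval acquisition interval, seconds (default 2).
#' @param baseline_dur baseline epoch duration, seconds (default 60).
#' @param epochs data.frame with columns `label`, `duration` (s) and
#'   `amplitude` (multiplicative, >= 0; 1 = no response) for each test
#'   epoch, in perfusion order.
#' @param noise_sd SD of additive Gaussian noise on the ratio.
#' @param drift_slope slow linear drift, ratio units per second.
#' @param positive_control_amplitude multiplicative amplitude of the
#'   positive-control epoch, applied to every cell (default 1.5).
#' @param positive_control_dur positive-control duration, s (default 30).
#' @param responder_fraction probability that a cell carries the effect in
#'   a test epoch; scalar or one value per epoch.
#' @param baseline_ratio resting ratio level (default 1).
#' @param onset_ramp if `TRUE`, responses ramp in over one sample instead
#'   of stepping instantaneously.
#' @param include_positive_control set `FALSE` to waive the positive
#'   control (e.g. null-calibration cohorts).
#' @param seed mandatory RNG seed; simulators keep no global random state.
#' @return A validated `imaging_sim_config` list.
#' @export
imaging_sim_config <- function(n_cells, sample_interval = 2,
                               baseline_dur = 60, epochs,
                               noise_sd = 0.05, drift_slope = 0,
                               positive_control_amplitude = 1.5,
                               positive_control_dur = 30,
                               responder_fraction = 1,
                               baseline_ratio = 1,
                               onset_ramp = FALSE,
                               include_positive_control = TRUE,
                               seed) {
  n_cells <- check_count(n_cells, "n_cells")
  check_number(sample_interval, "sample_interval",
               lower = .Machine$double.eps)
  check_number(baseline_dur, "baseline_dur", lower = .Machine$double.eps)
  epochs <- as.data.frame(epochs)
  if (!all(c("label", "duration", "amplitude") %in% names(epochs)))
    stopf("'epochs' needs columns label, duration, amplitude")
  if (any(epochs$duration <= 0)) stopf("'epochs$duration' must be > 0")
  if (any(epochs$amplitude < 0)) stopf("'epochs$amplitude' must be >= 0")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(drift_slope, "drift_slope")
  check_number(positive_control_amplitude, "positive_control_amplitude",
               lower = 0)
  check_number(positive_control_dur, "positive_control_dur",
               lower = .Machine$double.eps)
  if (length(responder_fraction) == 1L)
    responder_fraction <- rep(responder_fraction, nrow(epochs))
  if (length(responder_fraction) != nrow(epochs))
    stopf("'responder_fraction' must be scalar or one value per epoch")
  if (any(responder_fraction < 0 | responder_fraction > 1))
    stopf("'responder_fraction' must be in [0, 1]")
  check_number(baseline_ratio, "baseline_ratio",
               lower = .Machine$double.eps)
  seed <- check_seed(seed)
  structure(list(n_cells = n_cells, sample_interval = sample_interval,
                 baseline_dur = baseline_dur, epochs = epochs,
                 noise_sd = noise_sd, drift_slope = drift_slope,
                 positive_control_amplitude = positive_control_amplitude,
                 positive_control_dur = positive_control_dur,
                 responder_fraction = responder_fraction,
                 baseline_ratio = baseline_ratio,
                 onset_ramp = onset_ramp,
                 include_positive_control = include_positive_control,
                 seed = seed),
            class = "imaging_sim_config")
}

#' Simulate a perfusion-imaging cohort with known ground truth
#'
#' Every cell shares one epoch schedule: baseline, the configured test
#' epochs in order, then (unless waived) the positive control. Each cell
#' is independently a true responder in each test epoch with probability
#' `responder_fraction`; responders have their ratio multiplied by the
#' epoch amplitude inside the epoch. The positive-control amplitude is
#' applied to all cells. Traces are emitted as two-channel recordings with
#' the simulated ratio in channel A over a unit channel B, so
#' [ratio()] recovers the simulated ratio exactly.
#'
#' @param cfg an [imaging_sim_config].
#' @return list with `traces` (list of [ratio_trace]), `schedule`
#'   ([epoch_schedule]), and `truth` — a data.frame of per-cell,
#'   per-epoch true amplitudes and responder flags.
#' @export
simulate_imaging_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "imaging_sim_config"))
  set.seed(cfg$seed)

  labels <- c("baseline", cfg$epochs$label)
  durs <- c(cfg$baseline_dur, cfg$epochs$duration)
  roles <- c("baseline", rep("test", nrow(cfg$epochs)))
  if (cfg$include_positive_control) {
    labels <- c(labels, "positive_control")
    durs <- c(durs, cfg$positive_control_dur)
    roles <- c(roles, "positive_control")
  }
  ends <- cumsum(durs)
  starts <- c(0, ends[-length(ends)])
  schedule <- epoch_schedule(labels, starts, ends, roles)

  total <- ends[length(ends)]
  t <- seq(0, total - cfg$sample_interval / 2, by = cfg$sample_interval)
  n_epochs <- nrow(cfg$epochs)

  # per-cell, per-test-epoch responder draws
  resp <- matrix(stats::runif(cfg$n_cells * n_epochs) <
                   rep(cfg$responder_fraction, each = cfg$n_cells),
                 nrow = cfg$n_cells)

  traces <- vector("list", cfg$n_cells)
  truth <- vector("list", cfg$n_cells)
  ids <- sprintf("cell%04d", seq_len(cfg$n_cells))
  for (i in seq_len(cfg$n_cells)) {
    mult <- rep(1, length(t))
    for (j in seq_len(n_epochs)) {
      b <- epoch_bounds(schedule, cfg$epochs$label[j])
      amp <- if (resp[i, j]) cfg$epochs$amplitude[j] else 1
      inside <- t >= b["start"] & t < b["end"]
      mult[inside] <- amp
      if (cfg$onset_ramp && any(inside) && amp != 1) {
        first <- which(inside)[1L]
        mult[first] <- 1 + (amp - 1) / 2
      }
    }
    if (cfg$include_positive_control) {
      b <- epoch_bounds(schedule, "positive_control")
      mult[t >= b["start"] & t < b["end"]] <-
        cfg$positive_control_amplitude
    }
    r <- cfg$baseline_ratio * mult + cfg$drift_slope * t
    if (cfg$noise_sd > 0)
      r <- r + stats::rnorm(length(t), 0, cfg$noise_sd)
    traces[[i]] <- ratio_trace(ids[i], t, chanA = r,
                               chanB = rep(1, length(t)),
                               modality = "fret")
    truth[[i]] <- data.frame(cell_id = ids[i],
                             epoch = cfg$epochs$label,
                             amplitude = ifelse(resp[i, ],
                                                cfg$epochs$amplitude, 1),
                             responder = resp[i, ],
                             stringsAsFactors = FALSE)
  }
  list(traces = traces, schedule = schedule,
       truth = do.call(rbind, truth))
}
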