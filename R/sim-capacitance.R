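#' Depolarization pulse-train protocols
#'
#' `pool10` is the vesicle-pool dissection train: 6 short 10-ms
#' depolarizations followed by 4 longer 100-ms depolarizations (-70 to
#' +20 mV) with a 300-ms interpulse interval during which Cm is measured.
#' `potentiation15` is the exocytosis-potentiation train: 15 square
#' 500-ms depolarizations (-60 to 0 mV) with 300-ms interpulse
#' measurements. `custom` takes an explicit pulse table.
#'
#' @param name `"pool10"`, `"potentiation15"` or `"custom"`.
#' @param pulses for `custom`: data.frame with `start`, `duration` (ms),
#'   `from_mV`, `to_mV`.
#' @param interpulse_ms interpulse (measurement) interval, ms.
#' @param pre_ms pre-train measurement window before the first pulse, ms.
#' @param post_train_s post-train measurement window after the last
#'   pulse, seconds (default 9.5).
#' @param window_ms landmark averaging-window length, ms (default 300).
#' @return An object of class `pulse_protocol`.
#' @export
pulse_protocol <- function(name = c("pool10", "potentiation15", "custom"),
                           pulses = NULL, interpulse_ms = 300,
                           pre_ms = 300, post_train_s = 9.5,
                           window_ms = 300) {
  name <- match.arg(name)
  if (name == "pool10") {
    durs <- c(rep(10, 6), rep(100, 4))
    from <- -70; to <- 20
  } else if (name == "potentiation15") {
    durs <- rep(500, 15)
    from <- -60; to <- 0
  } else {
    if (is.null(pulses)) stopf("custom protocol needs a 'pulses' table")
    pulses <- as.data.frame(pulses)
    req <- c("start", "duration", "from_mV", "to_mV")
    if (!all(req %in% names(pulses)))
      stopf("pulses must have columns %s", paste(req, collapse = ", "))
    pulses <- pulses[order(pulses$start), , drop = FALSE]
    ends <- pulses$start + pulses$duration
    if (nrow(pulses) > 1L &&
        any(pulses$start[-1L] < ends[-nrow(pulses)]))
      stopf("pulses must not overlap")
  }
  if (name != "custom") {
    starts <- pre_ms + cumsum(c(0, durs[-length(durs)] + interpulse_ms))
    pulses <- data.frame(start = starts, duration = durs,
                         from_mV = from, to_mV = to)
  }
  structure(list(name = name, pulses = pulses,
                 interpulse_ms = interpulse_ms, pre_ms = pre_ms,
                 post_train_s = post_train_s, window_ms = window_ms),
            class = "pulse_protocol")
}

#' Configuration for the sequential-pool capacitance forward model
#'
#' Phenomenological depletion model of depolarization-evoked exocytosis.
#' Short (10-ms) pulses release a fixed fraction of the *remaining*
#' immediately releasable pool (IRP); long (>= 100 ms) pulses release any
#' IRP still remaining (first long pulse) plus a fixed fraction of the
#' remaining readily releasable pool (RRP). A sustained-release component
#' adds linear Cm growth during the post-train window, and endocytosis
#' (default 0) removes membrane linearly after the first pulse. Each Cm
#' step lands at pulse end; samples exist only in measurement windows.
#'
#' @param irp_size,rrp_size pool sizes, fF.
#' @param sustained_rate post-train sustained release, fF/s.
#' @param release_fraction_short fraction of remaining IRP released per
#'   10-ms pulse, in `[0, 1]`.
#' @param release_fraction_long fraction of remaining RRP released per
#'   100-ms pulse, in `[0, 1]`.
#' @param endocytosis_rate linear membrane retrieval, fF/s (>= 0).
#' @param cm0 initial whole-cell capacitance, pF (default 10.8, a typical
#'   EC-cell size).
#' @param noise_sd per-sample Gaussian noise on Cm, fF.
#' @param sample_interval_ms Cm sampling interval inside measurement
#'   windows, ms (default 10, i.e. 30 samples per 300-ms window).
#' @param peak_current_pA peak inward current annotated on each pulse;
#'   scalar or per-pulse vector. Set near 0 to fabricate the
#'   "no exocytosis despite robust currents" QC fixture's converse.
#' @param seed mandatory RNG seed.
#' @return A validated `pool_sim_config` list.
#' @export
pool_sim_config <- function(irp_size, rrp_size, sustained_rate = 0,
                            release_fraction_short = 0.3,
                            release_fraction_long = 0.5,
                            endocytosis_rate = 0, cm0 = 10.8,
                            noise_sd = 0, sample_interval_ms = 10,
                            peak_current_pA = -250, seed) {
  check_number(irp_size, "irp_size", lower = 0)
  check_number(rrp_size, "rrp_size", lower = 0)
  check_number(sustained_rate, "sustained_rate", lower = 0)
  check_number(release_fraction_short, "release_fraction_short",
               lower = 0, upper = 1)
  check_number(release_fraction_long, "release_fraction_long",
               lower = 0, upper = 1)
  check_number(endocytosis_rate, "endocytosis_rate", lower = 0)
  check_number(cm0, "cm0", lower = .Machine$double.eps)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(sample_interval_ms, "sample_interval_ms",
               lower = .Machine$double.eps)
  seed <- check_seed(seed)
  structure(list(irp_size = irp_size, rrp_size = rrp_size,
                 sustained_rate = sustained_rate,
                 release_fraction_short = release_fraction_short,
                 release_fraction_long = release_fraction_long,
                 endocytosis_rate = endocytosis_rate, cm0 = cm0,
                 noise_sd = noise_sd,
                 sample_interval_ms = sample_interval_ms,
                 peak_current_pA = peak_current_pA, seed = seed),
            class = "pool_sim_config")
}

# Cumulative release (fF) at the end of each pulse under the depletion
# model; the closed form behind the simulator and the oracle tests.
pool_model_release <- function(cfg, pulses) {
  short <- pulses$duration < 100
  irp_rem <- cfg$irp_size
  rrp_rem <- cfg$rrp_size
  rel <- numeric(nrow(pulses))
  first_long_seen <- FALSE
  for (i in seq_len(nrow(pulses))) {
    if (short[i]) {
      r <- cfg$release_fraction_short * irp_rem
      irp_rem <- irp_rem - r
    } else {
      r <- cfg$release_fraction_long * rrp_rem
      rrp_rem <- rrp_rem - r
      if (!first_long_seen) {       # remaining IRP dumps on first long pulse
        r <- r + irp_rem
        irp_rem <- 0
        first_long_seen <- TRUE
      }
    }
    rel[i] <- r
  }
  cumsum(rel)
}

#' Simulate a capacitance recording under a pulse-train protocol
#'
#' @param cfg a [pool_sim_config].
#' @param protocol a [pulse_protocol]; for `potentiation15` every pulse is
#'   long, so each releases `release_fraction_long` of the remaining RRP
#'   (plus the IRP on the first).
#' @param cell_id identifier for the simulated cell.
#' @return list with `recording` (a [capacitance_recording]) and `truth`
#'   (pool sizes, per-pulse cumulative release, and the model's closed-form
#'   Cm before noise as a function, `cm_at(t_ms)`).
#' @export
simulate_capacitance <- function(cfg, protocol = pulse_protocol("pool10"),
                                 cell_id = "cell0001") {
  stopifnot(inherits(cfg, "pool_sim_config"),
            inherits(protocol, "pulse_protocol"))
  set.seed(cfg$seed)
  pulses <- protocol$pulses
  np <- nrow(pulses)
  ends <- pulses$start + pulses$duration
  cum_rel <- pool_model_release(cfg, pulses)
  t_first <- pulses$start[1L]
  t_last_end <- ends[np]
  base_fF <- cfg$cm0 * 1000

  cm_at <- function(t) {
    released <- vapply(t, function(tt) {
      k <- sum(ends <= tt)
      if (k == 0) 0 else cum_rel[k]
    }, numeric(1))
    sustained <- cfg$sustained_rate * pmax(0, t - t_last_end) / 1000
    endo <- cfg$endocytosis_rate * pmax(0, t - t_first) / 1000
    base_fF + released + sustained - endo
  }

  win_starts <- c(t_first - protocol$pre_ms, ends)
  win_ends <- c(pulses$start, t_last_end + protocol$post_train_s * 1000)
  t <- unlist(lapply(seq_along(win_starts), function(i) {
    if (win_ends[i] <= win_starts[i]) return(numeric(0))
    seq(win_starts[i], win_ends[i] - cfg$sample_interval_ms / 2,
        by = cfg$sample_interval_ms)
  }))
  cm <- cm_at(t)
  if (cfg$noise_sd > 0)
    cm <- cm + stats::rnorm(length(t), 0, cfg$noise_sd)

  peak <- cfg$peak_current_pA
  if (length(peak) == 1L) peak <- rep(peak, np)
  if (length(peak) != np)
    stopf("'peak_current_pA' must be scalar or one value per pulse")
  pulses$peak_pA <- peak

  rec <- capacitance_recording(cell_id, t, cm, pulses, cfg$cm0)
  list(recording = rec,
       truth = list(irp = cfg$irp_size, rrp = cfg$rrp_size,
                    cumulative_release = cum_rel, cm_at = cm_at,
                    first_pulse_ms = t_first,
                    last_pulse_end_ms = t_last_end))
}
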