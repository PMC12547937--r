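# Shared fixture builders and independent oracles. Oracles deliberately
# re-derive quantities with different primitives than the package code.

# A flat ratio series with chosen values painted over chosen epochs.
make_series <- function(time, value) data.frame(time = time, value = value)

# Simple two-epoch schedule: 60 s baseline then one test epoch.
basic_schedule <- function(test_dur = 60, pc_dur = 0) {
  labels <- c("baseline", "stim")
  starts <- c(0, 60)
  ends <- c(60, 60 + test_dur)
  roles <- c("baseline", "test")
  if (pc_dur > 0) {
    labels <- c(labels, "positive_control")
    starts <- c(starts, 60 + test_dur)
    ends <- c(ends, 60 + test_dur + pc_dur)
    roles <- c(roles, "positive_control")
  }
  epoch_schedule(labels, starts, ends, roles)
}

# Independent brute-force oracle for the z-score responder rule:
# fraction of pure-noise cells called responders, fully vectorized and
# sharing no code with the package implementation.
oracle_null_responder_rate <- function(n_rep, n_base = 30, n_epoch = 30,
                                       threshold = 3, min_run = 2) {
  stopifnot(min_run == 2)
  base <- matrix(rnorm(n_rep * n_base), n_rep)
  ep <- matrix(rnorm(n_rep * n_epoch), n_rep)
  m <- rowMeans(base)
  s <- sqrt(rowSums((base - m)^2) / (n_base - 1))
  z <- (ep - m) / s
  above <- z > threshold
  hit <- rowSums(above[, -1L, drop = FALSE] &
                   above[, -n_epoch, drop = FALSE]) > 0
  mean(hit)
}

# Staircase capacitance fixture on the pool10 geometry: Cm steps up by
# `step_fF` at the end of each of the first `n_steps` pulses.
staircase_recording <- function(step_fF = 2, n_steps = 6, cm0 = 12,
                                peak_pA = -250, noise_sd = 0,
                                protocol = pulse_protocol("pool10")) {
  p <- protocol$pulses
  ends <- p$start + p$duration
  win_starts <- c(p$start[1] - protocol$pre_ms, ends)
  win_ends <- c(p$start, ends[nrow(p)] + protocol$post_train_s * 1000)
  t <- unlist(lapply(seq_along(win_starts), function(i)
    seq(win_starts[i], win_ends[i] - 5, by = 10)))
  cm <- cm0 * 1000 + step_fF * pmin(vapply(t, function(tt)
    sum(ends <= tt), numeric(1)), n_steps)
  if (noise_sd > 0) cm <- cm + rnorm(length(t), 0, noise_sd)
  p$peak_pA <- peak_pA
  capacitance_recording("fix", t, cm, p, cm0)
}

# Flat-Cm recording (with annotated currents) on the pool10 geometry.
flat_recording <- function(cm0 = 12, peak_pA = -250,
                           protocol = pulse_protocol("pool10")) {
  staircase_recording(step_fF = 0, cm0 = cm0, peak_pA = peak_pA,
                      protocol = protocol)
}

# Random-walk Cm uncorrelated with the pulses (spontaneous fixture).
random_walk_recording <- function(step_sd = 4, cm0 = 12, seed = 11,
                                  protocol = pulse_protocol("pool10")) {
  set.seed(seed)
  p <- protocol$pulses
  ends <- p$start + p$duration
  win_starts <- c(p$start[1] - protocol$pre_ms, ends)
  win_ends <- c(p$start, ends[nrow(p)] + protocol$post_train_s * 1000)
  t <- unlist(lapply(seq_along(win_starts), function(i)
    seq(win_starts[i], win_ends[i] - 5, by = 10)))
  cm <- cm0 * 1000 + cumsum(rnorm(length(t), 0, step_sd))
  p$peak_pA <- -250
  capacitance_recording("walk", t, cm, p, cm0)
}

# Closed-form cumulative release of the depletion model, re-derived as
# explicit geometric-series sums (oracle for the simulator + estimator).
oracle_cumulative_release <- function(irp, rrp, fs, fl, n_short, n_long_so_far) {
  irp_part <- if (n_long_so_far >= 1) irp else irp * (1 - (1 - fs)^n_short)
  rrp_part <- rrp * (1 - (1 - fl)^n_long_so_far)
  irp_part + rrp_part
}
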