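#' Two-channel ratiometric fluorescence trace
#'
#' Container for a single cell's timestamped two-channel fluorescence
#' recording. Channel A is the numerator channel (340 nm excitation for
#' Fura2, CFP emission for the FRET cAMP sensor), channel B the denominator
#' (380 nm or YFP). Optional per-sample backgrounds are subtracted before
#' the ratio is formed.
#'
#' @param cell_id single string identifying the cell.
#' @param time numeric vector of acquisition times in seconds, strictly
#'   increasing.
#' @param chanA,chanB fluorescence intensities (arbitrary units), same
#'   length as `time`.
#' @param bgA,bgB optional per-sample backgrounds; `NULL` means zero.
#' @param modality `"fura2"` (Ca2+) or `"fret"` (cAMP).
#' @return An object of class `ratio_trace`.
#' @export
ratio_trace <- function(cell_id, time, chanA, chanB, bgA = NULL, bgB = NULL,
                        modality = c("fura2", "fret")) {
  modality <- match.arg(modality)
  if (!is.character(cell_id) || length(cell_id) != 1L)
    stopf("'cell_id' must be a single string")
  n <- length(time)
  if (length(chanA) != n || length(chanB) != n)
    stopf("cell '%s': time, chanA, chanB must have equal length", cell_id)
  if (!is.null(bgA) && length(bgA) != n)
    stopf("cell '%s': bgA length mismatch", cell_id)
  if (!is.null(bgB) && length(bgB) != n)
    stopf("cell '%s': bgB length mismatch", cell_id)
  if (n > 1L && any(diff(time) <= 0))
    stopf("cell '%s': time must be strictly increasing", cell_id)
  structure(
    list(cell_id = cell_id, time = as.numeric(time),
         chanA = as.numeric(chanA), chanB = as.numeric(chanB),
         bgA = if (is.null(bgA)) NULL else as.numeric(bgA),
         bgB = if (is.null(bgB)) NULL else as.numeric(bgB),
         modality = modality),
    class = "ratio_trace")
}

#' Labeled epoch schedule for a perfusion recording
#'
#' Ordered, non-overlapping half-open time intervals `[start, end)` tagging
#' stretches of a recording: baseline perfusion, test-substance additions,
#' washouts, the positive-control addition (KCl or forskolin/IBMX), or a
#' preincubation period.
#'
#' @param label character vector of epoch labels.
#' @param start,end numeric vectors, seconds; intervals are half-open
#'   `[start, end)`.
#' @param role one of `"baseline"`, `"test"`, `"washout"`,
#'   `"positive_control"`, `"preincubation"` per epoch.
#' @return An object of class `epoch_schedule` (a data.frame).
#' @export
epoch_schedule <- function(label, start, end, role) {
  roles <- c("baseline", "test", "washout", "positive_control",
             "preincubation")
  n <- length(label)
  if (length(start) != n || length(end) != n || length(role) != n)
    stopf("label, start, end, role must have equal length")
  if (!all(role %in% roles))
    stopf("unknown role(s): %s",
          paste(setdiff(role, roles), collapse = ", "))
  if (any(end <= start)) stopf("every epoch must have end > start")
  ord <- order(start)
  sched <- data.frame(label = as.character(label)[ord],
                      start = as.numeric(start)[ord],
                      end = as.numeric(end)[ord],
                      role = as.character(role)[ord],
                      stringsAsFactors = FALSE)
  if (n > 1L && any(sched$start[-1L] < sched$end[-n]))
    stopf("epochs must not overlap")
  if (anyDuplicated(sched$label))
    stopf("epoch labels must be unique")
  class(sched) <- c("epoch_schedule", "data.frame")
  sched
}

epoch_bounds <- function(schedule, label) {
  i <- match(label, schedule$label)
  if (is.na(i)) stopf("epoch label '%s' not found in schedule", label)
  c(start = schedule$start[i], end = schedule$end[i])
}

#' Background-subtracted channel ratio
#'
#' Computes `r_t = (chanA_t - bgA_t) / (chanB_t - bgB_t)` at every sample;
#' a missing background is treated as zero. This is the Fura2 340/380 or
#' FRET CFP/YFP ratio on which all downstream imaging quantification
#' operates.
#'
#' @param trace a [ratio_trace].
#' @return data.frame with columns `time` and `value`, aligned to the
#'   input timestamps.
#' @export
ratio <- function(trace) {
  stopifnot(inherits(trace, "ratio_trace"))
  num <- trace$chanA - (trace$bgA %||% 0)
  den <- trace$chanB - (trace$bgB %||% 0)
  bad <- which(den <= 0)
  if (length(bad))
    stopf("cell '%s': non-positive denominator after background subtraction at sample %d",
          trace$cell_id, bad[1L])
  data.frame(time = trace$time, value = num / den)
}

#' Extract the samples falling in one epoch
#'
#' Half-open selection: samples with `start <= time < end` belong to the
#' epoch, so adjacent epochs partition a regular grid with no sample
#' counted twice.
#'
#' @param series data.frame with a `time` column (e.g. from [ratio()]).
#' @param schedule an [epoch_schedule].
#' @param label epoch label to extract.
#' @return The subset of `series` rows inside the epoch.
#' @export
slice_epoch <- function(series, schedule, label) {
  b <- epoch_bounds(schedule, label)
  out <- series[series$time >= b["start"] & series$time < b["end"], ,
                drop = FALSE]
  if (nrow(out) == 0L)
    stopf("epoch '%s' [%g, %g) contains no samples", label,
          b["start"], b["end"])
  rownames(out) <- NULL
  out
}

# Samples in an arbitrary half-open window [a, b); used for the rolling
# 60-s baseline reference preceding each test addition.
slice_window <- function(series, a, b) {
  out <- series[series$time >= a & series$time < b, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Membrane-potential trace with current-step annotations
#'
#' @param cell_id single string.
#' @param time_ms sample times, milliseconds, strictly increasing.
#' @param vm_mV membrane potential at each sample.
#' @param steps data.frame with columns `start`, `end` (ms) and
#'   `current_pA` describing the injected square current steps.
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(cell_id, time_ms, vm_mV, steps) {
  if (length(time_ms) != length(vm_mV))
    stopf("time_ms and vm_mV must have equal length")
  if (length(time_ms) > 1L && any(diff(time_ms) <= 0))
    stopf("cell '%s': time must be strictly increasing", cell_id)
  steps <- as.data.frame(steps)
  req <- c("start", "end", "current_pA")
  if (!all(req %in% names(steps)))
    stopf("steps must have columns %s", paste(req, collapse = ", "))
  steps <- steps[order(steps$start), , drop = FALSE]
  if (nrow(steps) > 1L &&
      any(steps$start[-1L] < steps$end[-nrow(steps)]))
    stopf("current steps must not overlap")
  structure(list(cell_id = cell_id, time_ms = as.numeric(time_ms),
                 vm_mV = as.numeric(vm_mV), steps = steps),
            class = "voltage_trace")
}

#' Membrane-capacitance recording with depolarization-pulse annotations
#'
#' Cm is measured with a sine-wave technique that is suspended during each
#' depolarization, so samples exist only in the pre-train, interpulse and
#' post-train windows; the constructor rejects samples inside pulses.
#'
#' @param cell_id single string.
#' @param time_ms sample times, milliseconds, strictly increasing.
#' @param cm_fF membrane capacitance at each sample, femtofarads.
#' @param pulses data.frame with columns `start`, `duration` (ms),
#'   `from_mV`, `to_mV`, `peak_pA` (peak inward current).
#' @param cm0_pF initial whole-cell capacitance (cell size), picofarads.
#' @return An object of class `capacitance_recording`.
#' @export
capacitance_recording <- function(cell_id, time_ms, cm_fF, pulses, cm0_pF) {
  if (length(time_ms) != length(cm_fF))
    stopf("time_ms and cm_fF must have equal length")
  if (length(time_ms) > 1L && any(diff(time_ms) <= 0))
    stopf("cell '%s': time must be strictly increasing", cell_id)
  check_number(cm0_pF, "cm0_pF", lower = .Machine$double.eps)
  pulses <- as.data.frame(pulses)
  req <- c("start", "duration", "from_mV", "to_mV", "peak_pA")
  if (!all(req %in% names(pulses)))
    stopf("pulses must have columns %s", paste(req, collapse = ", "))
  pulses <- pulses[order(pulses$start), , drop = FALSE]
  ends <- pulses$start + pulses$duration
  if (nrow(pulses) > 1L && any(pulses$start[-1L] < ends[-nrow(pulses)]))
    stopf("pulses must not overlap")
  for (i in seq_len(nrow(pulses))) {
    inside <- time_ms >= pulses$start[i] & time_ms < ends[i]
    if (any(inside))
      stopf("cell '%s': Cm samples present inside pulse %d (measurement is undefined during depolarization)",
            cell_id, i)
  }
  structure(list(cell_id = cell_id, time_ms = as.numeric(time_ms),
                 cm_fF = as.numeric(cm_fF), pulses = pulses,
                 cm0_pF = cm0_pF),
            class = "capacitance_recording")
}
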