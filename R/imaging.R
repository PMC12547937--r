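# Baseline reference window: the 60 s of datapoints immediately preceding
# a test (or positive-control) addition. Re-derived per stimulus so
# multi-stimulus protocols are re-baselined before each addition.
baseline_window_before <- function(series, epoch_start, baseline_s = 60) {
  w <- slice_window(series, epoch_start - baseline_s, epoch_start)
  if (nrow(w) < 2L)
    stopf("fewer than 2 baseline samples in the %g s before t = %g s",
          baseline_s, epoch_start)
  w
}

first_epoch_start <- function(schedule, role) {
  i <- which(schedule$role == role)
  if (!length(i)) return(NA_real_)
  schedule$start[i[1L]]
}

#' Positive-control inclusion gate
#'
#' A cell enters the analysis only if its positive control (KCl for Ca2+,
#' forskolin/IBMX for cAMP) elevated the ratio by at least
#' `threshold_pct` percent over the baseline reference: the maximum ratio
#' within the positive-control epoch must reach
#' `(1 + threshold_pct/100)` times the mean of the 60-s window preceding
#' the first test epoch (boundary inclusive). A cell with no
#' positive-control epoch is excluded with a reason code rather than
#' dropped.
#'
#' @param series ratio series (data.frame `time`, `value`) from [ratio()].
#' @param schedule an [epoch_schedule].
#' @param threshold_pct required elevation, percent (default 10).
#' @param baseline_s baseline reference window length, s (default 60).
#' @return list with `included` (logical), `reason` (`NA` when included),
#'   `control_max` and `baseline_ref`.
#' @export
inclusion_gate <- function(series, schedule, threshold_pct = 10,
                           baseline_s = 60) {
  pc <- which(schedule$role == "positive_control")
  if (!length(pc))
    return(list(included = FALSE, reason = "no_positive_control_epoch",
                control_max = NA_real_, baseline_ref = NA_real_))
  ref_t <- first_epoch_start(schedule, "test")
  if (is.na(ref_t)) ref_t <- schedule$start[pc[1L]]
  bw <- baseline_window_before(series, ref_t, baseline_s)
  baseline_ref <- mean(bw$value)
  ctrl <- slice_epoch(series, schedule, schedule$label[pc[1L]])
  control_max <- max(ctrl$value)
  included <- control_max >= (1 + threshold_pct / 100) * baseline_ref
  list(included = included,
       reason = if (included) NA_character_ else "failed_positive_control",
       control_max = control_max, baseline_ref = baseline_ref)
}

#' z-scores of a test epoch against its preceding baseline
#'
#' For every sample in the test epoch,
#' `z_t = (F_t - mean F_b) / SD F_b`, where the baseline statistics are
#' computed over the 60 s of datapoints immediately preceding the test
#' addition (SD with the n-1 denominator).
#'
#' @param series ratio series (data.frame `time`, `value`).
#' @param schedule an [epoch_schedule].
#' @param label label of the test epoch.
#' @param baseline_s baseline window length, s (default 60).
#' @return data.frame with `time` and `z` for the test-epoch samples.
#' @export
zscore_series <- function(series, schedule, label, baseline_s = 60) {
  b <- epoch_bounds(schedule, label)
  bw <- baseline_window_before(series, b["start"], baseline_s)
  m <- mean(bw$value)
  s <- stats::sd(bw$value)
  if (s == 0)
    stopf("degenerate baseline before '%s': SD of baseline ratios is 0",
          label)
  ep <- slice_epoch(series, schedule, label)
  data.frame(time = ep$time, z = (ep$value - m) / s)
}

#' Responder classification from a z-score series
#'
#' A cell is a responder to a stimulus if its z-score exceeds the
#' threshold (strictly) for at least `min_run` consecutive acquired
#' timepoints during perfusion of the stimulus. The longest such run is
#' reported even when it falls short.
#'
#' @param z numeric z-score vector restricted to the test epoch (or the
#'   data.frame from [zscore_series()]).
#' @param threshold z threshold (default 3; ties are non-responses).
#' @param min_run minimum consecutive samples above threshold (default 2).
#' @return list with `responder` (logical) and `run_length` (integer).
#' @export
classify_responder <- function(z, threshold = 3, min_run = 2) {
  if (is.data.frame(z)) z <- z$z
  if (!length(z)) stopf("empty test epoch: no z-scores to classify")
  run <- max_run_length(z > threshold)
  list(responder = run >= min_run, run_length = as.integer(run))
}

#' Stimulus-to-baseline fold change R/R0
#'
#' `R` aggregates the ratio over the stimulus epoch and `R0` aggregates
#' it over the basal reference window (the 60 s preceding that stimulus);
#' the fold change is `R/R0`. The aggregator defaults to the maximum, with
#' the mean available, and is recorded in every output row because the
#' emulated Fura2 conventions leave it ambiguous.
#'
#' @param series ratio series (data.frame `time`, `value`).
#' @param schedule an [epoch_schedule].
#' @param stimulus_label label of the stimulus epoch.
#' @param aggregator `"max"` (default) or `"mean"`.
#' @param baseline_s basal reference window length, s (default 60).
#' @return the fold change `R/R0` (single number).
#' @export
fold_change <- function(series, schedule, stimulus_label,
                        aggregator = c("max", "mean"), baseline_s = 60) {
  aggregator <- match.arg(aggregator)
  agg <- if (aggregator == "max") max else mean
  b <- epoch_bounds(schedule, stimulus_label)
  ep <- slice_epoch(series, schedule, stimulus_label)
  bw <- baseline_window_before(series, b["start"], baseline_s)
  R <- agg(ep$value)
  R0 <- agg(bw$value)
  if (R0 <= 0) stopf("non-positive basal reference for '%s'", stimulus_label)
  R / R0
}

#' Quantify Gi-mediated cAMP inhibition against the positive control
#'
#' For the preincubation protocol (IBMX plateau, IBMX + inhibitory
#' agonist, IBMX washback, then forskolin + IBMX), expresses the maximum
#' ratio during each IBMX epoch and the *minimum* ratio during the
#' IBMX + agonist epoch as a percentage of the forskolin + IBMX maximum
#' recorded in the same cell.
#'
#' @param series ratio series (data.frame `time`, `value`).
#' @param schedule an [epoch_schedule] containing the four labeled epochs.
#' @param labels named character vector mapping `pre`, `agonist`, `post`,
#'   `positive` to epoch labels.
#' @return list of class `inhibition_call`: `pct_pre_max`,
#'   `pct_agonist_min`, `pct_post_max` (each % of the positive-control
#'   maximum), plus the raw positive-control maximum.
#' @export
quantify_inhibition <- function(series, schedule,
                                labels = c(pre = "IBMX1",
                                           agonist = "IBMX+agonist",
                                           post = "IBMX2",
                                           positive = "F+I")) {
  req <- c("pre", "agonist", "post", "positive")
  if (!all(req %in% names(labels)))
    stopf("'labels' must name epochs %s", paste(req, collapse = ", "))
  missing_lab <- setdiff(labels[req], schedule$label)
  if (length(missing_lab))
    stopf("schedule is missing required epoch(s): %s",
          paste(missing_lab, collapse = ", "))
  fimax <- max(slice_epoch(series, schedule, labels[["positive"]])$value)
  if (fimax <= 0) stopf("non-positive positive-control maximum")
  structure(list(
    pct_pre_max = 100 * max(slice_epoch(series, schedule,
                                        labels[["pre"]])$value) / fimax,
    pct_agonist_min = 100 * min(slice_epoch(series, schedule,
                                            labels[["agonist"]])$value) / fimax,
    pct_post_max = 100 * max(slice_epoch(series, schedule,
                                         labels[["post"]])$value) / fimax,
    positive_max = fimax), class = "inhibition_call")
}

#' Run the full single-cell imaging quantification over a cohort
#'
#' Applies the positive-control inclusion gate, then for every included
#' cell and every test epoch computes the z-score series against the 60-s
#' pre-addition baseline, the responder call (z > 3 for >= 2 consecutive
#' timepoints by default) and the R/R0 fold change. Gated-out cells stay
#' in the table with `included = FALSE` so exclusions are auditable; they
#' are omitted from cohort statistics.
#'
#' @param traces list of [ratio_trace] objects.
#' @param schedule shared [epoch_schedule].
#' @param stimuli labels of the test epochs to score; default all
#'   `role == "test"` epochs.
#' @param threshold,min_run responder-rule parameters (defaults 3 and 2).
#' @param gate_pct positive-control inclusion threshold, percent
#'   (default 10); `NA` waives the gate (all cells included).
#' @param aggregator fold-change aggregator, `"max"` or `"mean"`.
#' @param baseline_s baseline window, s (default 60).
#' @return data.frame of class `responder_calls`, one row per cell x
#'   stimulus: `cell_id`, `stimulus`, `included`, `exclusion_reason`,
#'   `responder`, `run_length`, `z_max`, `fold_change`, `aggregator`.
#' @export
analyze_imaging <- function(traces, schedule, stimuli = NULL,
                            threshold = 3, min_run = 2, gate_pct = 10,
                            aggregator = c("max", "mean"),
                            baseline_s = 60) {
  aggregator <- match.arg(aggregator)
  if (is.null(stimuli))
    stimuli <- schedule$label[schedule$role == "test"]
  rows <- lapply(traces, function(tr) {
    series <- ratio(tr)
    if (is.na(gate_pct)) {
      gate <- list(included = TRUE, reason = NA_character_)
    } else {
      gate <- inclusion_gate(series, schedule, threshold_pct = gate_pct,
                             baseline_s = baseline_s)
    }
    do.call(rbind, lapply(stimuli, function(lab) {
      zs <- zscore_series(series, schedule, lab, baseline_s = baseline_s)
      cl <- classify_responder(zs$z, threshold = threshold,
                               min_run = min_run)
      fc <- fold_change(series, schedule, lab, aggregator = aggregator,
                        baseline_s = baseline_s)
      data.frame(cell_id = tr$cell_id, stimulus = lab,
                 included = gate$included,
                 exclusion_reason = gate$reason %||% NA_character_,
                 responder = gate$included && cl$responder,
                 run_length = cl$run_length,
                 z_max = max(zs$z), fold_change = fc,
                 aggregator = aggregator, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_id = character(), stimulus = character(),
                      included = logical(),
                      exclusion_reason = character(),
                      responder = logical(), run_length = integer(),
                      z_max = numeric(), fold_change = numeric(),
                      aggregator = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("responder_calls", "data.frame")
  out
}

#' @export
summary.responder_calls <- function(object, ...) {
  inc <- object[object$included, , drop = FALSE]
  split_inc <- split(inc, inc$stimulus)
  out <- do.call(rbind, lapply(names(split_inc), function(s) {
    d <- split_inc[[s]]
    data.frame(stimulus = s, n_included = nrow(d),
               n_responders = sum(d$responder),
               responder_rate = mean(d$responder),
               median_fold = stats::median(d$fold_change),
               stringsAsFactors = FALSE)
  }))
  n_total <- length(unique(object$cell_id))
  n_inc <- length(unique(inc$cell_id))
  structure(list(per_stimulus = out, n_cells = n_total,
                 n_included = n_inc),
            class = "summary.responder_calls")
}

#' @export
print.summary.responder_calls <- function(x, ...) {
  cat(sprintf("Imaging cohort: %d cells, %d passed the positive-control gate\n",
              x$n_cells, x$n_included))
  print(x$per_stimulus, row.names = FALSE)
  invisible(x)
}

#' @export
print.responder_calls <- function(x, ...) {
  cat(sprintf("Responder calls: %d cells x %d stimuli (aggregator: %s)\n",
              length(unique(x$cell_id)), length(unique(x$stimulus)),
              x$aggregator[1L]))
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
print.inhibition_call <- function(x, ...) {
  cat(sprintf(
    "cAMP inhibition (%% of forskolin+IBMX max): IBMX %0.1f%% -> +agonist min %0.1f%% -> IBMX %0.1f%%\n",
    x$pct_pre_max, x$pct_agonist_min, x$pct_post_max))
  invisible(x)
}
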