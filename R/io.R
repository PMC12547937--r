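#' Write an imaging cohort to CSV (+ JSON epoch sidecar)
#'
#' Long-format CSV with columns `cell_id, time_s, chanA, chanB[, bgA, bgB]`;
#' the epoch schedule goes to a JSON sidecar so the pair round-trips
#' losslessly.
#'
#' @param traces list of [ratio_trace] objects.
#' @param path CSV output path.
#' @param schedule optional [epoch_schedule]; written to `schedule_path`.
#' @param schedule_path sidecar path; default `<path>.epochs.json`.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, schedule = NULL,
                         schedule_path = paste0(path, ".epochs.json")) {
  rows <- lapply(traces, function(tr) {
    data.frame(cell_id = tr$cell_id, time_s = tr$time,
               chanA = tr$chanA, chanB = tr$chanB,
               bgA = tr$bgA %||% 0, bgB = tr$bgB %||% 0,
               modality = tr$modality, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  if (!is.null(schedule))
    jsonlite::write_json(as.data.frame(unclass(schedule)), schedule_path,
                         digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read an imaging cohort from CSV (+ JSON epoch sidecar)
#'
#' @param path CSV path as written by [write_traces()].
#' @param schedule_path sidecar path; read if the file exists.
#' @return list with `traces` (list of [ratio_trace]) and `schedule`
#'   ([epoch_schedule] or `NULL`).
#' @export
read_traces <- function(path, schedule_path = paste0(path, ".epochs.json")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cell_id", "time_s", "chanA", "chanB")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stopf("CSV '%s' is missing required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  traces <- lapply(split(df, df$cell_id), function(d) {
    if (nrow(d) > 1L && any(diff(d$time_s) <= 0))
      stopf("cell '%s': time_s is not strictly increasing in '%s'",
            d$cell_id[1L], path)
    ratio_trace(d$cell_id[1L], d$time_s, d$chanA, d$chanB,
                bgA = if ("bgA" %in% names(d)) d$bgA else NULL,
                bgB = if ("bgB" %in% names(d)) d$bgB else NULL,
                modality = if ("modality" %in% names(d)) d$modality[1L]
                           else "fura2")
  })
  traces <- traces[order(names(traces))]
  schedule <- NULL
  if (file.exists(schedule_path)) {
    s <- jsonlite::read_json(schedule_path, simplifyVector = TRUE)
    schedule <- epoch_schedule(s$label, s$start, s$end, s$role)
  }
  list(traces = unname(traces), schedule = schedule)
}

#' Read/write secretion plate tables
#'
#' CSV columns: `plate_id, well, condition, ng_per_ml[, in_range]`.
#'
#' @param path CSV path.
#' @return data.frame plate table.
#' @export
read_plate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("plate_id", "well", "condition", "ng_per_ml")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stopf("CSV '%s' is missing required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  if (!"in_range" %in% names(df)) df$in_range <- TRUE
  df
}

#' @rdname read_plate
#' @param table plate table data.frame.
#' @export
write_plate <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
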