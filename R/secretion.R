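#' Normalize a secretion plate to its basal wells
#'
#' Every well's analyte concentration is divided by the mean of the basal
#' wells *on the same plate* (basal wells included, so basal folds average
#' exactly 1 per plate). Out-of-assay-range wells are excluded from the
#' basal mean and flagged, but still receive a fold value; set
#' `include_out_of_range = TRUE` to use them.
#'
#' @param table plate table: `plate_id`, `well`, `condition`, `ng_per_ml`
#'   and optionally `in_range` (default all `TRUE`).
#' @param basal_label condition label of the basal wells (default
#'   `"basal"`).
#' @param include_out_of_range include flagged wells in basal means and
#'   downstream statistics (default `FALSE`).
#' @return the table with a `fold` column appended, class
#'   `secretion_folds`.
#' @export
normalize_plate <- function(table, basal_label = "basal",
                            include_out_of_range = FALSE) {
  table <- as.data.frame(table)
  req <- c("plate_id", "well", "condition", "ng_per_ml")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols))
    stopf("plate table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (!"in_range" %in% names(table)) table$in_range <- TRUE
  if (any(table$ng_per_ml < 0)) stopf("analyte concentrations must be >= 0")
  out <- lapply(split(table, table$plate_id), function(p) {
    basal <- p$condition == basal_label &
      (include_out_of_range | p$in_range)
    if (!any(basal))
      stopf("plate '%s' has no usable basal wells", p$plate_id[1L])
    m <- mean(p$ng_per_ml[basal])
    if (m <= 0)
      stopf("plate '%s': mean basal concentration is not positive",
            p$plate_id[1L])
    p$fold <- p$ng_per_ml / m
    p
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("secretion_folds", "data.frame")
  out
}

#' One-sample fold-change test for a secretion condition
#'
#' Mean fold with a 95% confidence interval and a two-sided one-sample
#' t-test against a baseline fold of 1. Zero-variance inputs yield a
#' flagged non-result (`p = NA`, `degenerate = TRUE`) rather than an
#' error.
#'
#' @param folds numeric vector of per-well fold changes (>= 2 values).
#' @return list: `n`, `mean`, `ci` (length-2), `p`, `degenerate`.
#' @export
condition_test <- function(folds) {
  folds <- folds[!is.na(folds)]
  if (length(folds) < 2L)
    stopf("need at least 2 fold values, got %d", length(folds))
  if (stats::sd(folds) == 0)
    return(list(n = length(folds), mean = mean(folds),
                ci = c(mean(folds), mean(folds)), p = NA_real_,
                degenerate = TRUE))
  tt <- stats::t.test(folds, mu = 1)
  list(n = length(folds), mean = mean(folds),
       ci = unname(tt$conf.int), p = tt$p.value, degenerate = FALSE)
}

#' Normalize and test every condition on one or more plates
#'
#' @param table plate table (see [normalize_plate()]).
#' @param basal_label basal condition label.
#' @param include_out_of_range see [normalize_plate()].
#' @return data.frame of class `secretion_tests`, one row per non-basal
#'   condition: `condition`, `n`, `mean_fold`, `ci_lo`, `ci_hi`, `p`,
#'   `degenerate`; the fold table is attached as attribute `"folds"`.
#' @export
analyze_secretion <- function(table, basal_label = "basal",
                              include_out_of_range = FALSE) {
  folds <- normalize_plate(table, basal_label = basal_label,
                           include_out_of_range = include_out_of_range)
  use <- folds[include_out_of_range | folds$in_range, , drop = FALSE]
  conds <- setdiff(unique(use$condition), basal_label)
  rows <- lapply(conds, function(cn) {
    ct <- condition_test(use$fold[use$condition == cn])
    data.frame(condition = cn, n = ct$n, mean_fold = ct$mean,
               ci_lo = ct$ci[1L], ci_hi = ct$ci[2L], p = ct$p,
               degenerate = ct$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "folds") <- folds
  class(out) <- c("secretion_tests", "data.frame")
  out
}

#' @export
print.secretion_tests <- function(x, ...) {
  cat("Secretion fold changes vs plate basal (one-sample t vs 1):\n")
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
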