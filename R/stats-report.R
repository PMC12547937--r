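#' One-sample Wilcoxon signed-rank test against a fold of 1
#'
#' Used for cohort-level "is there a response across all cells" questions
#' on R/R0 fold changes, which are not normally distributed. Values tied
#' at exactly 1 are dropped per the signed-rank convention and the count
#' recorded. The median confidence interval comes from order statistics
#' (binomial/sign construction, conservative coverage).
#'
#' @param values numeric vector of per-cell fold changes.
#' @param conf confidence level for the median CI (default 0.95).
#' @return list: `n_used`, `n_dropped` (ties at 1), `median`, `ci`,
#'   `p` (two-sided; exact when n < 50 and tie-free).
#' @export
one_sample_wilcoxon_vs_1 <- function(values, conf = 0.95) {
  values <- values[!is.na(values)]
  dropped <- sum(values == 1)
  used <- values[values != 1]
  if (length(used) < 5L)
    stopf("need >= 5 values different from 1 for the exact test, got %d",
          length(used))
  wt <- stats::wilcox.test(used, mu = 1, exact = length(used) < 50 &&
                             !anyDuplicated(abs(used - 1)))
  n <- length(values)
  srt <- sort(values)
  alpha <- 1 - conf
  k <- stats::qbinom(alpha / 2, n, 0.5)
  ci <- if (k >= 1 && n - k + 1 <= n) c(srt[k], srt[n - k + 1]) else
    c(srt[1L], srt[n])
  list(n_used = length(used), n_dropped = dropped,
       median = stats::median(values), ci = ci, p = wt$p.value)
}

#' Friedman test with Dunn's post-hoc multiple comparisons
#'
#' Repeated-measures rank test across conditions measured in the same
#' cells (complete blocks), followed by Dunn's pairwise z-tests on mean
#' within-block ranks with a tie correction. By default the pairwise
#' family is every condition against the first (control) column,
#' mirroring the control-versus-treatment comparison structure; pass
#' `control = NA` for all pairs.
#'
#' @param mat numeric matrix, rows = cells (blocks), columns = repeated
#'   conditions (named).
#' @param control column name or index of the control condition
#'   (default 1); `NA` compares all pairs.
#' @param p_adjust adjustment method for the pairwise family (default
#'   `"bonferroni"`, the classical Dunn correction).
#' @return list: `friedman_chisq`, `friedman_p`, `pairwise` (data.frame
#'   with `comparison`, `z`, `p`, `p_adj`), `mean_ranks`.
#' @export
friedman_dunn <- function(mat, control = 1L, p_adjust = "bonferroni") {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stopf("complete blocks required: matrix contains NA")
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2L || n < 2L) stopf("need >= 2 conditions and >= 2 blocks")
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("cond", seq_len(k))
  ft <- stats::friedman.test(mat)
  # fully tied blocks give a 0/0 statistic; report the null result
  if (is.nan(ft$statistic)) {
    ft$statistic[] <- 0
    ft$p.value <- 1
  }

  ranks <- t(apply(mat, 1L, rank))
  rbar <- colMeans(ranks)
  # tie correction over blocks
  ties <- sum(apply(mat, 1L, function(row) {
    tt <- table(row); sum(tt^3 - tt)
  }))
  se <- sqrt((k * (k + 1) / (6 * n)) * (1 - ties / (n * k * (k^2 - 1))))

  if (length(control) == 1L && is.na(control)) {
    pairs <- utils::combn(k, 2L)
  } else {
    ci <- if (is.character(control)) match(control, colnames(mat))
          else as.integer(control)
    if (is.na(ci) || ci < 1L || ci > k) stopf("invalid control column")
    pairs <- rbind(rep(ci, k - 1L), setdiff(seq_len(k), ci))
  }
  z <- (rbar[pairs[1L, ]] - rbar[pairs[2L, ]]) / se
  p <- 2 * stats::pnorm(-abs(z))
  pw <- data.frame(
    comparison = paste(colnames(mat)[pairs[1L, ]], "vs",
                       colnames(mat)[pairs[2L, ]]),
    z = unname(z), p = unname(p),
    p_adj = stats::p.adjust(p, method = p_adjust),
    stringsAsFactors = FALSE)
  list(friedman_chisq = unname(ft$statistic), friedman_p = ft$p.value,
       pairwise = pw, mean_ranks = rbar)
}

#' Two-group and multi-group comparisons used across the figures
#'
#' A thin dispatcher over the standard tests: Mann-Whitney (unpaired,
#' rank-based), paired t, or one-way ANOVA with Dunnett's post-hoc
#' comparisons against a designated control group.
#'
#' @param a,b numeric vectors (two-group designs).
#' @param design `"mann_whitney"`, `"paired_t"` or `"anova_dunnett"`.
#' @param values,groups for `anova_dunnett`: all observations and their
#'   group labels (factor or character).
#' @param control control group label for Dunnett (default: first level).
#' @return For the two-group designs, a list with `p` (and `statistic`);
#'   for Dunnett, a data.frame with one row per treatment-vs-control
#'   comparison (`estimate`, `p`), plus the ANOVA `anova_p` attribute.
#' @export
group_compare <- function(a = NULL, b = NULL,
                          design = c("mann_whitney", "paired_t",
                                     "anova_dunnett"),
                          values = NULL, groups = NULL, control = NULL) {
  design <- match.arg(design)
  if (design == "mann_whitney") {
    wt <- stats::wilcox.test(a, b)
    return(list(p = wt$p.value, statistic = unname(wt$statistic)))
  }
  if (design == "paired_t") {
    if (length(a) != length(b)) stopf("paired design needs equal lengths")
    d <- a - b
    if (stats::sd(d) == 0) {
      # zero-variance differences: flagged limit result, not an exception
      return(list(p = if (mean(d) == 0) NA_real_ else 0,
                  statistic = if (mean(d) == 0) NA_real_ else
                    sign(mean(d)) * Inf,
                  degenerate = TRUE))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    return(list(p = tt$p.value, statistic = unname(tt$statistic),
                degenerate = FALSE))
  }
  if (is.null(values) || is.null(groups))
    stopf("anova_dunnett needs 'values' and 'groups'")
  g <- factor(groups)
  if (!is.null(control)) g <- stats::relevel(g, ref = control)
  if (nlevels(g) < 2L) stopf("need >= 2 groups")
  d <- data.frame(y = values, g = g)
  fit <- stats::aov(y ~ g, data = d)
  anova_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(gl)
  out <- data.frame(comparison = names(sm$test$coefficients),
                    estimate = unname(sm$test$coefficients),
                    p = unname(as.numeric(sm$test$pvalues)),
                    stringsAsFactors = FALSE)
  attr(out, "anova_p") <- anova_p
  out
}
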