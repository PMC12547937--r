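#' Configuration for a synthetic secretion plate
#'
#' Well-level serotonin (5-HT) concentrations are log-normal around the
#' plate's basal mean (treatment wells around `true_fold` times it), with
#' a fractional coefficient of variation `cv`. Values outside the ELISA
#' assay range are clipped to the bound and flagged out-of-range. Defaults
#' mirror the emulated assay: basal 0.47 ng/mL, range 0.015-2.5 ng/mL.
#'
#' @param n_basal_wells,n_treatment_wells well counts (>= 1).
#' @param basal_mean mean basal 5-HT release, ng/mL (default 0.47).
#' @param true_fold multiplicative treatment effect on the mean.
#' @param cv fractional coefficient of variation of well-level noise
#'   (log-normal; `cv = 0` gives exact values).
#' @param lod_low,lod_high assay quantification range, ng/mL
#'   (defaults 0.015 and 2.5).
#' @param seed mandatory RNG seed.
#' @return A validated `secretion_sim_config` list.
#' @export
secretion_sim_config <- function(n_basal_wells, n_treatment_wells,
                                 basal_mean = 0.47, true_fold = 1,
                                 cv = 0, lod_low = 0.015, lod_high = 2.5,
                                 seed) {
  n_basal_wells <- check_count(n_basal_wells, "n_basal_wells")
  n_treatment_wells <- check_count(n_treatment_wells, "n_treatment_wells")
  check_number(basal_mean, "basal_mean", lower = .Machine$double.eps)
  check_number(true_fold, "true_fold", lower = 0)
  check_number(cv, "cv", lower = 0)
  check_number(lod_low, "lod_low", lower = 0)
  check_number(lod_high, "lod_high")
  if (lod_low >= lod_high) stopf("'lod_low' must be below 'lod_high'")
  seed <- check_seed(seed)
  structure(list(n_basal_wells = n_basal_wells,
                 n_treatment_wells = n_treatment_wells,
                 basal_mean = basal_mean, true_fold = true_fold, cv = cv,
                 lod_low = lod_low, lod_high = lod_high, seed = seed),
            class = "secretion_sim_config")
}

# Log-normal draws with a given arithmetic mean and fractional CV.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one secretion plate with known ground truth
#'
#' @param cfg a [secretion_sim_config].
#' @param plate_id plate identifier.
#' @param condition_label label for treatment wells (default "treatment").
#' @return list with `plate` (data.frame: `plate_id`, `well`, `condition`,
#'   `ng_per_ml`, `in_range`) and `truth` (the configured means and fold).
#' @export
simulate_secretion_plate <- function(cfg, plate_id = "plate01",
                                     condition_label = "treatment") {
  stopifnot(inherits(cfg, "secretion_sim_config"))
  set.seed(cfg$seed)
  basal <- rlnorm_mean_cv(cfg$n_basal_wells, cfg$basal_mean, cfg$cv)
  treat <- rlnorm_mean_cv(cfg$n_treatment_wells,
                          cfg$true_fold * cfg$basal_mean, cfg$cv)
  vals <- c(basal, treat)
  in_range <- vals >= cfg$lod_low & vals <= cfg$lod_high
  vals <- pmin(pmax(vals, cfg$lod_low), cfg$lod_high)
  n <- length(vals)
  plate <- data.frame(
    plate_id = plate_id,
    well = sprintf("W%02d", seq_len(n)),
    condition = c(rep("basal", cfg$n_basal_wells),
                  rep(condition_label, cfg$n_treatment_wells)),
    ng_per_ml = vals,
    in_range = in_range,
    stringsAsFactors = FALSE)
  list(plate = plate,
       truth = list(basal_mean = cfg$basal_mean,
                    treatment_mean = cfg$true_fold * cfg$basal_mean,
                    true_fold = cfg$true_fold))
}
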