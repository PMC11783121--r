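#' Diplotype frequency presets
#'
#' Two CYP2D6 diplotype mixes whose activity-bin frequencies match the two
#' cohort structures the generator emulates: `"control"` (bins
#' 14.0/18.7/34.3/20.3/12.6 % from lowest to highest activity) and
#' `"intervention"` (19.8/21.6/23.6/17.9/17.0 %, i.e. more impaired
#' metabolisers). The mismatch between the two mixes is the main confounder
#' when cohorts are compared, so both must be available.
#'
#' @param preset `"control"` or `"intervention"`.
#' @return named numeric vector of diplotype probabilities (sums to 1).
#' @export
diplotype_preset <- function(preset = c("control", "intervention")) {
  preset <- match.arg(preset)
  if (preset == "control") {
    c("*4/*4" = 0.085, "*4/*5" = 0.035, "*3/*4" = 0.020,
      "*1/*4" = 0.159, "*9/*10" = 0.015, "*9/*9" = 0.013,
      "*1/*41" = 0.200, "*1/*10" = 0.144,
      "*1/*9" = 0.203,
      "*1/*1" = 0.080, "*1/*2" = 0.040, "*1x2/*1" = 0.006)
  } else {
    c("*4/*4" = 0.120, "*4/*5" = 0.050, "*3/*4" = 0.028,
      "*1/*4" = 0.184, "*9/*10" = 0.018, "*9/*9" = 0.014,
      "*1/*41" = 0.140, "*1/*10" = 0.097,
      "*1/*9" = 0.179,
      "*1/*1" = 0.110, "*1/*2" = 0.050, "*1x2/*1" = 0.010)
  }
}

# log-normal location/scale matched to cohort medians and IQRs
covariate_preset <- function(preset = c("control", "intervention")) {
  preset <- match.arg(preset)
  iqr_sdlog <- function(lo, hi) (log(hi) - log(lo)) / (2 * stats::qnorm(0.75))
  if (preset == "control") {
    list(age    = list(meanlog = log(57),   sdlog = iqr_sdlog(48, 66)),
         height = list(meanlog = log(168),  sdlog = iqr_sdlog(163, 173)),
         bmi    = list(meanlog = log(26.2), sdlog = iqr_sdlog(23.0, 30.0)))
  } else {
    list(age    = list(meanlog = log(60),   sdlog = iqr_sdlog(50, 68)),
         height = list(meanlog = log(166),  sdlog = iqr_sdlog(161, 170)),
         bmi    = list(meanlog = log(27.3), sdlog = iqr_sdlog(24.0, 31.3)))
  }
}

#' Configuration for a virtual cohort
#'
#' @param n number of virtual patients (>= 1).
#' @param seed RNG seed (integer) making the cohort reproducible.
#' @param preset `"control"` (default) or `"intervention"`; sets both the
#'   diplotype mix and the covariate distributions unless overridden.
#' @param diplotype_freqs optional named probability vector overriding the
#'   preset mix (must sum to 1).
#' @param covariates optional list like `covariate_preset()`'s return value
#'   (log-normal `meanlog`/`sdlog` per covariate: age, height, bmi).
#' @param allele_table allele-activity table used to score diplotypes.
#' @param nonadherent_fraction fraction of patients taking effectively less
#'   drug than prescribed (default 0).
#' @param nonadherence_multiplier exposure multiplier applied to all
#'   concentrations of a non-adherent patient (default 0.5).
#' @param sample_days observation days for the generated samples
#'   (default c(35, 90): the mid 4-6-week visit and the steady-state visit).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n, seed = 1L, preset = c("control", "intervention"),
                          diplotype_freqs = NULL, covariates = NULL,
                          allele_table = default_allele_table(),
                          nonadherent_fraction = 0,
                          nonadherence_multiplier = 0.5,
                          sample_days = c(35, 90)) {
  preset <- match.arg(preset)
  if (n < 1) stop_domain("n must be >= 1")
  if (nonadherent_fraction < 0 || nonadherent_fraction > 1) {
    stop_domain("nonadherent_fraction must be in [0, 1]")
  }
  freqs <- diplotype_freqs %||% diplotype_preset(preset)
  if (abs(sum(freqs) - 1) > 1e-9) {
    stop_domain("diplotype frequencies must sum to 1 (got ", sum(freqs), ")")
  }
  if (any(sample_days < 0)) stop_domain("sample_days must be >= 0")
  structure(list(
    n = as.integer(n), seed = as.integer(seed), preset = preset,
    diplotype_freqs = freqs,
    covariates = covariates %||% covariate_preset(preset),
    allele_table = allele_table,
    nonadherent_fraction = nonadherent_fraction,
    nonadherence_multiplier = nonadherence_multiplier,
    sample_days = sample_days
  ), class = "cohort_config")
}

#' Generate a virtual patient cohort
#'
#' Draws diplotypes from the configured mix, covariates from log-normal
#' distributions matched to the cohort medians/IQRs (weight is derived from
#' BMI and height so the BMI distribution is the one controlled), an
#' individual deviation `eta ~ N(0, omega^2)`, and timed endoxifen
#' observations at the configured sample days under the standard 20 mg dose
#' with log-normal residual error (SD sigma). Non-adherent patients have all
#' concentrations multiplied by the configured exposure multiplier.
#' Identical config and seed give an identical cohort.
#'
#' @param config a [cohort_config()].
#' @param model a [pk_model()].
#' @return object of class `virtual_cohort`: a list with `patients` (one row
#'   per patient: covariates, diplotype, activity, bin, true_eta, adherent,
#'   css20_true), `observations` (long format: patient_id, day,
#'   concentration, dose), and the `config` and `model` used.
#' @export
generate_cohort <- function(config, model = pk_model()) {
  stopifnot(inherits(config, "cohort_config"), inherits(model, "pk_model"))
  set.seed(config$seed)
  n <- config$n
  dip <- sample(names(config$diplotype_freqs), n, replace = TRUE,
                prob = config$diplotype_freqs)
  activity <- activity_score(dip, config$allele_table)
  cv <- config$covariates
  age <- stats::rlnorm(n, cv$age$meanlog, cv$age$sdlog)
  height <- stats::rlnorm(n, cv$height$meanlog, cv$height$sdlog)
  bmi <- stats::rlnorm(n, cv$bmi$meanlog, cv$bmi$sdlog)
  weight <- bmi * (height / 100)^2
  eta <- stats::rnorm(n, 0, model$omega)
  adherent <- stats::runif(n) >= config$nonadherent_fraction
  patients <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = age, height = height, weight = weight, bmi = bmi,
    diplotype = dip, activity = activity, bin = assign_bin(activity),
    true_eta = eta, adherent = adherent,
    css20_true = predict_css(model, dose = 20, activity = activity,
                             eta = eta, age = age, bmi = bmi,
                             height = height),
    stringsAsFactors = FALSE
  )
  mult <- ifelse(adherent, 1, config$nonadherence_multiplier)
  obs <- do.call(rbind, lapply(config$sample_days, function(day) {
    conc <- patients$css20_true * accumulation_fraction(model, day) *
      exp(stats::rnorm(n, 0, model$sigma)) * mult
    data.frame(patient_id = patients$patient_id, day = day,
               concentration = conc, dose = 20,
               stringsAsFactors = FALSE)
  }))
  structure(list(patients = patients, observations = obs,
                 config = config, model = model),
            class = "virtual_cohort")
}

#' @export
print.virtual_cohort <- function(x, ...) {
  cat(sprintf("Virtual cohort: %d patients (preset '%s', seed %d)\n",
              nrow(x$patients), x$config$preset, x$config$seed))
  print(round(100 * table(x$patients$bin) / nrow(x$patients), 1))
  invisible(x)
}

#' Simulate a dosing-policy trial on a virtual cohort
#'
#' Generates a cohort from `config` and evaluates steady-state (day 90)
#' attainment of the endoxifen threshold under one of three policies:
#' \describe{
#'   \item{FIXED_20}{everyone receives 20 mg/day (the one-dose-fits-all
#'     comparator);}
#'   \item{MIPD}{each patient receives the dose recommended from the
#'     a-priori covariate prediction ([recommend_dose()]); patients in the
#'     SWITCH_AI category are treated at 40 mg;}
#'   \item{MIPD_WITH_UPDATE}{as MIPD, plus an empirical-Bayes update from a
#'     day-35 sample at the a-priori dose and re-dosing before the day-90
#'     evaluation.}
#' }
#' Patients are always *grouped* by their a-priori predicted category (or,
#' for the update policy, the updated category), so the comparator cohort
#' can be stratified the same way as an MIPD cohort. Attainment is reported
#' both as treated (SWITCH_AI patients evaluated on their 40 mg level) and
#' under the "switched" convention in which SWITCH_AI patients are counted
#' as attained because they would have left tamoxifen for an aromatase
#' inhibitor.
#'
#' The same config and seed produce the same patients and the same residual
#' draws under every policy, so policies are directly comparable.
#'
#' @param config a [cohort_config()].
#' @param model a [pk_model()].
#' @param policy `"MIPD"`, `"FIXED_20"` or `"MIPD_WITH_UPDATE"`.
#' @param threshold therapeutic threshold (nM).
#' @return object of class `trial_summary`: attainment overall (both
#'   conventions), per dose category and per activity bin, prediction
#'   metrics of the a-priori predictions against the day-90 observations,
#'   dose-increase detection statistics (update policy), and the per-patient
#'   data frame.
#' @export
simulate_trial <- function(config, model = pk_model(),
                           policy = c("MIPD", "FIXED_20", "MIPD_WITH_UPDATE"),
                           threshold = 16) {
  policy <- match.arg(policy)
  cohort <- generate_cohort(config, model)
  pat <- cohort$patients
  n <- nrow(pat)
  # residuals for the two trial visits, drawn once per seed (policy-neutral)
  eps35 <- stats::rnorm(n, 0, model$sigma)
  eps90 <- stats::rnorm(n, 0, model$sigma)
  mult <- ifelse(pat$adherent, 1, config$nonadherence_multiplier)

  css20_pred <- predict_css(model, dose = 20, activity = pat$activity,
                            eta = 0, age = pat$age, bmi = pat$bmi,
                            height = pat$height)
  apriori <- recommend_dose(css20_pred, threshold = threshold)
  administered <- if (policy == "FIXED_20") rep(20, n) else
    apriori$administered_dose

  final_cat <- apriori$category
  final_dose <- administered
  detection <- NULL
  if (policy == "MIPD_WITH_UPDATE") {
    obs35 <- pat$css20_true * (administered / 20) *
      accumulation_fraction(model, 35) * exp(eps35) * mult
    pred35 <- css20_pred * (administered / 20) *
      accumulation_fraction(model, 35)
    fit <- eta_map(log(obs35) - log(pred35), 1, model$omega, model$sigma)
    updated <- recommend_dose(css20_pred * exp(fit$eta_hat),
                              threshold = threshold)
    final_cat <- updated$category
    final_dose <- updated$administered_dose
    # detection: patients whose true steady state at the a-priori dose
    # misses the threshold, excluding those already flagged for a switch
    true90_apriori <- pat$css20_true * (administered / 20) *
      accumulation_fraction(model, 90)
    cand <- true90_apriori < threshold & apriori$category != "SWITCH_AI"
    moved_up <- as.integer(final_cat) > as.integer(apriori$category)
    detection <- list(n_candidates = sum(cand),
                      n_detected = sum(moved_up & cand),
                      fraction_detected = mean(moved_up[cand]))
  }

  obs90 <- pat$css20_true * (final_dose / 20) *
    accumulation_fraction(model, 90) * exp(eps90) * mult
  pred90 <- css20_pred * (final_dose / 20) * accumulation_fraction(model, 90)
  attained <- classify_attainment(obs90, threshold)
  attained_switch <- attained | final_cat == "SWITCH_AI"

  pat$css20_pred <- css20_pred
  pat$category <- final_cat
  pat$administered_dose <- final_dose
  pat$observed_day90 <- obs90
  pat$attained <- attained

  structure(list(
    policy = policy, n = n, threshold = threshold,
    attainment_pct = 100 * mean(attained),
    attainment_switch_counted_pct = 100 * mean(attained_switch),
    by_category = attainment_table(obs90, final_cat, threshold),
    by_bin = attainment_table(obs90, pat$bin, threshold),
    metrics = prediction_metrics(pred90, obs90),
    detection = detection,
    patients = pat
  ), class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("Simulated trial under policy %s (n = %d, threshold %g nM)\n",
              x$policy, x$n, x$threshold))
  cat(sprintf("  attainment at day 90 : %.1f %% (as treated)\n",
              round_half_up(x$attainment_pct, 1)))
  cat(sprintf("  switched counted     : %.1f %%\n",
              round_half_up(x$attainment_switch_counted_pct, 1)))
  cat("  sub-therapeutic by dose category:\n")
  print(x$by_category, row.names = FALSE)
  cat("  sub-therapeutic by CYP2D6 activity bin:\n")
  print(x$by_bin, row.names = FALSE)
  if (!is.null(x$detection)) {
    cat(sprintf("  dose-increase candidates detected by day-35 update: %d/%d (%.1f %%)\n",
                x$detection$n_detected, x$detection$n_candidates,
                100 * x$detection$fraction_detected))
  }
  invisible(x)
}
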