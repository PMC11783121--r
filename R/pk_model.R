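#' Steady-state endoxifen population model
#'
#' A log-linear covariate surrogate for the population-PK prediction of
#' steady-state endoxifen. The individual steady-state concentration at dose
#' \eqn{D} (mg/day) is
#' \deqn{C_{ss} = \frac{D}{20}\,\mathrm{tvc20}\,
#'   e^{\theta_{AS}(AS - AS_{ref})}
#'   (age/age_{ref})^{\theta_{age}}
#'   (BMI/BMI_{ref})^{\theta_{BMI}}
#'   (height/height_{ref})^{\theta_{height}} e^{\eta},}
#' with \eqn{\eta \sim N(0, \omega^2)} the individual log-scale deviation and
#' a log-normal residual of SD \eqn{\sigma} on any measured concentration.
#' Accumulation towards steady state is first-order with effective half-life
#' `t_half_acc` (days), so at time \eqn{t} the concentration is
#' \eqn{C_{ss}(1 - 2^{-t/t_{1/2}})}.
#'
#' Defaults are calibrated so that a standard-dose (20 mg) virtual cohort
#' drawn with [generate_cohort()] reproduces the target-attainment structure
#' reported for large tamoxifen TDM cohorts (about 78\% of patients at or
#' above 16 nM, with sub-therapeutic fractions per CYP2D6 activity bin of
#' roughly 95/30/7/4/0 percent from the lowest to the highest bin); see the
#' methods vignette for the calibration procedure.
#'
#' @param tvc20 typical steady-state endoxifen concentration (nM) at 20
#'   mg/day for the reference patient.
#' @param theta_as activity-score coefficient (log scale, per activity unit).
#' @param theta_age,theta_bmi,theta_height power-law covariate exponents.
#' @param ref_age,ref_bmi,ref_height,ref_as reference covariate values
#'   (cohort medians: 57 y, 26.2 kg/m2, 168 cm, activity 0.68).
#' @param omega between-patient SD of the individual deviation eta (log
#'   scale).
#' @param sigma residual SD of a measured concentration (log scale).
#' @param t_half_acc effective accumulation half-life (days).
#' @return object of class `pk_model`.
#' @examples
#' m <- pk_model()
#' predict_css(m) # reference patient at 20 mg -> tvc20
#' @export
pk_model <- function(tvc20 = 31.3, theta_as = 2.15,
                     theta_age = -0.2, theta_bmi = -0.3, theta_height = 0,
                     ref_age = 57, ref_bmi = 26.2, ref_height = 168,
                     ref_as = 0.68,
                     omega = 0.50, sigma = 0.20, t_half_acc = 14) {
  if (tvc20 <= 0) stop_domain("tvc20 must be > 0")
  if (omega < 0) stop_domain("omega must be >= 0")
  if (sigma <= 0) stop_domain("sigma must be > 0")
  if (t_half_acc <= 0) stop_domain("t_half_acc must be > 0")
  if (ref_age <= 0 || ref_bmi <= 0 || ref_height <= 0) {
    stop_domain("reference covariates must be > 0")
  }
  structure(list(
    tvc20 = tvc20, theta_as = theta_as,
    theta_age = theta_age, theta_bmi = theta_bmi, theta_height = theta_height,
    ref_age = ref_age, ref_bmi = ref_bmi, ref_height = ref_height,
    ref_as = ref_as, omega = omega, sigma = sigma, t_half_acc = t_half_acc
  ), class = "pk_model")
}

#' @export
print.pk_model <- function(x, ...) {
  cat("Steady-state endoxifen population model\n")
  cat(sprintf("  typical Css at 20 mg: %.1f nM (reference patient)\n", x$tvc20))
  cat(sprintf("  activity coefficient: %.2f per activity unit (log scale)\n",
              x$theta_as))
  cat(sprintf("  covariate exponents : age %.2f, BMI %.2f, height %.2f\n",
              x$theta_age, x$theta_bmi, x$theta_height))
  cat(sprintf("  reference covariates: %g y, %g kg/m2, %g cm, activity %g\n",
              x$ref_age, x$ref_bmi, x$ref_height, x$ref_as))
  cat(sprintf("  variability         : omega %.2f, sigma %.2f (log scale)\n",
              x$omega, x$sigma))
  cat(sprintf("  accumulation t1/2   : %g days\n", x$t_half_acc))
  invisible(x)
}

#' Predict individual steady-state endoxifen concentration
#'
#' @param model a [pk_model()].
#' @param dose tamoxifen dose in mg/day (> 0); predictions are exactly
#'   dose-proportional.
#' @param activity CYP2D6 activity score (see [activity_score()]).
#' @param eta individual log-scale deviation (0 = population prediction).
#' @param age,bmi,height patient covariates; default to the model's
#'   reference values. `bmi` may be supplied directly or derived from
#'   `weight` (kg) and `height` (cm).
#' @param weight optional body weight (kg), used only to derive `bmi`.
#' @return numeric vector of steady-state concentrations (nM).
#' @examples
#' m <- pk_model()
#' predict_css(m, dose = 40) / predict_css(m, dose = 20) # exactly 2
#' @export
predict_css <- function(model, dose = 20, activity = model$ref_as, eta = 0,
                        age = model$ref_age, bmi = NULL,
                        height = model$ref_height, weight = NULL) {
  stopifnot(inherits(model, "pk_model"))
  if (any(dose <= 0)) stop_domain("dose must be > 0")
  if (any(activity < 0)) stop_domain("activity score must be >= 0")
  if (is.null(bmi)) {
    bmi <- if (!is.null(weight)) weight / (height / 100)^2 else model$ref_bmi
  }
  if (any(age <= 0) || any(bmi <= 0) || any(height <= 0)) {
    stop_domain("covariates (age, bmi, height) must be > 0")
  }
  (dose / 20) * model$tvc20 *
    exp(model$theta_as * (activity - model$ref_as)) *
    (age / model$ref_age)^model$theta_age *
    (bmi / model$ref_bmi)^model$theta_bmi *
    (height / model$ref_height)^model$theta_height *
    exp(eta)
}

#' Fraction of steady state accumulated by a given time
#'
#' @param model a [pk_model()].
#' @param time days since treatment start (>= 0).
#' @return numeric in [0, 1): \eqn{1 - 2^{-t/t_{1/2}}}.
#' @export
accumulation_fraction <- function(model, time) {
  stopifnot(inherits(model, "pk_model"))
  if (any(time < 0)) stop_domain("time must be >= 0")
  1 - 2^(-time / model$t_half_acc)
}

#' Predict endoxifen concentration before steady state
#'
#' Steady-state prediction scaled by the accumulation fraction: 0 at
#' treatment start, half the steady-state level after one accumulation
#' half-life, and >= 98% of steady state by 3 months at the default
#' half-life of 14 days.
#'
#' @inheritParams predict_css
#' @param time days since treatment start (>= 0).
#' @return numeric vector of concentrations (nM).
#' @export
predict_concentration <- function(model, dose = 20, activity = model$ref_as,
                                  eta = 0, time,
                                  age = model$ref_age, bmi = NULL,
                                  height = model$ref_height, weight = NULL) {
  predict_css(model, dose, activity, eta, age, bmi, height, weight) *
    accumulation_fraction(model, time)
}

#' Convert endoxifen concentrations between nM and ng/mL
#'
#' Uses the molar mass of endoxifen (373.5 g/mol by default), under which
#' the 16 nM therapeutic threshold corresponds to 5.97 ng/mL.
#'
#' @param x concentrations (nM for `nm_to_ngml`, ng/mL for `ngml_to_nm`).
#' @param mw molar mass in g/mol.
#' @return converted concentrations.
#' @examples
#' nm_to_ngml(16) # 5.976
#' @export
nm_to_ngml <- function(x, mw = 373.5) {
  if (any(x < 0)) stop_domain("concentration must be >= 0")
  x * mw / 1000
}

#' @rdname nm_to_ngml
#' @export
ngml_to_nm <- function(x, mw = 373.5) {
  if (any(x < 0)) stop_domain("concentration must be >= 0")
  x * 1000 / mw
}
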