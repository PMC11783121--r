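# MAP estimate of eta from k residuals: with a normal prior N(0, omega^2) and
# log-normal residuals of SD sigma, the posterior mode is the shrunken mean
# residual. Shared by estimate_eta() and the vectorised trial simulator.
eta_map <- function(mean_residual, k, omega, sigma) {
  shrinkage <- omega^2 / (omega^2 + sigma^2 / k)
  list(eta_hat = shrinkage * mean_residual, shrinkage = shrinkage)
}

#' Empirical-Bayes estimate of the individual deviation
#'
#' Maximum-a-posteriori (MAP) estimate of a patient's log-scale deviation
#' \eqn{\eta} from one or more timed endoxifen observations. For a single
#' observation with log-residual \eqn{r = \log C_{obs} - \log \hat C(\eta=0)}
#' the posterior mode is available in closed form,
#' \deqn{\hat\eta = \frac{\omega^2}{\omega^2 + \sigma^2}\, r,}
#' and with \eqn{k} observations the residual variance shrinks to
#' \eqn{\sigma^2/k}. The estimate is deterministic.
#'
#' Samples drawn within the first 21 days of treatment lack informative
#' value; observations at or after `informative_cutoff` days (22 by default,
#' so the intended 4-6 week window qualifies) are used for the update, and
#' earlier samples are excluded unless `include_uninformative = TRUE`. When
#' *no* informative sample exists, the estimate falls back to all samples
#' and is flagged `informative = FALSE` with a warning rather than an error.
#'
#' @param model a [pk_model()].
#' @param observations data frame with columns `time` (days since treatment
#'   start, > 0), `concentration` (nM, > 0) and `dose` (mg/day at sampling).
#' @param activity CYP2D6 activity score of the patient.
#' @param age,bmi,height,weight patient covariates (see [predict_css()]).
#' @param informative_cutoff first informative day (default 22).
#' @param include_uninformative use pre-cutoff samples as well.
#' @return object of class `ebe_result`: `eta_hat`, `shrinkage`,
#'   `css20_updated` (nM, the re-predicted steady state at 20 mg),
#'   `informative`, `n_used`, `n_obs`, `residuals`.
#' @examples
#' m <- pk_model()
#' obs <- data.frame(time = 35, dose = 20,
#'                   concentration = predict_concentration(m, time = 35))
#' estimate_eta(m, obs)$eta_hat # 0: observation equals the prediction
#' @export
estimate_eta <- function(model, observations, activity = model$ref_as,
                         age = model$ref_age, bmi = NULL,
                         height = model$ref_height, weight = NULL,
                         informative_cutoff = 22,
                         include_uninformative = FALSE) {
  stopifnot(inherits(model, "pk_model"))
  obs <- as.data.frame(observations)
  need <- c("time", "concentration", "dose")
  if (!all(need %in% names(obs))) {
    stop_domain("observations need columns: ", paste(need, collapse = ", "))
  }
  if (nrow(obs) == 0) stop_domain("at least one observation is required")
  if (any(obs$concentration <= 0)) {
    stop_domain("observed concentration must be > 0")
  }
  if (any(obs$time <= 0)) stop_domain("observation time must be > 0 days")

  pred <- predict_concentration(model, dose = obs$dose, activity = activity,
                                eta = 0, time = obs$time,
                                age = age, bmi = bmi, height = height,
                                weight = weight)
  r <- log(obs$concentration) - log(pred)

  informative_obs <- obs$time >= informative_cutoff
  use <- if (include_uninformative) rep(TRUE, nrow(obs)) else informative_obs
  informative <- any(informative_obs)
  if (!any(use)) {
    warning("no sample at or after day ", informative_cutoff,
            ": update is advisory only (early samples lack informative value)",
            call. = FALSE)
    use <- rep(TRUE, nrow(obs))
  }

  # dose-corrected concentration dropping over time suggests non-adherence
  if (sum(use) >= 2) {
    o <- order(obs$time[use])
    dc <- (obs$concentration[use] / (obs$dose[use] / 20))[o]
    if (any(diff(dc) < 0)) {
      warning("dose-corrected concentration decreased between samples: ",
              "possible treatment non-adherence", call. = FALSE)
    }
  }

  fit <- eta_map(mean(r[use]), sum(use), model$omega, model$sigma)
  structure(list(
    eta_hat = fit$eta_hat,
    shrinkage = fit$shrinkage,
    css20_updated = predict_css(model, dose = 20, activity = activity,
                                eta = fit$eta_hat, age = age, bmi = bmi,
                                height = height, weight = weight),
    informative = informative,
    n_used = sum(use),
    n_obs = nrow(obs),
    residuals = r
  ), class = "ebe_result")
}

#' @export
print.ebe_result <- function(x, ...) {
  cat(sprintf("Empirical-Bayes update (%d of %d samples used)\n",
              x$n_used, x$n_obs))
  cat(sprintf("  eta_hat %.4f (shrinkage %.3f)\n", x$eta_hat, x$shrinkage))
  cat(sprintf("  updated Css at 20 mg: %.2f nM\n", x$css20_updated))
  if (!x$informative) cat("  advisory only: no informative sample (>= day 22)\n")
  invisible(x)
}

#' Re-recommend the dose from an empirical-Bayes update
#'
#' Applies [recommend_dose()] to the updated steady-state prediction. When
#' the update was based only on uninformative early samples the
#' recommendation is flagged `advisory = TRUE` and should not change dosing.
#'
#' @param ebe an `ebe_result` from [estimate_eta()].
#' @param threshold therapeutic threshold (nM).
#' @param margin optional threshold margin, see [recommend_dose()].
#' @return one-row data frame as from [recommend_dose()], with an extra
#'   `advisory` column.
#' @export
update_recommendation <- function(ebe, threshold = 16, margin = 0) {
  stopifnot(inherits(ebe, "ebe_result"))
  rec <- recommend_dose(ebe$css20_updated, threshold = threshold,
                        margin = margin)
  rec$advisory <- !ebe$informative
  rec
}
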