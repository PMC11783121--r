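#' Dose categories, lowest to highest
#'
#' `SWITCH_AI` (a recommendation to switch to an aromatase inhibitor because
#' even 40 mg tamoxifen is predicted insufficient) ranks above `D40`; such
#' patients are nevertheless *treated* at 40 mg/day when they stay on
#' tamoxifen, to evaluate their chance of reaching the target.
#'
#' @return character vector of category labels in increasing order.
#' @export
dose_categories <- function() c("D20", "D30", "D40", "SWITCH_AI")

#' A-priori tamoxifen dose recommendation
#'
#' Converts a predicted steady-state endoxifen concentration at the standard
#' 20 mg dose into the trial dose category. With effective threshold
#' \eqn{T = \mathrm{threshold}(1 + \mathrm{margin})} and dose-proportional
#' predictions, the lowest dose whose prediction reaches \eqn{T} is chosen
#' (ties at the boundary take the lower dose); if even 40 mg falls short the
#' recommendation is a switch to an aromatase inhibitor. With `margin = 0`
#' the category boundaries on `css20` are exactly 16, 32/3 and 8 nM.
#'
#' @param css20 predicted steady-state endoxifen (nM) at 20 mg/day (> 0).
#' @param threshold therapeutic endoxifen threshold in nM (default 16).
#' @param margin optional fractional safety margin on the threshold, in
#'   [0, 1). Off (0) by default; a model-error margin such as 0.186 can be
#'   supplied to demand predictions clear the threshold with headroom.
#' @param upper_threshold optional upper bound of the therapeutic window
#'   (nM); when set, predictions at the administered dose above it are
#'   flagged in an `overexposed` column. Disabled (`NULL`) by default.
#' @return data frame with one row per element of `css20`: `category`
#'   (factor, levels [dose_categories()]), `administered_dose` (mg/day; 40
#'   for SWITCH_AI), `predicted_css_at_administered` and `predicted_css_20`
#'   (nM), plus `overexposed` when `upper_threshold` is set.
#' @examples
#' recommend_dose(c(20, 8.01, 7.99))$category
#' @export
recommend_dose <- function(css20, threshold = 16, margin = 0,
                           upper_threshold = NULL) {
  if (any(!is.finite(css20)) || any(css20 <= 0)) {
    stop_domain("css20 must be finite and > 0")
  }
  if (threshold < 0) stop_domain("threshold must be >= 0")
  if (margin < 0 || margin >= 1) stop_domain("margin must be in [0, 1)")
  eff <- threshold * (1 + margin)
  category <- ifelse(css20 >= eff, "D20",
              ifelse(css20 * 1.5 >= eff, "D30",
              ifelse(css20 * 2 >= eff, "D40", "SWITCH_AI")))
  category <- factor(category, levels = dose_categories())
  administered <- c(D20 = 20, D30 = 30, D40 = 40, SWITCH_AI = 40)[
    as.character(category)]
  out <- data.frame(
    category = category,
    administered_dose = unname(administered),
    predicted_css_at_administered = css20 * administered / 20,
    predicted_css_20 = css20,
    row.names = NULL
  )
  if (!is.null(upper_threshold)) {
    out$overexposed <- out$predicted_css_at_administered > upper_threshold
  }
  out
}

#' Therapeutic target attainment
#'
#' An observed steady-state endoxifen level is therapeutic when it is at or
#' above the threshold (>= 16 nM by default; the comparison is inclusive).
#'
#' @param observed_css observed concentrations (nM, >= 0).
#' @param threshold therapeutic threshold (nM).
#' @return logical vector.
#' @examples
#' classify_attainment(c(16, 15.999)) # TRUE FALSE
#' @export
classify_attainment <- function(observed_css, threshold = 16) {
  if (any(observed_css < 0)) stop_domain("observed concentration must be >= 0")
  observed_css >= threshold
}
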