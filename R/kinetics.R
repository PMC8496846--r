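#' Dendritic-cell recruitment by mass-action kinetics
#'
#' The number of DCs newly recruited from circulation into islets in one
#' simulation step follows mass-action kinetics in the apoptotic beta-cell
#' count and the (constant) circulating DC count:
#' \deqn{DC_r|_{t=j+1} - DC_r|_{t=j} = k_r \, \beta_{AP}|_{t=j} \, DC_c}
#' The product is generally non-integer; by default a Poisson draw with that
#' mean is returned (preserving the expectation while adding demographic
#' noise); `rounding = "nearest"` gives deterministic rounding.
#'
#' @param k_r Recruitment rate (per apoptotic beta cell per circulating DC
#'   per hour); in a run it is drawn once from Normal(mu_r, sigma_r)
#'   truncated at zero.
#' @param beta_ap Apoptotic beta-cell count.
#' @param dc_c Circulating DC count.
#' @param rounding `"poisson"` (default) or `"nearest"`.
#' @return Integer count of DCs recruited this step.
#' @examples
#' dc_recruited(0.01, 200, 50, rounding = "nearest")  # 100
#' @export
dc_recruited <- function(k_r, beta_ap, dc_c, rounding = c("poisson", "nearest")) {
  rounding <- match.arg(rounding)
  if (any(c(k_r, beta_ap, dc_c) < 0)) stop("dc_recruited() inputs must be >= 0")
  mu <- k_r * beta_ap * dc_c
  if (rounding == "poisson") stats::rpois(1, mu) else round(mu)
}

#' Beta-cell quiescence period under glucose load
#'
#' Surviving beta cells re-enter the division cycle after a quiescence
#' period that shortens as the apoptotic fraction (a proxy for glucose load)
#' rises:
#' \deqn{T_{\beta i}|_{t=j} = (1 - \beta_{AP}|_{t=j} / \beta_{init})^\gamma
#'   \times T_{\beta i}|_{t=0}}
#' At 70 percent apoptotic cells and gamma = 1 the baseline 7-day period
#' shortens to about 2 days, matching the glucose-stimulated measurement.
#'
#' @param T0 Baseline quiescence period (hours; 168 by default in the model).
#' @param beta_ap Apoptotic beta-cell count.
#' @param beta_init Initial healthy beta-cell count (> 0).
#' @param gamma Glucose-metabolism exponent (>= 0).
#' @return Quiescence period in the units of `T0`; non-increasing in
#'   `beta_ap` and equal to `T0` at `beta_ap = 0`.
#' @examples
#' quiescence_period(168, 0.7 * 8080, 8080, 1)  # 50.4 h = 2.1 days
#' @export
quiescence_period <- function(T0, beta_ap, beta_init, gamma) {
  if (beta_init <= 0) stop("beta_init must be positive")
  if (any(beta_ap < 0) || any(beta_ap > beta_init))
    stop("beta_ap must lie in [0, beta_init]")
  if (gamma < 0) stop("gamma must be >= 0")
  (1 - beta_ap / beta_init)^gamma * T0
}

#' Estimate the glucose-metabolism exponent gamma
#'
#' Solves \eqn{T_0 (1 - f)^\gamma = T_{target}} for gamma and rounds to the
#' nearest integer. The model's calibration point — baseline 7 days, target
#' 2 days at apoptotic fraction 0.7 — gives gamma = 1.
#'
#' @param T0_days Baseline quiescence period (days).
#' @param target_days Observed shortened period (days), `0 < target <= T0`.
#' @param apoptotic_fraction Apoptotic fraction f in (0, 1).
#' @return Integer gamma.
#' @examples
#' estimate_gamma(7, 2, 0.7)    # 1
#' estimate_gamma(10, 2.5, 0.5) # 2
#' @export
estimate_gamma <- function(T0_days, target_days, apoptotic_fraction) {
  if (!(apoptotic_fraction > 0 && apoptotic_fraction < 1))
    stop("apoptotic_fraction must lie in (0, 1)")
  if (!(target_days > 0)) stop("target_days must be positive")
  if (target_days > T0_days)
    stop("target_days must not exceed T0_days (gamma would be negative)")
  as.integer(round(log(target_days / T0_days) / log(1 - apoptotic_fraction)))
}
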