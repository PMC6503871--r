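#' Re-express SEM-scale effects in years via Cohen's d
#'
#' Effects on the log epimutation burden are not directly comparable with
#' clock effects, which are in years. The two-step standardization first
#' divides the estimate (and its standard error) by the standard deviation
#' of the log-SEM outcome, giving a unitless Cohen's d, then multiplies by
#' the standard deviation of a reference clock's age acceleration (years):
#' `d = beta / sigma_outcome`, `beta_years = d * sigma_reference_years`.
#' Confidence limits transform by the same factor; the sigmas are treated
#' as known constants (no uncertainty propagation from their estimation —
#' a documented simplification).
#'
#' @param estimates `data.frame` with `beta` and `se` columns (per-cohort
#'   or pooled rows), or a single numeric `beta` with `se` supplied.
#' @param sigma_outcome Standard deviation of the (log) SEM outcome in the
#'   same data the estimate came from. Must be positive.
#' @param sigma_reference_years Standard deviation, in years, of the
#'   reference clock's age acceleration. Must be positive.
#' @param se Standard error(s), when `estimates` is a bare numeric vector.
#' @return For data-frame input, the input with added columns `cohen_d`,
#'   `se_d`, `beta_years`, `se_years`, `ci_lo_years`, `ci_hi_years`,
#'   `sigma_outcome`, `sigma_reference_years`; for numeric input, a one-row
#'   `data.frame` of the same columns.
#' @export
rescale_sem_effect <- function(estimates, sigma_outcome,
                               sigma_reference_years, se = NULL) {
  if (any(sigma_outcome <= 0)) stop("sigma_outcome must be positive")
  if (any(sigma_reference_years <= 0)) {
    stop("sigma_reference_years must be positive")
  }
  if (!is.data.frame(estimates)) {
    estimates <- data.frame(beta = estimates, se = se)
  }
  if (is.null(estimates$se)) stop("standard errors required")
  d <- estimates$beta / sigma_outcome
  se_d <- estimates$se / sigma_outcome
  z <- stats::qnorm(0.975)
  estimates$cohen_d <- d
  estimates$se_d <- se_d
  estimates$beta_years <- d * sigma_reference_years
  estimates$se_years <- se_d * sigma_reference_years
  estimates$ci_lo_years <- estimates$beta_years - z * estimates$se_years
  estimates$ci_hi_years <- estimates$beta_years + z * estimates$se_years
  estimates$sigma_outcome <- sigma_outcome
  estimates$sigma_reference_years <- sigma_reference_years
  estimates
}
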