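#' Mills ratio of the standard normal
#'
#' Computes `phi(w) / Phi(w)`, the hazard-type factor that appears in all
#' truncated-normal conditional expectations used by the conditionally
#' unbiased estimators. Evaluated on the log scale,
#' `exp(dnorm(w, log = TRUE) - pnorm(w, log.p = TRUE))`, which stays
#' accurate far into the lower tail where both numerator and denominator
#' underflow (R's log-scale `pnorm` switches to an asymptotic expansion
#' there). `mills_ratio(-Inf)` is `Inf`; `mills_ratio(Inf)` is `0`.
#'
#' @param w Numeric vector.
#' @return `phi(w)/Phi(w)`, same shape as `w`.
#' @examples
#' mills_ratio(0)            # dnorm(0)/0.5
#' mills_ratio(-40)          # ~ 40.02, no overflow
#' @export
mills_ratio <- function(w) {
  out <- exp(stats::dnorm(w, log = TRUE) - stats::pnorm(w, log.p = TRUE))
  out[w == Inf] <- 0
  out[w == -Inf] <- Inf
  out
}
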