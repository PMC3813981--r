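#' Conditioning statistics for the Rao-Blackwell estimators
#'
#' Computes the quantities through which the interim decision enters the
#' conditionally unbiased estimators:
#' * `B  = x_0 + b`: continuation requires the selected arm's stage-1 mean
#'   to reach `B`;
#' * `B1 = x_S - b`: equivalently, continuation caps the control's stage-1
#'   mean at `B1`;
#' * `x_second`: the second-largest experimental stage-1 mean, `X_(2)`
#'   (`-Inf` when `k = 1`, where the conditioning event degenerates to the
#'   futility gate alone);
#' * `m = max(B, x_second)`: the effective lower truncation point for the
#'   selected arm's stage-1 mean;
#' * `W_B = (Z_S,MLE - m) / sqrt((1 - t) * sigma1_sq)`: the standardised
#'   argument of the Mills-ratio correction. `sqrt((1 - t) * sigma1_sq)` is
#'   the conditional standard deviation of the stage-1 mean given the
#'   pooled mean, equal to `sigma1_sq / sqrt(sigma1_sq + sigma2_sq)`.
#'
#' @inheritParams pooled_means
#' @return An object of class `"asd_condstats"`: a list with `B`, `B1`,
#'   `x_second`, `m`, `W_B`, `z0_mle`, `zS_mle`, `tau` (the conditional SD).
#' @examples
#' d <- asd_design(k = 3, n1 = 71, n2 = 71, sigma = 6, b = 0)
#' tr <- asd_trial(c(-0.082, 0.413, 1.766, 1.567), 0.049, 1.451, d)
#' conditioning_stats(tr)  # B = -0.082, m = 1.567
#' @export
conditioning_stats <- function(trial) {
  .stop_if_stopped(trial)
  des <- trial$design
  z <- pooled_means(trial)
  x_second <- if (des$k >= 2L) max(trial$x[-c(1L, trial$S + 1L)]) else -Inf
  B <- trial$x[1L] + des$b
  tau <- sqrt((1 - des$t) * des$sigma1_sq)
  m <- max(B, x_second)
  structure(list(
    B = B,
    B1 = trial$x[trial$S + 1L] - des$b,
    x_second = x_second,
    m = m,
    W_B = (z[["zS_mle"]] - m) / tau,
    z0_mle = z[["z0_mle"]], zS_mle = z[["zS_mle"]],
    tau = tau
  ), class = "asd_condstats")
}

#' @export
print.asd_condstats <- function(x, ...) {
  cat(sprintf("Conditioning statistics: B = %g, B1 = %g, X_(2) = %g\n",
              x$B, x$B1, x$x_second))
  cat(sprintf("  truncation m = max(B, X_(2)) = %g;  W_B = %g\n", x$m, x$W_B))
  invisible(x)
}

#' Conditionally unbiased (UMVUE) estimate of the selected arm's mean
#'
#' Rao-Blackwellises the stage-2 mean `Y_S` (unbiased given selection and
#' continuation) by taking its expectation given the pooled mean
#' `Z_S,MLE`, the remaining stage-1 means and the conditioning event. Given
#' those statistics the event is exactly `X_S >= m` with
#' `m = max(B, X_(2))`, and `X_S | Z_S,MLE` is normal with mean `Z_S,MLE`
#' and variance `(1 - t) * sigma1_sq`, so the estimator has closed form
#'
#' `Z_S,CHN = Z_S,MLE - (t / (1 - t)) * tau * phi(W_B) / Phi(W_B)`,
#'
#' with `tau` and `W_B` as in [conditioning_stats()]. The Mills-ratio
#' correction is strictly positive for finite `W_B`, so the estimate always
#' shrinks the pooled mean downward, and it vanishes as
#' `Z_S,MLE - m -> Inf`. With no futility gate and unit-stage design
#' (`b = -Inf`, `sigma = 1`, `n1 = n2 = 1`) the formula reduces to the
#' classical Cohen-Sackrowitz two-stage UMVUE (see [cohen_sackrowitz()]).
#'
#' @inheritParams pooled_means
#' @return The mean estimate `zS_chn` (scalar).
#' @export
umvue_selected <- function(trial) {
  cs <- conditioning_stats(trial)
  t <- trial$design$t
  unname(cs$zS_mle - (t / (1 - t)) * cs$tau * mills_ratio(cs$W_B))
}

#' Conditionally unbiased (UMVUE) estimate of the control mean
#'
#' The control-side Rao-Blackwell step: given the experimental stage-1
#' means and the control's pooled mean `Z_0,MLE`, the continuation event is
#' exactly `X_0 <= B1` with `B1 = x_S - b`, truncating the control's
#' stage-1 mean from above. The resulting estimator,
#'
#' `Z_0,CHN = Z_0,MLE + (t / (1 - t)) * tau * phi(W) / Phi(W)`,
#' `W = (B1 - Z_0,MLE) / tau`,
#'
#' corrects the pooled control mean upward (continuation favours low
#' control means). With `b = -Inf` the truncation deactivates and
#' `Z_0,CHN` equals `Z_0,MLE` exactly.
#'
#' @inheritParams pooled_means
#' @return The mean estimate `z0_chn` (scalar).
#' @export
umvue_control <- function(trial) {
  .stop_if_stopped(trial)
  des <- trial$design
  z0 <- pooled_means(trial)[["z0_mle"]]
  if (is.infinite(des$b) && des$b < 0) return(z0)   # exact reduction, no gate
  tau <- sqrt((1 - des$t) * des$sigma1_sq)
  B1 <- trial$x[trial$S + 1L] - des$b
  z0 + (des$t / (1 - des$t)) * tau * mills_ratio((B1 - z0) / tau)
}

#' Conditionally unbiased estimate of the selected treatment difference
#'
#' The difference of the two conditional UMVUEs,
#' `D_S,CHN = Z_S,CHN - Z_0,CHN`, unbiased for `theta_S = mu_S - mu_0`
#' conditional on the selected arm and on the trial continuing to stage 2.
#'
#' @inheritParams pooled_means
#' @return The difference estimate (scalar).
#' @export
unbiased_estimate <- function(trial) {
  umvue_selected(trial) - umvue_control(trial)
}

#' Single-arm (k = 1) conditional UMVUE after a futility gate
#'
#' For a trial with one experimental arm there is no selection, only the
#' futility gate, and the UMVUE takes the same Mills-ratio form with the
#' truncation point equal to the boundary itself. With `scale = "mean"`
#' (no control arm) the statistic is the pooled sample mean and the
#' boundary `B` is on the mean scale, with stage variances
#' `sigma^2 / n1`, `sigma^2 / n2`. With `scale = "difference"` the
#' statistic is the pooled treatment-minus-control difference and the
#' boundary is on the difference scale; the stage variances double to
#' `2 * sigma^2 / n_j`. Equivalent to the (corrected) Koopmeiners-type
#' single-arm estimator.
#'
#' @param zS_mle Pooled estimate (mean or difference per `scale`).
#' @param design An [asd_design()] with `k = 1`; `design$b` is the
#'   boundary `B` on the chosen scale (`-Inf` for no truncation).
#' @param scale `"mean"` (single arm, no control) or `"difference"`.
#' @return The corrected estimate (scalar).
#' @export
umvue_k1 <- function(zS_mle, design, scale = c("mean", "difference")) {
  stopifnot(inherits(design, "asd_design"))
  scale <- match.arg(scale)
  if (design$k != 1L) stop("'umvue_k1' requires a design with k = 1", call. = FALSE)
  mult <- if (scale == "difference") 2 else 1
  tau <- sqrt((1 - design$t) * mult * design$sigma1_sq)
  zS_mle - (design$t / (1 - design$t)) * tau * mills_ratio((zS_mle - design$b) / tau)
}

#' Cohen-Sackrowitz two-stage UMVUE (unit-variance reference form)
#'
#' The classical conditionally unbiased estimator of the selected mean for
#' the drop-the-losers design with one observation per stage and unit
#' variance (`X_i, Y ~ N(mu, 1)`), always continuing to stage 2:
#'
#' `z - (1/sqrt(2)) * phi(sqrt(2) * (z - x2)) / Phi(sqrt(2) * (z - x2))`,
#'
#' where `z = (X_(1) + Y) / 2` and `x2 = X_(2)`. Coded directly from this
#' published closed form (independently of [umvue_selected()]) so that the
#' stated reduction of the general estimator can be asserted against it.
#'
#' @param z Pooled mean `(X_(1) + Y) / 2`.
#' @param x_second Second-largest stage-1 value `X_(2)`.
#' @return The estimate (vectorised over `z`/`x_second`).
#' @export
cohen_sackrowitz <- function(z, x_second) {
  w <- sqrt(2) * (z - x_second)
  z - (1 / sqrt(2)) * mills_ratio(w)
}
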