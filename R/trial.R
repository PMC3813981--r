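#' Interim selection and futility gate
#'
#' Applies the stage-1 decision rule: the experimental arm with the largest
#' stage-1 sample mean is selected (ties broken towards the lowest arm
#' index, a fixed deterministic rule; ties have probability zero under the
#' continuous model), and the trial continues to stage 2 if the selected
#' arm beats the control by at least the futility boundary,
#' `x_S - x_0 >= b` (non-strict).
#'
#' @param x Numeric vector of stage-1 sample means, `length k + 1`; entry 1
#'   is the control, entries `2..(k+1)` the experimental arms.
#' @param design An [asd_design()].
#' @return A list with `S` (selected arm index in `1..k`) and `continued`
#'   (logical).
#' @examples
#' d <- asd_design(k = 3, n1 = 71, n2 = 71, sigma = 6, b = 0)
#' select_and_gate(c(-0.082, 0.413, 1.766, 1.567), d)  # S = 2, continued
#' @export
select_and_gate <- function(x, design) {
  stopifnot(inherits(design, "asd_design"))
  if (length(x) != design$k + 1L)
    stop(sprintf("'x' must have k + 1 = %d entries (control first)", design$k + 1L), call. = FALSE)
  if (!all(is.finite(x))) stop("stage-1 means must all be finite", call. = FALSE)
  S <- which.max(x[-1L])               # ties -> lowest index
  list(S = as.integer(S), continued = (x[S + 1L] - x[1L] >= design$b))
}

#' Observed data from a seamless phase II/III trial
#'
#' Arm-level sample means are sufficient under the known-variance normal
#' model, so a trial is recorded as its stage-1 mean vector plus, when the
#' trial passed the futility gate, the stage-2 means of the selected arm
#' and the control. Selection and continuation are recomputed from `x` and
#' must be consistent with the supplied stage-2 data.
#'
#' @param x Stage-1 sample means, control first (`length k + 1`).
#' @param y0,yS Stage-2 sample means for control and selected arm; supply
#'   both exactly when the trial continued, and neither when it stopped.
#' @param design An [asd_design()].
#' @return An object of class `"asd_trial"` with fields `x`, `S`,
#'   `continued`, `y0`, `yS`, `design`.
#' @examples
#' d <- asd_design(k = 3, n1 = 71, n2 = 71, sigma = 6, b = 0)
#' asd_trial(c(-0.082, 0.413, 1.766, 1.567), y0 = 0.049, yS = 1.451, d)
#' @export
asd_trial <- function(x, y0 = NULL, yS = NULL, design) {
  sel <- select_and_gate(x, design)
  if (sel$continued) {
    if (is.null(y0) || is.null(yS))
      stop("trial continued to stage 2: 'y0' and 'yS' are required", call. = FALSE)
    if (!is.finite(y0) || !is.finite(yS) || length(y0) != 1L || length(yS) != 1L)
      stop("'y0' and 'yS' must be single finite numbers", call. = FALSE)
  } else if (!is.null(y0) || !is.null(yS)) {
    stop("trial stopped for futility at stage 1: stage-2 means must be absent", call. = FALSE)
  }
  new_asd_trial(as.numeric(x), sel$S, sel$continued,
                if (sel$continued) as.numeric(y0) else NULL,
                if (sel$continued) as.numeric(yS) else NULL, design)
}

# fast internal constructor (no validation) used by the simulator/oracle
new_asd_trial <- function(x, S, continued, y0, yS, design) {
  structure(list(x = x, S = S, continued = continued, y0 = y0, yS = yS,
                 design = design), class = "asd_trial")
}

#' @export
print.asd_trial <- function(x, ...) {
  cat(sprintf("Seamless-trial data (k = %d):\n", x$design$k))
  cat("  stage-1 means (control first):", paste(format(x$x), collapse = ", "), "\n")
  if (x$continued)
    cat(sprintf("  selected arm S = %d; continued; stage-2 means y0 = %g, yS = %g\n",
                x$S, x$y0, x$yS))
  else
    cat(sprintf("  selected arm S = %d; stopped for futility at stage 1\n", x$S))
  invisible(x)
}

.stop_if_stopped <- function(trial) {
  stopifnot(inherits(trial, "asd_trial"))
  if (!trial$continued)
    stop("trial stopped for futility at stage 1: no stage-2 estimate is defined",
         call. = FALSE)
}

#' Pooled (maximum-likelihood) means for the two continuing arms
#'
#' The per-arm MLE pools the stage means at the selection time:
#' `Z_MLE = t * X + (1 - t) * Y` with `t = n1 / (n1 + n2)`.
#'
#' @param trial An [asd_trial()] that continued to stage 2.
#' @return Named numeric vector `c(z0_mle, zS_mle)`.
#' @export
pooled_means <- function(trial) {
  .stop_if_stopped(trial)
  t <- trial$design$t
  c(z0_mle = t * trial$x[1L] + (1 - t) * trial$y0,
    zS_mle = t * trial$x[trial$S + 1L] + (1 - t) * trial$yS)
}

#' Naive maximum-likelihood estimate of the selected-arm difference
#'
#' The pooled-mean difference `Z_S,MLE - Z_0,MLE`, ignoring both the
#' interim selection and the futility gate. Conditional on continuation it
#' is positively biased for the selected difference.
#'
#' @inheritParams pooled_means
#' @return The difference estimate (scalar).
#' @export
naive_estimate <- function(trial) {
  z <- pooled_means(trial)
  unname(z[2L] - z[1L])
}

#' Stage-2-only estimate of the selected-arm difference
#'
#' `y_S - y_0`, using stage-2 data alone. Because selection and the
#' futility decision use only stage-1 data, this estimator is exactly
#' unbiased conditional on the selected arm and on continuation, at the
#' price of discarding all stage-1 information.
#'
#' @inheritParams pooled_means
#' @return The difference estimate (scalar).
#' @export
stage2_estimate <- function(trial) {
  .stop_if_stopped(trial)
  trial$yS - trial$y0
}

#' Naive MLE vector for all k treatment differences
#'
#' Entry `S` is the pooled-mean difference [naive_estimate()]; dropped arms
#' have stage-1 data only, so their entries are the stage-1 differences
#' `x_i - x_0`.
#'
#' @inheritParams pooled_means
#' @return Numeric vector of length `k`.
#' @export
naive_vector <- function(trial) {
  .stop_if_stopped(trial)
  out <- trial$x[-1L] - trial$x[1L]
  out[trial$S] <- naive_estimate(trial)
  out
}
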