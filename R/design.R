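#' Trial design for a two-stage seamless phase II/III trial
#'
#' Fixes the quantities that define a drop-the-losers adaptive seamless
#' design: `k` experimental arms plus a shared control, per-arm stage sample
#' sizes `n1` and `n2`, a known common outcome standard deviation `sigma`,
#' and a futility boundary `b` on the stage-1 selected-vs-control difference.
#' Allocation is equal across arms within each stage; the selected arm and
#' the control each receive `n2` further subjects in stage 2.
#'
#' Derived constants are stored alongside the inputs:
#' * `t = n1 / (n1 + n2)`, the selection time (fraction of the final
#'   per-arm information available at the interim analysis);
#' * `sigma1_sq = sigma^2 / n1`, the variance of a stage-1 arm mean;
#' * `sigma2_sq = sigma^2 / n2`, the variance of a stage-2 arm mean;
#' * `se_unit = sqrt(2 * sigma^2 / (n1 + n2))`, the standard deviation of a
#'   single treatment-minus-control difference estimator pooled over both
#'   stages, used as the reporting unit for bias and root-MSE.
#'
#' @param k Number of experimental arms (integer, `k >= 1`).
#' @param n1,n2 Per-arm sample sizes in stages 1 and 2 (scalars; passing a
#'   vector, i.e. unequal allocation, is an error).
#' @param sigma Known common outcome standard deviation (`> 0`).
#' @param b Futility boundary on the stage-1 difference scale. `-Inf`
#'   (the default) disables the futility gate.
#' @return An object of class `"asd_design"`.
#' @examples
#' asd_design(k = 3, n1 = 71, n2 = 71, sigma = 6, b = 0)
#' @export
asd_design <- function(k, n1, n2, sigma, b = -Inf) {
  for (nm in c("k", "n1", "n2", "sigma")) {
    v <- get(nm)
    if (length(v) != 1L || !is.numeric(v) || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number%s", nm,
                   if (nm %in% c("n1", "n2"))
                     " (equal per-arm allocation within each stage)" else ""),
           call. = FALSE)
  }
  if (k < 1 || k != round(k)) stop("'k' must be an integer >= 1", call. = FALSE)
  if (n1 < 1 || n1 != round(n1)) stop("'n1' must be an integer >= 1", call. = FALSE)
  if (n2 < 1 || n2 != round(n2)) stop("'n2' must be an integer >= 1", call. = FALSE)
  if (sigma <= 0) stop("'sigma' must be > 0", call. = FALSE)
  if (length(b) != 1L || !is.numeric(b) || is.na(b) || b == Inf)
    stop("'b' must be a single number or -Inf (no futility gate)", call. = FALSE)

  t <- n1 / (n1 + n2)
  out <- structure(list(
    k = as.integer(k), n1 = as.integer(n1), n2 = as.integer(n2),
    sigma = as.numeric(sigma), b = as.numeric(b),
    t = t,
    sigma1_sq = sigma^2 / n1,
    sigma2_sq = sigma^2 / n2,
    se_unit = sqrt(2 * sigma^2 / (n1 + n2))
  ), class = "asd_design")
  stopifnot(abs(out$se_unit^2 - 2 * sigma^2 / (n1 + n2)) < 1e-12 * sigma^2,
            out$t > 0, out$t < 1)
  out
}

#' @export
print.asd_design <- function(x, ...) {
  cat(sprintf("Two-stage seamless design: k = %d experimental arms + control\n", x$k))
  cat(sprintf("  n1 = %d, n2 = %d per arm;  selection time t = %.4g\n", x$n1, x$n2, x$t))
  cat(sprintf("  sigma = %g (known);  futility boundary b = %s\n", x$sigma,
              if (is.infinite(x$b)) "-Inf (no gate)" else format(x$b)))
  cat(sprintf("  SE unit sqrt(2*sigma^2/(n1+n2)) = %.6g\n", x$se_unit))
  invisible(x)
}

#' True mean configuration
#'
#' Bundles the control mean `mu0` and the experimental-arm means
#' `mu = (mu_1, ..., mu_k)`; the treatment differences
#' `theta_i = mu_i - mu0` are derived and stored.
#'
#' @param mu0 Control mean.
#' @param mu Numeric vector of experimental-arm means (length `k`).
#' @return An object of class `"asd_truth"` with fields `mu0`, `mu`, `theta`.
#' @examples
#' parameter_vector(0, c(0.8, 1.5, 2.6))
#' @export
parameter_vector <- function(mu0, mu) {
  if (length(mu0) != 1L || !is.finite(mu0)) stop("'mu0' must be a single finite number", call. = FALSE)
  if (length(mu) < 1L || !all(is.finite(mu))) stop("'mu' must be a finite vector of length k >= 1", call. = FALSE)
  structure(list(mu0 = as.numeric(mu0), mu = as.numeric(mu),
                 theta = as.numeric(mu) - as.numeric(mu0)),
            class = "asd_truth")
}

#' @export
print.asd_truth <- function(x, ...) {
  cat("True means: mu0 =", x$mu0, "; mu =", paste(format(x$mu), collapse = ", "), "\n")
  cat("Differences theta =", paste(format(x$theta), collapse = ", "), "\n")
  invisible(x)
}
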