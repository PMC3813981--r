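#' Monte-Carlo conditional expectation of a trial-level statistic
#'
#' Plain brute-force oracle: simulates trials, keeps exactly `n` that
#' continue to stage 2 (optionally restricted to a given selected arm),
#' applies `statistic` to each, and returns the Monte-Carlo mean with its
#' standard error. No variance reduction on purpose — the oracle's only
#' virtue is being trivially correct, which is what lets it arbitrate the
#' analytic estimators and bias integrals.
#'
#' The oracle draws from an RNG stream offset from `seed` so that oracle
#' runs never share a stream with simulator runs at the same seed.
#'
#' @param statistic Function mapping an `"asd_trial"` to a single number
#'   (e.g. [unbiased_estimate()], [naive_estimate()]).
#' @param truth A [parameter_vector()].
#' @param design An [asd_design()].
#' @param n Number of conditional replicates (`>= 1000`).
#' @param seed RNG seed.
#' @param arm Optional: restrict to trials with `S == arm`.
#' @param target Optional label stored in the result.
#' @param max_attempts Cap on total simulated trials.
#' @return An object of class `"asd_oracle"`: list with `estimate`,
#'   `mc_se`, `n_used`, `target`.
#' @examples
#' \donttest{
#' d <- asd_design(k = 2, n1 = 50, n2 = 50, sigma = 1, b = 0)
#' mc_conditional_mean(stage2_estimate, parameter_vector(0, c(0.1, 0.3)),
#'                     d, n = 2000, seed = 7, arm = 2)
#' }
#' @export
mc_conditional_mean <- function(statistic, truth, design, n = 1e5, seed = 1L,
                                arm = NULL, target = NULL, max_attempts = 1e9) {
  stopifnot(is.function(statistic), inherits(truth, "asd_truth"),
            inherits(design, "asd_design"), n >= 1000)
  if (!is.null(arm)) stopifnot(arm %in% seq_len(design$k))
  set.seed(.oracle_seed(seed))
  draws <- .rcond(truth, design, n, arm = arm, max_attempts = max_attempts)
  vals <- vapply(seq_len(n), function(i) {
    statistic(new_asd_trial(draws$X[i, ], draws$S[i], TRUE,
                            draws$y0[i], draws$yS[i], design))
  }, numeric(1))
  structure(list(estimate = mean(vals), mc_se = stats::sd(vals) / sqrt(n),
                 n_used = as.integer(n),
                 target = if (is.null(target)) deparse(substitute(statistic)) else target),
            class = "asd_oracle")
}

# oracle runs use a different stream family than the simulator
.oracle_seed <- function(seed) (as.numeric(seed) * 69069 + 12345) %% 2147483647

#' @export
print.asd_oracle <- function(x, ...) {
  cat(sprintf("MC oracle [%s]: %.6g (MC SE %.3g, n = %d)\n",
              x$target, x$estimate, x$mc_se, x$n_used))
  invisible(x)
}

#' Monte-Carlo histogram of the selection event
#'
#' Bins the joint outcome `(S, D_S)` over `n` unconditional simulated
#' trials (no futility conditioning — the selection density is a stage-1
#' object). The per-bin relative frequencies, with binomial Monte-Carlo
#' SEs, are the brute-force comparison target for the integrated analytic
#' [selection_density()].
#'
#' @inheritParams mc_conditional_mean
#' @param breaks Numeric vector of bin edges for the selected stage-1
#'   difference `D_S` (values outside the range are dropped into none of
#'   the bins but still counted in the denominator).
#' @return An object of class `"asd_selhist"`: list with `freq` and
#'   `mc_se` (arm x bin matrices), `breaks`, `n`.
#' @export
mc_selection_histogram <- function(truth, design, breaks, n = 1e5, seed = 1L) {
  stopifnot(inherits(truth, "asd_truth"), inherits(design, "asd_design"),
            length(breaks) >= 2, !is.unsorted(breaks))
  k <- design$k
  set.seed(.oracle_seed(seed))
  s1 <- sqrt(design$sigma1_sq)
  X <- matrix(stats::rnorm(n * (k + 1L), mean = rep(c(truth$mu0, truth$mu), each = n),
                           sd = s1), n, k + 1L)
  S <- max.col(X[, -1L, drop = FALSE], ties.method = "first")
  D <- X[cbind(seq_len(n), S + 1L)] - X[, 1L]
  nb <- length(breaks) - 1L
  freq <- matrix(0, k, nb,
                 dimnames = list(arm = seq_len(k),
                                 bin = paste0("[", utils::head(breaks, -1L), ",",
                                              breaks[-1L], ")")))
  bin <- findInterval(D, breaks, rightmost.closed = TRUE)
  ok <- bin >= 1L & bin <= nb
  for (a in seq_len(k)) {
    tb <- tabulate(bin[ok & S == a], nbins = nb)
    freq[a, ] <- tb / n
  }
  structure(list(freq = freq, mc_se = sqrt(freq * (1 - freq) / n),
                 breaks = breaks, n = as.integer(n)),
            class = "asd_selhist")
}

#' @export
print.asd_selhist <- function(x, ...) {
  cat(sprintf("Selection histogram over %d draws (frequencies):\n", x$n))
  print(round(x$freq, 4))
  invisible(x)
}
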