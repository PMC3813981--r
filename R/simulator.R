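#' Simulate one seamless trial
#'
#' Draws stage-1 arm means as independent normals with variance
#' `sigma^2 / n1`, applies the selection-and-futility rule, and, when the
#' trial continues, draws stage-2 means for the selected arm and control
#' with variance `sigma^2 / n2`. Uses the current RNG state, so results
#' are reproducible under [set.seed()].
#'
#' @param truth A [parameter_vector()] with `length(mu) == design$k`.
#' @param design An [asd_design()].
#' @return An `"asd_trial"` (possibly stopped at stage 1).
#' @examples
#' set.seed(1)
#' simulate_trial(parameter_vector(0, c(0.05, 0.05)),
#'                asd_design(k = 2, n1 = 50, n2 = 50, sigma = 1, b = 0))
#' @export
simulate_trial <- function(truth, design) {
  stopifnot(inherits(truth, "asd_truth"), inherits(design, "asd_design"),
            length(truth$mu) == design$k)
  x <- stats::rnorm(design$k + 1L, c(truth$mu0, truth$mu), sqrt(design$sigma1_sq))
  sel <- select_and_gate(x, design)
  if (!sel$continued)
    return(new_asd_trial(x, sel$S, FALSE, NULL, NULL, design))
  y <- stats::rnorm(2L, c(truth$mu0, truth$mu[sel$S]), sqrt(design$sigma2_sq))
  new_asd_trial(x, sel$S, TRUE, y[1L], y[2L], design)
}

# Vectorised rejection sampler: exactly n continuing trials (optionally
# restricted to S == arm). Returns arm-mean matrices, not trial objects.
.rcond <- function(truth, design, n, arm = NULL, max_attempts = 1e9) {
  k <- design$k
  s1 <- sqrt(design$sigma1_sq); s2 <- sqrt(design$sigma2_sq)
  got <- 0L; attempts <- 0
  X <- matrix(NA_real_, n, k + 1L); S <- integer(n)
  y0 <- numeric(n); yS <- numeric(n)
  batch <- max(1000L, 2L * n)
  while (got < n) {
    if (attempts >= max_attempts)
      stop(sprintf("attempt cap reached (%g draws) with only %d of %d continuing trials; Pr(continue) may be ~0",
                   max_attempts, got, n), call. = FALSE)
    m <- min(batch, ceiling(max_attempts - attempts))
    xb <- matrix(stats::rnorm(m * (k + 1L), mean = rep(c(truth$mu0, truth$mu), each = m),
                              sd = s1), m, k + 1L)
    Sb <- max.col(xb[, -1L, drop = FALSE], ties.method = "first")
    xs <- xb[cbind(seq_len(m), Sb + 1L)]
    keep <- (xs - xb[, 1L]) >= design$b
    if (!is.null(arm)) keep <- keep & (Sb == arm)
    idx <- which(keep)
    # count attempts only up to the draw that yields the last needed keeper
    attempts <- attempts + if (length(idx) > n - got) idx[n - got] else m
    if (length(idx)) {
      take <- idx[seq_len(min(length(idx), n - got))]
      rows <- got + seq_along(take)
      X[rows, ] <- xb[take, , drop = FALSE]
      S[rows] <- Sb[take]
      y0[rows] <- stats::rnorm(length(take), truth$mu0, s2)
      yS[rows] <- stats::rnorm(length(take), truth$mu[S[rows]], s2)
      got <- got + length(take)
    }
  }
  list(X = X, S = S, y0 = y0, yS = yS, attempts = attempts)
}

# Vectorised estimator evaluation on .rcond output.
.estimates_batch <- function(draws, design, estimators, solver) {
  t <- design$t; k <- design$k; b <- design$b
  x0 <- draws$X[, 1L]
  xexp <- draws$X[, -1L, drop = FALSE]
  n <- nrow(xexp)
  xs <- xexp[cbind(seq_len(n), draws$S)]
  z0 <- t * x0 + (1 - t) * draws$y0
  zS <- t * xs + (1 - t) * draws$yS
  out <- list()
  if ("naive" %in% estimators) out$naive <- zS - z0
  if ("stage2" %in% estimators) out$stage2 <- draws$yS - draws$y0
  if ("unbiased" %in% estimators) {
    tau <- sqrt((1 - t) * design$sigma1_sq)
    if (k >= 2L) {
      xm <- xexp; xm[cbind(seq_len(n), draws$S)] <- -Inf
      x2 <- do.call(pmax, as.data.frame(xm))
    } else x2 <- rep(-Inf, n)
    m <- pmax(x0 + b, x2)
    zS_chn <- zS - (t / (1 - t)) * tau * mills_ratio((zS - m) / tau)
    z0_chn <- if (is.infinite(b) && b < 0) z0 else
      z0 + (t / (1 - t)) * tau * mills_ratio((xs - b - z0) / tau)
    out$unbiased <- zS_chn - z0_chn
    out$zS_chn <- zS_chn
    out$z0_chn <- z0_chn
  }
  if ("bias_adjusted" %in% estimators) {
    th_mle <- xexp - x0
    th_mle[cbind(seq_len(n), draws$S)] <- zS - z0
    fit <- .bias_adjust_batch(th_mle, draws$S, design, solver)
    out$bias_adjusted <- fit$estimate
    out$stl_iterations <- fit$iterations
  }
  out
}

#' Specification of one simulation cell
#'
#' Describes a conditional simulation at one design point: true means,
#' outcome SD, total per-arm sample size split at selection time `t`, a
#' futility boundary, and the number of continuing replicates to retain
#' (the study-condition default is 10,000). `n1` is `round(t * n_total)`;
#' the realised selection time is stored in the derived design.
#'
#' @param truth A [parameter_vector()].
#' @param sigma Known outcome SD (default 1, the standardised-effect
#'   scale).
#' @param n_total Per-arm total sample size across both stages (default
#'   100).
#' @param t Selection time in (0, 1).
#' @param b Futility boundary (`-Inf` disables the gate).
#' @param n_continuing Continuing replicates to retain (default 10000).
#' @param seed RNG seed for the cell.
#' @param max_attempts Cap on total simulated trials before giving up.
#' @return An object of class `"asd_simspec"` with the derived
#'   [asd_design()] in `$design`.
#' @export
sim_spec <- function(truth, sigma = 1, n_total = 100, t = 0.5, b = -Inf,
                     n_continuing = 10000, seed = 1L, max_attempts = 1e9) {
  stopifnot(inherits(truth, "asd_truth"), n_continuing >= 1,
            t > 0, t < 1, n_total >= 2)
  n1 <- round(t * n_total)
  if (n1 < 1 || n1 > n_total - 1)
    stop("'t' and 'n_total' give an empty stage; need 1 <= round(t * n_total) <= n_total - 1",
         call. = FALSE)
  design <- asd_design(k = length(truth$mu), n1 = n1, n2 = n_total - n1,
                       sigma = sigma, b = b)
  structure(list(truth = truth, design = design, t_nominal = t,
                 n_continuing = as.integer(n_continuing),
                 seed = as.integer(seed), max_attempts = max_attempts),
            class = "asd_simspec")
}

#' Conditional operating characteristics at one design point
#'
#' Rejection-samples trials until `n_continuing` continuing replicates are
#' collected, evaluates the requested estimators on each, and summarises
#' the conditional bias and root-MSE (raw and in SE units,
#' `se_unit = sqrt(2 sigma^2 / (n1 + n2))`) with Monte-Carlo standard
#' errors, plus the probability summaries: `Pr(continue)`,
#' `Pr(S = i | continue)` and `Pr(S = i, all other differences >= b |
#' continue)`.
#'
#' @param spec A [sim_spec()].
#' @param estimators Subset of
#'   `c("naive", "stage2", "unbiased", "bias_adjusted")`.
#' @param solver An [solver_config()] (used by the bias-adjusted solve).
#' @return An object of class `"asd_sim_summary"`: list with `estimates`
#'   (one row per estimator: bias, rmse, their MC SEs, and SE-unit
#'   versions), `probs`, `n_continuing`, `attempts`, `design`.
#' @export
run_conditional <- function(spec, estimators = c("naive", "stage2", "unbiased",
                                                 "bias_adjusted"),
                            solver = solver_config()) {
  stopifnot(inherits(spec, "asd_simspec"))
  estimators <- match.arg(estimators, several.ok = TRUE)
  design <- spec$design
  set.seed(spec$seed)
  draws <- .rcond(spec$truth, design, spec$n_continuing,
                  max_attempts = spec$max_attempts)
  est <- .estimates_batch(draws, design, estimators, solver)
  theta_S <- spec$truth$theta[draws$S]
  n <- spec$n_continuing
  rows <- lapply(estimators, function(e) {
    err <- est[[e]] - theta_S
    bias <- mean(err); rmse <- sqrt(mean(err^2))
    bias_se <- stats::sd(err) / sqrt(n)
    rmse_se <- stats::sd(err^2) / (2 * rmse * sqrt(n))
    data.frame(estimator = e, bias = bias, bias_se = bias_se,
               rmse = rmse, rmse_se = rmse_se,
               bias_se_units = bias / design$se_unit,
               bias_se_units_se = bias_se / design$se_unit,
               rmse_se_units = rmse / design$se_unit,
               rmse_se_units_se = rmse_se / design$se_unit)
  })
  k <- design$k
  p_cont <- n / draws$attempts
  sel_tab <- tabulate(draws$S, nbins = k) / n
  if (k >= 2L) {
    other_ok <- vapply(seq_len(n), function(i) {
      d <- draws$X[i, -1L] - draws$X[i, 1L]
      all(d[-draws$S[i]] >= design$b)
    }, logical(1))
    beat <- vapply(seq_len(k), function(a) mean(draws$S == a & other_ok), numeric(1))
  } else beat <- rep(NA_real_, k)
  probs <- data.frame(
    arm = seq_len(k),
    p_continue = p_cont,
    p_continue_se = sqrt(p_cont * (1 - p_cont) / draws$attempts),
    p_select_given_continue = sel_tab,
    p_select_se = sqrt(sel_tab * (1 - sel_tab) / n),
    p_select_others_beat = beat)
  structure(list(estimates = do.call(rbind, rows), probs = probs,
                 n_continuing = n, attempts = draws$attempts,
                 design = design, truth = spec$truth),
            class = "asd_sim_summary")
}

#' @export
print.asd_sim_summary <- function(x, ...) {
  cat(sprintf("Conditional simulation: %d continuing replicates (%.3g attempts, Pr(continue) ~ %.3f)\n",
              x$n_continuing, x$attempts, x$n_continuing / x$attempts))
  print(x$estimates, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Operating characteristics over a grid of selection times and boundaries
#'
#' Maps [run_conditional()] over grids of `t` and `b`, giving the
#' long-format table behind bias / root-MSE operating curves. Each cell
#' runs on its own reproducible substream derived from `seed` and the cell
#' indices, so cells can be recomputed independently.
#'
#' @inheritParams sim_spec
#' @param t_values,b_values Grids of selection times and futility
#'   boundaries.
#' @inheritParams run_conditional
#' @return A long `data.frame` (class `"asd_opgrid"`): one row per
#'   (t, b, estimator) with bias/rmse columns as in [run_conditional()]
#'   plus `p_continue`.
#' @export
operating_grid <- function(truth, sigma = 1, n_total = 100,
                           t_values = c(0.2, 0.5, 0.8), b_values = -Inf,
                           n_continuing = 10000, seed = 1L,
                           estimators = c("naive", "stage2", "unbiased",
                                          "bias_adjusted"),
                           solver = solver_config(), max_attempts = 1e9) {
  out <- NULL
  for (bi in seq_along(b_values)) for (ti in seq_along(t_values)) {
    cell_seed <- (seed + 1000003 * ti + 7919 * bi) %% 2147483647
    spec <- sim_spec(truth, sigma, n_total, t_values[ti], b_values[bi],
                     n_continuing, cell_seed, max_attempts)
    sm <- run_conditional(spec, estimators, solver)
    cell <- cbind(data.frame(t = t_values[ti], b = b_values[bi]),
                  sm$estimates,
                  p_continue = sm$probs$p_continue[1L])
    out <- rbind(out, cell)
  }
  class(out) <- c("asd_opgrid", class(out))
  out
}

#' Plot bias and root-MSE operating curves
#'
#' Draws the classic two-panel display (conditional bias and root-MSE in
#' SE units against selection time, one line per estimator, one facet per
#' futility boundary) from an [operating_grid()] table. Requires ggplot2.
#'
#' @param grid An `"asd_opgrid"` data frame.
#' @param metric `"bias"` or `"rmse"` (SE units).
#' @return A ggplot object.
#' @export
plot_operating_grid <- function(grid, metric = c("bias", "rmse")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is needed for plotting", call. = FALSE)
  metric <- match.arg(metric)
  ycol <- if (metric == "bias") "bias_se_units" else "rmse_se_units"
  ggplot2::ggplot(grid, ggplot2::aes(x = .data[["t"]], y = .data[[ycol]],
                                     colour = .data[["estimator"]])) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~b, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "selection time t",
                  y = sprintf("conditional %s (SE units)", metric)) +
    ggplot2::theme_bw()
}
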