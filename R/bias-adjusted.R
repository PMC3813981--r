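#' Working model for the selection-bias functions
#'
#' Holds a working vector of treatment differences `theta = (theta_1, ...,
#' theta_k)` together with the design, on the stage-1 difference scale
#' where the bias of the naive MLE lives: `D_i = X_i - X_0` has
#' `Var(D_i) = 2 * sigma1_sq` and `Cov(D_i, D_j) = sigma1_sq` through the
#' shared control mean. All conditional expectations are reduced to single
#' integrals by conditioning on the selected arm's stage-1 mean (for
#' dropped arms this is the decomposition `X_i = D_i + W_0` with
#' `W_0 = X_0`, which makes the `W_i = X_i` mutually independent).
#'
#' @param theta Numeric working difference vector, length `design$k`.
#' @param design An [asd_design()].
#' @param selected Index of the arm in the selected role (needed by
#'   [bias_dropped()] and [bias_vector()]; may be `NULL` for purely
#'   symmetric quantities such as [selection_density()]).
#' @return An object of class `"asd_biasmodel"`.
#' @export
bias_model <- function(theta, design, selected = NULL) {
  stopifnot(inherits(design, "asd_design"))
  if (length(theta) != design$k || !all(is.finite(theta)))
    stop(sprintf("'theta' must be a finite vector of length k = %d", design$k), call. = FALSE)
  if (!is.null(selected)) {
    if (length(selected) != 1L || !selected %in% seq_len(design$k))
      stop("'selected' must be an arm index in 1..k", call. = FALSE)
    selected <- as.integer(selected)
  }
  structure(list(theta = as.numeric(theta), design = design, selected = selected),
            class = "asd_biasmodel")
}

#' Numerical settings for the bias-adjusted solve
#'
#' @param tol Euclidean-distance stopping tolerance for the fixed-point
#'   iteration (default `5e-4`).
#' @param max_iter Iteration cap (default 500; the reference worked example
#'   converges in 15).
#' @param abs_tol,rel_tol Quadrature tolerances passed to
#'   [stats::integrate()].
#' @param nodes Number of Gauss-Legendre nodes for the vectorised
#'   simulation path.
#' @param halfwidth Integration range in marginal standard deviations
#'   around the integrand's centre; the integrands are Gaussian-tailed so
#'   the default 8.5 keeps truncation error below 1e-15.
#' @param box Half-width, in stage-1 difference SDs `sqrt(2 * sigma1_sq)`,
#'   of the admissible window around the naive vector to which the working
#'   differences are confined during the iteration. For extreme trials
#'   (typically a dropped arm whose stage-1 difference is implausibly
#'   large at late selection times) the Whitehead-type equation has no
#'   finite solution and the unconstrained iteration runs away; the bias
#'   integrands saturate in the tails, so clamping at a wide window leaves
#'   ordinary trials untouched while keeping the solve well defined.
#' @return An object of class `"asd_solver"`.
#' @export
solver_config <- function(tol = 5e-4, max_iter = 500L, abs_tol = 1e-10,
                          rel_tol = 1e-8, nodes = 161L, halfwidth = 8.5,
                          box = 5) {
  stopifnot(tol > 0, max_iter >= 1, abs_tol > 0, rel_tol > 0,
            nodes >= 21, halfwidth > 3, box > 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter), abs_tol = abs_tol,
                 rel_tol = rel_tol, nodes = as.integer(nodes),
                 halfwidth = halfwidth, box = box),
            class = "asd_solver")
}

# adaptive quadrature of f over centre +/- halfwidth * sd, with diagnostics
.quad <- function(f, centre, sd, solver) {
  r <- tryCatch(
    stats::integrate(f, centre - solver$halfwidth * sd, centre + solver$halfwidth * sd,
                     abs.tol = solver$abs_tol, rel.tol = solver$rel_tol),
    error = function(e) stop(sprintf(
      "quadrature failed on [%g, %g]: %s", centre - solver$halfwidth * sd,
      centre + solver$halfwidth * sd, conditionMessage(e)), call. = FALSE))
  r$value
}

#' Joint density of selection and the selected stage-1 difference
#'
#' Density of the event that arm `i` has the largest stage-1 mean and its
#' stage-1 difference takes the value `d`, i.e. the joint law of
#' `(S = i, D_i = d)`. The correlation among the `D_j` is induced entirely
#' by the shared control mean, so conditioning on `X_0` factorises the
#' event and leaves a single integral:
#' `f_i(d) = Int phi(x0; mu0, s1) phi(x0 + d; mu0 + theta_i, s1)
#'   prod_{j != i} Phi((x0 + d - mu0 - theta_j) / s1) dx0`,
#' with `s1 = sqrt(sigma1_sq)` (the value does not depend on `mu0`). The
#' futility boundary plays no role here; integrating over `d` and summing
#' over arms gives total probability 1.
#'
#' @param d Difference value(s) at which to evaluate (vectorised).
#' @param i Arm index in `1..k`.
#' @param model An [bias_model()].
#' @param solver An [solver_config()] (quadrature settings).
#' @return Density values, same length as `d`.
#' @export
selection_density <- function(d, i, model, solver = solver_config()) {
  stopifnot(inherits(model, "asd_biasmodel"), i %in% seq_len(model$design$k))
  if (!all(is.finite(d))) stop("'d' must be finite", call. = FALSE)
  th <- model$theta; s1 <- sqrt(model$design$sigma1_sq); k <- model$design$k
  vapply(d, function(dd) {
    f <- function(x0) {
      g <- stats::dnorm(x0, 0, s1) * stats::dnorm(x0 + dd, th[i], s1)
      for (j in seq_len(k)[-i]) g <- g * stats::pnorm((x0 + dd - th[j]) / s1)
      g
    }
    # the two normal kernels concentrate around (theta_i - dd)/2 with sd s1/sqrt(2)
    .quad(f, (th[i] - dd) / 2, s1, solver)
  }, numeric(1))
}

# ---- single-integral building blocks (integration over xi, the selected
# ---- arm's stage-1 mean; control mean integrated out analytically) -------

# P(S = i, D_i >= b)
.p_select <- function(i, th, s1, b, k, solver) {
  f <- function(xi) {
    g <- stats::dnorm(xi, th[i], s1) * stats::pnorm((xi - b) / s1)
    for (j in seq_len(k)[-i]) g <- g * stats::pnorm((xi - th[j]) / s1)
    g
  }
  .quad(f, th[i], s1, solver)
}

# E[D_i ; S = i, D_i >= b]  (inner expectation over X_0 <= xi - b in closed form)
.e_dsel <- function(i, th, s1, b, k, solver) {
  f <- function(xi) {
    w <- (xi - b) / s1
    g <- stats::dnorm(xi, th[i], s1) * (xi * stats::pnorm(w) + s1 * stats::dnorm(w))
    for (j in seq_len(k)[-i]) g <- g * stats::pnorm((xi - th[j]) / s1)
    g
  }
  .quad(f, th[i], s1, solver)
}

# E[X_ip ; S = i, D_i >= b] for a dropped arm ip != i
.e_xdrop <- function(ip, i, th, s1, b, k, solver) {
  f <- function(xi) {
    v <- (xi - th[ip]) / s1
    g <- stats::dnorm(xi, th[i], s1) * stats::pnorm((xi - b) / s1) *
      (th[ip] * stats::pnorm(v) - s1 * stats::dnorm(v))
    for (j in seq_len(k)[-c(i, ip)]) g <- g * stats::pnorm((xi - th[j]) / s1)
    g
  }
  .quad(f, th[i], s1, solver)
}

# E[X_0 ; S = i, D_i >= b]
.e_x0 <- function(i, th, s1, b, k, solver) {
  f <- function(xi) {
    g <- stats::dnorm(xi, th[i], s1) * (-s1 * stats::dnorm((xi - b) / s1))
    for (j in seq_len(k)[-i]) g <- g * stats::pnorm((xi - th[j]) / s1)
    g
  }
  .quad(f, th[i], s1, solver)
}

#' Probability of selecting an arm and passing the futility gate
#'
#' `Pr(S = i, D_i >= b)` under the working model, as a single integral
#' over the selected arm's stage-1 mean. Summed over arms this is the
#' probability that the trial continues to stage 2.
#'
#' @inheritParams selection_density
#' @return Probability in `(0, 1]`.
#' @export
prob_continue_select <- function(i, model, solver = solver_config()) {
  stopifnot(inherits(model, "asd_biasmodel"), i %in% seq_len(model$design$k))
  .p_select(i, model$theta, sqrt(model$design$sigma1_sq), model$design$b,
            model$design$k, solver)
}

#' Conditional bias of the naive estimate for the selected arm
#'
#' The naive pooled estimate for arm `i` can be written
#' `t * D_i + (1 - t) * (Y_i - Y_0)`; stage 2 is unbiased given
#' continuation, so the conditional bias is
#' `t * (E[D_i | S = i, D_i >= b] - theta_i)`. Positive under exchangeable
#' working differences: both picking the maximum and requiring the gate to
#' be passed inflate the selected stage-1 difference.
#'
#' @inheritParams selection_density
#' @return Bias value (scalar).
#' @export
bias_selected <- function(i, model, solver = solver_config()) {
  stopifnot(inherits(model, "asd_biasmodel"), i %in% seq_len(model$design$k))
  th <- model$theta; des <- model$design; s1 <- sqrt(des$sigma1_sq)
  p <- .p_select(i, th, s1, des$b, des$k, solver)
  des$t * (.e_dsel(i, th, s1, des$b, des$k, solver) / p - th[i])
}

#' Conditional bias of the naive estimate for a dropped arm
#'
#' A dropped arm's naive estimate is its stage-1-only difference
#' `X_{i'} - X_0`; its bias conditional on the observed selection and on
#' continuation is `E[X_{i'} - X_0 | S = s, D_s >= b] - theta_{i'}`, with
#' `s = model$selected`. Both expectations reduce to single integrals over
#' the selected arm's stage-1 mean because, given `X_0`, the stage-1 means
#' are independent (the `W_0 = X_0` decomposition). Typically negative:
#' conditional on losing the selection, the dropped arm's difference is
#' low, although the gate (which caps `X_0`) pushes the other way.
#'
#' @param i_prime Dropped arm index (`!= model$selected`); requires
#'   `k >= 2`.
#' @inheritParams selection_density
#' @return Bias value (scalar).
#' @export
bias_dropped <- function(i_prime, model, solver = solver_config()) {
  stopifnot(inherits(model, "asd_biasmodel"))
  des <- model$design
  if (des$k < 2L) stop("'bias_dropped' requires k >= 2", call. = FALSE)
  if (is.null(model$selected))
    stop("'model$selected' must identify the selected arm", call. = FALSE)
  s <- model$selected
  if (!i_prime %in% seq_len(des$k) || i_prime == s)
    stop("'i_prime' must be a dropped arm (index != selected)", call. = FALSE)
  th <- model$theta; s1 <- sqrt(des$sigma1_sq)
  p <- .p_select(s, th, s1, des$b, des$k, solver)
  (.e_xdrop(i_prime, s, th, s1, des$b, des$k, solver) -
     .e_x0(s, th, s1, des$b, des$k, solver)) / p - th[i_prime]
}

#' Conditional bias vector of the naive MLE
#'
#' Assembles the per-arm biases of the naive estimate vector given the
#' observed selection and continuation: the selected arm gets
#' [bias_selected()], every dropped arm [bias_dropped()]. For `k = 1` the
#' single entry is [bias_selected()] (identically zero when `b = -Inf`:
#' no selection and no gate).
#'
#' @inheritParams selection_density
#' @return Numeric vector of length `k`.
#' @export
bias_vector <- function(model, solver = solver_config()) {
  stopifnot(inherits(model, "asd_biasmodel"))
  k <- model$design$k
  if (k == 1L) return(bias_selected(1L, model, solver))
  if (is.null(model$selected))
    stop("'model$selected' must identify the selected arm", call. = FALSE)
  vapply(seq_len(k), function(i) {
    if (i == model$selected) bias_selected(i, model, solver)
    else bias_dropped(i, model, solver)
  }, numeric(1))
}

#' Bias-adjusted estimate of the selected treatment difference
#'
#' Whitehead-style iterative bias correction: starting from the naive MLE
#' vector `theta_hat`, repeat `theta^(r+1) = theta_hat - b(theta^(r))`
#' (plain fixed point, no damping) until the Euclidean step is at most
#' `solver$tol`. The converged vector's selected component is the
#' bias-adjusted estimate. Overcorrects on average: its conditional bias
#' is typically slightly negative.
#'
#' @inheritParams pooled_means
#' @param solver An [solver_config()].
#' @param theta_start Optional start vector (defaults to the naive MLE
#'   vector, the recommended choice).
#' @return An object of class `"asd_stl"`: list with `estimate`,
#'   `iterations`, `theta` (converged vector), `clamped` (whether the
#'   admissible window was active at the solution), `trace` (iteration
#'   matrix with step norms).
#' @export
bias_adjusted_estimate <- function(trial, solver = solver_config(),
                                   theta_start = NULL) {
  .stop_if_stopped(trial)
  des <- trial$design
  th_mle <- naive_vector(trial)
  half <- solver$box * sqrt(2 * des$sigma1_sq)
  lo <- th_mle - half; hi <- th_mle + half
  th <- if (is.null(theta_start)) th_mle else {
    stopifnot(length(theta_start) == des$k, all(is.finite(theta_start)))
    as.numeric(theta_start)
  }
  trace <- matrix(c(th, NA_real_), nrow = 1,
                  dimnames = list(NULL, c(paste0("theta", seq_len(des$k)), "step")))
  for (r in seq_len(solver$max_iter)) {
    bv <- bias_vector(bias_model(th, des, trial$S), solver)
    th_new <- pmin(pmax(th_mle - bv, lo), hi)
    step <- sqrt(sum((th_new - th)^2))
    trace <- rbind(trace, c(th_new, step))
    th <- th_new
    if (step <= solver$tol) {
      return(structure(list(estimate = th[trial$S], iterations = r, theta = th,
                            clamped = any(th <= lo | th >= hi), trace = trace),
                       class = "asd_stl"))
    }
  }
  cond <- simpleError(sprintf(
    "bias-adjusted iteration did not converge in %d steps (last step %.3g > tol %.3g)",
    solver$max_iter, trace[nrow(trace), "step"], solver$tol))
  cond$trace <- trace
  stop(cond)
}

#' @export
print.asd_stl <- function(x, ...) {
  cat(sprintf("Bias-adjusted estimate: %.4f (converged in %d iterations)\n",
              x$estimate, x$iterations))
  cat("  adjusted theta vector:", paste(sprintf("%.4f", x$theta), collapse = ", "), "\n")
  invisible(x)
}

# ---- vectorised Gauss-Legendre batch path (simulation workloads) ---------
# Same integrands as the scalar path on the same truncated range, evaluated
# on a fixed Gauss-Legendre rule so that thousands of trials can be solved
# as matrix operations. Agreement with the adaptive path is asserted in the
# test suite.

.gl_rule <- function(solver) {
  gl <- pracma::gaussLegendre(solver$nodes, -solver$halfwidth, solver$halfwidth)
  list(u = gl$x, w = gl$w * stats::dnorm(gl$x))   # fold the N(0,1) kernel in
}

# theta: M x k matrix of working vectors; S: length-M selected arms.
# Returns M x k matrix of conditional biases (selected role per row).
.bias_vector_batch <- function(theta, S, design, rule) {
  M <- nrow(theta); k <- design$k
  s1 <- sqrt(design$sigma1_sq); b <- design$b; t <- design$t
  out <- matrix(NA_real_, M, k)
  G <- length(rule$u)
  for (s in unique(S)) {
    idx <- which(S == s); Mp <- length(idx)
    ths <- theta[idx, s]
    XI <- s1 * rule$u %o% rep(1, Mp) + matrix(ths, G, Mp, byrow = TRUE)
    W <- (XI - b) / s1
    Pfac <- stats::pnorm(W)                       # gate factor, 1 when b = -Inf
    phiW <- stats::dnorm(W)
    Fj <- vector("list", k)                       # P(X_j <= xi) per dropped arm
    for (j in seq_len(k)[-s])
      Fj[[j]] <- stats::pnorm((XI - matrix(theta[idx, j], G, Mp, byrow = TRUE)) / s1)
    Sfac <- matrix(1, G, Mp)
    for (j in seq_len(k)[-s]) Sfac <- Sfac * Fj[[j]]
    P  <- colSums(rule$w * (Pfac * Sfac))
    ED <- colSums(rule$w * ((XI * Pfac + s1 * phiW) * Sfac))
    out[idx, s] <- t * (ED / P - ths)
    if (k >= 2L) {
      EX0 <- colSums(rule$w * (-s1 * phiW * Sfac))
      for (j in seq_len(k)[-s]) {
        thj <- matrix(theta[idx, j], G, Mp, byrow = TRUE)
        Sex <- matrix(1, G, Mp)
        for (l in seq_len(k)[-c(s, j)]) Sex <- Sex * Fj[[l]]
        inner <- thj * Fj[[j]] - s1 * stats::dnorm((XI - thj) / s1)
        EXj <- colSums(rule$w * (Pfac * Sex * inner))
        out[idx, j] <- (EXj - EX0) / P - theta[idx, j]
      }
    }
  }
  out
}

# Batch fixed-point solve; th_mle M x k, S length M.
# Returns list(theta, estimate, iterations, converged).
.bias_adjust_batch <- function(th_mle, S, design, solver) {
  M <- nrow(th_mle)
  rule <- .gl_rule(solver)
  half <- solver$box * sqrt(2 * design$sigma1_sq)
  lo <- th_mle - half; hi <- th_mle + half
  th <- th_mle
  iters <- integer(M)
  active <- rep(TRUE, M)
  for (r in seq_len(solver$max_iter)) {
    if (!any(active)) break
    ia <- which(active)
    bv <- .bias_vector_batch(th[ia, , drop = FALSE], S[ia], design, rule)
    th_new <- pmin(pmax(th_mle[ia, , drop = FALSE] - bv, lo[ia, , drop = FALSE]),
                   hi[ia, , drop = FALSE])
    step <- sqrt(rowSums((th_new - th[ia, , drop = FALSE])^2))
    th[ia, ] <- th_new
    iters[ia] <- r
    active[ia[step <= solver$tol]] <- FALSE
  }
  if (any(active))
    stop(sprintf("batch bias-adjusted solve: %d of %d trials not converged after %d iterations",
                 sum(active), M, solver$max_iter), call. = FALSE)
  list(theta = th, estimate = th[cbind(seq_len(M), S)],
       iterations = iters, converged = !active)
}
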