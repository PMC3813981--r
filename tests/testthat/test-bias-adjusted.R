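test_that("selection density is symmetric, normalised, and matches sampling", {
  d <- asd_design(k = 2, n1 = 50, n2 = 50, sigma = 1, b = 0)
  m_exch <- bias_model(c(0.1, 0.1), d)
  dd <- seq(-0.4, 0.4, by = 0.2)
  expect_equal(selection_density(dd, 1, m_exch), selection_density(dd, 2, m_exch),
               tolerance = 1e-8)

  # total probability over arms is 1 (the boundary plays no role here)
  d3 <- asd_design(k = 3, n1 = 100, n2 = 100, sigma = 3, b = 0.5)
  m3 <- bias_model(c(0, 0.1, 0.2), d3)
  tot <- sum(vapply(1:3, function(i) {
    integrate(function(v) selection_density(v, i, m3), -3, 3,
              abs.tol = 1e-9)$value
  }, numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-6)

  # pointwise agreement with a brute-force histogram of (S, D_S), sigma1 = 0.3
  hist <- mc_selection_histogram(parameter_vector(0, c(0, 0.1, 0.2)), d3,
                                 breaks = c(-0.55, -0.45, -0.05, 0.05, 0.45, 0.55),
                                 n = 1e5, seed = 5)
  for (i in 1:3) for (bin in c(1, 3, 5)) {
    lo <- hist$breaks[bin]; hi <- hist$breaks[bin + 1]
    p_an <- integrate(function(v) selection_density(v, i, m3), lo, hi,
                      abs.tol = 1e-9)$value
    se <- max(hist$mc_se[i, bin], sqrt(p_an * (1 - p_an) / hist$n))
    expect_lt(abs(hist$freq[i, bin] - p_an), 3 * se)
  }
})

test_that("selection-and-continuation probabilities behave analytically", {
  # no gate, exchangeable arms: each arm is selected with probability 1/k
  for (k in c(2, 3, 5)) {
    d <- asd_design(k = k, n1 = 50, n2 = 50, sigma = 1, b = -Inf)
    m <- bias_model(rep(0.05, k), d)
    for (i in seq_len(k))
      expect_equal(prob_continue_select(i, m), 1 / k, tolerance = 1e-7)
  }
  # k = 1 with the boundary at the true difference: exactly 1/2
  d1 <- asd_design(k = 1, n1 = 50, n2 = 50, sigma = 1, b = 0.3)
  expect_equal(prob_continue_select(1, bias_model(0.3, d1)), 0.5, tolerance = 1e-9)

  # per-arm probabilities sum to Pr(continue) = 1 when b = -Inf
  d3 <- asd_design(k = 3, n1 = 40, n2 = 60, sigma = 1, b = -Inf)
  m3 <- bias_model(c(-0.1, 0, 0.2), d3)
  expect_equal(sum(vapply(1:3, prob_continue_select, numeric(1), model = m3)),
               1, tolerance = 1e-7)

  # Monte-Carlo agreement with a gate: sigma1^2 = 1/100
  d2 <- asd_design(k = 2, n1 = 100, n2 = 100, sigma = 1, b = 0)
  m2 <- bias_model(c(0.05, 0.05), d2)
  set.seed(17)
  n <- 1e5
  x0 <- rnorm(n, 0, 0.1); x1 <- rnorm(n, 0.05, 0.1); x2 <- rnorm(n, 0.05, 0.1)
  p_mc <- mean(x1 >= x2 & x1 - x0 >= 0)
  p_an <- prob_continue_select(1, m2)
  expect_lt(abs(p_mc - p_an), 3 * sqrt(p_an * (1 - p_an) / n))
})

test_that("bias functions have the analytic signs and symmetries", {
  # no selection, no gate: zero bias for any theta
  d1 <- asd_design(k = 1, n1 = 30, n2 = 70, sigma = 1, b = -Inf)
  for (th in c(-0.2, 0, 0.4)) {
    expect_equal(bias_selected(1, bias_model(th, d1)), 0, tolerance = 1e-9)
    expect_equal(bias_vector(bias_model(th, d1, selected = 1)), 0, tolerance = 1e-9)
  }
  # exchangeable arms: selected-arm bias identical across arms, positive
  d2 <- asd_design(k = 2, n1 = 50, n2 = 50, sigma = 1, b = 0.05)
  m2 <- bias_model(c(0.05, 0.05), d2)
  b1 <- bias_selected(1, m2); b2 <- bias_selected(2, m2)
  expect_equal(b1, b2, tolerance = 1e-9)
  expect_gt(b1, 0)
  # dropped arm is conditionally the smaller one when there is no gate
  d2n <- asd_design(k = 2, n1 = 50, n2 = 50, sigma = 1, b = -Inf)
  expect_lt(bias_dropped(2, bias_model(c(0.05, 0.05), d2n, selected = 1)), 0)
  # exchangeable: dropped-arm biases identical across dropped arms
  d3 <- asd_design(k = 3, n1 = 50, n2 = 50, sigma = 1, b = 0)
  m3 <- bias_model(rep(0.05, 3), d3, selected = 1)
  expect_equal(bias_dropped(2, m3), bias_dropped(3, m3), tolerance = 1e-9)
  # argument validation
  expect_error(bias_dropped(1, bias_model(0.1, d1)), "k >= 2")
  expect_error(bias_dropped(1, m3), "dropped")
  expect_error(bias_vector(bias_model(rep(0.05, 3), d3)), "selected")
})

test_that("analytic biases match brute-force conditional Monte-Carlo", {
  d <- asd_design(k = 3, n1 = 50, n2 = 50, sigma = 1, b = 0)
  truth <- parameter_vector(0, c(0, 0.05, 0.05))
  m <- bias_model(truth$theta, d, selected = 2)
  # selected arm: E[naive] - theta_S given S = 2 and continuation
  sel <- mc_conditional_mean(naive_estimate, truth, d, n = 3e4, seed = 31, arm = 2)
  expect_lt(abs(sel$estimate - (truth$theta[2] + bias_selected(2, m))), 3 * sel$mc_se)
  # dropped arm: E[x_1 - x_0] - theta_1 given the same conditioning
  drp <- mc_conditional_mean(function(tr) tr$x[2] - tr$x[1], truth, d,
                             n = 3e4, seed = 32, arm = 2)
  expect_lt(abs(drp$estimate - (truth$theta[1] + bias_dropped(1, m))), 3 * drp$mc_se)
})

test_that("the vectorised quadrature path agrees with adaptive quadrature", {
  set.seed(41)
  d <- asd_design(k = 3, n1 = 71, n2 = 71, sigma = 6, b = 0)
  rule <- seamest:::.gl_rule(solver_config())
  for (rep in 1:5) {
    th <- rnorm(3, 1, 0.8); s <- sample(1:3, 1)
    bv_scalar <- bias_vector(bias_model(th, d, selected = s))
    bv_batch <- seamest:::.bias_vector_batch(matrix(th, 1), s, d, rule)
    expect_equal(as.numeric(bv_batch), bv_scalar, tolerance = 1e-8)
  }
})

test_that("the fixed-point solve reproduces the case-study estimate and trajectory", {
  fit <- bias_adjusted_estimate(table1_trial())
  expect_equal(fit$estimate, 1.135, tolerance = 5e-4)
  expect_true(abs(fit$iterations - 15) <= 2)   # printed trajectory stops at 15
  expect_equal(nrow(fit$trace), fit$iterations + 1L)
  expect_lte(fit$trace[nrow(fit$trace), "step"], 5e-4)

  # a zero bias function converges at the start in one step
  d1 <- asd_design(k = 1, n1 = 30, n2 = 70, sigma = 1, b = -Inf)
  tr1 <- asd_trial(c(0, 0.4), y0 = 0.1, yS = 0.5, design = d1)
  fit1 <- bias_adjusted_estimate(tr1)
  expect_equal(fit1$estimate, naive_estimate(tr1), tolerance = 1e-9)
  expect_equal(fit1$iterations, 1L)

  # non-convergence raises with the trajectory attached
  err <- tryCatch(bias_adjusted_estimate(table1_trial(),
                                         solver_config(max_iter = 2)),
                  error = identity)
  expect_match(conditionMessage(err), "did not converge")
  expect_true(is.matrix(err$trace) && nrow(err$trace) == 3L)
})

test_that("estimate_all bundles consistent components", {
  est <- estimate_all(table1_trial())
  expect_equal(est$naive, est$zS_mle - est$z0_mle)
  expect_equal(est$unbiased, est$zS_chn - est$z0_chn)
  expect_equal(est$S, 2L)
  expect_lt(est$bias_adjusted, est$unbiased)  # STL corrects hardest here
  expect_lt(est$unbiased, est$naive)
})
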