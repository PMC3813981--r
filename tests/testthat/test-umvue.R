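test_that("mills_ratio is stable and accurate deep in the lower tail", {
  # continued-fraction reference for phi(w)/Phi(w), w << 0 (independent of pnorm)
  cf <- function(w, depth = 80) {
    x <- -w; f <- 0
    for (j in depth:1) f <- j / (x + f)
    x + f
  }
  for (w in c(-10, -15, -20, -30, -50))
    expect_lt(abs(mills_ratio(w) / cf(w) - 1), 1e-10)
  expect_equal(mills_ratio(0), dnorm(0) / 0.5)
  expect_identical(mills_ratio(Inf), 0)
  expect_identical(mills_ratio(-Inf), Inf)
  w <- seq(-8, 8, by = 0.25)              # Mills ratio is strictly decreasing
  expect_true(all(diff(mills_ratio(w)) < 0))
})

test_that("conditioning statistics match the case study and degenerate correctly", {
  cs <- conditioning_stats(table1_trial())
  expect_equal(cs$B, -0.082)
  expect_equal(cs$B1, 1.766)
  expect_equal(cs$x_second, 1.567)
  expect_equal(cs$m, 1.567)              # max{B, X_(2)} = max{-0.082, 1.567}
  expect_equal(cs$tau, sqrt(0.5 * 36 / 71))
  expect_equal(cs$W_B, (1.6085 - 1.567) / sqrt(0.5 * 36 / 71))

  # no futility gate: truncation comes from selection alone
  d <- asd_design(k = 3, n1 = 71, n2 = 71, sigma = 6, b = -Inf)
  tr <- asd_trial(c(-0.082, 0.413, 1.766, 1.567), 0.049, 1.451, design = d)
  expect_equal(conditioning_stats(tr)$m, 1.567)
  expect_identical(conditioning_stats(tr)$B, -Inf)

  # k = 1: X_(2) is vacuous, the gate is the only conditioning event
  d1 <- asd_design(k = 1, n1 = 50, n2 = 50, sigma = 1, b = 0.1)
  tr1 <- asd_trial(c(0, 0.4), y0 = 0.05, yS = 0.35, design = d1)
  cs1 <- conditioning_stats(tr1)
  expect_identical(cs1$x_second, -Inf)
  expect_equal(cs1$m, cs1$B)
})

test_that("the selected-arm UMVUE shrinks the pooled mean and is monotone in it", {
  set.seed(21)
  for (rep in 1:15) {
    d <- asd_design(k = sample(2:4, 1), n1 = sample(10:90, 1), n2 = sample(10:90, 1),
                    sigma = runif(1, 0.5, 3), b = runif(1, -0.3, 0.1))
    tr <- random_continued_trial(d)
    expect_lt(umvue_selected(tr), pooled_means(tr)[["zS_mle"]])
  }
  # monotone non-decreasing in zS_mle holding the truncation point fixed
  tr <- table1_trial()
  vals <- vapply(seq(-2, 4, by = 0.1), function(y) {
    umvue_selected(asd_trial(tr$x, y0 = tr$y0, yS = y, design = tr$design))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  # correction vanishes when the pooled mean is far above the truncation
  far <- asd_trial(tr$x, y0 = tr$y0, yS = 60, design = tr$design)
  expect_equal(umvue_selected(far), pooled_means(far)[["zS_mle"]], tolerance = 1e-12)
})

test_that("with no futility gate the control UMVUE is exactly the pooled mean", {
  set.seed(22)
  for (rep in 1:10) {
    d <- asd_design(k = 3, n1 = sample(10:90, 1), n2 = sample(10:90, 1),
                    sigma = runif(1, 0.5, 3), b = -Inf)
    tr <- random_continued_trial(d)
    expect_identical(umvue_control(tr), unname(pooled_means(tr)[["z0_mle"]]))
  }
})

test_that("unit-stage no-gate case reduces to the Cohen-Sackrowitz estimator", {
  set.seed(23)
  d <- asd_design(k = 3, n1 = 1, n2 = 1, sigma = 1, b = -Inf)
  for (rep in 1:50) {
    tr <- random_continued_trial(d, parameter_vector(0, rnorm(3, 0, 0.5)))
    z <- pooled_means(tr)[["zS_mle"]]
    x2 <- max(tr$x[-c(1, tr$S + 1)])
    expect_equal(umvue_selected(tr), cohen_sackrowitz(z, x2), tolerance = 1e-12)
  }
})

test_that("the k = 1 estimator matches the general formula and drops its correction", {
  d1 <- asd_design(k = 1, n1 = 40, n2 = 60, sigma = 2, b = 0.1)
  tr <- asd_trial(c(0.05, 0.3), y0 = 0.1, yS = 0.25, design = d1)
  # general estimator truncates at B = x0 + b; umvue_k1 expects that boundary
  d_eq <- asd_design(k = 1, n1 = 40, n2 = 60, sigma = 2, b = tr$x[1] + 0.1)
  expect_equal(umvue_selected(tr),
               umvue_k1(pooled_means(tr)[["zS_mle"]], d_eq, scale = "mean"),
               tolerance = 1e-12)
  # no truncation: returns the pooled mean unchanged
  d_no <- asd_design(k = 1, n1 = 40, n2 = 60, sigma = 2, b = -Inf)
  expect_identical(umvue_k1(0.42, d_no), 0.42)
  expect_identical(umvue_k1(0.42, d_no, scale = "difference"), 0.42)
  # difference-scale variant uses doubled stage variances
  db <- asd_design(k = 1, n1 = 50, n2 = 50, sigma = 1, b = 0)
  tau_d <- sqrt(0.5 * 2 / 50)
  expect_equal(umvue_k1(0.1, db, scale = "difference"),
               0.1 - tau_d * mills_ratio(0.1 / tau_d), tolerance = 1e-12)
  expect_error(umvue_k1(0.1, asd_design(k = 2, n1 = 5, n2 = 5, sigma = 1)), "k = 1")
})

test_that("the UMVUEs are conditionally unbiased given the selected arm", {
  d <- asd_design(k = 2, n1 = 50, n2 = 50, sigma = 1, b = 0)
  truth <- parameter_vector(0, c(0.1, 0.3))
  for (arm in 1:2) {
    sel <- mc_conditional_mean(umvue_selected, truth, d, n = 3e4,
                               seed = 100 + arm, arm = arm)
    expect_lt(abs(sel$estimate - truth$mu[arm]), 3 * sel$mc_se)
    ctl <- mc_conditional_mean(umvue_control, truth, d, n = 3e4,
                               seed = 200 + arm, arm = arm)
    expect_lt(abs(ctl$estimate - truth$mu0), 3 * ctl$mc_se)
  }
  # and the difference, for each selected arm, under a boundary-hugging truth
  d2 <- asd_design(k = 2, n1 = 50, n2 = 50, sigma = 1, b = 0.05)
  truth2 <- parameter_vector(0, c(0.025, 0.05))
  for (arm in 1:2) {
    dif <- mc_conditional_mean(unbiased_estimate, truth2, d2, n = 3e4,
                               seed = 300 + arm, arm = arm)
    expect_lt(abs(dif$estimate - truth2$theta[arm]), 3 * dif$mc_se)
  }
})
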