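# Worked-example fixture built in code (anxiety case study: 3 doses vs
# placebo, HAM-A change score, sigma = 6, n1 = n2 = 71, futility boundary 0).
table1_design <- function() asd_design(k = 3, n1 = 71, n2 = 71, sigma = 6, b = 0)
table1_trial <- function() {
  asd_trial(c(-0.082, 0.413, 1.766, 1.567), y0 = 0.049, yS = 1.451,
            design = table1_design())
}

# Random continued trial (rejection-samples until the gate is passed).
random_continued_trial <- function(design, truth = NULL) {
  if (is.null(truth))
    truth <- parameter_vector(0, stats::runif(design$k, -0.2, 0.4))
  repeat {
    tr <- simulate_trial(truth, design)
    if (tr$continued) return(tr)
  }
}

grid_theta <- function(k, kind) {
  if (kind == "exch") rep(0.05, k) else c(0.025, rep(0.05, k - 1))
}
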