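---
title: "Conditional estimation after two-stage seamless phase II/III trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional estimation after two-stage seamless phase II/III trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seamest)
```

## The estimation problem

A two-stage adaptive seamless phase II/III (drop-the-losers) trial compares
$k$ experimental treatments with a shared control. Outcomes on arm $i$
($i = 0$ the control) are normal with mean $\mu_i$ and *known* common
variance $\sigma^2$. Stage 1 allocates $n_1$ subjects per arm and yields
sample means $X_0, X_1, \dots, X_k$ with variance
$\sigma_1^2 = \sigma^2/n_1$. The arm with the largest stage-1 mean is
selected, $S = \arg\max_i X_i$ (ties, a probability-zero event, break to the
lowest index so runs are reproducible), and the trial continues to stage 2
only if the selected stage-1 difference passes a futility boundary,
$X_S - X_0 \ge b$; the inequality is non-strict, fixing the measure-zero
boundary case. `b = -Inf` is an explicit sentinel for "no gate", never a
large negative float, so the no-gate reductions are exact rather than
approximate. Stage 2 adds $n_2$ subjects per arm for the selected arm and
the control, giving means $Y_S, Y_0$ with variance
$\sigma_2^2 = \sigma^2/n_2$.

The target is $\theta_S = \mu_S - \mu_0$, and every expectation below is
conditional on the selected arm **and** on the trial continuing — the only
situation in which anyone reports a confirmatory estimate from such a
trial. Writing $t = n_1/(n_1+n_2)$ for the selection time, the pooled MLE
$Z_{i,\mathrm{MLE}} = tX_i + (1-t)Y_i$ yields the naive difference
estimator $D_{S,\mathrm{MLE}} = Z_{S,\mathrm{MLE}} - Z_{0,\mathrm{MLE}}$,
which is positively biased under this conditioning: picking the empirical
winner inflates $X_S$, and requiring $X_S - X_0 \ge b$ both inflates $X_S$
further and deflates $X_0$. The stage-2 difference $Y_S - Y_0$ is exactly
conditionally unbiased (selection used only stage-1 data) but wastes all
stage-1 information. The package implements two estimators that keep the
stage-1 data while removing the conditional bias.

## The conditionally unbiased (UMVUE) estimator

Both arms are handled by one Rao–Blackwell step applied to an estimator
that is trivially unbiased under the conditioning.

**Selected arm.** $Y_S$ is conditionally unbiased for $\mu_S$. Condition it
on the pooled mean $Z_{S,\mathrm{MLE}}$, the control's stage-1 mean and the
dropped arms' stage-1 means. Given those statistics the conditioning event
is exactly a one-sided truncation
$X_S \ge m = \max\{B, X_{(2)}\}$, where $B = X_0 + b$ is the gate
threshold and $X_{(2)}$ the runner-up stage-1 mean (for $k = 1$ there is no
runner-up and $m = B$: the event degenerates to the gate alone). Because
$X_S \mid Z_{S,\mathrm{MLE}}$ is normal with mean $Z_{S,\mathrm{MLE}}$ and
variance $\tau^2 = (1-t)\,\sigma_1^2$, the conditional expectation is a
truncated-normal mean and the estimator has the closed form
$$
Z_{S,\mathrm{CHN}} \;=\; Z_{S,\mathrm{MLE}}
  - \frac{t}{1-t}\,\tau\,\frac{\phi(W_B)}{\Phi(W_B)},
\qquad
W_B = \frac{Z_{S,\mathrm{MLE}} - m}{\tau}.
$$
The Mills-ratio correction is strictly positive, so the estimate always
sits below the pooled mean, and it vanishes when the pooled mean is far
above the truncation point.

**Control arm.** Symmetrically, conditioning $Y_0$ on
$Z_{0,\mathrm{MLE}}$ and the experimental stage-1 means turns the event
into an upper truncation $X_0 \le B_1 = X_S - b$, giving
$$
Z_{0,\mathrm{CHN}} \;=\; Z_{0,\mathrm{MLE}}
  + \frac{t}{1-t}\,\tau\,\frac{\phi(W_{B_1})}{\Phi(W_{B_1})},
\qquad
W_{B_1} = \frac{B_1 - Z_{0,\mathrm{MLE}}}{\tau},
$$
an upward correction: continuation favours low control means. With no gate
the truncation deactivates and $Z_{0,\mathrm{CHN}} \equiv
Z_{0,\mathrm{MLE}}$ exactly — in that setting the whole conditional bias of
the naive difference comes from the selected arm.

The difference $D_{S,\mathrm{CHN}} = Z_{S,\mathrm{CHN}} -
Z_{0,\mathrm{CHN}}$ is unbiased conditional on each selected arm
separately, a property the test suite certifies by brute-force conditional
Monte Carlo (the package's `mc_conditional_mean()` oracle) on a grid of
$k$, $b$, $t$ and mean configurations. Two exact reductions serve as
further certificates: with $\sigma^2 = 1$, $n_1 = n_2 = 1$ and no gate the
formula collapses to the classical Cohen–Sackrowitz two-stage UMVUE (coded
independently as `cohen_sackrowitz()` and asserted equal on random
inputs), and for $k = 1$ it collapses to the known single-arm
futility-gate UMVUE (`umvue_k1()`, on the mean scale without a control, on
the difference scale with one).

A note on uniqueness: any estimator built from these statistics that is
exactly unbiased conditional on the selection event is forced — the
truncated family is complete — so the constants $\tau$ and $W_B$ above are
not a modelling choice but the only ones compatible with conditional
unbiasedness. The Monte-Carlo oracle would flag any transcription slip in
them at many multiples of its standard error.

## The bias-adjusted estimator

The second estimator subtracts an estimate of the naive estimator's
conditional bias. If the true $\boldsymbol\theta$ were known, the bias
vector $\mathbf b(\boldsymbol\theta)$ of the naive estimate vector (pooled
difference for the selected arm, stage-1-only differences
$X_{i'} - X_0$ for dropped arms) could be computed and subtracted. It is
not known, so the package iterates the Whitehead-style fixed point
$$
\hat{\boldsymbol\theta}^{(r+1)}
 = \hat{\boldsymbol\theta}_{\mathrm{MLE}}
 - \mathbf b\!\left(\hat{\boldsymbol\theta}^{(r)}\right),
\qquad \hat{\boldsymbol\theta}^{(0)} = \hat{\boldsymbol\theta}_{\mathrm{MLE}},
$$
plain and undamped, stopping when the Euclidean step is at most `tol`
(default $5\times10^{-4}$); the selected component of the converged vector
is the estimate.

The bias components are exact single integrals. Conditional on the control
mean $X_0$, the stage-1 means are independent, which is the device that
collapses every multidimensional selection integral to one dimension
(equivalently: the variables $W_i = D_i + W_0$ with $W_0 = X_0$ are
mutually uncorrelated). For the selected arm,
$$
b_i(\boldsymbol\theta) = t\left(E[D_i \mid S = i,\, D_i \ge b] - \theta_i\right),
$$
with numerator and denominator ($\Pr(S=i, D_i \ge b)$, also exposed as
`prob_continue_select()`) reduced to integrals over the selected arm's
stage-1 mean with closed-form inner control-mean expectations. For a
dropped arm the package evaluates
$E[X_{i'} - X_0 \mid S = s,\, D_s \ge b] - \theta_{i'}$ **given the
observed selected arm** $s$, not averaged over all arms that might have
been selected. The observed-selection version is the one whose fixed point
matches the reference worked example below to print precision, including
its iteration count; the mixture version changes the third decimal and the
trajectory length, and was rejected on that evidence.

Simulations show the expected behaviour, certified in the test suite: the
adjustment overshoots slightly (mean conditional bias $\le 0$,
increasingly so at late selection times), in exchange for a root-MSE close
to the conditionally unbiased estimator and well below the stage-2
estimator.

## Numerical choices

* **Mills ratio.** `exp(dnorm(log = TRUE) - pnorm(log.p = TRUE))`; R's
  log-scale normal CDF is itself asymptotic-series-backed in the far lower
  tail, and a test certifies relative error below $10^{-10}$ against an
  independent continued-fraction reference down to $w = -50$.
* **Quadrature.** User-facing bias functions use adaptive Gauss–Kronrod
  (`stats::integrate`) on the integrand's centre $\pm 8.5$ marginal SDs
  (absolute tolerance $10^{-10}$; the integrands are Gaussian-tailed, so
  the truncation error is below $10^{-15}$). The simulation path evaluates
  the same integrands on a fixed 161-node Gauss–Legendre rule over the
  same interval so that $10^4$ trials iterate as matrix operations; the
  two routes agree to $10^{-8}$ in the tests.
* **Existence of the fixed point.** For a small fraction of extreme trials
  at late selection times (about 5 in $10^4$ at $t = 0.8$ in the test
  grids) a dropped arm's observed stage-1 difference is too large to be
  consistent with any working mean given the observed selection, and the
  fixed-point equation has no finite solution: the dropped component
  escapes linearly. The working vector is therefore confined to a wide
  admissible window, the naive vector $\pm 5$ stage-1-difference SDs
  (`solver_config(box = )`). The bias integrands saturate in the tails, so
  the clamp is inert for ordinary trials — the worked example's trajectory
  and iteration count are identical with and without it — while keeping
  the solve well defined for every simulated trial.
* **Degenerate inputs.** Stopped trials refuse estimation (there is
  nothing to estimate conditional on continuation); `k = 1` designs route
  the selection machinery through $m = B$; `b = -Inf` short-circuits the
  control correction exactly.

## The worked example

The packaged fixture (`load_table1()`) is a case study of three doses of
an experimental drug for generalized anxiety disorder against placebo;
the endpoint is the 8-week change in Hamilton Rating Scale for Anxiety
total score, taken normal with known SD 6 points, $n_1 = n_2 = 71$
($t = 0.5$) and futility boundary 0. Dose 2 wins the interim
($X_{(2)} = 1.567$ from dose 3, $B = -0.082$) and the trial continues.

```{r example}
run_example()
```

The four estimates order as the theory predicts: naive highest, the two
corrected estimators below the stage-2 value, the bias adjustment
correcting hardest. The bias-adjusted solve stops at iteration 15 under
the default tolerance.

## The simulator and what it does (not) show

`run_conditional()` reproduces the conditional-on-continuation design:
trials are rejection-sampled — not sampled from a truncated law — until a
target number of continuing replicates is reached (default 10,000, the
study-condition replication), with an attempt cap guarding cells whose
continuation probability is near zero, and all four estimators are
evaluated per replicate. Bias and $\sqrt{\mathrm{MSE}}$ are reported both
raw and in SE units, $\mathrm{SE} = \sqrt{2\sigma^2/(n_1+n_2)}$, the SD of
a single two-stage difference estimator. Because the continuation
probability depends on $b/\sigma_1$ and not on $t$ alone, SE-unit results
are *not* fully invariant to the sample-size split at fixed $t$; both
scalings are therefore reported and only the raw scale is used in
assertions. The default grids use $\sigma = 1$ with per-comparison total
$n_1 + n_2 = 100$ and small standardized differences (0.025–0.05), the
effect-size regime these designs target; cells run on substreams derived
from the seed and the cell index so any cell can be recomputed alone. The
test suite runs $10^5$ conditional replicates per cell for the
unbiasedness grid and $10^4$ for the operating-characteristic patterns —
sizes at which the 3-MC-SE certificates are sharp to a few times
$10^{-3}$.

The generator emulates exactly the model under which the estimators are
derived: arm-level normal means with known, common, homoscedastic
variance. Real trials violate this in ways the simulator deliberately does
not model — estimated variances, non-normal or skewed endpoints, unequal
allocation, overrunning patients recruited between the interim cutoff and
the selection decision, and selection rules that weigh safety as well as
efficacy. Passing tests certify the mathematics of the estimators under
their stated model, not robustness to those departures.

## Known limitations

* The variance must be known; no plug-in or $t$-type extension is
  provided.
* Dropped arms get no conditionally unbiased mean estimate (no such
  estimator is available under this conditioning); only the bias-adjusted
  machinery covers them.
* Estimation applies only to trials that continue; a stopped trial yields
  no stage-2 estimate by design.
* Confidence intervals matched to these point estimators are out of
  scope.
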