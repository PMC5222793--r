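---
title: "Two-dimensional Bayesian estimation of the contrast sensitivity function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-dimensional Bayesian estimation of the contrast sensitivity function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfbayes)
```

## The model

The spatial contrast sensitivity function (CSF) gives an observer's
sensitivity — the reciprocal of their threshold Michelson contrast — as a
function of the spatial frequency $f$ (cycles/degree) of a grating.
`csfbayes` parameterizes it with the double-exponential form

$$S(f) = M\, f^{A} e^{-f/F},$$

which rises as a power law at low frequencies, decays exponentially at high
frequencies, peaks at $f = A F$, and has peak amplitude
$M (F A)^A e^{-A}$. Along the contrast dimension, the probability of a
positive response in a two-alternative forced-choice (2AFC) detection task
is a logistic function of log contrast whose midpoint is the CSF threshold
$1/S(f)$:

$$P(f, c) \;=\; \gamma + \frac{1 - \gamma - \delta}
  {1 + \exp\!\big(-\beta\,(\ln c + \ln M + A \ln f - f/F)\big)}.$$

Here $\gamma$ is the guess rate — a fixed property of the task, $1/2$ for
2AFC, never an inferred quantity — and $\delta$ is the lapse rate, the
small probability of missing an arbitrarily visible stimulus. A single
slope $\beta$ is shared across frequencies. The full parameter vector is
$\theta = (M, A, F, \beta, \delta)$.

All internal likelihood arithmetic uses natural logarithms; the parameter
grid, priors, and reported point estimates live in $\log_{10}$ coordinates,
with the conversions centralized in the model layer.

## Gridded Bayesian inference

`infer_csf()` represents the posterior over $\theta$ on a rectangular
$\log_{10}$-space grid, by default $32 \times 32 \times 32 \times 8 \times
8$ nodes over $(M, A, F, \beta, \delta)$. The prior is an independent
normal per dimension with means $(2.00, -0.30, 0.78, 0.62, -1.70)$ and
dispersions $(0.50, 0.50, 0.50, 0.11, 0.02)$. Two of these defaults
deserve explanation:

* **Lapse-rate prior mean.** A prior centered at $\log_{10}\delta = -0.30$
  would place the typical observer at $\delta \approx 0.5$, which in a 2AFC
  task makes every response uninformative ($P \equiv 1/2$). The package
  centers the lapse prior at $-1.70$ ($\delta \approx 0.02$), the narrow
  nuisance prior that psychometric-fitting practice recommends; the wider
  alternative remains available through `prior_mean`.
* **Dispersion values are standard deviations.** Read as variances, the
  same numbers produce a prior wide enough that occasional degenerate CSF
  shapes dominate the pooled error; read as standard deviations they
  reproduce this package's reference precision benchmarks. The default is
  therefore `diag_is_sd = TRUE`, with the variance reading one flag away
  for sensitivity analyses.

Each grid axis spans the prior mean $\pm 2.5$ prior standard deviations,
linearly spaced in $\log_{10}$ with endpoints included. This covers both
reference observers (normal and amblyopic, below) while keeping the node
spacing informative. The trial likelihood at a node is Bernoulli,
$P^{r}(1-P)^{1-r}$, accumulated in log space per node so that
hundreds of trials cannot underflow double precision. Because the
likelihood factorizes over trials, batch inference is order-invariant and
exactly equals the fold of single-trial updates; the test suite asserts
both, plus node-by-node agreement with a brute-force loop implementation.

The point estimate is the **marginal posterior mean of each parameter in
$\log_{10}$ space** (the grid's native coordinates), exponentiated to the
linear scale, and the estimated CSF is $S(f)$ evaluated at that point.

### The fast likelihood path

A session of Monte-Carlo evaluation performs thousands of full-grid
inferences, each touching two million nodes per trial cell. The exact
vectorized evaluation (the `approx = FALSE` default of `infer_csf()`) costs
a few seconds per 108-trial log. The `approx = TRUE` path used by the
evaluation harness exploits the model's structure: at fixed $(\beta,
\delta)$ the cell log-likelihood depends on the node only through the
scalar $z_0 = \ln c - \ln \alpha(f)$, where $\alpha(f) = 1/S(f)$. The
kernel therefore (1) tabulates $\log P$ and $\log(1-P)$ once per grid
configuration on a dense uniform $z_0$ axis (32,768 points) for every
$(\beta, \delta)$ node, (2) accumulates each log's pooled cell
contributions on a dense per-frequency $\ln\alpha$ axis (4,096 points) by
linear interpolation, and (3) maps those curves onto the actual grid nodes
with a second linear interpolation. The interpolation error is bounded by
the curvature of $\log P$ over one table step (worst case about $10^{-4}$
per cell at the steepest admissible slope); in practice the two paths agree
to better than $2 \times 10^{-3}$ in every $\log_{10}$ marginal mean and
0.05 dB in the estimated CSF, which the test suite asserts. All reported
precision figures are insensitive to this choice.

## The four adaptive samplers

All samplers propose stimuli on a shared grid: 12 spatial frequencies from
0.5 to 22.6 c/d in half-octave steps, and 151 contrasts from 0.001 to 1 in
0.02 $\log_{10}$ steps.

**Weighted up-down staircase.** One independent staircase per frequency,
randomly interleaved. After a negative response the contrast steps up by a
factor $4/3$ (+33%); after a positive response it steps down by $0.9$
(−10%); during each staircase's first four trials the cubed factors are
used to traverse the range quickly. Steps snap to the nearest contrast
node (ties toward the lower contrast) and clamp to $[0.001, 1]$. The
asymmetric steps equilibrate where the response probability is
$\ln(4/3) / (\ln(4/3) + \ln(10/9)) \approx 0.73$, just below the 2AFC
midpoint of 0.74 — verified in a 12,000-trial convergence test. The native
threshold estimate is the reciprocal geometric-mean contrast of the trials
after the four warmup trials. At a 48-trial budget each staircase gets
exactly four trials, so the exclusion rule would discard everything; the
estimator then discards only $\min(4, n-1)$ leading trials so the final
trial always contributes.

**Psi method.** One independent two-parameter $(\alpha, \beta)$ posterior
per frequency, randomly interleaved. The $\log_{10}\alpha$ axis has 64
nodes, clamped to $[-3, 0]$ (the presentable contrast range); the
$\log_{10}\beta$ axis has 8 nodes spanning $0.62 \pm 2.5 \times 0.11$. The
per-frequency prior is normal with $\alpha$ mean $-\log_{10} S(f)$ at the
prior-mean CSF and dispersions $(5, 0.11)$; guess and lapse rates are fixed
at $0.5$ and $0.02$ inside each run. Each trial selects the contrast
minimizing the expected posterior entropy; the native sensitivity estimate
is $10^{-\mathrm{E}[\log_{10}\alpha]}$.

**qCSF-style sampler.** Expected-entropy minimization over the joint
frequency-contrast grid using a 5-D CSF-parameter posterior. The package
uses the information-gain identity: the expected posterior entropy after
observing the response to stimulus $x$ equals the current entropy minus the
mutual information $I(r; \theta \mid x)$, which needs only two inner
products per candidate against precomputed tables of $P$ and
$\phi(P) = P\ln P + (1-P)\ln(1-P)$. Candidates may be randomly subsampled
each trial (default 100 of 1,812) — selection quality degrades negligibly
while the per-trial cost drops an order of magnitude.

**Fisher information gain (FIG).** One-step-ahead D-optimality: each
candidate is scored by $\det(J + I(x; \hat\theta))$, where $J$ is the
accumulated information matrix (ridge-initialized with $10^{-8} I$) and
$I(x; \hat\theta) = \nabla P\, \nabla P^{\top} / [P(1-P)]$ is the rank-one
Fisher information of a Bernoulli trial at the current posterior-mean
parameters, using analytic gradients with respect to $(\log_{10} M,
\log_{10} A, \log_{10} F, \log_{10}\beta)$. The lapse rate is excluded
from the matrix: its near-zero derivatives would make the determinant
ill-conditioned, and it is a nuisance parameter. By the matrix-determinant
lemma the ranking reduces to the quadratic form $u^{\top} J^{-1} u$, so
scoring all 1,812 candidates is cheap. The stimulus is drawn uniformly
among the top 10% of candidates, which avoids locking onto a single
stimulus and spreads sampling over the frequency range.

**Sampler-internal posteriors.** FIG and the qCSF-style sampler need a
posterior only to *choose stimuli*, a far less demanding job than final
estimation. Their internal posteriors therefore run on reduced grids by
default ($12^3 \times 6 \times 6$ for FIG; $8^3 \times 5 \times 5$ for
qCSF, whose per-candidate tables grow with the node count), while every
*reported* estimate — for all four samplers — is recomputed on the full
$32^3 \times 8 \times 8$ grid from the complete trial log. This mirrors
the practice of re-estimating with one common engine whatever toolbox
collected the data, and it is what makes the estimates comparable across
samplers.

### Randomness

Every session derives two independent RNG streams from its seed: one for
the sampler (interleaving schedules, tie-breaks, top-10% draws) and one for
the observer's Bernoulli responses. Switching samplers therefore never
perturbs the observer's draws at a matched seed, which keeps method
comparisons paired; and `"stc"`/`"bayes_stc"` (likewise
`"psi"`/`"bayes_psi"`) are computed from the *same* sampled logs. Full
trial sequences are bit-reproducible given a seed.

## Simulated observers and the Monte-Carlo harness

The simulated observer draws Bernoulli responses from the 2-D psychometric
function. Two presets define the study conditions: a **normal** observer
$\{M, A, F, \beta, \delta\} = \{100, 0.8, 4, 4, 0.02\}$ (peak 3.2 c/d) and
an **amblyopic** observer $\{40, 1.2, 6, 4, 0.02\}$ (peak 7.2 c/d), both
2AFC ($\gamma = 1/2$). The amblyopic case deliberately mismatches the
prior, probing robustness; all priors and grids stay at their
normal-vision defaults when it is simulated.

`monte_carlo()` runs `N` seeded sessions per trial budget (the reference
budgets are 48–300 trials) and pools the error in sensitivity decibels,
$20 \log_{10} S$:

$$\mathrm{RMSE} = \sqrt{\overline{(20\log_{10}\hat S - 20\log_{10}S_{\mathrm{true}})^2}},$$

one grand mean over all (run, frequency) pairs, and the mean signed error
as the bias. The $20\log_{10}$ convention is the standard contrast
sensitivity decibel; `db_factor = 10` is available for sensitivity
analyses. Run-level bootstrap standard errors (1,000 resamples) qualify
scaled-down comparisons. The area under the log CSF (`aulcsf()`, the
trapezoidal integral of $\log_{10} S$ over $\log_2 f$) is reported
alongside as a scalar CSF summary.

### Problem sizes

The package's own benchmark runs use $N = 1000$ sessions for the cheap 1-D
estimates and $N = 200$ for pipelines requiring a full 5-D inference per
run, at the 108-trial budget; the test suite uses $N = 200$ throughout
with $\pm 3$ bootstrap-SE tolerances. Under these conditions the pooled
RMSE of a pipeline is determined to roughly $\pm 0.1$–0.3 dB.

### What the simulations do and do not show

The simulated observer is stationary: no learning, fatigue, attention
lapses beyond the constant $\delta$, or sequential dependencies. Passing
benchmarks therefore demonstrate correctness of the estimation machinery
and the relative efficiency of sampling strategies under the stated
generative model — not robustness to the nonstationarities of real
psychophysical data. The double-exponential CSF also cannot express
notches or other local irregularities; data from such observers will be
fit by the nearest smooth CSF.

A caveat worth stating plainly: with the wide shape priors above, roughly
2% of 108-trial 1-D-sampled sessions produce posteriors whose mass slides
along the $(A, F)$ ridge toward degenerate CSF shapes (typically when an
edge frequency's staircase sees an uninformative run). These rare sessions
dominate the *pooled* RMSE of the Bayesian re-estimates — the median
session is 0.5–0.8 dB better than the pooled figure. Narrowing the grid,
clamping thresholds to the presentable range, or replacing the estimator
with the posterior mean of $\log_{10} S(f)$ were all evaluated and do not
remove the tail; it is a property of the posterior under this prior.

## Numerical choices

* Likelihood accumulation in log space per node; softmax with max
  subtraction before exponentiation.
* Contrast snapping in $\log_{10}$ space with ties toward the lower
  contrast.
* Expected-information tie-breaks are uniform draws from the sampler's
  stream; exact ties occur when the posterior is a point mass (every
  candidate has zero gain).
* The qCSF candidate tables are packed to single precision, which only
  ranks candidates (never enters the posterior); the ranking agrees with
  the double-precision computation in the tests.
* A posterior update that annihilates all mass (data impossible under
  every node) raises an error rather than returning NaNs.
* Degenerate inputs: empty logs return the prior; responses outside
  $\{0, 1\}$, non-positive contrasts or frequencies, and unknown sampler
  names are rejected with informative errors.

## Known limitations

* The guess rate is a configuration constant; designs with $n > 2$
  alternatives are expressed only through `gamma`.
* The staircase's 3:1 up/down step ratio is implemented with the literal
  factors $4/3$ and $0.9$; exact-ratio variants are reachable through
  `up_factor`/`down_factor`.
* MAP/median point estimates and particle or MCMC posterior
  representations are out of scope; the marginal mean is the estimator.
* The Monte-Carlo harness evaluates simulated observers only; validating
  against human data requires external trial logs, which `cmd_infer()`
  accepts in CSV form from any sampling procedure.
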