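---
title: "Models and methods behind uaeopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind uaeopt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uaeopt)
```

uaeopt implements the two surrogate-modeling routes commonly used to
optimize ultrasound-assisted extraction of plant bioactives —
response-surface methodology and a feed-forward network coupled to a
genetic algorithm — together with the designed experiment that feeds
them. This vignette records the models, the defaults and the numerical
decisions, so that a user (or reviewer) can see exactly what is computed
and why.

## The designed experiment

A rotatable central composite design (RCCD) in $k$ factors consists of a
$2^k$ factorial block at coded $\pm 1$, $2k$ axial runs at coded
$\pm\alpha$ with $\alpha = (2^k)^{1/4}$, and $n_c$ replicated center
runs. Rotatability makes the prediction variance of the fitted quadratic
constant on spheres around the center; the center replicates supply a
model-free estimate of replicate variance (pure error). The bundled
garlic-leaf study uses $k = 3$ (ultrasound amplitude, centered at 45 %
with a 15 % step; treatment time, 10 min ± 5 min; ethanol concentration,
50 % ± 10 %) and $n_c = 6$, hence 20 runs and $\alpha = 2^{3/4} = 1.6818$.

Coding is affine, $x = (\text{actual} - \text{center})/\text{step}$, and
all models are fit in coded units so coefficient magnitudes are
comparable across factors.

**Snapping.** Published run tables print rounded actual values at axial
runs (e.g. 70 for 70.23 % amplitude, 18 for 18.41 min). Ingestion
therefore codes each value and replaces any coordinate within `tol` of a
nominal level $\{-\alpha,-1,0,1,\alpha\}$ by that level. The default
`tol = 0.1` was set from the worst rounding present in the study table:
the time axials print as 2 and 18 min, which code to $\pm 1.6$, i.e.
0.082 coded units from $\pm\alpha$ — beyond the 0.05 one might first
guess — while genuinely off-design points of interest (53 % amplitude
codes to 0.533) sit at least 0.13 from any level. A tolerance of 0.05
would silently leave two axial runs mis-coded at $\pm 1.6$ and bias every
coefficient; this is why the looser default matters.

## Response-surface route

Each response is modeled by the full second-order polynomial in coded
variables (10 terms for $k=3$), estimated by ordinary least squares. The
ANOVA splits the residual sum of squares into *pure error* (within groups
of runs with identical coded coordinates) and *lack of fit*, compared by
an F test with, here, 5 and 5 degrees of freedom; per-term significance
uses partial (type III) F tests, which for single-degree terms coincide
with the squared coefficient t tests. When a design has no replicated
point the lack-of-fit rows are reported as `NA` rather than failing,
since the decomposition is simply unavailable.

Two printed-source discrepancies are worth recording. First, the study's
equation listing gives the yield $X_2^2$ coefficient as −0.3482 while its
coefficient table prints −0.2192; refitting the published run table
reproduces the table (and the table alone is consistent with the printed
per-run predictions), so the coefficient table is treated as
authoritative. Second, the printed $R^2$ formula centers the *predicted*
values in the denominator; only the standard form
$R^2 = 1 - \sum(x_p - x_a)^2 / \sum(x_a - \bar x_a)^2$ reproduces the
published values, so the standard form is the default and the printed
variant is available via `r2_denominator = "predicted"`.

`optimize_rsm()` maximizes a composite objective (by default the
unweighted sum of all fitted responses, matching the GA's fitness) by a
dense grid scan — 101 points per axis over the coded box, $[-1,1]^3$ by
default — followed by an `L-BFGS-B` polish from the best grid point. For
a quadratic objective in three dimensions this is exhaustive at
sub-second cost; doubling the grid moves the optimum by less than one
grid step, which the tests assert.

## Error statistics

`model_metrics()` computes MSE, RMSE, AAD (mean absolute deviation), MPE
(mean percentage error), the mean-normalized NMSE and NRMSE, and $R^2$.
Two conventions needed a decision:

* **MPE denominator.** The printed formula divides by the predicted
  value, but recomputing the published comparison grid shows it was
  actually produced with the *experimental* value in the denominator
  (both conventions agree to 2 decimals for three responses; the TFC
  column discriminates and matches only the experimental form). The
  default is therefore `mpe_denominator = "experimental"`, with the
  literal printed form behind a flag.
* **NMSE/NRMSE rows.** The published table's NMSE and NRMSE rows are
  numerically RMSE/mean and MSE/mean respectively — transposed relative
  to their own definitions. uaeopt implements the definitions
  (NMSE = MSE/mean, NRMSE = RMSE/mean) and does not attempt to match
  those two rows.

## Neural surrogate route

Each response gets its own $3\!-\!H\!-\!1$ network ($H = 10$ by default)
with a `tansig` (hyperbolic tangent) hidden layer and linear output.
Inputs and target are min–max normalized to $[-1,1]$ over the full
dataset — the silent default of the toolbox this architecture mirrors.
The runs are split 70/15/15 into training, validation and test subsets
(14/3/3 for 20 runs), deterministically per seed.

Training is Levenberg–Marquardt on the training subset: solve
$(J^\top J + \mu I)\,\delta = -J^\top r$, accept the step if the training
error drops (then $\mu \leftarrow 0.1\mu$), otherwise grow
$\mu \leftarrow 10\mu$ and retry. The normal equations are formed on the
*mean*-square scale so that $\mu$'s conventional starting value
($10^{-3}$) has the same meaning whatever the training-set size; on the
raw sum-of-squares scale the first steps are effectively undamped
Gauss–Newton and a 41-parameter network interpolates 14 points within two
or three epochs, skipping the well-generalizing part of the trajectory.
Weights start from the Nguyen–Widrow rule (hidden units of magnitude
$0.7H^{1/k}$ with biases spread across the input cube), which in our
measurements removed the frequent bad local minima of naive small-uniform
initialization. Stopping: gradient norm below $10^{-7}$, $\mu > 10^{10}$,
an epoch budget of 1000, or six consecutive validation epochs without
improvement; the returned weights are those of the best validation epoch.
A split with no validation points disables early stopping and returns the
final weights — tests use this to probe pure optimizer correctness and
surrogate capacity separately from generalization.

With 20 runs, three validation points make early stopping noisy: some
seeds freeze an early epoch and generalize poorly, others nearly
interpolate. This is inherent to the data size, which is why surrogate
quality statements in the tests are made about the median over 25 seeds,
and why the optimization outcome (next section) — not per-run prediction
equality — is the meaningful reproduction target for retrained networks.

## Genetic-algorithm route

The GA minimizes $f = -(Y_1+Y_2+Y_3+Y_4)$, each $Y_i$ from its surrogate,
over a box of actual factor values. Defaults follow the toolbox settings
the study reports keeping: population 50, 100 generations, crossover
fraction 0.8, elitism 2, roulette selection. Three operators required
interpretation:

* **Rank scaling + roulette.** Raw-fitness roulette is ill-defined for
  negative fitness; selection therefore draws with probabilities
  proportional to $1/\sqrt{r}$ for rank $r$, the standard rank scaling.
* **Scattered crossover** is a uniform random mask between two parents.
* **Mutation** approximates the toolbox's adaptive operator by Gaussian
  noise with standard deviation 0.1 coded units, decaying linearly to
  zero over the generation budget, clipped to the bounds.

Bounds default to the factorial region (amplitude 30–60 %, time
5–15 min, ethanol 40–60 %): the study's reported ANN-GA optimum sits
exactly on the 60 % amplitude bound, which is only a boundary under
these bounds (the axial range is configurable). With elitism the best
fitness is non-increasing by construction, and the run stops on a
50-generation stall ($<10^{-6}$ improvement) or the generation budget.
The result reports both the best and the population-mean fitness; the
mean at convergence is the study's headline quantity. Migration settings
are meaningless for a single population and are not supported.

## Synthetic ground truth

`true_surface()` + `simulate_runs()` generate run tables from known
quadratic coefficients plus homoscedastic Gaussian replicate noise,
deterministically per seed, with one substream per response (derived
from the response name) so adding a response never perturbs the others'
draws. `garlic_scenario()` instantiates the study itself as ground
truth: its design, its published coefficients, and per-response noise
equal to the published residual RMSE (0.163 % EY, 0.0353 TPC, 0.1442
TFC, 0.5298 % AA) — the replicate scatter the study exhibits.

What the generator emulates: a correctly specified quadratic signal with
i.i.d. Gaussian noise over an exactly executed design. What it does not:
heteroscedasticity, factor-setting error, drift between runs, model
misspecification. Passing parameter-recovery tests therefore
demonstrates correctness of the estimation and optimization machinery,
not robustness to those real-data features.

## Problem sizes and numerical choices

The test-suite simulations use the study's own scale: the 20-run design
throughout, 200 replications for bias checks (Monte-Carlo standard
errors ≈ 0.002–0.01 response units, comfortably resolving biases of
interest), 25 seeds for network/GA medians, and a 201-per-axis
brute-force grid as the optimization oracle. Grid evaluation is chunked
by axis slabs to keep memory flat. Optimizer determinism is anchored by
`withr::with_seed()` around every stochastic block; file outputs are
plain CSV with full-precision text serialization for network weights
(reload reproduces predictions bit-for-bit).

## Known limitations

* The quadratic route cannot express asymmetric or plateau responses;
  that is a property of RSM, not of the implementation.
* Network training on 20 runs is seed-sensitive by nature; single-seed
  results should never be interpreted alone.
* The GA handles box bounds only — no nonlinear constraints, no
  multi-objective front.
* Assay helpers implement the standard sign convention for DPPH
  scavenging, $(A_C - A_S)/A_C \times 100$; the occasionally printed
  sign-flipped form is available behind `as_printed = TRUE` but yields
  negative values for any scavenging sample.
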