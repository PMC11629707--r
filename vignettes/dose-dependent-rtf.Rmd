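---
title: "Modelling time- and dose-dependent signalling responses with rtfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling time- and dose-dependent signalling responses with rtfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

Many cellular signalling readouts — phosphorylation levels, reporter
intensities, released cytokines — respond to a stimulus with a rise to a
new steady state, possibly with a transient overshoot, and never with
sustained oscillations.  `rtfit` models such responses with the retarded
transient function (RTF), a phenomenological curve family

$$R(t) \;=\; A\,\bigl(1 - e^{-\alpha\,t'}\bigr) \;+\;
  B\,\bigl(1 - e^{-\beta\,t'}\bigr)\,e^{-\gamma\,t'} \;+\; b ,$$

a sum of a *sustained* component with amplitude $A$ and rate $\alpha$, a
*transient* component with amplitude $B$, rise rate $\beta$ and decay rate
$\gamma$, and an offset $b$.  The argument $t'$ is not raw time but the
retarded transformation

$$t'(t, \tau) \;=\; \log_{10}\!\bigl(10^{\,t \cdot 10 / T} + 10^{\tau}\bigr)
  \;-\; \log_{10}\!\bigl(1 + 10^{\tau}\bigr),$$

where $T$ is the time range of the dataset (making the model independent of
time units; the transformed axis spans roughly $[0, 10]$) and the time
shift $\tau$ delays the onset of the response: larger $\tau$, later
response.  At $t = 0$ the curve equals $b$ exactly; for $\gamma > 0$ it
approaches $A + b$ at late times.  Measurements are modelled as the curve
plus additive Gaussian noise with a single standard deviation $\sigma$,
shared by all doses, conditions and replicates.

## Dose dependence

To describe how the kinetics change with the stimulation dose $d$, each of
the six dynamic parameters is replaced by a Hill function of dose,
$H(d) = M\,d^h / (K^h + d^h)$, with maximum $M$, half-maximal dose $K$
(the EC50) and Hill coefficient $h$.  The time shift is the one parameter
that *decreases* with dose — stronger stimulation produces an earlier
response — so $\tau(d) = M_\tau\,(1 - d^{h_\tau} / (K_\tau^{h_\tau} +
d^{h_\tau}))$.  The fully dose-dependent model therefore has
$6 \times 3 + 2 = 20$ free parameters.

Setting $K = 0$ makes a Hill curve constant and the Hill coefficient
irrelevant; `rtfit` treats $K = 0$ as the explicit "no dose dependency"
marker, under which the parameter equals the constant $M$ at every dose
(for the decreasing $\tau$-form as well — this is what makes the
dose-dependent model collapse exactly onto the plain time-dependent RTF
when all $K$ are zero, a property the test suite checks to $10^{-12}$).
Note the distinction from the raw algebra of the decreasing Hill form,
which would give $0$ for $d > 0$; the primitive `rtf_hill()` follows the
algebra, the model layer `rtf_params_at_dose()` follows the sentinel
convention.

## Conditions and fold-changes

When the same dose-response design is measured in several biological
conditions (wild-type vs. knockout cells, say), one condition is declared
the reference and every other condition re-uses the reference parameters
except for named scalars that carry a multiplicative fold-change
$\Delta > 0$ (e.g. $M_A^{(ko)} = \Delta_{M_A} M_A^{(wt)}$).  $\Delta = 1$
means no condition effect, so "is this parameter different in the
knockout?" becomes the sharp null hypothesis $\log\Delta = 0$.

# Estimation

`rtf()` maximizes the Gaussian log-likelihood over a box-constrained
parameter space with `stats::nlminb`, from multiple starts: the default
initial guess plus Latin-hypercube draws (`lhs::randomLHS`) spread over
each parameter's box.  Strictly positive parameters (rates, $K$, $h$,
$\sigma$, $\Delta$) are optimized and profiled on the $\log_{10}$ scale;
amplitudes, the time shift and the offset, which may legitimately be zero
or negative, stay linear.  The sorted final objectives of all starts form
the waterfall diagnostic (`waterfall()`, `plot(fit, which = "waterfall")`);
a fit is flagged as reliably converged when at least two starts reach the
best optimum within $10^{-3}$ log-likelihood units.  The default of 50
starts is deliberately conservative; the examples and tests use 4–8 starts,
which on the package's synthetic designs find the same optimum repeatedly.

## Default parameter box

`rtf_bounds()` derives bounds and initial guesses from the data (reference
condition only, when several conditions are present):

| parameter | lower | upper | initial |
|---|---|---|---|
| $M_A$, $M_B$ | $0$ | $2(\max y - \min y)$ | $0.1\,lb + 0.9\,ub$ |
| $M_\alpha$, $M_\beta$, $M_\gamma$ | $1/(2\,(\max t' - \min t'))$ | $2/\min_i(t'_{i+1}-t'_i)$ | midpoint |
| $M_\tau$ | $-(\max t' - \min t')/5$ | $(\max t' - \min t')/2$ | $-(\max t' - \min t')/10$ |
| $h$ | $1$ | $10$ | midpoint |
| $K$ | $\min(d > 0)/10$ | $10 \max d$ | midpoint |
| $b$ | $\min y$ | $\max y$ | midpoint |
| $\sigma$ | $\min(ub, \max(10^{-10}, (\max y - \min y)/10^4))$ | $\max(10^{-10}, \mathrm{SD}(y))$ | midpoint |
| $\Delta$ | $10^{-2}$ | $10^{2}$ | $1$ |

Here $t'$ are the raw distinct measurement times: the rate and time-shift
rows are expressed in units of the experimental time axis.  This is one of
two defensible readings (the other uses transformed times); we use raw
times, which coincide with the transformed scale whenever the measurement
window spans about ten units, as in all shipped designs.  For a
down-regulated amplitude (`sign = c(A = "down")`) the amplitude box is
mirrored to $[-ub, 0]$; $K$ and $h$ stay positive.  The $\Delta$ box of two
orders of magnitude around 1 covers biologically plausible fold-changes
without allowing the condition difference to absorb the whole signal.

Because the sustained and transient parts of a response are usually
triggered together, $\beta$ and $\gamma$ are tied to $\alpha$ by default
(`ties = c(beta = "alpha", gamma = "alpha")`); pass `ties = NULL` for the
fully free 8- or 20-parameter model.  Fixing $B = 0$
(`fixed_to_zero = "B"`) removes the transient component entirely, including
$\beta$ and $\gamma$.

# Uncertainty

Confidence intervals come from the profile likelihood: one parameter is
stepped away from its estimate while all others are re-optimized, and the
interval is the region where the profile stays within
$\chi^2_1(0.95)/2 = 1.92$ log-likelihood units of the optimum.  The
stepping is adaptive, targeting a drop of about $0.1$ per step with
backtracking when a step overshoots by more than $0.5$, capped at 100 steps
per direction, and always traced slightly beyond the 99% threshold so that
`confint(profile, level = ...)` supports any level up to 0.99 from a single
profile.  Crossings are located by linear interpolation on the profiling
scale.  If a profile reaches a bound of the parameter box before crossing
the threshold, the interval is reported open on that side; a profile flat
on both sides marks the parameter as unidentifiable.  Re-optimization
failures at single grid points are recorded as gaps and profiling
continues.

`test_fold_change()` declares a fold-change significant exactly when 1
falls outside its profile CI, which is equivalent to a likelihood-ratio
test of $\log\Delta = 0$ at the same level (`lrt()` provides the explicit
test for nested fits).

# Model reduction

`backward_eliminate()` greedily simplifies a model: at each round every
removable dose dependency ($K \to 0$, two parameters saved) and condition
dependency ($\Delta \to 1$, one parameter per extra condition) is
tentatively removed and refitted — warm-started from the current estimates
plus 10 fresh Latin-hypercube starts — and the removal with the largest
likelihood-ratio p-value is accepted if that p-value exceeds
$\alpha = 0.05$.  The procedure stops at the first round where every
removal would significantly worsen the fit.  Greedy elimination can depend
on the removal order, so the returned trail records every tested removal
(statistic, df, p-value, log-likelihoods) for auditing; terms given in
`protect =` are never offered, encoding prior biological knowledge.

# The synthetic data generator

`simulate_timecourse()` draws data from the exact generative model the
estimator assumes: RTF surface plus i.i.d. Gaussian noise.
`simulate_inflammasome()` is a ready-made two-condition design emulating a
cytokine-release ELISA under an ionophore dose ladder: 7 doses (1–10
concentration units), 8 time points (0–10 time units), 3 replicates,
sustained-only responses ($B = 0$), and a "knockout" condition that is
weakened, slowed and delayed relative to the "wildtype" reference through
fold-changes on $M_A$ (0.4), $M_\alpha$ (0.6), $M_\tau$ (1.5), $K_A$ (1.5)
and $h_\alpha$ (0.7).  The generating truth uses mid-box Hill parameters
($M_A = 1$, $K_A = 4$, $h = 2$; $M_\alpha = 0.8$, $K_\alpha = 3$;
$M_\tau = 2$, $K_\tau = 5$; $b = 0.05$) and, by default, noise of exactly
2% of the noise-free response range ($\sigma \approx 0.017$).

What the generator deliberately does *not* emulate: plate effects,
heteroscedastic or multiplicative ELISA error, dropout, dose-measurement
error, or any deviation of the true dose-response shape from a Hill curve.
Tests passing on these data therefore demonstrate the correctness and
calibration of the machinery under its own assumptions — not robustness to
the ways real ELISA data violate them.

# Numerical choices and problem sizes

* Optimizer: `nlminb` with `rel.tol = 1e-10`, at most 500 iterations and
  2000 objective evaluations per start, driven by an analytic gradient of
  the negative log-likelihood (chain rule through the Hill dose
  resolution, fold-changes, ties and the time transformation; verified
  against central finite differences in the test suite).  Profile
  re-optimizations use `L-BFGS-B` with a 20-pair correction history, which
  handles the ill-conditioned ridge left by the fixed parameter markedly
  better than a short-memory method.
* The time transformation is evaluated in a log-sum-exp-stable form and
  does not overflow for exponents far beyond double range.
* Ties are applied after Hill evaluation at each dose, so a tied $\gamma$
  inherits $\alpha$'s full dose dependency, including any fold-changes.
* Degenerate inputs fail fast with informative errors: non-positive time
  range, fewer than 3 distinct time points, fewer than 2 distinct doses
  for a dose-dependent model, negative doses, non-positive $\sigma$.
* The simulation studies shipped with the package use 20 seeds for
  recovery and type-I-error checks, 50 for the coverage check and 10 for
  reduction recovery, with 4–8 optimizer starts per fit; these sizes give
  stable medians and binomial counts while keeping each study in the
  minutes range on a single core.

# Known limitations

* Single-peak, non-oscillatory responses only; oscillations are averaged
  over, not described.
* One shared $\sigma$; grouped or signal-dependent error models are not
  implemented.
* Profile-based intervals are pointwise, not simultaneous.
* Greedy backward elimination explores one removal order; the trail makes
  the path auditable but no exhaustive subset search is attempted.
* Hill $K$ and $h$ are independent per dynamic parameter; only their
  bounds are shared.

# A worked two-condition analysis

```{r, eval = FALSE}
library(rtfit)

d <- simulate_inflammasome(seed = 1)
spec <- rtf_spec(dose_dependent = c("A", "alpha", "tau"),
                 fixed_to_zero = "B",
                 conditions = c("wildtype", "knockout"),
                 condition_dependent = c("M_A", "M_alpha", "M_tau",
                                         "K_A", "h_alpha"))
fit <- rtf(d, spec, n_starts = 8, seed = 1)
print(fit)
plot(fit)

prof <- profile(fit, "delta_M_A")
test_fold_change(prof)
confint(fit, parm = c("M_A", "K_A"))
```
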