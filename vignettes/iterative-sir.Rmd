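---
title: "Iterative sampling importance resampling for parameter uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative sampling importance resampling for parameter uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirnlme)
```

## The problem

A fitted nonlinear mixed-effects model (NLMEM) reports point estimates for
its fixed effects, random-effect variances and residual variances.  Most
downstream uses — trial simulation, dose adaptation, interaction
assessment — also need the joint *uncertainty* of those estimates.  The
standard options all have failure modes: the asymptotic covariance matrix
forces symmetric normal uncertainty (variances are bounded at zero and
right-skewed in practice, and the matrix itself is often unobtainable for
difficult models); the case bootstrap needs a thousand re-estimations and
breaks on small or unbalanced designs; the parametric bootstrap (SSE)
inherits every estimation problem of the model.

Sampling importance resampling (SIR) avoids re-estimation entirely.  It
needs only the ability to *evaluate* the likelihood at arbitrary parameter
vectors:

1. **Sample** $M$ parameter vectors from a parametric proposal
   distribution.
2. **Weight** each vector by its importance ratio
   $$IR = \frac{\exp(-\tfrac12\, dOFV)}{relPDF},$$
   where $dOFV$ is the vector's objective function value
   ($OFV = -2\log L$ up to a constant) minus the OFV at the final
   estimates, and $relPDF$ is the proposal density at the vector relative
   to the proposal density at the final estimates.  The numerator is the
   (relative) likelihood of the data under the vector; the denominator
   corrects for how often the proposal generates it.
3. **Resample** $m < M$ vectors with probabilities proportional to $IR$.

The $m$ resampled vectors are an empirical sample of the parameter
uncertainty distribution.  As $M \to \infty$ they represent it exactly;
at finite $M$ they are closer to it than the proposal was.

## The iterative, automated procedure

A single SIR pass depends on the quality of the proposal.  The procedure
implemented in `run_sir()` iterates: the resamples of one iteration are
fitted with a multivariate Box-Cox distribution, which becomes the
proposal of the next iteration.  Iterations continue until the dOFV
distributions of the resamples of two consecutive iterations are overlaid
up to resampling noise.

The **schedule** defaults to $M = 1000$ with $m = 200, 400, 500$ for the
first three iterations (high $M/m$ buys fast improvement of the proposal
cheaply) and $M = 2000$, $m = 1000$ thereafter (precise estimation of the
final uncertainty).  The schedule affects efficiency, not the converged
answer, and is user-configurable.

The **Box-Cox proposal** transforms each parameter with
$z_k = ((x_k + s_k)^{\lambda_k} - 1)/\lambda_k$ ($\lambda_k = 0$ meaning
$\log$) and places a multivariate normal on $z$.  Parameter-specific
shapes let fixed effects stay symmetric ($\lambda \approx 1$) while
variances come out right-skewed ($\lambda \approx 0$, log-normal-like),
which is what their bounded, skewed uncertainty calls for.  Correlations
are linear on the transformed scale.  The density used in $relPDF$
includes the Jacobian $\prod_k (x_k + s_k)^{\lambda_k - 1}$.

The **dOFV diagnostic** rests on the likelihood-ratio argument: if the
resamples truly represented the uncertainty, their dOFV values would
follow (at most) a $\chi^2_k$ distribution with $k$ the number of
estimated parameters.  `estimate_df()` fits the $\chi^2$ degrees of
freedom by maximum likelihood; a final df at or somewhat below $k$ marks
adequate uncertainty, a df above $k$ marks vectors that the model and
data consider too unlikely.

**Underestimated proposals.**  If the *first* proposal's dOFV curve lies
below the $\chi^2_k$ reference, the initial uncertainty is likely
underestimated, and it is harder for SIR to widen than to narrow a
proposal.  `run_sir()` then inflates the initial proposal — all variances
and covariances multiplied by one factor, correlations untouched — trying
1.5, 2, 3 and then doubling until the curve lies above the reference
(configurable ladder and cap).  Later iterations are not checked: the
Box-Cox refit is trusted from there.

**Local minima.**  Any sampled vector whose OFV beats the final estimates
by more than 0.1 triggers a warning and is reported, since it indicates
the original estimation may have stopped at a local minimum.  The engine
never re-anchors silently.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| schedule | (1000, 200/400/500), then (2000, 1000) | samples/resamples per iteration |
| `max_iterations` | 15 | hard cap; typical convergence is ~3, difficult models up to ~11 |
| `inflation_ladder` | 1.5, 2, 3, then doubling | inflation factors for an underestimated first proposal |
| `envelope_B` / `envelope_coverage` | 200 / 0.95 | replicate resamplings and coverage of the noise envelope |
| `convergence_fraction` / `convergence_band` | 0.70 / 5–95 | containment rule for convergence (see below) |
| `underest_fraction` / `underest_band` | 0.50 / 10–90 | how much of the proposal curve must sit below the reference |
| `cap_correlation` | off (suggested 0.95) | cap on transformed-scale proposal correlations |
| `fixed_shapes` | off | fix Box-Cox shapes, e.g. 1 for fixed effects, 0 for variances |

### Numerical conventions

* **OFV constant**: built-in models include the full $n\log(2\pi)$ term
  so OFV values match direct density computations; every downstream
  quantity uses only differences, so the convention is inert.
* **Importance ratios** are computed in log space; a dOFV of thousands
  underflows to $IR = 0$ rather than NaN.  Vectors with failed OFV
  evaluations or zero proposal density get $IR = 0$ and are excluded
  from resampling (with counts logged) — sampled tails may simply be
  unphysical, and this must not abort a run.
* **Resampling** is sequential and without replacement (weights
  renormalised after each draw, order retained), which is what the
  temporal-trends diagnostic needs; with-replacement is an option.
* **Truncation** to parameter bounds is by rejection, never clipping:
  clipping would put probability atoms on the bounds and corrupt
  $relPDF$.  A rejection rate above 50% aborts with a diagnostic.
* **df fitting**: the $\chi^2$ MLE solves
  $\psi(df/2) = \overline{\log x} - \log 2$ by root finding on the
  digamma function.  Negative dOFV values are clipped to zero for the
  fit (raw values are kept for the local-minimum warning); exact zeros
  are excluded from the mean-log statistic, both with logged counts.
* **Non-PSD covariance inputs** (common in published matrices) are
  repaired by eigenvalue clipping, with a warning.
* **Quantiles** are type-7 (linear interpolation) everywhere.
* **Seeds**: one master seed; iteration $i$ uses child seed
  `master + 1000*i + step`, so any single iteration can be reproduced
  alone.

### The convergence rule

"Overlaid up to sampling noise" is, in practice, a visual judgement on
the dOFV plot.  The numeric rule here is: the previous iteration's resamples
curve must lie inside the current iteration's resampling-noise envelope
(per-percentile 95% interval over `envelope_B = 200` replicate
resamplings) at $\ge$ 70% of the percentiles in the 5–95 band.  The 70%
was calibrated on the package's own fixtures: deviations at neighbouring
percentiles are strongly correlated, so even two independent resamplings
of the *same* weighted sample produce containment fractions with a heavy
left tail — a 90% containment demand would reject a true overlay about
30% of the time, while 70% accepts it at $\ge$ 90% of seeds and still
rejects curves shifted by ten envelope widths at every seed.  This rule
is a package convention, not an intrinsic part of the SIR procedure.

## Built-in models and what the fixtures do (and do not) show

The engine only requires an OFV evaluator — any function
`(data, theta) -> OFV` can be plugged in.  Three synthetic families are
built in:

* **conjugate_toy** (linear regression, known residual SD): the
  estimator's sampling covariance is exactly
  $\sigma_0^2 (X^\top X)^{-1}$ and dOFV under the true uncertainty is
  *exactly* $\chi^2_k$.  SIR started from this truth must converge, keep
  df $\approx k$, and reproduce the analytic covariance — the strongest
  end-to-end correctness anchor available anywhere, because the answer
  is known in closed form.
* **linear_mixed** (random intercept + slope covariate, 20 or 200
  subjects $\times$ 4 observations): exact compound-symmetric marginal
  likelihood; large enough for asymptotics, used as the cross-method
  anchor where covariance matrix, bootstrap, SSE and SIR must agree.
* **onecomp_pk** (one-compartment oral PK, log-normal IIV on CL and V,
  proportional error, 30 subjects $\times$ 3 samples): marginal
  likelihood by the Laplace approximation (per-subject mode search),
  checked against 9-node adaptive Gauss-Hermite quadrature.

These fixtures emulate the *mechanics* of population-model uncertainty —
bounded variances, skewed uncertainty of random-effect parameters, sparse
designs — at sizes that run in minutes on one CPU (the problem sizes in
the tests: $M \le 2000$, $m \le 1000$, bootstrap/SSE at 200 replicates).
They do not emulate what makes real pharmacometric models hard:
high-dimensional correlated parameter spaces (up to dozens of
parameters), categorical endpoints, model misspecification, or
likelihoods that are themselves unstable to evaluate.  A passing test
suite therefore validates the procedure's logic and calibration, not its
behaviour on any particular real model.

## Worked example

```{r example, eval = FALSE}
fx  <- make_fixture("conjugate_toy", seed = 7)
fit <- estimate_parameters(fx$model, fx$data)
prop <- proposal_mvn(fit$theta, fit$cov, fx$model$spec)
res <- run_sir(fx$model, fx$data, prop,
               config = sir_config(master_seed = 11))
res
#> Iterative SIR result
#>   status: converged after 3 iteration(s)
#>   initial proposal inflated by 1.5
#>   estimated df by iteration: 3.03, 3.09, 2.98
#>   final df / k: 0.99 (k = 3)

rse(res$final_resamples, fit$theta)
ci95(res$final_resamples)
```

The inflation message illustrates a borderline case worth knowing about:
when the initial proposal is exactly right, its dOFV curve straddles the
reference, and the >50%-below rule can fire on sampling noise.  The
consequence is a slightly widened first proposal, which the iterations
then shrink back — visible above in the df returning to $k$.

## Design choices that were genuinely open

* **Box-Cox fitting**: per-parameter profile-likelihood $\lambda$ on the
  marginals (grid on $[-2, 2]$, then local refinement), then the sample
  covariance of the transformed vectors.  Joint estimation of all
  $\lambda_k$ with the covariance would be more efficient statistically
  but is slower and less robust at $m = 200$; marginal profiles match
  the "parameter-specific shapes, linear correlations on the transformed
  scale" construction.
* **Shifts** $s_k$: zero when all fitted values are positive (variances,
  typical PK fixed effects), otherwise $-\min + 0.1(\max-\min)$, so
  sign-indefinite fixed effects remain fittable.  $relPDF$ uses the
  untruncated density ratio.
* **Inflation ladder**: factors 1.5, 2 and 3 are tried as absolute
  factors on the original proposal; if the curve still sits below the
  reference the last factor doubles until it clears (cap 100).  The
  alternative — aborting after factor 3 — would strand any proposal more
  than ~3x too narrow, including the quarter-scale case the test suite
  exercises.
* **Underestimation is only checked for the first proposal**; afterwards
  the Box-Cox refit is trusted.  Checking every iteration would conflate
  proposal underestimation with genuine uncertainty shrinkage.
* **Oscillation** (df repeatedly crossing its previous value with
  relative changes above 5%) is reported as a status rather than an
  error; the known failure mode is a likelihood that cannot be evaluated
  reliably, which no amount of iteration fixes.
* **df of proposal samples** is computed from unweighted dOFV values
  (the weighting belongs to the resamples, not the proposal).

## Known limitations

* The Laplace approximation in `onecomp_pk` carries an error of order
  0.5 units of $-2\log L$ on sparse designs; accurate on dOFV
  differences (<1% in the quadrature comparison) but not bit-exact.
* The Box-Cox family cannot represent multimodal or heavy-tailed
  uncertainty; with high $M/m$ ratios this costs efficiency, not
  correctness.
* `estimate_parameters()` for the PK model is a plain nested
  optimisation and may flag non-convergence on difficult bootstrap
  replicates; vectors are retained regardless of termination status,
  matching the comparator-method convention.
* No categorical endpoints, no ODE models, no priors: the OFV-evaluator
  contract is the extension point for all of these.
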