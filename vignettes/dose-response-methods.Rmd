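---
title: "Dose-response models, estimation and inference in dosefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response models, estimation and inference in dosefit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosefit)
```

dosefit fits parametric dose-response curves and carries the uncertainty of
the fit through to the quantities a study reports: effective doses,
benchmark doses, relative potencies. This vignette documents the model, the
estimation machinery, the numerical choices, and the conditions under which
the package validates itself — in enough detail that a reader can judge what
a passing test suite does and does not demonstrate.

## The mean model

An observed response $y$ at dose $x \ge 0$ is modelled through its mean,
$E(y) = f(x, \beta)$, with $f$ a parametric curve and the response
distribution supplied separately: normal for continuous responses (possibly
after a variance-stabilizing transform), binomial for quantal data, Poisson
for counts. All built-in families use a unified parameter vocabulary —
steepness $b$, lower/upper limits $c$ and $d$, location $e$, extra shape
$f$ — so that fixing, sharing and comparing parameters works identically
across families.

Sign conventions differ by family and are worth stating explicitly:

* **Log-logistic, Weibull I** — $b > 0$ gives a curve *decreasing* from $d$
  at dose 0 to $c$ at large dose; $b < 0$ the mirror image.
* **Weibull II** — the complement: $b > 0$ is increasing from $c$ to $d$.
* **Log-normal** — $c + (d-c)\Phi(b(\log x - \log e))$ is *increasing* in
  $x$ for $b > 0$ as written; a decreasing curve takes $b < 0$.
* **Gamma** — $c + (d-c)\,G(bx;\, e)$ with $G$ the gamma cdf with shape $e$
  and scale 1. The roles of the arguments are a design decision of this
  package (shape = $e$); the model needs $b > 0$ and is increasing (use
  $d < c$ for decreasing data).
* **NEC threshold** — flat at $d$ up to dose $e$, then exponential decay
  with rate $b < 0$ towards $c$.
* **Hormesis (Brain-Cousens, Cedergreen-Ritz-Streibig)** — decreasing
  overall with a low-dose bump of size governed by $f > 0$; the CRS
  exponent $\alpha$ is a model constant restricted to $(0,1)$. These two
  families are *not* scale invariant: rescaling doses changes the curve
  shape, so doses may need manual rescaling before fitting. All
  log-logistic/log-normal/Weibull families are scale invariant ($e$ absorbs
  the dose unit).
* **Fractional-polynomial logistic** — exponents $p_1, p_2$ are
  user-supplied constants restricted to the grid
  $\{-2, -1, -0.5, 0.5, 1, 2, 3\}$, not estimated; estimating fractional
  exponents alongside coefficients is numerically treacherous and the
  customary usage picks them from a small grid.

Dose 0 is always evaluated through the analytic limit of the mean function
(e.g. $d$ for a decreasing log-logistic), never by adding a small constant
to the dose. Zero doses therefore participate in estimation on equal terms.

Sub-models arise by *fixing* parameters: `LL.4` $\equiv$ `LL.5` with
$f = 1$, `LL.3` additionally $c = 0$, `LL.2` also $d = 1$, and
`dr_model(name, fixed = ...)` generalizes this to any parameter of any
family. Fixed parameters are removed from estimation entirely, which is
distinct from *constraining* a parameter's range (`lower`/`upper` in
`dr_fit_ls`), where the parameter is still estimated.

An optional `log_e` parameterization estimates $\tilde e = \log e$ instead
of $e$; for small samples the normal approximation is usually better on the
log-dose scale, and it enables back-transformed ("fls") intervals.

## Estimation

**Least squares.** Continuous fits minimize
$\sum_i w_i^2 (y_i - f(x_i, \beta))^2$. Weights multiply the residual, so
they live on the response scale: to downweight by variability, pass
reciprocal standard deviations, not variances. The optimizer pipeline is:
parameters pre-scaled by $\max(|\text{start}_j|, 10^{-4})$ so the search
runs near unit scale; Nelder-Mead simplex ($500p$ iterations, relative
tolerance $10^{-8}$); BFGS polish with a central-difference gradient
(restarted up to three times while it improves); finally up to two Newton
steps on the numeric gradient/Hessian, accepted only while the objective
improves. With box constraints the pipeline is L-BFGS-B from the projected
start. The Newton tail matters for the package's own identities (fits that
should coincide exactly, scale-equivariance of refits): it lands optima at
$\sim 10^{-10}$ relative precision instead of the $\sim 10^{-6}$ a tolerance-
terminated quasi-Newton run leaves behind.

The covariance of the estimates is the scaled inverse of the observed
information. For least squares the information of the normal log-likelihood
is $H_{RSS}/(2\sigma^2)$ with $H_{RSS}$ the Hessian of the sum of squares,
so $\widehat{\text{cov}}(\hat\beta) = 2\hat\sigma^2 H_{RSS}^{-1}$ with
$\hat\sigma^2 = RSS/(n-p)$. $H_{RSS}$ is computed by central differences
(step $\varepsilon^{1/4}\max(|\theta_j|,1)$). A singular Hessian yields
`NA` standard errors, never a silent zero and never a failure of the fit
itself. Wald inference is t-based with $n - p$ degrees of freedom for
continuous fits and z-based for likelihood fits.

**Maximum likelihood.** Binomial fits keep $f(x,\beta)$ inside $(0,1)$
during the search (candidates outside the support score an infinite
deviance and are rejected); Poisson fits keep the mean positive. The
covariance is the inverse numeric Hessian of the negative log-likelihood.
Reported log-likelihoods include all constants (binomial coefficients,
$\log y!$), so they are comparable across parameterizations of the same
data.

**Robust M-estimation.** The objective is
$\tilde\sigma^2 \sum_i \rho(w_i r_i / \tilde\sigma)$ with $\rho$ Huber
(default tuning 1.345) or Tukey bisquare (4.685), both scaled so
$\rho(u) \approx u^2$ near zero. The scale $\tilde\sigma$ is the rescaled
MAD of the residuals, alternated with full optimization passes until the
estimates stabilise. The covariance
$\tilde\sigma^2 (\tfrac12 H_\rho)^{-1}$ reduces *exactly* to the
least-squares formula when $\rho(u) = u^2$ — the factor $\tfrac12$ makes
the two conventions line up, and a very large Huber constant is verified to
reproduce the LS estimates to $10^{-6}$. Hampel's loss is not offered.
Robust fits benefit from decent starting values; by default the self-starter
supplies them, but for heavily contaminated data passing the clean-data
estimates is advisable.

**Transform-both-sides.** With a Box-Cox transform
$g_\lambda(y) = (y^\lambda - 1)/\lambda$ ($\log$ at $\lambda = 0$) and
shift $C$, the objective becomes
$\sum_i w_i^2 \{g_\lambda(y_i + C) - g_\lambda(f(x_i,\beta) + C)\}^2$; the
mean structure keeps its interpretation on the original scale while the
variance is stabilised on the transformed one. $\lambda = 1$ is
special-cased to the untransformed objective ($g_1$ is affine, the
residuals are mathematically identical), so "no transformation" is exact
rather than a numerically equivalent detour. `dr_boxcox()` selects
$\lambda$ over a grid (default $[-2, 2]$ in steps of 0.1, $C = 0$) by the
profile log-likelihood *including* the Jacobian term
$(\lambda - 1)\sum_i \log(y_i + C)$ — the Jacobian is included in both the
profile and the ANOVA variant so the two criteria are likelihoods on the
same scale. The ANOVA variant replaces the parametric curve with the
saturated one-mean-per-dose model; it needs replicates (at two or more
doses) but is robust to curve misspecification and is two orders of
magnitude cheaper, which is why the package's own simulations use it.

**Self-starter.** Starting values are derived by linearization: asymptote
guesses $c_0, d_0$ from the per-dose means at the extreme doses expanded by
a 5% margin of the response range (fixed values are used verbatim when a
limit is fixed); the rescaled means $(\bar y_i - c_0)/(d_0 - c_0)$ clipped
to $[0.001, 0.999]$; the family's linearizing transform (logit for
log-logistic, probit for log-normal, log-log for Weibull) regressed on
log-dose over the positive doses. Zero doses inform the asymptotes but not
the regression. Both margin and clipping bounds are configurable; they are
conventional values, not estimated quantities. Hormesis families start from
the nested log-logistic solution with $f_0 = 0$ (Brain-Cousens) or a small
positive bump (CRS); the multistage model takes $b_1$ from the scaled
response at the smallest positive dose, $b_2$ from a log-linear regression
and $b_3 = 0$; the NEC threshold starts at the smallest dose whose mean has
dropped 5% of the range below the plateau. Degenerate data (a single
positive dose, zero response range) raise an explicit error asking for
manual starts rather than returning junk.

## Inference on derived doses

**Effective doses.** The relative effective dose at level $\alpha$ solves

$$f(ED_{100\alpha}) = (1-\alpha)\lim_{x\to 0} f + \alpha\lim_{x\to\infty} f,$$

i.e. $\alpha$ is the fraction of the journey from the control-side
asymptote to the infinite-dose asymptote. Written with the limits rather
than with $c$ and $d$, the definition applies unchanged to increasing and
decreasing curves — ED50 is always the halfway dose and $ED_{100\alpha}$ is
always increasing in $\alpha$ — so no internal level-flipping is needed for
increasing fits. Absolute effective doses solve $f(ED) = y_0$ directly.

Inversion is closed-form for the log-logistic (any $f$), log-normal and
both Weibull families, and numeric root finding on log-dose otherwise, with
bracket $[10^{-6}e,\ 10^{6}e]$ (or three decades beyond the observed doses
for families without a dose-scale $e$). For non-monotone hormesis curves
the *smallest* positive root is returned and all roots are kept in the
result's diagnostics; levels $\alpha < 0$ (doses in the stimulation bump
above the control asymptote) are admitted only with an explicit
`hormesis = TRUE` flag.

Standard errors come from the delta method with the gradient of the inverse
map obtained numerically by re-solving at perturbed parameters — no
implicit-function shortcut, so the gradient is exact for whatever
composition of limits, targets and roots defines the estimate. A
consequence worth flagging: when a relative target involves the estimated
limits $\hat c, \hat d$, their sampling variance *is* propagated into the
ED standard error here. Intervals are Wald (t or z per the fit), or "fls"
(delta on $\log ED$, exponentiated) for log-scale fits.

**Benchmark doses** are absolute effective doses with the target defined
from the background $f(0)$: added risk solves $f(BMD) = f(0) + BMR$, excess
risk $f(BMD) = f(0) + BMR(1 - f(0))$. The curve must be increasing (risk
grows with dose); the BMDL is the one-sided 95% lower Wald bound by
default. At zero background the two definitions coincide, and with
$BMR = (d-c)/2$ the added-risk BMD is the relative ED50 — both identities
are exercised in the tests.

**Ratios.** Relative potency $\rho(\alpha_1, \alpha_2) =
ED^A_{100\alpha_1} / ED^B_{100\alpha_2}$ from a joint fit carries three
interval flavours: delta, Fieller (the exact ratio interval from the
quadratic; unbounded intervals are flagged, not raised — they are the
honest answer when the denominator is weakly determined), and fls. Under
parallelism (shared $b$, $c$, $d$; per-curve $e$) the potency is constant
in $\alpha$, which the suite verifies to $10^{-6}$.

**Model averaging.** `dr_ma_ed()` combines ED estimates across candidate
fits with Akaike weights $w_k \propto \exp(-\Delta_k/2)$ and the
Buckland-style standard error
$\sum_k w_k \sqrt{se_k^2 + (ED_k - \overline{ED})^2}$, which folds
between-model disagreement into the uncertainty. AIC weighting is a design
choice (the weighting scheme is otherwise unconstrained); AIC and BIC are
likewise the information criteria reported by `dr_mselect()`, with ties
broken by fewer parameters.

**Tests.** `dr_anova()` compares nested fits (F on residual sums of squares
for least squares, likelihood ratio for ML); nesting is verified
structurally (parameter counts on identical data), and comparing a fit with
itself degenerates to statistic 0, p = 1 rather than an error.
`dr_no_effect()` tests against the constant-mean model with
$F(p-1,\, n-p)$; `dr_model_fit()` tests lack of fit against the saturated
one-mean-per-dose model and requires replicates. One calibration caveat,
measured rather than assumed: under an exactly flat truth ($d = c$) the
no-effect F test is mildly conservative (empirical size $\approx$ 0.02–0.03
at nominal 0.05 in this package's simulations) because $b$ and $e$ are
unidentified on the null — the classical unidentified-nuisance boundary
situation. The test is reported as is; users should read a borderline
non-significant no-effect p-value with that conservatism in mind.
`dr_compparm()` reports unadjusted p-values for pairwise parameter
comparisons; family-wise adjustment belongs to dedicated multiple-testing
machinery and is out of scope.

## The synthetic-data generator and the validation conditions

`dr_simulate()` draws responses around any built-in mean: normal with
constant sd, heteroscedastic normal with $sd \propto |\mu|^\theta$
(exercising the Box-Cox machinery), binomial, or Poisson. It emulates
designed experiments: fixed dose grids, balanced replicates, independent
errors. It does *not* emulate between-run variability, serial correlation,
non-normal continuous error, overdispersed counts, or dose measurement
error — so a green simulation suite certifies the estimation and inference
pipeline under its stated assumptions, not robustness to their violation
(the robust fitter addresses gross outliers specifically).

The canonical fixtures (`dr_fixtures()`, base seed 20151230 with
deterministic per-fixture offsets) define the package's study conditions:

* `ll4_clean` — 8 geometric doses 0.125–16, 4 replicates,
  $\beta = (2, 0.1, 0.9, 3)$, sd 0.05: a clean, well-identified sigmoid.
* `ll2_binom` — 6 doses, binomial totals 50, $b = -1.5$, $e = 10$.
* `hormesis_crs` — CRS curve with bump $f = 0.5$, $\alpha = 0.25$,
  including dose 0.
* `two_curve` — shared $(b, c, d)$, $e = 2$ vs 6: the parallelism setting.
* `outlier_ll4` — `ll4_clean` with one response replaced by ten times the
  response range.

Validation problem sizes were chosen to give stable rates at moderate cost:
500 replications for parameter bias and ED50 coverage, 1000 for test size,
200 for self-start convergence and BMDL coverage, 100 for Box-Cox exponent
recovery ($10 \times 8$ heteroscedastic design, $sd = 0.1\,\mu^{0.5}$,
i.e. true $\lambda = 0.5$), $10^5$ draws for the Fieller/Monte-Carlo
comparison. The full suite runs in about three minutes on one CPU.

## Numerical conventions, edge cases, limitations

* Derivative steps: $\sqrt{\varepsilon}\max(|\theta_j|,1)$ for gradients,
  $\varepsilon^{1/4}\max(|\theta_j|,1)$ for Hessians, central differences
  throughout.
* Covariance inversion via Cholesky with a `solve()` fallback; failure
  means `NA` standard errors, with the point estimates untouched.
* Non-convergence is flagged on the fit object, not raised; downstream
  extractors work from whatever optimum was reached, and model averaging
  drops non-converged fits with a warning.
* Equal-response data defeat the self-starter by construction (the
  linearizing transform is undefined); this is an error with advice, not a
  fallback.
* The Fieller interval with an exactly zero denominator variance reduces to
  the normal interval for numerator/denominator; with a zero covariance
  matrix it collapses to a point.
* Event-time responses, natural-immunity binomial extensions, sandwich
  standard errors, simultaneous inference across curves or BMD levels, and
  mixed-effects dose-response models are out of scope.
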