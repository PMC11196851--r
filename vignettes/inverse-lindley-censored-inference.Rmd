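---
title: "Inverse Lindley inference under adaptive Type-I progressive censoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse Lindley inference under adaptive Type-I progressive censoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilcens)
```

## The model and the censoring mechanism

The inverse Lindley (IL) distribution is the law of $Z = 1/X$ when $X$ is
Lindley distributed.  With scale $\theta > 0$ and
$\bar\theta = \theta/(1+\theta)$,

$$f(z;\theta) = \theta\bar\theta\, e^{-\theta/z}\,\frac{1+z}{z^3},\qquad
  F(z;\theta) = \Bigl(1+\frac{\bar\theta}{z}\Bigr)e^{-\theta/z},$$

with reliability $R(t) = 1-F(t)$ and hazard $h(t) = f(t)/R(t)$.  The hazard
rises to a single interior maximum and then falls (upside-down bathtub), a
shape typical of repair and inter-failure times.  Moments of $Z$ beyond the
first do not exist, so all inference here targets $\theta$, $R(t)$ and
$h(t)$ rather than means or variances.

Under **adaptive Type-I progressive censoring**, $n$ units start on test;
at the $i$-th observed failure, $i \le m-1$, the plan removes $S_i$
surviving units; afterwards failures keep being recorded *without* further
removals; at the fixed time $\tau$ the $S^* = n - k - \sum_{i\le\min(k,m-1)}
S_i$ surviving units are withdrawn.  The realized number of failures $k$ is
random and can be smaller or larger than $m$; the test never runs past
$\tau$.  The rule that planned removals stop at failure $m-1$ (not $m$) is
the one consistent with all six bundled censored sub-samples: each
reproduces its published terminal count $S^*$ under it, and
`atipc()` enforces it.

## Estimators

All six estimators live behind `il_fit(sample, method = ...)`.

**Maximum likelihood.**  The censored log-likelihood is
$\ell(\theta)=\sum_i\log f(z_i)+\sum_i S_i\log R(z_i)+S^*\log R(\tau)$.
`il_loglik()` includes the $\theta$-free density constants so that
$-2\ell$ feeds information criteria directly.  The observed information
$-\ell''(\hat\theta)$ gives the Wald variance; intervals for $R(t)$ and
$h(t)$ use the delta method with analytic gradients
$\partial R/\partial\theta$ and $\partial h/\partial\theta$ (derived from
the closed forms above and verified against finite differences in the test
suite).  Wald bounds are reported unclipped even when a lower bound falls
below 0, matching standard practice for these intervals.

**Maximum product of spacings.**  The objective replaces the density
product by the product of cdf increments $D_i = F(z_i)-F(z_{i-1})$,
$z_0 = 0$, keeping the censoring terms.  Two conventions are genuinely
open and exposed in `spacing_control()`:

* *Boundary*: the upper $(k{+}1)$-th spacing is $1-F(z_k)$ by default
  (`"one"`), with $F(\tau)-F(z_k)$ (`"tau"`) selectable.  The default is
  the standard choice for censored spacings and is the one that reproduces
  the published spacing estimates of the bundled samples.
* *Ties*: tied observations produce zero spacings.  The default `"merge"`
  drops them, leaving one spacing across each run of ties; the Cheng–Amin
  `"density"` substitution is selectable.  Merging is the convention that
  reproduces the published estimates on the tied active-repair samples, so
  it is the default even though density substitution is more common in the
  literature.

**Bayes (LF and SF).**  $\theta$ receives a gamma$(a,b)$ prior; either the
likelihood or the spacing function serves as the data source, giving the
two posteriors
$H_{LF} \propto \theta^{a-1}e^{-b\theta}L(\theta)$ and
$H_{SF} \propto \theta^{a-1}e^{-b\theta}P(\theta)$.
$a = b = 0$ is accepted as the improper $1/\theta$ limit; the posterior is
proper whenever at least one failure is observed.  A random-walk
Metropolis–Hastings sampler with a normal proposal explores the posterior,
started at the MLE (LF) or MPSE (SF).  Point estimates are posterior means
of the *transformed* draws (squared-error loss); intervals are equal-tailed
percentile intervals.  Percentile rather than HPD intervals were chosen
because they are order-preserving under the monotone $\theta \mapsto R(t)$
transform and are the default in the surrounding workflow.

**E-Bayes (LF and SF).**  The gamma hyperparameters are treated as random:
$a \sim \mathrm{beta}(\varepsilon_1,\varepsilon_2)$ on $(0,1)$ and
$b \sim U(0,c)$, independent.  The E-Bayes point estimate is the Monte
Carlo evaluation of the double integral of the Bayes estimator over this
hyperprior: $J$ hyperprior draws, one Metropolis–Hastings chain per draw,
and the average of the per-draw posterior means.  Credible intervals pool
the draws of all $J$ chains — the Monte-Carlo analogue of mixing the
posterior over the hyperprior.  Shape parameters $\varepsilon_i \ge 1$ are
permitted (the beta support keeps $a < 1$ regardless), although the
decreasing-prior argument behind the construction strictly needs
$0 < a < 1$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `level` | 0.95 | interval confidence/credibility level |
| `prior = c(a, b)` | `c(0, 0)` | gamma prior shape/rate; `c(0,0)` = noninformative limit |
| `hyper = c(eps1, eps2, c)` | `c(0.75, 0.75, 1)` | beta shapes for $a$, uniform bound for $b$ |
| `mcmc_control(n_iter, burn_in)` | 10000, 2000 | chain sizes (30000/5000 is a sensible choice for final data analyses) |
| `proposal_scale` | 0.25 | proposal sd as a fraction of the frequentist standard error; keeps acceptance in the 85–99% band.  Larger values (≈1) mix faster and are used in the quadrature cross-checks |
| `J`, `inner_n_iter`, `inner_burn_in` | 100, 2000, 500 | E-Bayes hyperprior draws and inner chain sizes |

`il_elicit()` picks an informative prior from pilot data: it simulates $G$
complete samples of size $n$ at a working $\theta$, estimates each, and
moment-matches the gamma prior, $\breve a = \bar\theta^2/s^2$,
$\breve b = \bar\theta/s^2$ with the $(G-1)$-denominator variance, so the
prior mean equals the pilot-estimate mean exactly.  Only $(a, b)$ are
elicited; $(\varepsilon_1, \varepsilon_2, c)$ remain user configuration, as
no comparably well-defined moment-matching recipe exists for them.

## The synthetic-data generator

`ratipc()` draws one AT-IPC sample sequentially: with $r$ units at risk
after time $t$, the next failure time is
$F^{-1}\!\bigl(1-(1-F(t))U^{1/r}\bigr)$, removals follow the scheme at the
first $m-1$ failures, and generation stops at the first candidate failure
past $\tau$.  The test suite checks this generator against a brute-force
simulator that draws all $n$ latent lifetimes and applies the bookkeeping
directly, both on the joint $(k, S^*)$ distribution of a small design and
on the mean realized $k$ of a large one.

What the generator emulates is exactly the idealized censoring mechanism:
i.i.d. IL lifetimes, faithful removal plans, a hard deadline.  What it does
not emulate are the blemishes of real reliability data — rounding of
recorded times (which produces the ties seen in the active-repair data),
model misspecification, covariate heterogeneity, or dependence between
units.  Passing tests therefore demonstrate correctness of the estimators
under the model, not robustness beyond it; the tie-handling rule is the one
place where a data blemish is handled explicitly.

A design note on the simulation harness: published designs fix an
"effective sample size" per test although $k$ is random under this
censoring scheme.  `il_simstudy()` does not condition on $k$ by default and
reports the mean realized $k$ alongside the metrics; a
`condition_on_k = TRUE` switch redraws until the realized $k$ matches $m$
for designs where that event is not too rare.

## Numerical choices

* $e^{-\theta/z}$ products are evaluated in log space; reliabilities use
  `log1p`/`expm1` so that $\log R$ stays accurate when $F \to 1$.
* The quantile function solves $F(z) = p$ on the inverse scale $x = 1/z$ by
  a bracketed root search plus Newton polishing (round-trip accurate to
  about $10^{-12}$).  The closed form through the secondary Lambert-W
  branch serves as an independent oracle in the tests, not as the
  production path — the root search is more robust near $p \to 0, 1$.
* Both objectives are maximized by Newton iteration on the analytic score
  with analytic curvature, seeded by a cheap moment-style guess and falling
  back to a log-spaced grid scan plus golden-section pass: the spacing
  objective underflows to $-\infty$ far from the optimum, which strands a
  blind golden-section search.  Convergence requires the score to vanish
  to $10^{-6}$ relative.
* Degenerate inputs fail loudly: samples with $k = 0$, all-tied samples
  under the spacing objective, infeasible removal plans, nonpositive
  information.
* Monte-Carlo replicates use child seeds derived deterministically from
  `(seed, replicate)`, so a study is reproducible and independent of
  execution order.

## Problem sizes

The test suite runs scaled-down studies — 30 to 500 replicates, chains of
2,000–12,000 iterations, E-Bayes with $J \le 60$ — chosen so the whole
suite completes in a few minutes while every Monte-Carlo assertion keeps an
explicit standard-error-based tolerance.  `scripts/acceptance.R` runs the
headline simulation at 1,000 replicates, matching the published design.
Bayesian point estimates are validated against one-dimensional adaptive
quadrature of the posterior (and nested quadrature over a hyperparameter
grid for E-Bayes) rather than against published table entries, because
those entries depend on unlogged random seeds.

## Known limitations

* Squared-error loss only; no LINEX or other asymmetric losses.
* Percentile credible intervals, not HPD.
* One-parameter model: no covariates, no competing distributions.
* The sampler is a plain random walk without adaptation or thinning;
  heavy-tailed posteriors from very small $k$ may need manual tuning of
  `proposal_scale`.
* Conditioning on the realized $k$ by rejection is impractical for designs
  where the target $k$ is far from its expectation.
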