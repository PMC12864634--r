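---
title: "Model-averaged Bayesian meta-analysis: models, priors, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-averaged Bayesian meta-analysis: models, priors, and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabf)
```

## The statistical model

`metabf` pools log odds ratios from K two-arm trials with a binary
outcome. Study i contributes an estimate $y_i$ with standard error
$\sigma_i$, treated as known — the usual normal approximation
$y_i \sim N(\theta_i, \sigma_i^2)$, which is accurate when every cell of
the 2×2 table is reasonably large and degrades for very small or
zero-event trials. Under the fixed-effect assumption all studies share
one effect, $\theta_i = \mu$; under random effects,
$\theta_i \sim N(\mu, \tau^2)$ with $\tau$ the between-study standard
deviation in log odds ratio units, so marginally
$y_i \sim N(\mu, \sigma_i^2 + \tau^2)$.

The frequentist track estimates $\mu$ by inverse-variance weighting, with
$\tau^2$ from REML (default, via `metafor`) or DerSimonian–Laird, and
reports Wald intervals with the conventional fixed 1.96 multiplier,
Cochran's Q, and $I^2 = \max(0, (Q - (K-1))/Q) \cdot 100$. We read
heterogeneity figures printed by standard random-effects software as
$\tau^2$, not $\tau$; sources are not always explicit about which they
print, and the two are easy to confuse when $\tau < 1$.

The Bayesian track does not choose between fixed and random effects, nor
between null and alternative. It computes the marginal likelihood of four
models — `fe0` ($\mu = 0$, $\tau = 0$), `fe1` ($\mu$ free, $\tau = 0$),
`re0` ($\mu = 0$, $\tau$ free), `re1` (both free) — and averages over
them with prior probability ¼ each. The inclusion Bayes factor

$$\mathrm{BF}_{10} = \frac{m(y\,|\,\texttt{fe1}) + m(y\,|\,\texttt{re1})}
                          {m(y\,|\,\texttt{fe0}) + m(y\,|\,\texttt{re0})}$$

is the model-averaged evidence for a nonzero pooled effect, and
$\mathrm{BF}_{rf}$ is the analogous random-versus-fixed ratio. With a
non-uniform model prior the sums become prior-weighted averages,
renormalized within each hypothesis. `interpret_bf()` folds a Bayes
factor into "the data are r times more likely under H1 (or H0)" and
deliberately applies no evidential cutoffs: categorical thresholds are
exactly the habit the Bayes factor is meant to replace.

## Priors and tunable parameters

* **Effect prior**: Cauchy with location 0 and scale 0.707 on $\mu$ (log
  odds ratio units). The scale puts half the prior mass inside
  OR $\in (0.49, 2.03)$ — weak but not absurd for clinical effects — and
  the heavy tails keep the prior from dominating when the data point to a
  large effect. It is two-sided and untruncated: benefit and harm are a
  priori equally plausible.
* **Heterogeneity prior**: inverse-gamma with shape 1 and **scale** 0.15
  on $\tau$ (the standard deviation, *not* $\tau^2$; and scale, *not*
  rate — both conventions exist, so `prior_spec()` names the arguments
  explicitly). Its median is about 0.22, matching the degree of
  between-study spread typically seen in surgical trial meta-analyses,
  while the $e^{-0.15/\tau}$ factor keeps $\tau$ away from exactly zero,
  which `fe0`/`fe1` already cover.
* **Model prior**: uniform over the four models. Any probability
  4-vector may be supplied; a zero on a model needed for a requested
  Bayes factor is an error rather than a silent 0/0.

The posterior for $\mu$ reported by `meta_bayes()` averages over the two
*alternative* models only, weighted by their posterior model
probabilities. Averaging over all four would mix in a point mass at 0;
that spike-and-slab summary answers a different question (an unconditional
estimate) and is deliberately not the default — the credible interval is
conditional on there being an effect, which is how such intervals are
usually read alongside a Bayes factor.

## Numerical scheme

Marginal likelihoods are integrals of the likelihood against the priors.
Each parameter is substituted by its prior quantile function, turning
$\int L(\theta)\,\pi(\theta)\,d\theta$ into $\int_0^1 L(F^{-1}(u))\,du$:
the heavy Cauchy and inverse-gamma tails are absorbed by the change of
variable instead of being truncated. The unit interval is integrated by
Gauss–Legendre rules, starting at 201 nodes per axis and roughly doubling
(201 → 401 → 801 → 1601) until two successive refinements of the log
marginal likelihood agree within $10^{-6}$; `re1` uses the 2-D product
rule. An unmet tolerance at the 1601-node cap attaches a warning to the
result — never a silent answer. All averaging uses log-sum-exp; raw
products of K normal densities underflow long before K gets interesting.
The scheme is deterministic and seed-free, so identical inputs give
byte-identical reports.

The posterior density of $\mu$ is tabulated per component on a uniform
grid, initially spanning the fixed-effect pooled estimate ±6 pooled
standard errors and doubled in span *and* point count until the grid
integral matches that component's quadrature marginal likelihood (within
`mass_tol`, floored at five times the marginal's own refinement error —
capture cannot be verified more tightly than the reference is known). The
doubling matters: with weak data the heavy-tailed priors leave
polynomially decaying posterior tails, and the `fe1` and `re1` components
can live on very different scales (a near-degenerate dataset produces a
spike-plus-hump mixture). A fixed span proportional to the largest study
standard error — the more obvious rule — fails in both directions: it is
far too wide when one study is nearly uninformative and too narrow for
polynomial tails, which is why the adaptive per-component rule replaced
it. The mixture is assembled on the union of the component grids.
Credible intervals are equal-tailed, inverted from the numeric CDF with
flat segments dropped; highest-posterior-density intervals are available
via `cri_method = "hpd"` (greedy accumulation of the densest grid cells,
appropriate only for unimodal posteriors). Shrinkage estimates integrate
the conditional normal posterior of $\theta_i$ given $(\mu, \tau)$ over
the joint quadrature posterior (201 nodes per axis by default), with
interval bounds found by root-finding on the normal-mixture CDF.

Degenerate inputs are handled explicitly: a 2×2 table with a zero cell
gets the Haldane–Anscombe correction (0.5 added to all four cells, only
when a zero is present) or raises an error if the correction is disabled;
tables with no events (or no non-events) in either arm are rejected as
carrying no odds ratio information; a single-study random-effects request
degrades to fixed-effect with a warning so sequential analyses can start
at k = 1, where Q and $I^2$ are undefined and reported as `NA`. REML
retries with damped Fisher-scoring steps before raising a convergence
error. When extracting effects from published intervals,
`se_from_ci()` uses the fixed 1.96 quantile, matching how such intervals
were constructed.

## Sequential analysis

`meta_sequential()` reanalyses every chronological prefix (publication
year, ties broken by input order — recorded in the output, since
cumulative results are meaningful only when the ordering is). Steps are
computed as batch runs on prefixes rather than literal posterior-as-prior
propagation: within any fixed model the marginal likelihood telescopes,
$m(y_{1..k}) = m(y_{1..k-1}) \cdot p(y_k | y_{1..k-1})$, so the two are
mathematically identical; `sequential_decomposition()` returns the
predictive factors and the test suite verifies that their product
reproduces the batch marginal likelihood and that the final step equals a
fresh batch analysis. No multiplicity adjustment is applied across looks;
within the Bayesian framework repeated updating does not spend error
rate.

## The synthetic-trial generator

`sim_config()` defaults describe the evidence base the package is aimed
at: K = 6 two-arm trials, control-arm event risk 10%, 100–400 patients
per arm, true pooled log OR −0.5 (OR ≈ 0.61), between-study SD 0.2 —
a handful of moderately sized surgical RCTs of a protective intervention
against an uncommon complication, with the moderate heterogeneity typical
of such literatures. Two modes: `binomial-trials` draws full 2×2 tables
(including occasional zero cells, exercising the continuity-correction
path; tables degenerate even after correction are redrawn, as such trials
would be excluded from a real meta-analysis), while `normal-effects`
draws directly from the pooling model for calibration experiments where
the model is exactly true. One top-level seed derives one sub-seed per
replicate, so any replicate can be regenerated alone; the global RNG
state is saved and restored.

What the generator does *not* emulate bounds what green tests mean:
no publication bias or small-study effects, no outcome misclassification,
no non-normal random-effects distributions, no correlation between arm
size and effect. Calibration verified on generated data (type-I error,
coverage) is calibration under the model's own assumptions, not a
guarantee for any real literature.

## Experiment sizes

The operating-characteristic experiments run at: type-I error, 2000
replicates of K = 10 null datasets (frequentist track; the band checked
is 0.03–0.07); credible-interval coverage and bias, 500 replicates of
K = 50 under random-effects truth ($\mu = -0.5$, $\tau = 0.2$); null-direction
Bayes factors, 200 replicates; sequential BF trajectories, 200 replicates
of K = 6 sequences. These sizes give Monte-Carlo error comfortably below
the tolerances being checked (e.g. ±0.029 on a 95% coverage estimate at
500 replicates) while keeping a full run in the minutes range on one
core.

## Known limitations

* The normal likelihood for $y_i$ is an approximation; for very sparse
  tables a binomial-likelihood (GLMM) meta-analysis would be more
  faithful, and is out of scope here.
* Bayes factors with few studies are sensitive to the effect prior's
  scale; the defaults are weak, but they are still choices, and
  `prior_spec()` exists precisely so sensitivity can be explored.
* Sequential results depend on the ordering; the package records the
  order used and leaves the judgement of whether a chronological reading
  is meaningful to the analyst.
* Only log odds ratios are supported — no risk ratios, risk differences,
  or continuous outcomes, and no publication-bias adjustment or
  meta-regression.
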