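---
title: "Models and conventions for acute mixture-toxicity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions for acute mixture-toxicity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cilitox)
```

`cilitox` analyses acute toxicity bioassays with a unicellular test
organism — single compounds, binary mixtures on a Toxic-Unit grid, and
sublethal antioxidant biomarkers. This vignette is the package's
account of the models it fits, the conventions it commits to where the
field leaves a choice open, and what its tests do and do not
demonstrate.

## The dose–response model

Mortality after a fixed exposure window is modelled as a two-parameter
logit–log curve,

$$F(c) = \frac{1}{1 + e^{-(\alpha + \beta \log_{10} c)}},$$

with $\beta > 0$ for a toxicant. Two estimators are exposed because the
assay literature uses both interchangeably:

* `binomial_glm` (default): binomial maximum likelihood with a logit
  link on $\log_{10} c$, using the well-level death counts directly.
  This is the better-founded estimator — it weights concentrations by
  their information content and yields the standard asymptotic
  covariance used for delta-method intervals.
* `empirical_logit_ols`: ordinary least squares on logit-transformed
  observed proportions. Boundary wells (0% or 100% dead) use the
  empirical-logit adjustment $(k + 0.5)/(n + 1)$, without which the
  transform is undefined. This matches the older
  "transform-then-regress" practice.

On balanced, non-boundary designs the two agree on LC50 to well within
2% (a property test covers this). Controls at concentration zero are
excluded from fitting and no background-mortality (Abbott) correction
is applied; the model's support starts at the lowest positive
concentration.

$LC_x = 10^{(\mathrm{logit}(x/100) - \alpha)/\beta}$ is reported with a
delta-method standard error propagated to the arithmetic concentration
scale and a symmetric 95% interval $\pm 1.96\,SE$. Symmetric intervals
on the arithmetic scale are how acute LC tables are conventionally
printed; a log-scale interval would be asymmetric and slightly wider on
the upper side. Published LC tables can be inverted with
`curve_from_lcs()`: two (effect, concentration) points determine
$(\alpha, \beta)$ uniquely, which is how single-compound curves are
rebuilt when only LC20/LC50 summaries are available.

## Toxic Units and effect summation

One Toxic Unit of a compound is its own 24 h LC50, so a mixture cell
$(TU_a, TU_b)$ maps to concentrations $TU_i \times LC50_i$. The
*effect-summation* expectation adds the two marginal mortalities and
caps at 100%. It is deliberately naive — it ignores any joint-action
model — but it is the benchmark the TU framework uses, and it has the
convenient property of reaching exactly 100% when both components are
at 1 TU.

Each trial is classified by a one-sample two-sided t-test of the
replicate mortalities against the expected value at $\alpha = 0.05$.
The package tests against the *point* expectation and ignores any
uncertainty attached to the expected value, because the expectation is
a model output, not a measurement; published tables that print an SD on
the expected column do not document its provenance. Two edge rules: an
observed mean exactly equal to the expectation is never an interaction,
and a zero replicate SD with a non-zero difference is treated as
unambiguous (p = 0) — with three replicates on a percent scale a zero
SD means saturation at a bound, almost always 100% vs a sub-100%
expectation.

## CA/IA response surfaces and deviation functions

The surface module couples the two marginal curves through either
reference model:

* **Concentration Addition (CA)** — components are dilutions of one
  another. The predicted effect $F$ solves
  $\sum_i c_i / EC_i(F) = e^{G}$, found by bisection on
  $F \in [10^{-9}, 1 - 10^{-9}]$ (48 halvings, i.e. to machine-level
  interval width). If even a vanishing effect over-satisfies the sum
  the prediction saturates at the corresponding bound rather than
  erroring, which keeps least-squares objectives finite at extreme
  deviation parameters.
* **Independent Action (IA)** — survival probabilities multiply:
  $F = 1 - [(1 - F_1)(1 - F_2)]^{\,e^{-G}}$.

The deviation term $G$ takes the standard three forms on the
toxic-unit fractions $z_1 + z_2 = 1$: synergism/antagonism
$G = a z_1 z_2$, dose-ratio $G = (a + b z_1) z_1 z_2$, and dose-level
$G = a z_1 z_2 (1 - b\,TU_{tot})$, with $TU_{tot} = c_1/LC50_1 +
c_2/LC50_2$ so the interaction reverses where $b\,TU_{tot} = 1$
($b = 1$ puts the reversal at the 1-TU level). Conventions the package
commits to, since the literature states them loosely:

* $z_i$ is evaluated at the surface's own effect level — inside the
  root solve for CA, by fixed-point iteration (damped, tolerance
  $10^{-12}$) for IA. This keeps the two references parallel.
* The IA deviation enters as the power $e^{-G}$ on the survival
  product. With this sign choice $a < 0$ means synergism under *both*
  references, so parameter signs are comparable across reference
  models. Published deviation parameters from other implementations
  are comparable only up to such conventions and are treated as
  qualitative references, not oracles.
* The dose-ratio asymmetry parameter $b$ attaches to $z_1$ of the
  first-listed component; component order is part of the model
  specification and is recorded in the pipeline run log.

### Fitting and model selection

Surfaces are fitted by least squares on the mortality fraction
(equivalently, Gaussian maximum likelihood with a common variance).
Deviation parameters are multi-started from a 5×5 grid on
$[-10, 10]^2$ — covering the magnitudes reported in practice — screened
by objective value, refined with Nelder–Mead (Brent for one free
parameter), and polished from the winner; the objective walls off
$|a|, |b| > 100$ because the DL and DR forms contain degenerate ridges
(e.g. $a \to 0$, $b \to \infty$ with $ab$ fixed) that are numerically
seductive and scientifically meaningless. Single-compound parameters
can be held fixed (two-stage fitting) or refit jointly; joint refit is
the default in the pipeline when the surface is fitted to mixture
means alone, where the marginals' information is weak.

Nested models are compared with $\chi^2 = n \ln(SSE_0/SSE_1)$ on the
added-parameter degrees of freedom. Children are started from their
parent's solution, so the nesting monotonicity
$SSE_{ref} \ge SSE_{S/A} \ge SSE_{DR/DL}$ holds by construction. The
selection walk accepts S/A over the reference at $\alpha = 0.05$, and a
two-parameter form only when it significantly improves on *both* the
reference and S/A — a pure dose-ratio interaction averages to a null
S/A term, so making S/A a hard gate would hide it.

The $n \ln(SSE_0/SSE_1)$ statistic is anti-conservative in small
samples: at $n = 16$ grid means its type-I rate at nominal 0.05 is
about 0.07, while at replicate level ($16 \times 3 = 48$ observations,
the package's default granularity when replicates exist) it calibrates
to about 0.05. The calibration test therefore runs at replicate level
with the marginal curves held fixed — it is the deviation test being
calibrated, not the marginal fit.

## Biomarker statistics

The sublethal battery follows the standard parametric chain:
Shapiro–Wilk per treatment group and Levene's test (median-centred,
via `car`) as assumption screens; one-way ANOVA; Bonferroni-corrected
unpooled pairwise t-tests only when the omnibus test is significant
(raw p × number of comparisons, capped at 1). Technical triplicates
are averaged into their biological replicate before any test —
treating them as independent would pseudo-replicate threefold.
Pearson correlations between endpoints are computed over
treatment-level means, matching how endpoint-correlation tables are
reported (one R per endpoint pair per exposure scenario); correlating
raw replicates instead would mix within- and between-treatment
variance. Constant groups are reported as degenerate for normality
testing, and zero-variance endpoints yield undefined (NA)
correlations, rather than erroring.

## The synthetic-data generators

The generators encode the study design the package expects: 100 cells
per well, 3 wells per concentration, 3 independent biological
replicates, 24 h binomial mortality, zero control mortality. Mixture
trials draw binomial well-level noise around a chosen surface (or
Gaussian noise on the percent scale, used where an explicitly
Gaussian error model is wanted, e.g. LR-test calibration); biomarker
panels draw treatment means from an exchangeable multivariate normal
with a target inter-endpoint correlation ρ and add Gaussian replicate
noise. Every generator is a pure function of its parameters and a
mandatory seed (`withr::with_seed`; the session's random stream is
untouched).

Recovery tests run the loop generator → fitter → estimate: the acute
loop at 5 concentrations spanning 0.3–3.3 × LC50 with 300 cells per
concentration over 200 seeds recovers LC50 with a median error under
1% and 95% CI coverage near nominal; the surface loop recovers
deviation parameters to $10^{-3}$ on noise-free grids and selects the
generating deviation form under strong interactions. What these tests
*do not* show: the generators are statistical idealisations — no
nanoparticle dissolution or aggregation kinetics, no dose-dependent
overdispersion, no plate or batch effects, no control mortality. A
real assay violating those idealisations can degrade interval coverage
and model selection in ways the synthetic loop cannot reveal.

## Numerical choices and degenerate inputs

* Dose–response fitting requires ≥ 3 distinct positive concentrations
  and at least one non-boundary response; all-dead/all-alive designs
  are rejected as degenerate rather than silently fitted.
* The CA bisection uses 48 halvings (interval $< 4 \times 10^{-15}$);
  the sham-combination identity — mixing a compound with itself
  reproduces its own curve exactly — holds to $10^{-8}$ and is the
  module's primary correctness oracle, since it is an exact property
  of CA independent of any implementation.
* $G$ is clamped to $[-50, 50]$ inside solvers: $e^{G}$ overflows long
  before a fit would ever accept such a value.
* An LR comparison where the child fits worse than its parent (only
  possible through optimizer failure) is floored at $\chi^2 = 0$ with
  a warning instead of reporting a negative statistic.
* Constant-response surface data (`SStot = 0`) are rejected — $R^2$ is
  undefined there.

## Known limitations

* Binary mixtures only; no ternary designs or hormetic marginals.
* The interaction t-test accepts summary statistics (mean/SD/n), which
  loses nothing for balanced designs but cannot model replicate-level
  covariance between observed and expected values.
* Joint-refit surface $R^2$ depends on the fitting granularity
  (means vs replicates); published values from other tools are
  reproducible only when that granularity matches.
* Delta-method LC intervals are first-order; for steep curves at
  extreme effect levels (LC1, LC99) a profile-likelihood interval
  would be preferable.
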