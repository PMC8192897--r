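---
title: "Multilevel ERGMs for school friendship and online group networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel ERGMs for school friendship and online group networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mergm)
```

## The setting and the model

A peer-led school health intervention trains nominated students (peer
supporters, PS) to diffuse messages through friendships and through closed
online groups they open and invite friends into.  The data for one school
are (i) a directed friendship network over the year-group roster, elicited
by asking each survey respondent to name up to six closest friends, (ii) a
fixed bipartite affiliation network between students and the online
groups, and (iii) individual covariates: gender (1 = male), PS status, and
continuous scores for sexual-health knowledge, adherence to positive
norms, and the tendency to talk with friends about these topics.

Two structural features of the survey are part of the model's sample
space, not nuisance:

* **Structural zeros.**  Students who did not complete the survey could
  not name friends, so any arc with a non-respondent sender is impossible;
  arcs *towards* non-respondents remain possible and are modelled.  The
  free tie variables are exactly the ordered pairs with respondent sender
  — with full response, the classical $n(n-1)$ dyads.
* **Out-degree conditioning.**  Respondents named at most six friends, so
  estimation conditions on networks in which no respondent's out-degree
  exceeds six.

Conditional on the affiliations $z$ and covariates $x$, the friendship
matrix $y$ follows an exponential family
$P(Y=y) \propto \exp\{\theta^\top s(y,x,z)\}$ over the constrained space.
The affiliations are exogenous throughout: friendship ties are the
dependent variables, group membership a predictor.

## The effect catalogue

Sixteen statistic families cover the standard specification.  Let
$d_{in}, d_{out}$ be friendship in/out-degrees, $TP(i,j)$ the number of
directed two-paths $i \to k \to j$, $d^X_i$ the number of groups of
student $i$ and $s_{ij}$ the number of groups shared by $i$ and $j$.

**Structural.**  Arc count; mutual-dyad count; alternating in-star
$\lambda^2 \sum_i [(1-1/\lambda)^{d_{in}(i)} + d_{in}(i)/\lambda - 1]$
(popularity spread; out-star version is activity spread); alternating
path closure $\lambda \sum_{(i,j): y_{ij}=1} [1-(1-1/\lambda)^{TP(i,j)}]$;
alternating multiple two-paths, the same kernel summed over *all* ordered
pairs.  The geometric damping (smoothing constant $\lambda \ge 1$,
default 2 — the conventional value in this software family) is what keeps
star and triangle effects estimable where raw counts degenerate.  The
alternating stars equal the explicit series
$\sum_{k\ge2} (-1)^k S_k / \lambda^{k-2}$ over star counts $S_k$; the test
suite verifies this identity numerically for several $\lambda$.

**Actor-relation.**  For covariate $x$: sender $\sum_{y_{ij}=1} x_i$,
receiver $\sum_{y_{ij}=1} x_j$, interaction $\sum_{y_{ij}=1} x_i x_j$
(binary homophily), difference $\sum_{y_{ij}=1} |x_i - x_j|$ (continuous
heterophily; negative estimates mean homophily).  The PS-by-talking
sender/receiver effects are the sender/receiver templates applied to the
constructed covariate $ps \cdot talking$ — the named rows of the
conventional report table give no formula, and this is the natural
reading of their names.

**Cross-level.**  In-degree and out-degree weighted by affiliation counts
($\sum_i d_{in}(i)\,d^X_i$, $\sum_i d_{out}(i)\,d^X_i$); cross-level
closure $\sum_{y_{ij}=1} s_{ij}$ (arcs between co-members — the alignment
of offline and online ties); cross-level three-paths
$\sum_{y_{ij}=1} [d^X_i d^X_j - s_{ij}]$, counting ordered pairs of
*distinct* groups bridged by an arc.  Whether the original estimation
software excludes the same-group pair from the three-path count is not
documented; we exclude it ($g \ne h$) and state the closed form so results
are self-consistent.

**Missing attributes.**  Non-respondents (and item non-response) have no
scores.  Before any statistic is computed, continuous covariates are
imputed at the respondent mean and binary covariates at zero, keeping
every arc's contribution defined while centring missing actors'
influence; both policies are configurable
(`resolve_covariates()`).  Continuous covariates enter on their raw scale
by default, with an optional centering flag for sensitivity checks.

## Simulation

`simulate_mergm()` runs Metropolis–Hastings with uniform single-dyad
toggle proposals over the free tie set.  Structural zeros cannot be
proposed at all; with conditioning on, a proposal that would push a
sender past the cap is rejected, so the chain never leaves the
constrained space.  Acceptance uses $\min(1, e^{\theta^\top\Delta z})$
with incremental change statistics; the accumulated statistic vector is
cross-checked against a full recount (an independent, vectorised R
implementation) at the end of every run and on retained samples, so a
bookkeeping error cannot pass silently.  Defaults scale with the free-set
size $|F|$: burn-in $50|F|$ toggles, thinning $10|F|$.  The test suite
validates the chain against the exhaustively enumerated Gibbs
distribution on a 64-state space (total-variation distance below 0.02
over $2\times10^6$ steps) and against the Bernoulli closed form for
density-only models.

## Estimation

`fit_mergm()` implements three-phase stochastic approximation
(Robbins–Monro):

1. **Phase 1** simulates briefly at the start value (logit of observed
   density on the arc term, zero elsewhere) and takes the statistic
   variances as a diagonal scaling $D$.
2. **Phase 2** runs 5 sub-phases of geometrically growing length
   ($40 \cdot 2^{k-1}$ iterations) and halving gains
   ($a_k = 0.1/2^{k-1}$), each iteration advancing the chain $|F|$ steps
   and updating $\theta \leftarrow \theta - a_k D^{-1}(z_{sim} -
   z_{obs})$, with per-component step clamping against excursions.
3. **Phase 3** draws a large sample (default 1000, spaced $5|F|$ steps)
   at the candidate $\hat\theta$, computes convergence t-ratios
   $(\bar z_{sim} - z_{obs})/sd(z_{sim})$, and declares convergence when
   all $|t| < 0.1$ — the conventional criterion for this model family.
   While not converged (up to `max_rounds`), $\hat\theta$ takes a Newton
   step using the phase-3 covariance and phase 3 is re-run; near the
   optimum this polish converges fast and leaves only Monte-Carlo noise.

Standard errors are $\sqrt{\mathrm{diag}(\hat\Sigma^{-1})}$ with
$\hat\Sigma$ the phase-3 statistic covariance (the Fisher information at
the MLE), falling back to a pseudo-inverse with a warning when
near-singular.  A parameter is marked significant when $|\hat\theta|/SE$
strictly exceeds 2, two-sided.  All chain lengths are package defaults —
the original analyses do not publish theirs — and every setting sits in
`estimation_config()`.

Rather than returning garbage on pathological inputs, the fitter raises
diagnostic errors: observed statistics at their boundary (an empty
network, zero reciprocated dyads with a reciprocity term), collinear
change-statistic columns (probed on up to 1000 dyads before fitting), and
degenerate simulation (statistics collapsing onto a constant).

For models whose terms are all dyad-independent given the fixed
affiliations, the likelihood is exactly logistic regression of the tie
indicators on the change-statistic design; the package exposes that
design (`dyad_design_matrix()`) and the acceptance checks require the
MCMC-MLE to agree with `glm()` within 0.05 on estimates and 10% on
standard errors.

## Goodness-of-fit

`goodness_of_fit()` simulates at $\hat\theta$ and reports t-ratios
$(obs - \bar{sim})/sd(sim)$ for every fitted statistic (adequacy
$|t| < 0.1$: they were matched during estimation) and for an auxiliary
panel not in the model: in/out-degree standard deviation and skewness,
global transitivity (closed fraction of directed two-paths), isolate
count and mutual-dyad count (adequacy $|t| < 2$).  The auxiliary panel is
our choice — published reports state GOF adequacy without listing their
panel — and is configurable.  With `use_phase3 = TRUE` the report is
computed on the estimator's own phase-3 sample and its fitted-statistic
t-ratios coincide with the convergence t-ratios (opposite sign
convention), which the tests assert to machine precision.  Note that with
a *fresh* finite sample the fitted-statistic threshold 0.1 is strict: the
Monte-Carlo error of the simulated mean alone contributes about
$1/\sqrt{n_{samples}}$ to $t$, so small GOF samples can flag a perfectly
converged fit.

## The synthetic generator

No real survey data ship with the package, so `generate_school()`
produces schools with the statistical structure the analysis assumes.
Defaults encode the emulated study conditions: 130 students per year
group, 79 % survey response, a six-nomination cap, the most-nominated
25 % of the year group invited to the PS role with 52 % uptake (about
13 % of students becoming PS), one online group per PS.  Friendship grows
by sequential arc proposals with reciprocity and transitivity bonuses, a
same-gender odds multiplier, and exponential decay in standardised
attribute distance; PS selection uses in-degree plus noise as the
nomination score (the real nomination instrument is a separate survey
that is only summarised, so in-degree popularity is the closest
observable proxy); group joining probability is multiplied by
`affiliation_alignment` (default 10) when an arc links the student to the
group's PS; non-response deletes outgoing arcs but keeps incoming ones
and blanks the continuous attributes.

Attribute scales (knowledge mean 7, sd 2; norms 3.5, 0.8; talking 2.5,
1.2; pairwise correlation 0.3; 45 % male) are plausible survey scales,
*not* published distributions — the real school-level tables are in
supplementary material not reproduced here.  The generator does not
emulate online-content engagement dynamics, multi-wave change, or
control schools.  Consequently, passing tests demonstrate that the
machinery is correct (statistics, sampler, estimator, GOF) and that the
generator produces the qualitative regularities the analysis needs
(alignment raises cross-level closure, homophily strength raises the
interaction statistic); they do not validate any substantive claim about
real school networks.

## Numerical conventions and edge cases

* Density of an empty free tie space is reported as `NA`; every statistic
  of an arcless network is 0; `0^0 = 1` makes the alternating closed
  forms correct at $\lambda = 1$.
* Identifiers are opaque strings; positional indices are internal,
  assigned in roster order, and never appear in files.  Statistics are
  invariant under roster relabelling (tested).
* Duplicate arc/affiliation records collapse to one binary tie with a
  warning.  Strict mode (default) rejects structural-zero and cap
  violations; non-strict mode drops the offending records with warnings,
  accommodating messy survey exports.  Whether any real respondent
  exceeded the cap after roster matching is unknowable from the published
  material, so both behaviours are provided.
* GOF t-ratios with a degenerate simulated distribution are 0 when the
  observation equals the constant and infinite otherwise.
* Change statistics are exact on-minus-off differences; incremental and
  recount paths agree below $10^{-9}$ (they cannot be bit-identical:
  the two evaluate the same closed forms in different operation orders).
* Seeds are mandatory wherever randomness enters (`sampler_config()`,
  `estimation_config()`, `school_sim_config()`); identical seeds give
  bit-identical batches, fits and schools.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script sizes are the package's chosen
trade-off between statistical resolution and a comfortable desk run: the
change-statistic oracle sweeps 500 six-student networks (every free dyad,
all sixteen families); the enumeration check uses a 64-state space and
$2\times10^6$ steps; the logistic-oracle school has 40 students; parameter
recovery refits ten 60-student schools simulated from
$\theta^* =(-3.0, 2.0, 1.0)$ on (arc, reciprocity, path closure); the
demonstration study in `analysis/` uses five schools of 85–150 students.

## Limitations

Estimates are school-specific: parameters are not comparable across
networks of different sizes and are never pooled.  There is no
longitudinal (actor-oriented) modelling and no model-based treatment of
missing ties beyond the structural-zero rule — both are natural
extensions.  The sampler is a single-site toggle chain; tie-swap
proposals would mix faster in strongly conditioned spaces and the
proposal layer is written to make that addition local.
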