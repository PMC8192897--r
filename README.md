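# mergm

Multilevel exponential random graph models (MERGMs) for school friendship
networks with fixed online-group affiliations.

## What this is for

Peer-led school health interventions train nominated students ("peer
supporters") to spread messages through their friendships, often backed by
closed online groups the peer supporters open and invite friends into.
Evaluating the *process* of such an intervention — was it delivered with
fidelity, through which relational mechanisms might it work, and in what
social context — can be done statistically with network models: the
observed friendship network and the student-to-group affiliation network
are analysed jointly, and each local tie configuration (reciprocated
dyads, triangles, same-gender arcs, arcs between co-members of a group)
gets a parameter measuring whether it occurs more or less often than
chance, conditional on everything else.

This package implements that analysis end to end for researchers running
or re-analysing such evaluations:

* a data model for one school: a directed friendship arc list over the
  student roster, an undirected student-to-group affiliation list, and an
  attribute table (gender, peer-supporter flag, knowledge / norms /
  talking scores, respondent flag).  Survey structure is enforced as
  constraints: arcs can only be sent by respondents (structural zeros) and
  respondents name at most six friends (out-degree conditioning);
* the full effect catalogue — structural (arc, reciprocity, alternating
  in/out-stars, alternating path closure, alternating two-paths),
  actor-relation (sender / receiver / interaction / difference per
  covariate, plus peer-supporter-by-talking products) and cross-level
  (degree-by-affiliation stars, cross-level closure, cross-level three
  paths) — with exact incremental change statistics;
* Metropolis–Hastings simulation on the constrained tie space, three-phase
  Robbins–Monro MCMC maximum likelihood with convergence t-ratios and
  standard errors, simulation-based goodness-of-fit, and a significance
  rule marking effects with |θ̂|/SE > 2;
* a synthetic school-network generator emulating the study conditions
  (79 % response, six-nomination cap, top-25 % peer nomination with 52 %
  uptake, online groups aligned with offline friendship), used as the
  stand-in for survey data that cannot be redistributed;
* per-school study orchestration and a multi-school report whose rows are
  tagged to the process-evaluation components they inform
  (implementation fidelity / mechanisms of impact / context).

## The model

For a school with students `1..n` and fixed group affiliations `z`, the
friendship arc matrix `y` follows the exponential family

    P(Y = y) ∝ exp( Σ_k θ_k · s_k(y, x, z) )

over the free tie variables (ordered pairs whose sender responded),
optionally restricted to networks where every respondent's out-degree is
at most six.  `s_k` are the effect statistics; for example the alternating
in-star statistic `λ² Σ_i [(1−1/λ)^{d_in(i)} + d_in(i)/λ − 1]` (λ = 2 by
default) measures in-degree spread, and the cross-level closure statistic
counts arcs whose endpoints share a group.  Estimation matches simulated
to observed statistics by stochastic approximation; a fit is converged
when every t-ratio `(E_θ̂ s_k − s_k(y_obs)) / sd_θ̂(s_k)` is below 0.1 in
absolute value.

## Worked example

```r
library(mergm)
school <- generate_school(school_sim_config(n_students = 60, seed = 42))
spec <- model_spec(list(
  effect_term("ArcA"), effect_term("ReciprocityA"),
  effect_term("AoutSA"), effect_term("ATA-T"),
  effect_term("Interaction", "gender"), effect_term("TXAXarc")))
fit <- fit_mergm(school$network, school$attrs, spec,
                 estimation_config(phase3_n = 500, seed = 7))
print(fit)
```

```
MERGM fit (converged; max |conv t| = 0.084)
                      effect parameter stderr significant
1             Density [ArcA]    -0.525  1.136            
2 Reciprocity [ReciprocityA]     1.079  0.363           *
3   Activity spread [AoutSA]    -1.646  0.684           *
4       Path closure [ATA-T]     0.320  0.157           *
5         Gender-Interaction     0.961  0.212           *
6  Cross-level arc [TXAXarc]     0.645  0.220           *
```

Reading the rows: friendships in this synthetic school are strongly
reciprocal and clustered (positive reciprocity and path closure),
same-gender arcs are over-represented (positive gender interaction), and
arcs are more likely between students sharing an online group (positive
cross-level closure — the alignment of offline and online ties that, in a
real evaluation, evidences delivery fidelity).  The asterisk marks
|θ̂|/SE > 2.

Goodness-of-fit simulates at the estimates and compares observed and
simulated statistics, including auxiliary descriptors not in the model:

```r
goodness_of_fit(school$network, school$attrs, fit,
                config = sampler_config(n_samples = 500, seed = 8))
```

```
MERGM goodness-of-fit (all statistics adequate) 
                  statistic observed sim_mean sim_sd      t fitted adequate
             Density [ArcA]  167.000  166.880  8.792  0.014   TRUE      yes
 Reciprocity [ReciprocityA]   12.000   11.742  3.178  0.081   TRUE      yes
   Activity spread [AoutSA]  169.188  169.335 15.003 -0.010   TRUE      yes
       Path closure [ATA-T]   39.000   38.903  9.882  0.010   TRUE      yes
         Gender-Interaction   75.000   75.236  7.074 -0.033   TRUE      yes
  Cross-level arc [TXAXarc]   23.000   22.706  4.511  0.065   TRUE      yes
               in_degree_sd    1.823    1.889  0.203 -0.323  FALSE      yes
             in_degree_skew    0.580    0.700  0.331 -0.363  FALSE      yes
              out_degree_sd    1.896    1.879  0.091  0.193  FALSE      yes
            out_degree_skew   -0.074   -0.154  0.127  0.625  FALSE      yes
               transitivity    0.102    0.084  0.017  1.063  FALSE      yes
                   isolates    1.000    1.230  1.052 -0.219  FALSE      yes
               mutual_dyads   12.000   11.742  3.178  0.081  FALSE      yes
```

## The analysis workflow

Numbered drivers under `analysis/` run the full study on five generated
schools; each writes its tables under `results/`:

```sh
Rscript analysis/01_generate_schools.R   # data + provenance records
Rscript analysis/02_fit_models.R         # per-school MERGM fits
Rscript analysis/03_goodness_of_fit.R    # GOF panels
Rscript analysis/04_report.R             # multi-school table + component reading
```

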