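---
title: "Modeling friendship-network and drinking co-evolution across schools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling friendship-network and drinking co-evolution across schools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(coevonet)
```

## The model

`coevonet` implements a stochastic actor-oriented model (SAOM) for the joint
dynamics of a directed friendship network and up to three ordinal behavior
dimensions — drinking frequency (1 = never ... 4 = weekly or more often) and
tertiled parental-control and adolescent-secrecy scores (1..3) — observed as
a multi-wave school panel in which each pupil may nominate up to 10 friends.

Between observation waves the system evolves in continuous time. Each actor
$i$ receives change opportunities at rate $\lambda_d$ per dimension
$d \in \{\text{network}, \text{alcohol}, \text{control}, \text{secrecy}\}$.
At a network opportunity the actor chooses among keeping the current state or
toggling one outgoing tie (additions are barred at the 10-nomination cap); at
a behavior opportunity the actor chooses among $\{-1, 0, +1\}$ level shifts
clipped to the scale. Each candidate state $x'$ is chosen with
multinomial-logit probability
$\exp f_i(x') / \sum_{x''} \exp f_i(x'')$, computed with log-sum-exp
stabilization, where the objective function
$f_i(x) = \sum_k \theta_k \, s_{ik}(x, z, v)$
is a weighted sum of effect statistics.

### Effect statistics and conventions

The tie-formation effects are: outdegree, reciprocity, transitive triplets,
square-root indegree popularity, same-gender, free-school-meal (FSM)
similarity, and — per behavior — alter, ego and similarity effects, plus a
control-ego × alcohol-similarity interaction. The behavior dynamics use
linear and quadratic shape terms, total alcohol similarity (influence through
the *absolute number* of similarly drinking friends), its interactions with
own control and secrecy, average secrecy similarity, average friends'
drinking on secrecy, the alcohol-to-control "effect from" term, and gender /
FSM main effects. `effect_catalog()` lists everything.

Fixed conventions, pinned by oracle tests:

* **Similarity kernel**: $\mathrm{sim}(v_i, v_j) = 1 - |v_i - v_j| / r$ with
  *theoretical* ranges ($r = 3$ for the 1–4 alcohol scale, 2 for tertiles,
  1 for binary FSM).
* **Transitive triplets** count the orientation $i \to j$, $j \to h$,
  $i \to h$ for actor $i$.
* **Centering**: behavior means $\bar z$ and mean similarities $\bar s$ are
  computed per school over all observed actor-waves (school-relative
  centering is what makes "relative to the school mean" selection tables
  well defined). Both are stored in the `model_spec`.
* **Isolates**: average-based statistics divide by $\max(1,
  \mathrm{outdeg}_i)$, so they vanish for isolates.
* **Single-sex schools**: the same-gender tie effect and the behavior gender
  main effects are automatically fixed at 0 (zero-variance covariate).

### Method-of-moments estimation

`estimate_school()` implements *unconditional* method of moments: the rate
parameters are free parameters matched to observed change-amount targets (the
Hamming distance between consecutive adjacency matrices on jointly observed
out-rows for the network; summed absolute level changes for behaviors), not
conditioned away. Evaluation effects are matched to their statistics summed
over actors and end-of-period waves.

The evaluation targets are **cross-lagged**: a network effect's statistic
pairs the end-of-period network with start-of-period behavior, and a behavior
effect's statistic pairs the end-of-period behavior with the start-of-period
network. Without the lag, the tie-similarity target and the total-similarity
target would be the *same* function of one state and the moment system
exactly singular; the lag is also what gives the moments the power to
distinguish selection (ties moving toward behavior) from influence (behavior
moving toward ties). Each period's simulation starts from the observed
(imputed) earlier wave, which conditions on the first observation of every
period and keeps periods independent.

The solver is Robbins–Monro stochastic approximation:

1. **Phase 1** estimates the Jacobian $\hat D$ of expected statistics at the
   starting point ($\theta_0 = 0$ except outdegree $-1$; rates initialized
   from observed change volumes) by forward finite differences with common
   random numbers.
2. **Phase 2** iterates $\theta \leftarrow \theta - a_k \hat D^{-1}
   (S(\theta) - s_{\mathrm{obs}})$ over subphases with the gain halved each
   subphase, componentwise step clamping, a positivity floor on rates, and
   the estimate taken as the average of the second half of each subphase's
   iterates.
3. **Phase 3** simulates independently at the estimate, giving per-target
   convergence t-ratios, the overall Mahalanobis convergence ratio, and the
   parameter covariance $\hat D^{-1} \hat\Sigma_S \hat D^{-\top}$ (with
   $\hat D$ re-estimated at the final point).

A fit is declared converged when every $|t| < .1$ and the overall ratio is
below $.25$ — the conventional thresholds. On failure the estimator performs
up to `max_restarts` Newton polish steps: the phase-3 *mean* deviation (much
less noisy than any single simulation) is corrected through the refreshed
Jacobian, followed by a fresh phase 3. Fixed effects keep their value exactly
and report no standard error; an exactly singular Jacobian raises an error
naming the collinear targets (e.g. fitting a quadratic shape when the
behavior occupies only two levels).

Defaults (`estimate_options()`): about 50 phase-1 simulations per parameter,
4 subphases of 40 iterations, 500 phase-3 simulations, 3 restarts,
finite-difference step 0.25, rate floor 0.05. The test suite runs reduced
settings (documented in each test) to keep a full run on one CPU in minutes;
the phase-3 size matters for the *convergence flag* because the t-ratio's
Monte-Carlo noise is $\approx 1/\sqrt{n_3}$, so a small `n3` can fail the .1
threshold even at the exact solution.

## Multi-school pooling

`meta_analyze()` pools each free effect across schools by random-effects
meta-analysis with the Paule–Mandel (empirical Bayes) $\tau^2$: the value at
which the weighted residual sum of squares, with weights
$w_s = 1/(se_s^2 + \tau^2)$, equals its degrees of freedom. With
$\hat\tau^2 = 0$ this reduces exactly to fixed-effect inverse-variance
pooling. Inference is Wald (normal); schools whose fit did not converge are
excluded with a message. `meta_regression()` regresses per-school estimates
on school context with the design `(1, boys, girls, prevalence - mean)`, so
the intercept is the expected parameter for a coeducational school at the
study-mean share of weekly-or-more drinkers. One meta-regression is fitted
per parameter, matching the layout in which such results are reported.

## Ego–alter selection tables

For a behavior with fitted ego, alter and similarity tie effects,
`school_log_odds_table()` evaluates, for every (sender level $v_e$, receiver
level $v_a$) pair, the log-odds of a tie relative to a dyad at the school
mean $\bar v$:

$$\beta_{ego}(v_e - \bar v) + \beta_{alt}(v_a - \bar v) +
  \beta_{sim}(\mathrm{sim}(v_e, v_a) - 1),$$

with the cell variance $g^\top \Sigma g$ from the fitted covariance. The
reference (mean–mean) cell is identically zero, so its odds ratio is exactly
1; because $\mathrm{sim}(k,k) = 1$, diagonal cells do not move with
$\beta_{sim}$ while every off-diagonal cell decreases in it. Tables are
pooled cellwise across schools on the log scale (variance-stabilized) with
the same random-effects machinery, overall and by school type. A cell is
flagged when the 95% CI of its pooled log-odds excludes 0 — equivalently the
OR interval excludes 1; this operationalizes "significant linear
combination" since CI overlap between different cells is ill-defined for a
single cell. `asymmetry_contrast()` reports
$\mathrm{cell}(e,a) - \mathrm{cell}(a,e)$ — the "opportunity hoarding"
contrast — treating the two pooled cells as independent (a documented
approximation); `school_asymmetry_contrast()` computes the exact per-school
version, $(\beta_{ego} - \beta_{alt})(v_e - v_a)$, with the full covariance,
and is what the tests rely on.

## Goodness of fit

`saom_gof()` simulates every period from its observed starting wave at the
fitted parameters and compares auxiliary statistics of the simulated networks
(indegree and outdegree histograms with a pooled top bin, and the 16-class
directed triad census computed by classifying all $\binom{n}{3}$ triples
through a canonicalized 64-pattern lookup) against the observed values via a
Mahalanobis distance with a Monte-Carlo p-value. `autoplot()` draws the
violin plots of the simulated distributions with the observed value overlaid;
`write_gof_csv()` exports the tidy draws.

## The synthetic-data generator

`synth_config()` defines the study conditions used throughout development
and testing: 22 schools (9 coeducational, 8 girls, 5 boys) of 60–210 pupils
followed over 5 annual waves; up to 10 nominations; wave-1 drinking at about
5% weekly (level probabilities .60/.27/.08/.05) rising to roughly 40% by
wave 5; uniform wave-1 control and secrecy tertiles; 12% wave-level absence
(capped so at least 80% of wave 1 is observed); FSM eligibility 20%. The
default true parameters are plausible pooled magnitudes — outdegree $-2.2$,
reciprocity $1.5$, transitive triplets $0.3$, indegree popularity $0.2$,
same-gender $0.5$, FSM similarity $0.2$, alcohol similarity $0.35$, alcohol
total similarity $0.46$, control similarity $0.12$, secrecy average
similarity $1.2$, alcohol-to-control $-0.25$ — plus an alcohol drift (linear
$0.55$, quadratic $0.05$ at behavior rate $1.6$) calibrated once so the
simulated prevalence trajectory tracks the observed cohort pattern
(.05/.12/.22/.34/.42 across waves). The default moderator offset adds $+0.4$
to the secrecy-alter tie effect in boys-only schools — ground truth the
school-context meta-regression should recover.

The wave-1 network is generated, not modeled: a gender-homophilous random
graph with mean outdegree $\approx 4$ suffices because estimation conditions
on the first wave. The generator emulates the *structure* of a school cohort
(sizes, scales, missingness, rising prevalence, context effects), not
item-level questionnaire responses, school recruitment, or pupils joining
and leaving mid-study; passing tests therefore certify the machinery under
the model's own assumptions, not robustness to real-data violations of them.

```{r, eval = FALSE}
cfg <- synth_config(seed = 1)
study <- generate_study(cfg)
study$metadata
```

## Missing data

A pupil absent on survey day loses their whole nomination out-row and all
behavior values for that wave; a present pupil's unlisted alters are observed
zeros, as roster instruments imply. For simulation, behaviors are
last-observation-carried-forward (wave-1 holes take the school-wave mode) and
missing out-rows are carried forward (zeros at wave 1). Imputed entries feed
the simulator but are excluded from the observed change (rate) targets, which
are computed on jointly observed actor-waves only. Schools with 20% or more
missing actor-waves are dropped by `filter_schools()` before analysis.

## Numerical choices and degenerate inputs

* Tertile ties go to the lower tertile; a constant score vector maps to the
  middle tertile. Tertiles are computed per school-wave (the natural frame
  when centering is school-relative).
* A respondent who reports ever drinking but no current frequency is an
  infrequent drinker (category 2); a never-drinker reporting a frequency is
  an inconsistency error.
* `choice_probabilities()` subtracts the maximum before exponentiating;
  probabilities are shift-invariant by construction.
* Rank-deficient simulated covariances (phase 3 or GOF) fall back to the
  Moore–Penrose pseudo-inverse with a warning; a zero-variance statistic
  reports t-ratio 0 when its deviation is 0 and `Inf` otherwise.
* Pure-outdegree dynamics have an exactly enumerable stationary law (each
  out-row is a reversible birth–death chain over its outdegree, truncated at
  the nomination cap); the tie probability equals
  $\mathrm{logit}^{-1}(\theta)$ exactly only in the single-dyad case, because
  with more candidates the choice-set normalizer couples the ties. The test
  suite pins both facts.

## Problem sizes used by the test suite

Oracle-equivalence checks run on 4–6 actor fixtures; analytic-limit checks on
2- and 20-actor chains; parameter recovery on 100 schools of 40 pupils and 3
waves (network + alcohol co-evolution); moderator recovery on 50 replicates
of a 22-school study of 25-pupil, 2-wave schools (network dynamics with a
static secrecy covariate); GOF calibration on 50 replicates of 25-pupil
schools. These sizes were chosen so a full run completes on one CPU in
minutes while leaving the statistical assertions (3 Monte-Carlo SEs, 85–99%
coverage, KS < 0.25) meaningful.

## Known limitations

* Score-type tests for time-heterogeneity of effects are not implemented;
  with 5 waves the rates are period-specific but evaluation effects are
  time-constant.
* Endowment/creation effects, GWESP, degree assortativity, and conditional
  or likelihood-based estimation are out of scope.
* The cross-cell independence approximation in pooled asymmetry contrasts
  slightly misstates their variance; use the per-school exact contrast when
  it matters.
* Composition change is modeled only as wave-level missingness.
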