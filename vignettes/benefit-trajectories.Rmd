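---
title: "Multi-state analysis of welfare-benefit registry episodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-state analysis of welfare-benefit registry episodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msregistry)
```

## The model

The package analyses life courses through eight states recorded (or
implied) by a national welfare-benefit registry: employment (1), sick
leave (2), vocational rehabilitation (3), medical rehabilitation (4),
time-limited disability benefits (5), disability benefits (6), emigrated
(7) and dead (8). Death is the only absorbing state. For mean-time and
regression summaries, states 3–5 are merged into a single *time limited
benefits* state, giving six states.

Movement between states is described by transition intensities
$h_{jk}(t)$, the instantaneous rate of moving from state $j$ to state $k$
at age $t$ given occupancy of $j$ just before $t$. The diagonal of the
intensity matrix is minus the row sum, so each row integrates to a proper
flow balance. Three layers of estimation are built on the counting
process $(n_{jk}(t), Y_j(t))$ of observed transitions and risk sets:

1. **Nelson–Aalen** cumulative intensities
   $\hat H_{jk}(t) = \sum_{T_s \le t} n_{jk}(T_s) / Y_j(T_s)$ with
   variance increments $n_{jk}(T_s)/Y_j(T_s)^2$.
2. **Aalen–Johansen** transition probabilities
   $\hat P(t_1, t_2) = \prod_{t_1 < s \le t_2} (I + \Delta \hat H(s))$,
   valid under the Markov assumption; every row sums to one by
   construction.
3. **State-occupation probabilities**
   $\hat Q_k(t) = \sum_j W_j \hat P_{jk}(t_0, t)$ with the initial
   distribution $W$ fixed to a point mass on employment at age 20
   (education is folded into employment), and **restricted mean times in
   state** $\hat E_k = \int_{t_0}^{t_1} \hat Q_k(u)\,du$, computed as
   exact areas of the piecewise-constant curve. The state means add up
   to $t_1 - t_0$ identically, which the code asserts before writing any
   table.

Occupation probabilities remain interpretable even where the Markov
assumption is doubtful; conditional transition probabilities are more
sensitive to it.

## Registry conventions

Raw data are benefit episodes (person, state, start and end age) plus a
conscription covariate record per person. Conversion to a counting
process applies the registry's reading rules:

* **Employment as gap.** Any period with no registered benefit is an
  employment spell, so each person's at-risk intervals tile the
  observation window exactly.
* **Calendar truncation.** Episodes are only visible inside 1992–2008,
  so a man born in year $b$ is observed between ages
  $\max(20, 1992-b)$ and $2008-b$ — delayed entry for older cohorts,
  early censoring for younger ones, at most 16 years each. Risk sets
  count only persons currently under observation, using left limits: a
  person transitioning or censored at $T_s$ is still at risk at $T_s$,
  a person entering at $T_s$ is not yet.
* **Half-open intervals.** A transition at $t$ closes one interval and
  opens the next at $t$; ties across different origin states at one
  event time enter the product-limit estimator through a single matrix
  factor.
* **Same-state re-episodes.** Back-to-back episodes of one benefit are
  counted in the transition tabulation (they are real registry events)
  but contribute no intensity, because a $j \to j$ intensity is
  undefined; the at-risk interval is left unbroken.
* **Rare transitions.** Pairs observed fewer than 10 times are removed.
  The package splices a removed event out: the person is treated as
  remaining in the current state, and a later transition out of the
  spliced-over state is re-attributed to the effective state. Whether
  the original analysis instead re-censored such spells is not
  documented; splicing keeps the window tiled and is the reading we
  adopted. The threshold and the removed pairs are recorded in the run
  manifest.

## Conscription covariates

General ability is scored on the STANINE scale (mean 5, SD 2); men
without a written test carry letter grades A/B/C. The unique linear map
matching the stated moments of the IQ-equivalent scale (mean 100, SD 15)
is $100 + (s - 5) \cdot 15/2$, so the class boundaries fall at 85 and
115. Scores 1–2 and C are *low*, 3–7 and B *average*, 8–9 and A *high*.
Mental health is scored 1–7 (problems) or 9 (none); 8 is never used and
is rejected as malformed input. The six analysis groups cross the IQ
class with the mental-health indicator; average IQ with no mental
problems is the reference throughout. Persons missing either score stay
in the non-parametric estimation but are excluded from regression
models.

## Simulation-based confidence intervals

Intervals for occupation probabilities and restricted means come from
perturbing the estimated increments: each $\Delta\hat H_{jk}(T_s)$ is
replaced by $\Delta\hat H_{jk}(T_s) + N(0, \widehat{\mathrm{var}})$,
independently across pairs and times, 1000 times by default, and the
functional is recomputed on each replicate. Numerical choices the
perturbation scheme itself does not determine:

* negative perturbed increments are truncated at zero, and if the
  perturbed mass out of one state at one time exceeds one the row is
  rescaled, so every replicate stays a valid probability path;
* intervals are empirical percentiles across replicates (robust to the
  skew the truncation induces); a normal-theory variant
  (point $\pm z \cdot$ replicate SD) is available through
  `type = "normal"`;
* the point estimate is always the unperturbed one.

## Discrete-time hazard models

Person-year indicators $Q_{ji} \in \{0, 1\}$ — state occupancy at any
point of age-year $j$ for person $i$ — are modelled marginally with a
complementary log-log link and one intercept per year,
$$\log(-\log(1 - Q_{ji})) = \alpha_j + \beta^\top Z_i,
  \qquad j = 20, \dots, 58,$$
the grouped proportional-hazards form in which $\exp(\beta)$ is a hazard
rate ratio. A one-year grid is used; a finer grid would multiply the
panel size without changing the marginal effects of interest. Estimation
is by GEE with an AR(1) working correlation across each person's years
(lag-one moment estimator for $\rho$, correlation $\rho^{|j-j'|}$ across
gaps), with robust sandwich standard errors always reported. Under an
independence working correlation the estimating equations reduce to the
pooled cloglog GLM score, which the test suite exploits as an exact
oracle.

Group effects are split at age 35 — the last age at which the targeted
young-age disability benefit can be granted — through one interacted
model per outcome rather than two stratified fits, so a single working
correlation is estimated per outcome; the period main effect is absorbed
by the year intercepts. Five outcomes are modelled separately on the
merged state space: death, emigration, disability benefits, time-limited
benefits, sick leave. Panel conventions: the occupancy indicator (not
first entry) is modelled because transient states recur; rows after
death carry a permanent one for the death outcome and terminate every
other panel; years spent entirely abroad are excluded from other
outcomes' risk rows. Age-years with no events in an outcome have
$\alpha_j = -\infty$ and are dropped, as is standard in discrete-time
survival; group-period cells with no events are reported as inestimable
(`NA`) rather than forced into the fit.

## The synthetic cohort generator

Because individual-level registry data cannot be distributed, the
package ships a seeded generator that reproduces the *structure* of the
study: continuous-time Markov paths from age 20 in employment with
piecewise-constant intensities over two age bands ([20, 35) and
[35, 58], the minimal structure supporting the before/after-35
contrast), multiplicative group effects, calendar truncation by birth
year, registry output containing only non-employment episodes, and
optional same-state re-episode injection (default probability 0.05,
roughly the share of back-to-back sick-leave re-episodes in the
published tabulation).

Default calibration, chosen once from the published aggregate tables
and not tuned afterwards:

* **Six-group prevalences.** The published captions give the marginal
  group sizes (57 092 low IQ of 863 369 scored; 33 880 with mental
  problems of 610 294 scored) and two joint anchors: 8 130 men with
  both low IQ and mental problems, and 518 852 with neither, among the
  585 061 complete-data men. Solving the remaining cells with the
  marginal low-IQ share, and splitting average/high by their marginal
  ratio, gives prevalences (reference 0.761, low-only 0.052,
  high-only 0.126, mental-only 0.040, low+mental 0.0139,
  high+mental 0.0067). The implied mental-problem share (0.061) sits
  slightly above the marginal one (0.055) because the joint anchors
  bind; we kept the anchors.
* **Baseline intensities** are order-of-magnitude calibrations to the
  published transition tabulation (e.g. employment→sick leave is by far
  the most frequent move; disability is nearly absorbing with rare
  returns; emigration allows return migration). Band two raises sick
  leave, disability entry and mortality and lowers emigration.
* **Group multipliers** follow the published ordering of hazard-rate
  ratios: disability entry 14.37-fold for low IQ with mental problems,
  about 4-fold for either factor alone, below 1 for high IQ; analogous
  patterns for sick leave, time-limited benefits, emigration and death.
* **Covariates** are drawn from the published score distributions
  (STANINE within class, letter-grade share 2.7%, missingness 8.8% for
  IQ and 33.6% for mental health), six physical scores with published
  impairment shares, and BMI $\sim N(23.5, 3^2)$.

What the generator does *not* emulate: non-Markov duration dependence,
seasonal or calendar-period effects, policy changes within 1992–2008,
and any dependence of covariate missingness on outcomes. Tests passing
on generated cohorts therefore validate the estimators and their
book-keeping, not the substantive findings on real registry data —
numerical reproduction of the published result tables is out of scope by
design.

## Verification strategy and problem sizes

The test suite checks every estimator against an independent oracle:
brute-force risk-set loops for Nelson–Aalen, Kaplan–Meier (via the
survival package) for the two-state reduction, explicit forward matrix
recursion for Aalen–Johansen, matrix exponentials (via Matrix::expm) of
the generating intensity matrix for occupation curves, uncensored
person-year tallies for restricted means, and the pooled cloglog GLM for
the independence-GEE. Consistency and parameter recovery run at cohort
sizes 3 000–5 000 with three-Monte-Carlo-SE bands; hazard-ratio recovery
of a 14-fold disability effect uses 100 replicates of 1 200 persons;
interval coverage uses 200 replicates of 300 persons with 500
perturbation draws each. These sizes give Monte-Carlo bands narrow
enough to detect implementation errors while keeping the default test
run inside a few minutes.

## Known limitations

* The Aalen–Johansen estimator is reported on the full observed age
  range even where late-age risk sets are thin; curves beyond roughly
  age 55 on small simulated cohorts are noisy.
* The GEE solver estimates a single scalar AR(1) parameter; more
  elaborate working structures (exchangeable, unstructured) are not
  implemented.
* The rare-transition splice is one defensible reading of an
  under-documented step; the alternative (re-censoring at the removed
  event) would shorten risk intervals slightly.
* Perturbation intervals are marginal per functional component; no
  simultaneous bands are provided.
* Truncating negative perturbed increments at zero — required to keep
  every replicate a valid probability path — discards part of the
  perturbation variance. A single-event increment has mean and standard
  deviation both equal to $1/Y_j(T_s)$, so truncation retains only about
  75% of its variance *at any cohort size*, and the resulting intervals
  are systematically somewhat narrow: on the coverage simulation in the
  test suite, nominal 95% intervals cover the true restricted means for
  83–95% of replicates depending on the state and interval type
  (percentile intervals additionally inherit the upward truncation
  shift; normal-theory intervals centred on the point estimate fare
  slightly better). Users needing strict nominal coverage should treat
  the intervals as mildly anti-conservative.
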