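---
title: "Modelling the co-evolution of friendship networks and adolescent alcohol use"
author: "netbehav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the co-evolution of friendship networks and adolescent alcohol use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netbehav)
```

## The scientific problem

Adolescents and their friends drink alike.  Two mechanisms can produce
that similarity: *selection* (adolescents befriend peers who already
drink like them) and *influence* (adolescents adjust their drinking
toward their friends').  Cross-lagged regressions cannot separate the
two, because friendship ties and drinking co-evolve and network ties
are not independent observations.  `netbehav` implements the
stochastic actor-oriented model (SAOM) for two-wave school friendship
panels with an ordinal alcohol-use frequency (six categories from
"never" to "more than once a week"), together with the
Method-of-Moments machinery needed to fit it school by school and the
meta-analytic machinery needed to pool a dozen schools.

## The model

Between the two observation waves, change unfolds in continuous time.
Opportunities for change arrive as a Poisson process with intensity
$n(\lambda_{net} + \lambda_{beh})$ over a unit-length period; each
opportunity belongs to the network side with probability
$\lambda_{net}/(\lambda_{net}+\lambda_{beh})$ and to a uniformly
random actor $i$.  A network opportunity lets $i$ toggle one outgoing
tie (or keep the status quo); a behavior opportunity lets $i$ move one
level up or down the alcohol scale (or stay).  Options are chosen by
multinomial logit on the actor's objective function

$$f_i = \sum_k \beta_k\, s_{ik}(x, z, v),$$

evaluated at each candidate state — the standard Gumbel-error
representation of the "random unexplained influence".  The effect
statistics $s_{ik}$ are the catalog documented in `?saom_effect`:
density, reciprocity, transitive triplets, 3-cycles, degree
popularity/activity terms, and covariate ego/alter/similarity/same
terms on the network side; linear and quadratic shape, average friend
alcohol use, and covariate terms on the behavior side.  Because the
logit is shift-invariant, the simulator evaluates objective
*differences* (change scores) rather than full objective values; the
test suite verifies the two routes agree exactly.

Two conventions matter and are deliberately fixed:

* **Centering.**  Covariates are centered at their school mean;
  similarity scores at the school's mean ordered-pair similarity at
  wave 1; behavior at its **wave-1** mean.  Wave-1 centering (rather
  than a both-waves grand mean) makes the process simulated forward
  from wave 1 identical to the process the estimator assumes — the
  constants involve nothing the model is supposed to predict.
* **Influence functional form.**  "Average friend alcohol use" is the
  average-alter product form
  $\tilde z_i \cdot \sum_j x_{ij}\tilde z_j / \sum_j x_{ij}$ (zero for
  actors without out-ties).  The average-similarity alternative is
  equally standard in the field; the average-alter form is the closest
  reading of "change based on the average drinking of immediate
  friends" and is what the package implements.

## Sample construction rules

`read_panel()` accepts delimited edge lists (one file per wave) plus an
actor table.  The cleaning pipeline applies, in order:

1. `filter_isolates()` — actors who neither name nor are named by
   anyone at either wave carry no information and are dropped.
2. `impute_locf()` — wave-2 non-responders keep their wave-1 outgoing
   ties and behavior, flagged non-informative; incoming ties reported
   by responders stay informative.
3. `screen_school()` — schools whose Jaccard tie-stability index
   $J = F_{11}/(F_{11}+F_{01}+F_{10})$ falls below 0.20 are excluded:
   too little persistence means the two waves barely constrain the
   micro-process.  The counts use observed cells only, so imputed
   copies of wave 1 cannot inflate stability.

Flagged cells are excluded from every estimation target: non-responder
rows are zeroed and their behavior replaced by the carried-forward
value in *both* the observed and the simulated statistics, so nothing
a non-responder "did" after wave 1 can move a moment condition.
Retention percentages are reported with a floor at one decimal, the
convention under which 2,299 of 2,563 is 89.6%.

## Estimation

`fit_school()` solves the moment equations
$E_\theta S(X(t_2), Z(t_2)) = s_{obs}$ by Robbins–Monro stochastic
approximation in the classic three phases:

* **Phase 1** estimates the sensitivity matrix
  $D = \partial E S/\partial\theta$ by common-random-number central
  differences (`estimate_derivative()`).  The default step is 0.15:
  at the school sizes of interest a 0.1 step left the weaker columns
  dominated by Monte Carlo noise, and the bias of the slightly larger
  step is negligible against the simulation noise it suppresses.
* **Phase 2** iterates
  $\theta \leftarrow \theta - a\,B^{-1}(S_{sim}-s_{obs})$
  with one simulated period per update, halving the gain $a$ across
  subphases and Polyak-averaging the trajectory of each subphase after
  discarding the first quarter as burn-in.  The step matrix $B$ is a
  half-and-half blend of $D$ with its own diagonal: with noisy
  simulated derivatives, pure full-matrix Newton updates occasionally
  amplify noise along near-collinear directions and diverge, while
  pure per-coordinate scaling cannot travel along correlated (ridge)
  directions at all; the blend keeps most of both virtues and is
  adjustable via `saom_control(phase2_blend =)`.  Subphase lengths
  grow as the gain shrinks (defaults 50/100/200/300) so that
  $a \times T \gg 1$ in every subphase and the average is not biased
  toward the subphase's starting point.
* **Phase 3** freezes $\hat\theta$, simulates $n_3$ replicates
  (default 500, scaled profile 250), and reports the convergence
  t-ratios $t_k = \overline{(S_k - s_{obs,k})}/sd(S_k)$, the
  conventional criterion being $\max_k |t_k| < 0.10$ over evaluation
  effects.  The sensitivity matrix is re-estimated at $\hat\theta$
  with twice the phase-1 replicate count — standard errors along
  weakly identified directions are only as honest as this matrix — and
  the covariance of $\hat\theta$ is the sandwich
  $D^{-1}\hat\Sigma (D^{-1})'$ with $\hat\Sigma$ the phase-3 target
  covariance.  If the criterion fails, the fit takes one full-matrix
  Newton correction from the precise phase-3 residual (averaged over
  $n_3$ replicates, this residual is accurate enough for the full
  inverse even along correlated directions) and re-enters phase 2, up
  to three times.

Rates are estimated unconditionally as parameters, with the observed
Hamming change counts as their targets; estimation conditional on the
observed number of changes is a recognised alternative that the
package does not implement.  Evaluation parameters are kept in
$[-12, 12]$ and rates in $[0.05, 100]$ during optimisation, outside
of which choice probabilities saturate and carry no gradient
information.

Identification caveat: with one period, one ordinal behavior and a
school of less than a hundred students, the behavior side is weakly
identified — the linear shape and average-alter statistics are highly
correlated, so their standard errors are honest but large.  Parameter
recovery holds in the sense that $\hat\theta$ falls within the
reported uncertainty of the generating values, not in the sense of
small absolute errors.

## Meta-analysis

Schools are fitted independently; `meta_analyze()` pools each effect
across schools two ways.  The Snijders–Baerveldt two-stage model
treats per-school estimates as $\hat\theta_j = \mu + U_j + E_j$ with
between-school variance $\sigma^2$, estimated by iterated weighted
least squares with a method-of-moments update for $\sigma^2$
(truncated at zero; the Paule–Mandel estimator).  The two-sided p for
$\mu$ uses a t reference with $N-1$ degrees of freedom, an honest
small-sample choice at 13 schools; the test suite cross-checks the
pooling against an independent Paule–Mandel implementation.  Fisher's
combination $-2\sum_j \log p_j \sim \chi^2_{2N}$ is applied separately
to the right- and left-sided per-school p-values.  An effect is
declared significant when either one-sided combination is at or below
0.025 (the multiplicity-halved level, boundary inclusive) or the
Snijders–Baerveldt p is below 0.05; on conflict the Fisher verdict is
treated as decisive, which is the appropriate reading when school
sizes span an order of magnitude.  `selection_odds_ratio()` converts a
similarity coefficient $\beta$ into the odds ratio $e^\beta$ of a tie
to an identical versus maximally different alter, with a
normal-approximation interval $e^{\beta \pm 1.96\,se}$ when a standard
error is supplied; no other interval construction is attempted.

## The synthetic study generator

Access-restricted survey data cannot ship with the package, so
`generate_study()` manufactures multi-school panels with the
statistical profile the analysis expects, and — crucially — with known
generating parameters, so estimation and pooling can be validated by
parameter recovery.  The defaults encode the published descriptive
profile of the motivating study population:

* 13 schools, 2,563 students, sizes 48–987 (mean 197);
* 50.8% male; age truncated-normal 15.8 (SD 1.3) on 12–18, recorded to
  the nearest month; five race/ethnicity categories (60.9% white,
  16.4% Black, 1.6% Native American, 3.4% Asian, 17.7% Hispanic) with
  minority = non-white; the five-level parental drinking distribution
  (56.2/27.1/7.4/5.6/3.7%); family bonding with 60% at level 4 or 5
  (the published table gives only that tail probability; the split
  across the five levels is the package's choice);
* wave-1 alcohol distribution 49.6/18.3/14.2/8.3/9.6%, the top
  "weekly or more" mass split evenly over the two internal top levels;
* wave-1 out-degrees Poisson with mean 2.04, truncated at the
  10-nomination instrument cap, targets drawn by a homophilous logit
  on age proximity, gender match, race match and alcohol similarity
  (weights 2 / 0.7 / 1 / 0.6 — chosen once to give visible
  assortativity at the observed density, not calibrated to any
  published statistic);
* wave 2 simulated forward under a generating model whose effect
  values are the pooled published estimates for the included subset
  (density −3.42, reciprocity 2.53, transitive triplets 0.84, age
  similarity 1.48, gender same 0.36, alcohol similarity 1.28; behavior
  linear −0.60, quadratic 0.07, average alter 0.07), with rates
  (network 3, behavior 3) set so that between-wave stability lands in
  the observed Jaccard range 0.20–0.33 and about half the students
  keep their drinking frequency;
* the density parameter of a school of size $n$ is offset by
  $-0.4\log(n/197)$: without an offset, expected degree drifts up with
  school size; a full $-\log(n/197)$ over-corrects because
  reciprocity, closure and homophily already concentrate choice in
  small candidate sets.  The exponent 0.4 was fixed by simulating the
  extreme school sizes once, before any estimation experiments;
* wave-2 non-response 10.0% for students below weekly drinking and
  14.1% at weekly or above.  The published contrast — 13% of the lost
  versus 9% of the retained were weekly-plus drinkers, with overall
  retention 89.6% — pins down exactly these conditional loss rates.

What the generator does **not** emulate: grade structure and
classroom sorting within schools, correlated covariates (age by race,
for instance), survey weights and stratification, and any wave-1
network feature beyond degree, assortativity and the nomination cap
(wave 1 is conditioned on, not modelled, in the analysis — so the
generator only needs its summary profile, and passing tests say
nothing about fitting real wave-1 structure).

## Problem sizes used in validation

The test suite exercises the full pipeline at sizes a laptop handles
comfortably: brute-force oracles on directed graphs of up to 7 actors;
choice-probability checks on 3–6 actors; moment self-consistency and
derivative checks on schools of 25–40; parameter recovery on ten
schools of 60 actors under the scaled estimation profile; pipeline
determinism on three schools of 30–44.  The default 13-school study
(2,563 actors) is generated in full for the calibration checks.  These
sizes are the package's validation choices; the machinery itself has
no hard-coded limits beyond memory for the $n \times n$ adjacency.

## Known limitations

* Method of Moments only; no maximum-likelihood or Bayesian
  estimation of the chain.
* Binary single-relation networks; no valued or multiplex ties, no
  time-varying covariates within a period.
* The behavior scale is fixed at six ordered levels internally.
* Degree popularity effects use raw degrees; square-root variants are
  common elsewhere and would need a catalog extension.
* Fits at the largest observed school sizes (near 1,000 actors) are
  computationally heavy in plain R; the package targets the study's
  typical school sizes.
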