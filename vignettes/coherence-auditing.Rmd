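---
title: "Auditing the coherence of model-based drug-combination designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the coherence of model-based drug-combination designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combcoherence)
```

## The problem

A phase I drug-combination trial searches a $J \times K$ lattice of dose
pairs for the maximum tolerated dose (MTD): the combination whose probability
of dose-limiting toxicity (DLT) is closest to a target $p_T$. Toxicity is
assumed to increase when either agent's dose increases with the other fixed,
but an anti-diagonal pair such as $(j{+}1, k{-}1)$ versus $(j, k)$ is
unordered a priori — the *partial order* that distinguishes combination
trials from single-agent ones.

A design is **coherent** when it never escalates after an observed toxicity
and never de-escalates after a non-toxicity. For combinations the notion is
relative to the design's candidate sets: given the current dose $X_n$, an
escalation set $E_n$ and a de-escalation set $D_n$ of adjacent doses are
defined, and coherence requires $\Pr(X_{n+1} \in E_n \mid Y_n = 1) = 0$ and
$\Pr(X_{n+1} \in D_n \mid Y_n = 0) = 0$. Two candidate-set geometries are in
common use: the **ND-design** (straight moves only,
$E_n = \{(j{+}1,k), (j,k{+}1)\}$, $D_n = \{(j{-}1,k),(j,k{-}1)\}$) and the
**D-design**, which additionally allows anti-diagonal moves, classified as
escalation or de-escalation by the *estimated* toxicity order (giving **weak
coherence**) or by the *true* order (giving **strong coherence**). The two
semantics differ only when the model misorders a diagonal — a misspecification
phenomenon with no single-agent analogue.

This package implements the model-based machinery end to end — eight
published dose-toxicity surfaces, reproducible posterior means, the
assignment rule, ND/D/two-stage trial engines — and an auditing layer that
classifies every simulated transition and empirically checks the sufficient
conditions that have been proposed for coherence:

* **the sign condition** (here called condition A): for every patient $n$
  and parameter component $t$,
  $(Y_n - p_T)\,(\hat\theta_{n,t} - \hat\theta_{n-1,t})\,
  \partial F(u_j, v_k, \theta)/\partial\theta_t \ge 0$
  at the treated dose;
* **uniform monotonicity**: $F(u,v,\theta)$ monotone in each $\theta_t$ with
  a dose-independent direction (claimed to imply the sign condition);
* **B1/B2**: the surface increases in both doses, and the model's
  anti-diagonal order agrees in sign with the truth for every $\theta$
  (claimed to upgrade weak to strong coherence);
* **the two-stage switch condition**: the transition from the last titration
  patient to the first model-based dose moves with (for toxicity, against)
  the model order for every $\theta$ in the prior's support.

## Models

The assignment rule is the CRM-type argmin
$X_{n+1} = \arg\min_{(j,k) \in A_n} |F_{jk}(\hat\theta_n) - p_T|$ over
$A_n = \{X_n\} \cup E_n \cup D_n$, with $\hat\theta_n = E(\theta \mid H_n)$
the posterior mean under a Bernoulli likelihood. The model families (see
`model_families()`) are the four-parameter logistic
$\mathrm{logit}\,F = \theta_1 + \theta_2 u + \theta_3 v + \theta_4 uv$, the
generalized CRM (categorical agent-2 intercepts plus a slope), the scaled
logistic $\rho\,\mathrm{logit}^{-1}(\cdot)$ (plateaus at $\rho < 1$), the
change-point model $\mathrm{logit}\,F = \min(\alpha + \beta u + \gamma v, w)$
(plateaus at $\mathrm{logit}^{-1}(w)$), the Clayton and Gumbel copula-type
models that combine single-agent skeleton estimates, the log-linear model
$\log(1 - F) = \alpha \log(1-u) + \beta \log(1-v) +
\gamma \log(1-u)\log(1-v)$, and a six-parameter ratio model
$F = G/(1+G)$. Each family carries its published admissibility constraints,
enforced strictly with a $10^{-10}$ margin; every admissible parameter vector
produces a surface respecting the partial order (the two plateau families
non-strictly on their caps).

Two readings deserve note. The Gumbel formula circulates with a
typographically truncated brace; we implement the Farlie–Gumbel–Morgenstern
form $F = 1 - (1-p^\alpha)(1-q^\beta)\{1 + p^\alpha q^\beta
(e^\gamma-1)/(e^\gamma+1)\}$, which matches the printed symbols and has the
correct independence limit at $\gamma = 0$; the reconstruction is noted here
rather than treated as certain. For the six-parameter model the printed
positivity constraints do not by themselves force monotonicity — the
exponents must also be positive — so the admissibility predicate includes
$\beta_1, \beta_2, \beta_3 > 0$; the interaction positivity condition is
treated as vacuous at a zero dose, where the term vanishes identically. The
log-linear model needs $u, v < 1$ for $\log(1-u)$ to exist; its grids are
restricted accordingly, and on $[0,1)$ the printed constraints guarantee the
partial order. The generalized CRM's intercepts are additionally required to
increase in $k$, without which the surface would not conform to the partial
order in the agent-2 level.

## Reproducible posterior means

Priors are not dictated by the designs themselves; the defaults here are
independent components — normal$(0, 2^2)$ on unconstrained parameters,
exponential$(1)$ on positive ones (negated for the log-linear interaction),
uniform$(0,1)$ on the scaled-logistic plateau — multiplied by the family's
admissibility indicator. Any component can be overridden per run.

`make_integrator()` evaluates the model surface once at a fixed set of
parameter points: a deterministic tensor-product Gauss–Legendre rule over the
prior box for $p \le 5$ (nodes per axis 48/32/20/12 for $p \le 2/3/4/\ge5$ by
default), or a seeded importance sample from the prior for the six-parameter
family. The four-parameter logistic's admissible set is not a box
($\theta_2 + \theta_4 v_k > 0$, $\theta_3 + \theta_4 u_j > 0$), so its
interaction nodes are mapped onto the admissible interval computed per
$(\theta_2, \theta_3)$ node; the generalized CRM integrates in transformed
coordinates (first intercept, positive increments, slope) so its ordered
support becomes a box.

The design choice that matters for auditing: because the node set is fixed,
every posterior mean computed along a trial is the *exact* posterior mean
under the discrete prior supported on those nodes. Audit verdicts therefore
cannot be artifacts of integration error — whatever the resolution, the
simulated trial is an exact realization of the design under a legitimate
(discretized) prior, and any theorem that holds "for any prior" must hold
for it. A Markov-chain sampler would reintroduce per-update stochastic error
and could manufacture spurious violations; the fixed-draw importance sampler
cannot. Estimates are flagged only when the effective sample size degenerates
(below 50); quadrature estimates are never flagged.

Accuracy *relative to the continuous prior* is a separate question, assessed
two ways: doubling the resolution moves the estimates by less than $10^{-3}$
on fixture histories, and on smooth-support fixtures (`oracle_fixture()`)
the posterior means agree with an independent brute-force oracle — a dense
midpoint lattice with Richardson extrapolation (`posterior_mean_oracle()`) —
to better than $10^{-5}$. The oracle fixtures use narrow uniform prior boxes
because the midpoint rule converges too slowly over wide truncation boxes at
$p = 4$ to serve as a $10^{-3}$ referee; the wide-prior configurations are
covered by the self-consistency check instead.

## Scenarios and fixtures

`gen_scenario()` builds true-DLT matrices from seeded positive logit-scale
increments (uniform on $0.4$–$1.2$ times a `spread` of $0.5$ by default,
spanning roughly $0.05$–$0.75$ on a $4\times4$ grid), anchored so the
scenario MTD hits $p_T$ exactly. The generator emulates the one structural
property the designs assume — strict partial-order monotonicity with free
anti-diagonal cells — and nothing else about real dose-toxicity data (no
plateaus, no ordinal toxicity grades, no patient heterogeneity, no late-onset
outcomes), so passing audits speak to the transition logic, not to clinical
operating characteristics.

Two constructed configurations drive the misspecification analyses.
`gen_misspecified_pair()` makes the working model's anti-diagonal order
oppose the truth (model dominated by agent 1, truth by agent 2), the setting
in which a D-design move can be weakly coherent yet strongly incoherent.
`certified_diag_pair()` is the opposite: a tight uniform prior whose *every*
admissible parameter ranks all anti-diagonal pairs the same way as the
scenario, so the B1/B2 conditions are certifiable over the whole support.

## What the audits find

Running the audit engine at scale (200 trials of 30 patients per family and
design, fresh seeded scenarios per trial; 50 trials for the six-parameter
family) produces two results that are worth stating plainly, because they are
properties of the printed design rule itself, not of the implementation:
the posterior means are exact under the discretized priors (so resolution
cannot manufacture them), and the first-update products are nonnegative
exactly as the association inequality requires.

**The per-component sign condition fails routinely for multi-parameter
models.** Coordinatewise monotonicity of $F$ in $\theta$ does not control the
*joint* posterior: cross-parameter correlation can reverse an individual
component's mean shift. A four-atom example makes this exact. Take two
binary parameters with prior masses $P\{(0,0)\} = 0.05$,
$P\{(1,0)\} = P\{(0,1)\} = 0.45$, $P\{(1,1)\} = 0.05$ and treated-dose
toxicities $F = 0, 0.01, 0.99, 1$ — increasing in both coordinates. After
observing $Y = 0$ the mean of the first parameter *rises* from $0.5$ to
$0.891$: the non-toxicity mostly rules out $(0,1)$, and the negatively
correlated prior shifts mass onto $(1,0)$. The inference "monotone in each
coordinate, hence each posterior mean moves against the outcome" is valid
for $p = 1$, and for the first update from a *product* prior (a Harris-type
association inequality — note the constrained logistic prior is not a
product measure, so even its first update is not protected), but not in
general. Empirically the sign condition fails on most 30-patient traces of
every family with $p > 1$, including verifiably uniformly monotone
configurations — so the claim that uniform monotonicity implies the sign
condition fails with it.

**The restricted argmin itself can be incoherent.** Even on updates where
the estimates shift monotonically everywhere, Definition-level violations
occur through a mechanism specific to the no-skipping candidate sets: the
argmin over $A_n$ can move the trial past a partial-order-*incomparable*
dose whose estimate sits just beyond the target; one step later that dose is
adjacent again, now on the near side of the target, and the rule legally
steps down onto it after a non-toxicity (or up onto it after a toxicity).
Every violating transition observed has this signature — the landing dose
was absent from the previous patient's candidate set. Violation counts vary
enormously by family (from zero for the log-linear ND configuration to
roughly half of all change-point and scaled-logistic trials), tracking how
often the estimated surface strands a neighbor on the wrong side of $p_T$.
As a control, the acceptance script reruns the same seeded batches with the
restriction dropped (`run_trial(..., restrict_candidates = FALSE)`, the
classical single-agent assignment, for which the coherence argument goes
through) and reports the violation count, which collapses to zero or near
zero. The restriction, not the model or the posterior, is the structural
cause; a practitioner who wants guaranteed coherence must either drop the
no-skipping restriction or add an explicit outcome gate to the rule.

The acceptance suite asserts the theorem-suite properties exactly as stated
— zero violations, nonnegative sign products — and those assertions fail
where the measurements above say they must; the audit reports, not the
assertions, are the package's considered output. The remaining suites behave
as the theory predicts: the weak/strong distinction appears exactly on
misordered diagonals (the misspecification fixture reliably yields traces
that pass the weak audit and fail the strong one), the monotonicity checker
certifies raw-dose logistic configurations and produces explicit witnesses
on mixed-sign standardized doses, the single-agent reduction reproduces the
classical classification, and the switch-condition checker accepts
partial-order-consistent switch transitions and flags constructed
violations.

## Numerical and design choices

* Exact argmin ties retain the current dose; remaining ties prefer doses
  lower in the known partial order, then lexicographic order. A diagonal
  neighbor whose ordering value ties the current dose exactly is excluded
  from both candidate sets — its order is indeterminate, and exclusion is the
  conservative reading.
* One-stage trials start at the prior estimate of the MTD (global argmin of
  the prior-mean surface); two-stage trials start at $(1,1)$ on a validated
  titration path (default: the staircase), escalate until the first
  toxicity, and also switch on path exhaustion, since a first-toxicity-only
  rule would stall at the path's top. Stage-1 never de-escalates. Cohorts
  are of size one; outcomes use one seeded uniform stream per trial so design
  variants are comparable under common random numbers.
* The switch-condition checker evaluates the transition from the last
  stage-1 patient to the first model-based dose — the only transition not
  covered by the stagewise coherence results — over a seeded sample of
  admissible parameters. Like the monotonicity and B1/B2 checkers it is a
  falsifier with witnesses, certifying only up to the sampled set.
* The sign-condition gradient is evaluated at the estimate in force when the
  patient was dosed; for the families used in the misspecification and
  certification analyses the gradient signs are parameter-independent, so
  this single evaluation point decides the condition for every $\theta$.
  Change-point updates whose differencing stencil straddles the kink surface
  return one-sided derivatives and are skipped with a count.
* Test-suite problem sizes: the theorem suites run 200 trials x 30 patients
  per family and design (50 for the six-parameter family) at reduced
  quadrature resolution (16/12/8 nodes per axis for p = 3/4/5), which leaves
  every audit conclusion unchanged by the exactness argument above; the
  oracle comparisons use 5 histories per family at full resolution.

## Limitations

The audits are finite: falsifiers certify nothing beyond the sampled
parameter sets, seeds, and scenario bank, and the violation *rates* reported
depend on the default priors and grids (the violations themselves are exact
counterexamples and depend on nothing). The engine implements the transition
rule only — no early stopping, no safety overdose control, no terminal MTD
selection, no cohorts — so it measures coherence, not full operating
characteristics. Late-onset toxicity and model averaging across orderings
are out of scope.
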