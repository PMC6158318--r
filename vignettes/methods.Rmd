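---
title: "Methods: belief updating, precision inference, and simulated lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: belief updating, precision inference, and simulated lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(activevision)
```

# The generative model

`activevision` simulates a synthetic subject foraging a simple visual scene
with saccades, inferring simultaneously *what is where* and *how much to
trust its own visual input*. The subject entertains a discrete-state Markov
decision process generative model

$$
P(\tilde o, \tilde s, \pi, \zeta) \;=\;
\underbrace{P(\pi)\,P(s_1)\,P(\zeta)}_{\text{priors}}\;
\prod_\tau
\underbrace{P(s_{\tau+1}\mid s_\tau,\pi)}_{\text{transitions}}\;
\underbrace{P(o_\tau\mid s_\tau,\zeta)}_{\text{likelihood}} ,
$$

with hidden states factorized into four *feature* factors (the circle at
each quadrant: white/absent, green, or blue) and one controllable *fixation*
factor. Feature transitions are identity matrices — the scene is static, so
all prior confidence about features lives in the initial-state prior
$P(s_1)$ — while fixation transitions are selected by the saccade the policy
commands. Two modalities report on the states: a visual outcome that depends
on the fixation and on the feature at the fixated location, and a
proprioceptive outcome that is an identity mapping of fixation.

The sensory precision $\zeta$ acts on the visual likelihood as an inverse
temperature, column by column:

$$
\bar A_{ij} \;=\; \frac{A_{ij}^{\,\zeta}}{\sum_k A_{kj}^{\,\zeta}},
$$

so $\zeta = 1$ leaves the mapping unchanged, $\zeta = 0$ makes every
observation uninformative, and $\zeta \to \infty$ makes the likelihood
deterministic (`modulate_likelihood()`). Each of the four locations carries
its own precision, believed under a $\mathrm{Gamma}(1, \beta)$ prior and
posterior with expectation $\zeta = 1/\beta$, and only the currently fixated
location's belief is updated. Proprioception is never modulated.

## Why the visual mapping is *near*-deterministic

`build_foraging_model()` gives the visual likelihood a `visual_confidence`
of 0.9 by default: the fixated feature is reported correctly with
probability 0.9, the remaining mass split over the other two values
(`visual_confidence = 1` recovers the exactly deterministic mapping). This
is a deliberate modelling choice, not a numerical convenience. The free
energy gradient that drives precision inference compares the log-likelihood
of the outcome actually observed with its modulated-average counterpart; if
the likelihood is an exact delta, both terms sit at $\log 1 = 0$ whenever
prediction and outcome agree, so *consistent evidence could never raise*
the inferred precision, and a single conflicting outcome would carry the
full weight of the probability floor ($|\ln 10^{-16}| \approx 37$ nats),
instantly overturning any realistic prior. A finite sensory channel with a
small error rate gives both effects their graded, biologically sensible
form: agreement nudges $\zeta$ up toward a self-limiting equilibrium
(about +20% under the defaults), conflict collapses it. The *world* itself
remains noiseless: the generative process always returns the true feature.

# State inference

The approximate posterior is the mean-field product
$Q(\tilde s,\pi,\zeta) = Q(\pi)\,Q(\zeta)\prod_f Q(\tilde s_f \mid \pi)$ —
factorized across policies, precision, and state *factors*, but **not**
across time. Each factor's temporal chain is kept jointly and updated by
exact forward–backward smoothing, with likelihood messages formed by
averaging the precision-modulated log-likelihood over the other factors'
current marginals. Coordinate sweeps over factors repeat until the largest
marginal change falls below `tol = 1e-4` (at most `max_sweeps = 16`); each
sweep can only lower the free energy, which `infer_states()` records per
sweep so the monotone descent is testable. Keeping the within-factor chains
exact means that on a single-factor model the scheme *is* exact Bayesian
smoothing — the package's tests exploit this by checking the variational
posteriors against brute-force enumeration over all state sequences, and
the free energy against the negative log evidence. A per-timestep
mean-field with (near-)deterministic transitions would instead collapse
toward deltas and could not meet those oracles; that is why this structured
scheme was chosen over naive damped fixed-point iteration of independent
marginals.

All probability arrays pass through `log_stable()`, which floors entries at
$\varepsilon = 10^{-16}$ before the logarithm: identity transition mappings
and lesioned priors contain exact zeros, and every update takes logs.

One subtlety matters for everything downstream: a location's precision
applies to **all** observations gathered there, because there is a single
$Q(\zeta)$ per location. When precision collapses after a conflict, the
smoothing pass reweights the *already seen* evidence with the new, lower
$\zeta$ — the model retrospectively discounts data it has decided not to
trust. This is what allows a sufficiently precise prior to dominate
perception indefinitely.

# Precision inference

After each observation the fixated location's rate $\beta$ takes
`precision_steps = 4` gradient steps of size `kappa = 0.2` on the
variational free energy, evaluated at $\zeta = 1/\beta$:

$$
\frac{\partial F}{\partial \zeta}
= \sum_j s_j \Big(\sum_i \bar A_{ij}\ln A_{ij}\Big)
- \sum_i o_i \sum_j s_j \ln A_{ij}
+ \beta_{\text{prior}} - \frac{1}{\zeta},
$$

where $s$ is the joint state belief over the likelihood's columns at the
fixated step and the last two terms are the derivative of
$\mathrm{KL}[\mathrm{Gamma}(1,\beta)\,\|\,\mathrm{Gamma}(1,\beta_{\text{prior}})]$
in $\zeta$. The update is $\beta \leftarrow \beta + \kappa\,\partial
F/\partial\zeta$ (a descent of $F$ in $\zeta$, since $\zeta = 1/\beta$),
clipped at $\beta \ge 10^{-6}$. The analytic form is verified against
central-difference differentiation of the assembled free energy to
$10^{-5}$ relative error across 100 random models in the test suite; the
same identity is re-derived at run time by `scripts/acceptance.R`.

The gradient is *online*: it uses the current observation, with the KL term
anchoring $\beta$ to its prior. Summing likelihood terms over all stored
observations instead would scale the data term with visit count against a
fixed-strength prior, driving $\beta$ to its clip bound (unbounded $\zeta$)
under repeated consistent data — the anchored online form keeps both the
agreement equilibrium (+~20%) and the conflict equilibrium (−~60%)
self-limiting. `kappa` and `precision_steps` are exposed in `av_config()`;
they were chosen so that a trial's worth of consistent observations
produces a clear but modest precision rise while a single conflict under a
precise prior produces a marked collapse.

# Action selection

Policies are scored by expected free energy. Per future step and modality,

$$
G_\pi \mathrel{+}= \underbrace{\,\mathbf o_{\pi\tau}\cdot(\ln \mathbf
o_{\pi\tau} - \ln \mathbf C_\tau)}_{\text{risk}}
\;\underbrace{-\,\mathbf H \cdot \mathbf s_{\pi\tau}}_{\text{expected
ambiguity}},
$$

with $H_i = \sum_j \bar A_{ji}\ln \bar A_{ji}$ the (negative) conditional
entropy of the outcome given the state. Outcome priors $\mathbf C$ default
to uniform, so nothing is "rewarded" and the risk term reduces to the
negative entropy of predicted outcomes: $G$ is then exactly $\ln 3$ minus
the mutual information between the fixated feature and the visual outcome,
and policy selection is purely epistemic — saccades go where uncertainty
can be resolved. Policies are all single saccades re-evaluated every step
(`policy_depth = 1`, configurable); the policy posterior is
$\sigma(-\gamma G)$ with the policy precision $\gamma$ fixed at 1 (only the
sensory precision is inferred; treating $\gamma$ as a free parameter is
deliberately out of scope). The executed saccade is the action with the
largest marginal posterior, ties broken toward the lowest location index
(LL, LR, UL, UR) — which is why a flat-prior trial begins in the lower
left and visits all four locations in its first four saccades.

Before each saccade is scored, the state posteriors are re-smoothed under
the *updated* precision. This matters: without it, a location whose
precision has just collapsed still looks uncertain to the policy stage
(its stale posterior carries the undiscounted conflict), and the agent is
drawn back to it; with it, the prior-dominated, precision-discounted
posterior is confident, its mutual information is small, and the agent
behaves as if contrary evidence were simply not worth collecting.

# The hierarchy

A second level holds a categorical belief over *scene* hypotheses — each a
deterministic assignment of one feature value to every location. The
default library (`default_scene_library()`) contains the eight one-object
scenes (green or blue circle at one of four locations, the rest white),
uniform prior, in a fixed documented order. Second-level transitions are
identity and there are no second-level policies; the level communicates
with the first only at epoch boundaries:

* **Descend** (`descend_empirical_prior()`): the level-1 feature prior at
  location $f$ is $\sum_m Q(m)\,[(1-\eta)\,\delta_{m(f)} + \eta/3]$.
* **Ascend** (`ascend_evidence()`): $\ln Q(m) \propto \ln \text{prior}(m) +
  \sum_f \sum_v s_f(v) \ln[(1-\eta)\,\mathbb 1\{m(f)=v\} + \eta/3]$, using
  the epoch's final smoothed feature posteriors as soft evidence.
* **Reset** (`reset_precision()`): every $\beta$ returns to its prior when a
  new empirical prior descends — the separation of temporal scales between
  levels leaves no inter-epoch memory of precision.

The smoothing $\eta = 10^{-3}$ appears symmetrically in both messages. On
the way up it prevents a single noisy belief from annihilating every scene;
on the way down it caps the empirical prior's log-odds at
$\ln[(1-\eta)/(\eta/3)] \approx 8$ nats, so that even a scene belief
sharpened over many epochs remains — in principle, with enough consistent
fixation — revisable at the first level. Both are exposed as `eta`.

A zero-prior (lesioned) scene cannot be resurrected by the ascending
message: the evidence any scene can gain over the 4 locations (~4 × 8
nats in the limit, ~8 nats in practice for one differing location) stays
below the log floor of a zeroed prior, and the tests assert the lesioned
hypothesis stays at numerically zero posterior.

The default schedule is 3 epochs × 5 saccades. The rescue probe appends a
forced-fixation epoch of 12 saccades at one location: under the 8-nat
descended prior gap and the conflict equilibrium $\zeta^\ast \approx 0.39$,
evidence accumulates at roughly $\zeta^\ast \ln(0.9/0.05) \approx 1.1$ nats
per fixation, so the false percept is overturned around the eighth
consistent fixation and the remaining saccades restore precision.

# Scenario parameters

| Parameter | Default | Meaning |
|---|---|---|
| `visual_confidence` | 0.9 | P(visual outcome = fixated feature) |
| `beta_prior` | 1 | prior Gamma rate; prior expected $\zeta = 1$ |
| `kappa` | 0.2 | precision learning rate |
| `precision_steps` | 4 | gradient steps per observation |
| `confidence_weak` | 0.5 | "imprecise" prior mass on the believed value |
| `confidence_precise` | 0.9999 | "precise" prior mass on the believed value |
| `eta` | 1e-3 | hierarchical message smoothing |
| `n_saccades` | 10 | single-level trial length |
| epochs × saccades | 3 × 5 | hierarchical schedule |

The "precise" confidence deserves comment, because it is the one genuinely
tuned constant. A confidently wrong prior is only *metastable* here: at the
conflict equilibrium each refixation of a contradicted location adds about
1.1 nats of retrospectively reweighted evidence, and epistemic action
selection preferentially revisits the location whose posterior is least
certain. A 10-saccade trial permits at most ~7 refixations of one location
(~8 nats), so "precise" must mean a prior log-odds gap above that — 0.9999
(9.9 nats) — for the prior to dominate throughout the trial, which is the
defining signature of that regime. At 0.998 the same simulation shows the
prior overturned around the ninth saccade; the `sweep_prior_precision()`
grid locates the crossover rather than hiding it. "Small change" in
precision is operationalized as $|\Delta\zeta|/\zeta_0 < 25\%$ and
"collapse" as a decrease beyond 25%; both thresholds are interpretive
conventions, exposed in the summaries rather than baked into the model.

# What the generator emulates — and what it does not

The synthetic worlds (`world_state()`, `generate_fixture()`) are static
four-location scenes with noiseless outcomes; randomness enters only
through which features are true, what the subject believes, and how
confidently. That emulates the study conditions — the interesting dynamics
are entirely in the *beliefs* — but it means passing tests say nothing
about: continuous retinal input, saccade kinematics or timing, multi-object
occluded scenes, outcome noise in the world, learning of the likelihood or
transition mappings (no Dirichlet updates anywhere), or fits to human
eye-tracking data. The lesion operator covers exactly one pathology
mechanism — zeroing a high-level hypothesis's prior — not disconnection or
attentional neglect.

# Numerical choices, degenerate inputs, problem sizes

* Probability floor $10^{-16}$ before every logarithm; modulation raises an
  error only if an entire column vanishes (impossible after flooring).
* Forward–backward runs in the linear domain with per-step rescaling; exact
  zeros in deterministic transitions are handled by the floored evidence
  messages keeping some path weight positive.
* $\beta$ clipped at $10^{-6}$; ties in action selection resolved within
  $10^{-9}$ toward the lowest index so every run is bit-reproducible.
* Non-convergence of the sweep loop (never observed at the defaults) is
  recorded in the trial record rather than raised.
* Test and acceptance problem sizes: exact-inference oracles enumerate
  chains of ≤3 states × ≤3 steps (≤27 sequences); the gradient oracle uses
  100 random models; recovery statistics use 50 random scene draws with
  2-epoch schedules. A full hierarchical trial takes well under a second,
  so the whole acceptance run completes in about a minute.

# Known limitations

The agreement-driven precision rise is modest by construction (the online
anchored gradient equilibrates near +20%); regimes requiring large
precision *increases* would need either a hierarchical prior on $\beta$
(conditioning precision on slower variables — explicitly not modelled) or
a non-anchored filtering update, which destabilizes the matched regime.
Policy precision $\gamma$ is fixed; the hierarchy is exactly two levels;
and the ascending message treats level-1 posteriors as independent soft
evidence across locations, which is a variational convenience rather than
an exact message.
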