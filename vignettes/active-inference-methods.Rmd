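---
title: "Methods: discrete-state active inference in actinfr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discrete-state active inference in actinfr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinfr)
```

## The generative model and its assumptions

`actinfr` implements the single-factor, single-modality categorical POMDP:
one hidden-state factor with `m` levels, one outcome modality with `n`
levels. The agent's beliefs comprise

* a likelihood mapping `A` (n × m, column-stochastic), held either as a
  known matrix ("point" mode) or as independent Dirichlet beliefs per
  column ("dirichlet" mode, strictly positive counts `a`);
* per-action transition matrices `B_u` (m × m, column-stochastic);
* an initial-state prior `D` (m-simplex);
* log-preferences `C` over outcomes *or* states, optionally per future
  epoch;
* a policy space Π of action sequences with a prior `E` (default uniform)
  and a precision `gamma` (default 16).

A trial has `T` observation epochs; actions are taken *between* epochs, so
policies store `T − 1` actions (the transition into epoch τ is conditioned
on the policy's action τ − 1; a policy's "T-th action" would never
condition anything and is not stored).

The approximate posterior is the structured mean field
`Q(s_{1:T}, A, π) = Q(A) Q(π) Π_τ Q(s_τ | π)`: beliefs about the state at
each time, under each policy, are independent categoricals; beliefs about
each likelihood column are independent Dirichlets. The mean field makes
inference a set of coupled softmax fixed points; it is exact for `T = 1`
and an upper bound otherwise. The marginal and Bethe message-passing
families are deliberately out of scope.

Two Dirichlet expectation operators are used everywhere:
`expected_likelihood()` returns `A̅` (columns normalised counts) and
`expected_log_likelihood()` returns `E[log A] = ψ(a) − ψ(a₀)`. These are
*not* logs of one another; the Jensen gap closes as counts grow (the
package tests this at count scale 10⁶, tolerance 1e-5).

## Perception

For each policy, `infer_states()` minimises

```
F_π = Σ_τ s_πτ·log s_πτ − Σ_{τ≤t} o_τ·logA̅ s_πτ − s_π1·log D
      − Σ_{τ≥2} s_πτ·log(B_{π,τ−1}) s_{π,τ−1}
```

by integrating log-space potentials, `v ← v − κ ∇F`, `s = softmax(v)`
row-wise. Numerical choices, all overridable:

* **Initialisation** `v = 0` (uniform beliefs): uninformative, and any
  constant shift of `v` is invisible to the softmax.
* **Step size** `κ = 0.1`. The continuous flow descends `F` exactly
  (the softmax Jacobian is positive semi-definite); at `κ = 0.1` the
  forward-Euler discretisation remains monotone on every random instance
  in the test suite (checked per step at tolerance 1e-10). The analytic
  gradient drops the constant 1-vector, which lies in the softmax's null
  direction.
* **Convergence** is declared when the max-norm change of `s` per
  iteration falls below `tol = 1e-6` by default; internal callers use
  1e-8. The linear convergence rate near a fixed point is roughly
  `1 − κ`, so the residual belief error is about `tol (1 − κ)/κ`; 1e-8
  leaves T = 1 posteriors exact to well within 1e-6, which is what the
  exactness tests assert. `max_iter = 500` (1000 internally) flags
  non-convergence without failing.
* **Schedule**: all (policy, epoch) factors update synchronously per
  iteration, matching the parallel-population reading of the dynamics. A
  `method = "fixedpoint"` mode instead sweeps coordinate fixed points
  (each row set to the softmax of its messages); it reaches the same
  fixed points in far fewer iterations and is the pragmatic choice inside
  long learning simulations.
* **Zeros**: `0·log 0 := 0` for belief entries; logs of structural zeros
  in `A̅`, `B`, `D` are floored at `log(1e-16)`, so belief mass on an
  impossible state is strongly but finitely penalised and the gradient
  stays finite.

The analytic gradient is pinned by a central finite-difference oracle over
random models (m, n ≤ 5, T ≤ 4, componentwise 1e-5), and converged free
energies are checked against exhaustive enumeration of `−log P(o | π)`
over all state trajectories on small instances (m, n ≤ 4, T ≤ 3) — the
bound always holds and is tight at `T = 1`.

## Planning

`expected_free_energy()` scores the epochs in `tau_set` (default: every
epoch after the current one; planning only at the horizon is the special
case `tau_set = T`) of a policy's belief trajectory:

```
G(π) = Σ_τ risk + ambiguity − novelty
```

* **risk** — KL from the predicted distribution (`A̅ s` for outcome
  preferences, `s` for state preferences) to `softmax(logC)`. Which
  target applies is task configuration; the package takes no default
  stance beyond requiring the preference object to say.
* **ambiguity** — `Σ_j s_j H_j` with `H_j = −Σ_k A̅_kj logA̅_kj`, the
  operational mixed form standard in existing active-inference software.
  The *exact* Dirichlet expectation of the conditional outcome entropy is
  `H_j^exact = −Σ_k A̅_kj (ψ(a_kj + 1) − ψ(a₀_j + 1))`, smaller by
  `(n − 1)/a₀_j`; `ambiguity(..., exact = TRUE)` computes it. The two
  coincide in point mode and as counts grow.
* **novelty** — the exact expected one-observation information gain about
  `A`: `Σ_{k,j} A̅_kj s_j KL[Dir(a_j + e_k) ‖ Dir(a_j)]`, zero in point
  mode.

`efe_decompositions()` additionally computes, with fictive posteriors by
exact Bayes over the `n` outcomes (tractable at these scales, so the
oracle *is* the implementation): **extrinsic value**
`−E_{Q(o)} log P_C(o)`, the **expected evidence bound**
`E_{Q(o)} KL[Q(s|o) ‖ P(s|o)]` (identically zero when preferences are
over outcomes, since the preferred joint is then built from the fictive
posterior itself), and **salience** `E_{Q(o)} KL[Q(s|o) ‖ Q(s)]`. The
additive identity

```
risk + ambiguity_exact = extrinsic + evidence_bound − salience − novelty
```

holds to machine precision in both likelihood modes and both preference
targets; the test suite asserts it at 1e-8. This is the reason the exact
ambiguity form exists: with the mixed form the identity is off by exactly
`Σ_j s_j (n − 1)/a₀_j`, an artefact of mixing `E[A]` with `E[log A]`. The
operational `G` keeps the mixed form (field convention, and the
difference is policy-independent whenever likelihood columns share a
count total); the decomposition pins the algebra with the exact form.
Dropping the nonnegative evidence bound yields the lower-bound form
(expected log evidence plus information gain), whose direction is also
asserted.

Two structural simplifications: the policy-independent term
`KL[Q(A) ‖ P(A)]` inside risk is dropped (constant across policies, it
cancels in the softmax), and the policy posterior follows
`Q(π) = σ(log E − γ G)` exactly — no `−F_π` term inside the softmax, as
some reference implementations add; that variant was considered and left
out to keep decision-making a pure function of expected free energy.

**Precision and pruning.** `gamma` defaults to 16: sharply selective
(nearly winner-take-all at typical nat-scale G differences) yet finite,
so ties and near-ties remain visible in `q_pi`. `prune_policies()`
retains policies within `window` nats of the best, flooring the rest at
1e-12 before renormalising; the argmin is always retained. The default
window `log(1000)/2 ≈ 3.45` nats corresponds to posterior odds of 1000:1
at unit precision — arbitrary, documented, configurable.

## The action–perception cycle

`run_trial()` iterates: observe → `infer_states_all()` →
`expected_free_energy()` over remaining epochs → `policy_posterior()` →
`select_action()` → act. Decisions taken once are facts about the world,
so from epoch `t` onward policies whose prefix contradicts the executed
actions are masked to a 1e-12 posterior floor — averaging first actions
over policies the agent can no longer follow is ill-posed. This masking rule is an implementation decision, not part
of the theory. At the final epoch there is no future left to score;
consistent policies share the prior, which suffices for the
policy-independent state average used by learning.

Beliefs are warm-started from the previous epoch's potentials
(`warm_start = FALSE` gives cold starts for exact reproduction of the
per-epoch dynamics). Ties in action mass are broken by the order of the
action set, for reproducibility. Trials are deterministic given
`(model, env, seed)`.

**Learning** happens once per trial, at the end:
`a ← a_prior + Σ_τ o_τ ⊗ s_τ` with the policy-averaged `s_τ`, then the
posterior counts roll over as the next trial's prior. Only `A` is
learned; `B` and `D` learning are natural extensions but out of scope. A
`rate` multiplier on the increment is exposed (default 1 reproduces the
plain conjugate update) since trial-weighting/forgetting is a standard
practical need. The continuous plasticity relaxation
(`plasticity_dynamics()`, `ȧ = −a + a_prior + Σ o ⊗ s`) is provided and
tested against its closed-form exponential solution, but is not wired
into the default loop — the one-step update is computationally far
cheaper and reaches the same fixed point.

## Bayesian model reduction and expansion

With columnwise-independent Dirichlets, a reduced prior `ã_prior` can be
scored against the full prior using only the full posterior: by
conjugacy the reduced posterior is `ã_post = a_post + ã_prior − a_prior`
and

```
Δ log evidence = Σ_cols [lnB(ã_post) − lnB(ã_prior)] − [lnB(a_post) − lnB(a_prior)]
```

(`lnB` = log multivariate beta). The conjugacy step is the one piece of
algebra the theory leaves implicit, so a Monte-Carlo oracle
(`bmr_monte_carlo()`: log of the sample-mean density ratio under
Dirichlet posterior samples, with a delta-method standard error) guards
it; closed form and sampling agree within 3 SE across random triples, and
the single-column case prior `[1,1]`, posterior `[3,1]`, reduced prior
`[2,1]` gives exactly `log(3/2)`. Reductions that would drive a reduced
posterior count nonpositive are rejected as invalid rather than clamped.

`expand_states()` adds hidden states with uniform likelihood counts
(`init_count` each), negligible initial-prior mass (1e-8 before
renormalisation) and absorbing self-transitions under every action — the
least-committal convention, leaving old dynamics untouched; inference on
pre-existing data changes below 1e-6. The theory does not operationalise
*when* to expand, so expansion is a manual operation paired with the BMR
comparison for rolling back unused states; no automatic trigger is
provided.

## Synthetic environments

The generative process (`pomdp_environment`) is deliberately a separate
object from the generative model: matched construction is the default,
and `make_random_pomdp(..., mismatch = TRUE)` draws the world's
contingencies independently for model-misspecification experiments. Each
environment owns a private, seeded RNG stream, so simulations never
perturb (and are never perturbed by) the caller's RNG state.

`make_tmaze()` fixes the canonical epistemic-foraging task: 4 locations ×
2 reward contexts, deterministic movement, absorbing arms, a
deterministic context cue (1 bit of mutual information), horizon 3, all
16 depth-2 policies. Defaults `reward_prob = 0.98` and
`preference_strength = 4`: a nearly-reliable arm (so exploitation alone
cannot explain cue visits — the expected reward is the same either way)
and preferences strong enough that the null outcome is decisively
dispreferred (softmax weight `e⁻⁴` relative to neutral) without swamping
the epistemic terms. The exact values are fixture parameters of this
package, chosen once as representative of the task family, not claims
about any dataset.

What the generators emulate: seeded categorical worlds with the same
structural form as the model, arbitrary stochasticity, optional
model–world mismatch. What they do not: multiple outcome modalities or
state factors, nonstationary contingencies, continuous observations, or
an environment altered by the agent. Tests passing here show the
machinery is correct on its own terms; they do not certify behaviour on
real behavioural data, where those missing features dominate.

## Problem sizes and test design

The suite's simulation scales are the package's own choices, picked so
that every oracle is exact or tightly bounded: random-model sweeps use
m, n ≤ 5 and T ≤ 4 (100 instances for the gradient oracle, 50 for
descent monotonicity); enumeration bounds use m, n ≤ 4, T ≤ 3 where the
state-trajectory sum is exhaustive; decomposition identities use 2 × 2
instances where fictive posteriors are exact; Monte-Carlo oracles use
10⁵ samples (BMR) and 3 × 10⁴ samples (Dirichlet KL) with 3-SE
acceptance bands; empirical sampling checks use a few thousand draws
with 3σ binomial bands; parameter recovery runs 200 trials of an 8-epoch
two-state chain whose deterministic, known dynamics make the state
sequence exact — so the learned likelihood tallies true outcome
frequencies and the total-variation target of 0.05 per column sits many
standard errors above the binomial sampling noise of ~800 observations
per column. `scripts/acceptance.R` re-runs all of these from scratch
under a caller-supplied seed.

## Known limitations

Single state factor, single outcome modality; no hierarchical or
continuous extensions. No learning of `B`, `D`, preferences or policy
priors. Mean-field (not marginal/Bethe) state estimation, so multi-epoch
posteriors are approximate. Planning enumerates the policy space —
Occam-window pruning mitigates but does not remove the combinatorial
growth in the horizon. Precision `gamma` is fixed, not inferred.
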