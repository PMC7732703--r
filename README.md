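# actinfr

Discrete state-space **active inference** agents for partially observed
Markov decision processes (POMDPs), in base R.

Active inference describes perception, planning, action and learning as
complementary consequences of one objective: minimising (expected) free
energy under a generative model of how outcomes are caused by hidden
states. `actinfr` implements the full belief-updating cycle for the
single-factor categorical generative model — likelihood matrix `A`
(outcomes × states), per-action transitions `B_u`, initial prior `D`,
log-preferences `C`, a policy space Π of action sequences and a policy
precision γ — together with Dirichlet learning of `A` and Bayesian model
reduction/expansion over its priors, plus synthetic task environments so
everything runs end-to-end without external data.

## The model in brief

For each policy π the approximate posterior over the state trajectory
factorises over time, `Q(s_τ | π) = Cat(s_πτ)`, and its variational free
energy is

    F_π = Σ_τ s_πτ·log s_πτ − Σ_{τ≤t} o_τ·logA̅ s_πτ − s_π1·log D
          − Σ_{τ≥2} s_πτ·log(B_{π,τ−1}) s_{π,τ−1}

which upper-bounds the surprise −log P(o_{1:t} | π). **Perception** runs a
gradient descent on log-space potentials, `v ← v − κ ∇F_π`,
`s = softmax(v)`, interpretable as membrane potentials driving population
firing rates. **Planning** scores each policy's future by expected free
energy,

    G(π) = Σ_{τ>t} risk + ambiguity − novelty
         = Σ_{τ>t} extrinsic value + evidence bound − salience − novelty,

balancing goal pursuit (risk: KL from predicted to preferred states or
outcomes) against uncertainty resolution about states (salience) and
parameters (novelty). **Decision-making** is a softmax posterior
`Q(π) = σ(log E − γ G)` with optional Occam-window pruning;
**action selection** takes the action with the most posterior mass;
**learning** accumulates Dirichlet counts `a ← a + Σ_τ o_τ ⊗ s_τ` at the
end of each trial, and **Bayesian model reduction** compares reduced
Dirichlet priors post hoc from posterior counts alone.

## Worked example: epistemic foraging in a T-maze

A rat starts at the centre of a T-maze. Reward is in the left or right arm
according to a hidden context; the arms are absorbing, and a cue at the
bottom of the maze reveals the context. Sampling the cue first is the
hallmark of epistemic (uncertainty-resolving) behaviour:

```r
library(actinfr)

tm  <- make_tmaze()        # reward_prob = 0.98, preference_strength = 4
print(tm$model)
#> <gen_model> 8 states, 5 outcomes, 4 actions, horizon 3, 16 policies
#>   likelihood: point mode; preferences over outcomes; gamma = 16

rec <- run_trial(tm$model, tm$env, seed = 3)
print(rec)
#> <trial_record> T = 3; observations: 1 5 2; actions: cue -> right
```

The agent saw the neutral centre outcome (1), chose to visit the **cue**,
observed `cue-right` (5), went **right** and collected the reward (2). The
preference for the cue is visible in the expected free energies at the
first decision:

```r
st <- agent_step(agent_init(tm$model), 1)
first <- tm$model$policies$policies[, 1]
min(st$G[first == "cue"])                      # 6.7213
min(st$G[first %in% c("left", "right")])       # 6.9174
```

Visiting the cue is cheaper in expected free energy than guessing an arm,
even though both lead to the same expected reward — the difference is the
ambiguity/salience credit for resolving the context before committing.
With `make_tmaze(preference_strength = 0)` (no reward preference at all)
the cue policy still wins on purely epistemic grounds.

Every component is also available directly: `infer_states()`,
`policy_free_energy()`, `expected_free_energy()`, `efe_decompositions()`,
`policy_posterior()`, `dirichlet_update_trial()`, `bmr_delta_evidence()`,
`expand_states()`, and plain-text model/trace serialisation
(`save_model_spec()`, `export_trace()`). A thin command-line wrapper lives
at `inst/cli/actinf.R` (`validate`, `run`, `demo tmaze`, `bmr`).

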