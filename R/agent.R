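# The action-perception cycle: at each observation epoch the agent infers
# policy-conditioned state beliefs (perception), scores the future epochs of
# every viable policy by expected free energy (planning), forms a softmax
# posterior over policies (decision-making), executes the modal action
# (action selection), and at the end of the trial accumulates Dirichlet
# evidence about the likelihood (learning).

#' Select the modal action under the policy posterior
#'
#' Aggregates posterior policy mass onto each action's share at decision
#' epoch `t` and returns the action with the most mass. Ties are broken in
#' favour of the action listed first in the policy space's action set, so
#' selection is reproducible.
#'
#' @param q_pi Policy posterior (probability vector, or a
#'   [policy_posterior()] object).
#' @param policies A [policy_space()].
#' @param t Decision epoch (1-based; must be at most `horizon - 1`).
#' @return The selected action label.
#' @export
select_action <- function(q_pi, policies, t) {
  if (inherits(q_pi, "policy_posterior")) q_pi <- q_pi$q_pi
  stopifnot(inherits(policies, "policy_space"))
  if (nrow(policies$policies) == 0L) stop("empty policy set", call. = FALSE)
  if (t < 1L || t > policies$horizon - 1L) {
    stop("t outside the policy length", call. = FALSE)
  }
  acts_t <- policies$policies[, t]
  mass <- vapply(policies$actions,
                 function(u) sum(q_pi[acts_t == u]), numeric(1L))
  policies$actions[which.max(mass)]
}

# policies whose prefix matches the actions already executed
.consistent_policies <- function(policies, actions_taken) {
  if (length(actions_taken) == 0L) return(seq_len(nrow(policies$policies)))
  pre <- policies$policies[, seq_along(actions_taken), drop = FALSE]
  which(apply(pre, 1L, function(row) all(row == actions_taken)))
}

#' One perception-planning-decision-action step
#'
#' Appends the new observation, re-infers state beliefs under every policy
#' still consistent with the actions already executed, scores those policies
#' by expected free energy over the remaining epochs, forms the policy
#' posterior and (except at the final epoch) selects an action. Policies
#' contradicted by executed actions keep a floor posterior mass of 1e-12.
#'
#' @param state Agent state from [agent_init()] or a previous `agent_step()`.
#' @param observation Outcome index observed at the current epoch.
#' @return The updated agent state; `state$action` holds the selected action
#'   (`NA` at the final epoch), `state$q_pi`, `state$G`, `state$F`,
#'   `state$bma` the current posterior summaries.
#' @export
agent_step <- function(state, observation) {
  model <- state$model
  dims <- .model_dims(model)
  state$obs <- c(state$obs, as.integer(observation))
  t <- length(state$obs)
  if (t > dims$T) stop("trial already complete", call. = FALSE)
  retain <- .consistent_policies(model$policies, state$actions)
  beliefs <- infer_states_all(state$obs, model, kappa = state$control$kappa,
                              tol = state$control$tol,
                              max_iter = state$control$max_iter,
                              method = state$control$method,
                              v_init = if (state$control$warm_start) state$v else NULL)
  G <- rep(Inf, dims$n_pi)
  if (t < dims$T) {
    for (p in retain) {
      G[p] <- expected_free_energy(model, beliefs, p, tau_set = (t + 1L):dims$T)$G
    }
    if (!is.null(state$control$occam_window)) {
      keep <- retain[G[retain] <= min(G[retain]) + state$control$occam_window]
    } else {
      keep <- retain
    }
    pp <- policy_posterior(G, gamma = model$gamma, prior = model$policies$prior,
                           retain = keep)
  } else {
    # final epoch: no future to score; consistent policies share the prior
    pp <- policy_posterior(rep(0, dims$n_pi), gamma = model$gamma,
                           prior = model$policies$prior, retain = retain)
    G <- rep(NA_real_, dims$n_pi)
  }
  state$q_pi <- pp$q_pi
  state$G <- G
  state$F <- beliefs$F
  state$beliefs <- beliefs
  state$v <- beliefs$v
  state$bma <- bma_states(beliefs, pp$q_pi)
  if (t < dims$T) {
    state$action <- select_action(pp$q_pi, model$policies, t)
    state$actions <- c(state$actions, state$action)
  } else {
    state$action <- NA_character_
  }
  state
}

#' Initialise agent state
#'
#' @param model A [generative_model()].
#' @param kappa,tol,max_iter,method Passed to [infer_states()].
#' @param warm_start Reuse the previous epoch's potentials to initialise
#'   inference (faster; cold starts reproduce the pure per-epoch dynamics).
#' @param occam_window Optional Occam window (nats) pruning policies during
#'   planning; `NULL` disables pruning.
#' @return An agent state list for [agent_step()].
#' @export
agent_init <- function(model, kappa = 0.1, tol = 1e-8, max_iter = 1000L,
                       method = "gradient", warm_start = TRUE,
                       occam_window = NULL) {
  validate_model(model)
  list(model = model, obs = integer(0), actions = character(0), v = NULL,
       control = list(kappa = kappa, tol = tol, max_iter = max_iter,
                      method = method, warm_start = warm_start,
                      occam_window = occam_window))
}

#' Run one trial of the action-perception cycle
#'
#' Resets the environment under `seed`, runs the agent for all T observation
#' epochs, and (optionally) applies the end-of-trial Dirichlet update to the
#' likelihood counts, rolling the posterior counts over as the next trial's
#' prior. Identical `(model, env, seed)` triples reproduce the record
#' exactly.
#'
#' @param model A [generative_model()].
#' @param env A [pomdp_environment()] whose dimensions match the model.
#' @param seed Integer seed for the environment.
#' @param learn Apply the Dirichlet likelihood update at trial end
#'   (requires Dirichlet-mode likelihood beliefs).
#' @param rate Learning-rate multiplier on the count increment.
#' @inheritParams agent_init
#' @return An object of class `trial_record`: `observations` (length T),
#'   `actions` (length T - 1), matrices `q_pi`, `G`, `F` (epoch x policy),
#'   `states` (final policy-independent beliefs, T x m), `beliefs` (final
#'   epoch's per-policy beliefs), `counts_before` / `counts_after`,
#'   `model` (with updated counts if learning), `env`, `seed`.
#' @export
run_trial <- function(model, env, seed, learn = FALSE, rate = 1,
                      kappa = 0.1, tol = 1e-8, max_iter = 1000L,
                      method = "gradient", warm_start = TRUE,
                      occam_window = NULL) {
  dims <- .model_dims(model)
  if (nrow(env$true_A) != dims$n || ncol(env$true_A) != dims$m) {
    stop("environment dimensions do not match the model", call. = FALSE)
  }
  if (learn && model$likelihood$mode != "dirichlet") {
    stop("learning requires dirichlet likelihood beliefs", call. = FALSE)
  }
  state <- agent_init(model, kappa, tol, max_iter, method, warm_start,
                      occam_window)
  res <- env_reset(env, seed)
  env <- res$env
  obs <- integer(0)
  q_pi <- G <- F_pi <- matrix(NA_real_, dims$T, dims$n_pi)
  for (t in seq_len(dims$T)) {
    state <- agent_step(state, res$observation)
    obs <- state$obs
    q_pi[t, ] <- state$q_pi
    G[t, ] <- state$G
    F_pi[t, ] <- state$F
    if (t < dims$T) {
      res <- env_step(env, state$action)
      env <- res$env
    }
  }
  counts_before <- if (model$likelihood$mode == "dirichlet") model$likelihood$counts else NULL
  counts_after <- counts_before
  model_out <- model
  if (learn) {
    counts_after <- dirichlet_update_trial(counts_before,
                                           list(o = obs, s = state$bma),
                                           rate = rate)
    # posterior counts become the next trial's prior
    model_out$likelihood <- likelihood_belief(counts = counts_after,
                                              counts_prior = counts_after)
  }
  structure(list(observations = obs, actions = state$actions,
                 q_pi = q_pi, G = G, F = F_pi, states = state$bma,
                 beliefs = state$beliefs, counts_before = counts_before,
                 counts_after = counts_after, model = model_out, env = env,
                 seed = as.integer(seed)),
            class = "trial_record")
}

#' Run a sequence of learning trials
#'
#' Repeats [run_trial()] with per-trial seeds `seed, seed + 1, ...`,
#' carrying the (possibly updated) model forward between trials.
#'
#' @inheritParams run_trial
#' @param n_trials Number of trials.
#' @return A list: `model` (after all trials), `records` (list of
#'   `trial_record`s).
#' @export
run_trials <- function(model, env, n_trials, seed, learn = TRUE, ...) {
  records <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    rec <- run_trial(model, env, seed = as.integer(seed) + i - 1L,
                     learn = learn, ...)
    records[[i]] <- rec
    model <- rec$model
    env <- rec$env
  }
  list(model = model, records = records)
}

#' Simulate trials from a generative model
#'
#' `simulate()` method wrapping [run_trials()]: runs `nsim` trials of the
#' action-perception cycle against an environment.
#'
#' @param object A [generative_model()].
#' @param nsim Number of trials.
#' @param seed Integer seed (required for reproducibility).
#' @param env A [pomdp_environment()].
#' @param learn Update likelihood counts between trials.
#' @param ... Passed to [run_trial()].
#' @return As [run_trials()].
#' @export
simulate.gen_model <- function(object, nsim = 1, seed = 1L, env, learn = FALSE, ...) {
  run_trials(object, env, n_trials = nsim, seed = seed, learn = learn, ...)
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> T = %d; observations: %s; actions: %s\n",
              length(x$observations),
              paste(x$observations, collapse = " "),
              if (length(x$actions)) paste(x$actions, collapse = " -> ") else "(none)"))
  invisible(x)
}

#' @export
summary.trial_record <- function(object, ...) {
  print(object)
  cat("\nFinal policy-independent state beliefs (epoch x state):\n")
  print(round(object$states, 4))
  t_last <- max(which(!is.na(object$q_pi[, 1L])))
  cat(sprintf("\nPolicy posterior at epoch %d (top 3):\n", t_last))
  q <- object$q_pi[t_last, ]
  top <- order(q, decreasing = TRUE)[seq_len(min(3L, length(q)))]
  for (p in top) cat(sprintf("  policy %d: q = %.4f\n", p, q[p]))
  invisible(object)
}

#' @export
plot.trial_record <- function(x, ...) {
  graphics::matplot(seq_len(nrow(x$states)), x$states, type = "b", pch = 16,
                    lty = 1, xlab = "epoch", ylab = "belief",
                    main = "Policy-independent state beliefs", ...)
  invisible(x)
}
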