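# Policy-conditioned state estimation.
#
# Per policy, the approximate posterior over the state trajectory factorises
# over time into categorical beliefs s[tau, ] (rows of a T x m matrix). The
# free energy of those beliefs is minimised by gradient descent on log-space
# potentials v with s = softmax(v) row-wise: the potentials accumulate
# negative free-energy gradients, mirroring membrane potentials driving
# population firing rates.

# Resolve a policy argument to a character vector of T - 1 actions.
.policy_actions <- function(model, policy) {
  pol <- model$policies
  if (length(policy) == 1L && is.numeric(policy)) {
    if (policy < 1 || policy > nrow(pol$policies)) {
      stop("policy index out of range", call. = FALSE)
    }
    return(as.character(pol$policies[policy, ]))
  }
  policy <- as.character(policy)
  if (length(policy) != pol$horizon - 1L) {
    stop("policy must list horizon - 1 actions", call. = FALSE)
  }
  if (!all(policy %in% model$transitions$actions)) {
    stop("unknown action in policy", call. = FALSE)
  }
  policy
}

.check_obs <- function(obs, model) {
  dims <- .model_dims(model)
  obs <- as.integer(obs)
  if (length(obs) > dims$T) {
    stop(sprintf("observation history longer (%d) than the horizon (%d)",
                 length(obs), dims$T), call. = FALSE)
  }
  if (length(obs) > 0L && (any(obs < 1L) || any(obs > dims$n))) {
    stop("observation index out of range", call. = FALSE)
  }
  obs
}

# Per-timestep constant part of the gradient (observation + initial prior),
# plus the floored log transition matrices along the policy.
.perception_terms <- function(obs, model, policy) {
  dims <- .model_dims(model)
  acts <- .policy_actions(model, policy)
  logA <- expected_log_likelihood(model$likelihood)
  logD <- .safe_log(model$D)
  tt <- length(obs)
  const <- matrix(0, dims$T, dims$m)
  for (tau in seq_len(dims$T)) {
    if (tau <= tt) const[tau, ] <- const[tau, ] + logA[obs[tau], ]
    if (tau == 1L) const[tau, ] <- const[tau, ] + logD
  }
  logB <- lapply(acts, function(u) .safe_log(model$transitions$B[[u]]))
  list(const = const, logB = logB, T = dims$T, m = dims$m, t = tt)
}

#' Variational free energy of policy-conditioned beliefs
#'
#' Evaluates the free energy of a belief trajectory under one policy:
#' the negative entropy of the beliefs minus the expected log-probability of
#' observed outcomes, the initial state and the transitions along the policy.
#' It upper-bounds the surprise `-log P(o_{1:t} | policy)` and equals it when
#' the beliefs are the exact posterior (attained for single-epoch trials,
#' where the time-factorised posterior is exact).
#'
#' @param beliefs T x m matrix, one simplex row of state beliefs per epoch.
#' @param obs Integer vector of observed outcome indices, times 1..t (t <= T).
#' @param model A [generative_model()].
#' @param policy Policy row index or character vector of T - 1 actions.
#' @return A single number (nats). Belief mass on a state the model rules out
#'   is penalised at the floored log (log 1e-16) rather than infinity.
#' @export
policy_free_energy <- function(beliefs, obs, model, policy) {
  obs <- .check_obs(obs, model)
  pt <- .perception_terms(obs, model, policy)
  beliefs <- as.matrix(beliefs)
  stopifnot(nrow(beliefs) == pt$T, ncol(beliefs) == pt$m)
  f <- 0
  for (tau in seq_len(pt$T)) {
    s <- beliefs[tau, ]
    f <- f + .neg_entropy(s) - sum(s * pt$const[tau, ])
    if (tau >= 2L) {
      f <- f - as.numeric(beliefs[tau, ] %*% pt$logB[[tau - 1L]] %*% beliefs[tau - 1L, ])
    }
  }
  f
}

#' Analytic free-energy gradient at one timestep
#'
#' The partial derivative of [policy_free_energy()] with respect to the belief
#' row at epoch `tau`: `1 + log s_tau` minus the observation term (if
#' `tau <= t`), the initial-prior term (if `tau == 1`), the forward transition
#' term (if `tau > 1`) and the backward contraction of the next epoch's
#' beliefs through the transition (if `tau < T`). Matches central finite
#' differences of [policy_free_energy()]; the constant 1-vector lies in the
#' direction the softmax ignores.
#'
#' @inheritParams policy_free_energy
#' @param tau Epoch index in 1..T.
#' @return An m-vector.
#' @export
free_energy_gradient <- function(beliefs, obs, model, policy, tau) {
  obs <- .check_obs(obs, model)
  pt <- .perception_terms(obs, model, policy)
  if (tau < 1L || tau > pt$T) stop("tau out of range 1..T", call. = FALSE)
  beliefs <- as.matrix(beliefs)
  g <- 1 + log(pmax(beliefs[tau, ], 1e-300)) - pt$const[tau, ]
  if (tau >= 2L) g <- g - as.numeric(pt$logB[[tau - 1L]] %*% beliefs[tau - 1L, ])
  if (tau < pt$T) g <- g - as.numeric(t(pt$logB[[tau]]) %*% beliefs[tau + 1L, ])
  g
}

#' Infer policy-conditioned state beliefs
#'
#' Minimises the policy-conditioned free energy over the belief trajectory.
#' The default (`method = "gradient"`) integrates the potentials
#' `v <- v - kappa * grad` with `s = softmax(v)` row-wise, all epochs updated
#' synchronously, until the max-norm change in `s` drops below `tol`.
#' `method = "fixedpoint"` instead sweeps coordinate fixed-point updates
#' (each row set to the softmax of its other-epoch messages), which converges
#' in far fewer iterations and reaches the same fixed points.
#'
#' @inheritParams policy_free_energy
#' @param kappa Step size for the gradient flow (default 0.1; descent per
#'   iteration is monotone at this scale).
#' @param tol Convergence tolerance on the max-norm belief change per
#'   iteration (default 1e-8).
#' @param max_iter Iteration cap (default 1000); hitting it flags
#'   `converged = FALSE` without failing.
#' @param method `"gradient"` (potential dynamics) or `"fixedpoint"`.
#' @param v_init Optional T x m initial potentials (default 0, i.e. uniform
#'   beliefs).
#' @param track_F Record the free energy after every iteration.
#' @param track_v Record the potential matrix after every iteration.
#' @return A list of class `policy_beliefs_entry`: `s` (T x m, rows on the
#'   simplex), `v` (potentials), `converged`, `iterations`, `F` (final free
#'   energy), and optionally `F_trace` / `v_trace`.
#' @export
infer_states <- function(obs, model, policy, kappa = 0.1, tol = 1e-8,
                         max_iter = 1000L, method = c("gradient", "fixedpoint"),
                         v_init = NULL, track_F = FALSE, track_v = FALSE) {
  method <- match.arg(method)
  if (kappa <= 0) stop("kappa must be positive", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  obs <- .check_obs(obs, model)
  pt <- .perception_terms(obs, model, policy)
  v <- if (is.null(v_init)) matrix(0, pt$T, pt$m) else as.matrix(v_init)
  stopifnot(all(dim(v) == c(pt$T, pt$m)))
  s <- t(apply(v, 1L, softmax))
  if (pt$m == 1L) s <- matrix(1, pt$T, 1L)
  F_trace <- if (track_F) numeric(0) else NULL
  v_trace <- if (track_v) list() else NULL
  converged <- FALSE
  iter <- 0L
  # messages into epoch tau from its neighbours plus its constant terms
  msg <- function(s) {
    out <- pt$const
    for (tau in seq_len(pt$T)) {
      if (tau >= 2L) out[tau, ] <- out[tau, ] + as.numeric(pt$logB[[tau - 1L]] %*% s[tau - 1L, ])
      if (tau < pt$T) out[tau, ] <- out[tau, ] + as.numeric(t(pt$logB[[tau]]) %*% s[tau + 1L, ])
    }
    out
  }
  while (iter < max_iter) {
    iter <- iter + 1L
    s_old <- s
    if (method == "gradient") {
      grad <- log(pmax(s, 1e-300)) - msg(s)  # 1-vector omitted (softmax-invariant)
      if (any(!is.finite(grad))) stop("non-finite free-energy gradient", call. = FALSE)
      v <- v - kappa * grad
    } else {
      v <- msg(s)
    }
    s <- t(apply(v, 1L, softmax))
    if (pt$m == 1L) s <- matrix(1, pt$T, 1L)
    if (track_F) F_trace <- c(F_trace, policy_free_energy(s, obs, model, policy))
    if (track_v) v_trace[[iter]] <- v
    if (max(abs(s - s_old)) < tol) {
      converged <- TRUE
      break
    }
  }
  out <- list(s = s, v = v, converged = converged, iterations = iter,
              F = policy_free_energy(s, obs, model, policy))
  if (track_F) out$F_trace <- F_trace
  if (track_v) out$v_trace <- v_trace
  class(out) <- "policy_beliefs_entry"
  out
}

#' Infer beliefs under every policy
#'
#' Runs [infer_states()] for each row of the model's policy space.
#'
#' @inheritParams infer_states
#' @param v_init Optional list of T x m potential matrices (one per policy)
#'   used to warm-start each policy's inference.
#' @return An object of class `policy_beliefs`: lists `s`, `v`, vectors
#'   `F`, `converged`, `iterations`, indexed by policy.
#' @export
infer_states_all <- function(obs, model, kappa = 0.1, tol = 1e-8,
                             max_iter = 1000L,
                             method = c("gradient", "fixedpoint"),
                             v_init = NULL) {
  method <- match.arg(method)
  n_pi <- nrow(model$policies$policies)
  res <- vector("list", n_pi)
  for (p in seq_len(n_pi)) {
    res[[p]] <- infer_states(obs, model, p, kappa = kappa, tol = tol,
                             max_iter = max_iter, method = method,
                             v_init = if (is.null(v_init)) NULL else v_init[[p]])
  }
  structure(list(
    s = lapply(res, `[[`, "s"),
    v = lapply(res, `[[`, "v"),
    F = vapply(res, `[[`, numeric(1L), "F"),
    converged = vapply(res, `[[`, logical(1L), "converged"),
    iterations = vapply(res, `[[`, integer(1L), "iterations")
  ), class = "policy_beliefs")
}

#' Policy-independent state estimate (Bayesian model average)
#'
#' Averages per-policy belief trajectories under the policy posterior:
#' `s_tau = sum_pi q_pi(pi) * s_pi_tau`.
#'
#' @param beliefs A `policy_beliefs` object, or a list of T x m belief
#'   matrices (one per policy).
#' @param q_pi Probability vector over policies.
#' @return A T x m matrix with simplex rows.
#' @export
bma_states <- function(beliefs, q_pi) {
  s_list <- if (inherits(beliefs, "policy_beliefs")) beliefs$s else beliefs
  if (length(s_list) != length(q_pi)) {
    stop("q_pi length must match the number of policies", call. = FALSE)
  }
  if (abs(sum(q_pi) - 1) > 1e-8) stop("q_pi must sum to 1", call. = FALSE)
  dims <- dim(s_list[[1L]])
  if (any(vapply(s_list, function(x) any(dim(x) != dims), TRUE))) {
    stop("belief matrices have inconsistent shapes", call. = FALSE)
  }
  out <- matrix(0, dims[1L], dims[2L])
  for (p in seq_along(s_list)) out <- out + q_pi[p] * s_list[[p]]
  out
}
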