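# Planning: expected free energy per policy and the policy posterior.
#
# For each future epoch the predicted state beliefs induce a fictive joint
# over (outcome, state) through the expected likelihood. Expected free energy
# scores a policy as risk (KL from predicted to preferred distributions) plus
# ambiguity (expected outcome entropy given states), minus - under Dirichlet
# likelihood beliefs - the novelty (expected information gain about the
# likelihood parameters). The same quantity decomposes into extrinsic value,
# an expected evidence bound, salience and novelty; `efe_decompositions()`
# computes all terms with exact fictive posteriors and verifies the identity.

#' Predicted outcome distribution
#'
#' Pushes state beliefs through the expected likelihood: `Abar %*% s`.
#'
#' @param s State belief m-vector (simplex).
#' @param lik A [likelihood_belief()].
#' @return An n-vector on the simplex.
#' @export
predict_outcomes <- function(s, lik) {
  A <- expected_likelihood(lik)
  if (length(s) != ncol(A)) stop("state belief length does not match the likelihood",
                                 call. = FALSE)
  as.numeric(A %*% s)
}

#' Risk of a predicted distribution
#'
#' KL divergence from the predicted distribution to the preferred one
#' (softmax of the log-preferences at epoch `tau`). Whether `predicted` is a
#' distribution over outcomes or states must agree with the model's
#' preference target.
#'
#' @param predicted Probability vector (length n for outcome preferences,
#'   m for state preferences).
#' @param model A [generative_model()].
#' @param tau Future epoch index (only relevant for time-varying preferences).
#' @return Nonnegative scalar (nats).
#' @export
risk <- function(predicted, model, tau = 1L) {
  pref <- model$preferences
  p0 <- .pref_dist(pref, tau)
  if (length(predicted) != length(p0)) {
    stop(sprintf("predicted distribution length %d does not match %s preferences (%d)",
                 length(predicted), pref$target, length(p0)), call. = FALSE)
  }
  .kl_cat(predicted, p0)
}

#' Ambiguity of state beliefs under the likelihood
#'
#' Expected conditional entropy of outcomes given states,
#' `sum_j s_j H_j`. By default `H_j = -sum_k Abar_kj logAbar_kj`, mixing the
#' expected likelihood with the expected log-likelihood - the operational
#' form used inside expected free energy. With `exact = TRUE` and Dirichlet
#' beliefs, `H_j` is the exact posterior expectation of the conditional
#' entropy, `-sum_k E[A_kj log A_kj]`; the two coincide in point mode and as
#' counts grow, differing by `(n - 1) / a0_j` per state, and the exact form
#' is the one entering the additive decomposition identity.
#'
#' @param s State belief m-vector.
#' @param lik A [likelihood_belief()].
#' @param exact Use the exact Dirichlet expectation of the entropy.
#' @return Nonnegative scalar (nats).
#' @export
ambiguity <- function(s, lik, exact = FALSE) {
  Abar <- expected_likelihood(lik)
  if (length(s) != ncol(Abar)) stop("state belief length does not match the likelihood",
                                    call. = FALSE)
  if (lik$mode == "point") {
    lp <- .safe_log(Abar)
    H <- -colSums(Abar * ifelse(Abar > 0, lp, 0))
  } else if (!exact) {
    logAbar <- expected_log_likelihood(lik)
    H <- -colSums(Abar * logAbar)
  } else {
    a <- lik$counts
    a0 <- colSums(a)
    # E[A log A] column-wise: Abar_kj * (digamma(a_kj + 1) - digamma(a0_j + 1))
    ElogA1 <- sweep(digamma(a + 1), 2L, digamma(a0 + 1), "-")
    H <- -colSums(Abar * ElogA1)
  }
  sum(s * H)
}

#' Novelty: expected information gain about the likelihood
#'
#' Under Dirichlet likelihood beliefs, the exact expected KL divergence from
#' the one-observation posterior back to the current beliefs, averaged over
#' the fictive joint `Q(o = k, s = j) = Abar_kj s_j`:
#' `sum_{k,j} Abar_kj s_j KL[Dir(a_j + e_k) || Dir(a_j)]`. Point-mode beliefs
#' have nothing to learn and return 0.
#'
#' @inheritParams ambiguity
#' @return Nonnegative scalar (nats).
#' @export
novelty <- function(s, lik) {
  if (lik$mode == "point") return(0)
  a <- lik$counts
  if (length(s) != ncol(a)) stop("state belief length does not match the likelihood",
                                 call. = FALSE)
  Abar <- expected_likelihood(lik)
  total <- 0
  for (j in seq_len(ncol(a))) {
    if (s[j] <= 0) next
    for (k in seq_len(nrow(a))) {
      aj <- a[, j]
      total <- total + s[j] * Abar[k, j] * dirichlet_kl(aj + .one_hot(k, length(aj)), aj)
    }
  }
  total
}

# All expected-free-energy terms for a single future epoch.
# Fictive joint: Q(o, s) = Abar(o | s) Q(s); fictive posteriors by exact Bayes.
.efe_terms <- function(model, s, tau) {
  lik <- model$likelihood
  Abar <- expected_likelihood(lik)
  n <- nrow(Abar)
  q_o <- as.numeric(Abar %*% s)
  pref <- model$preferences
  risk_tau <- if (pref$target == "outcomes") risk(q_o, model, tau) else risk(s, model, tau)
  amb <- ambiguity(s, lik)
  amb_exact <- ambiguity(s, lik, exact = TRUE)
  nov <- novelty(s, lik)

  # fictive state posteriors Q(s | o = k), one row per outcome
  post <- matrix(0, n, length(s))
  for (k in seq_len(n)) {
    if (q_o[k] > 0) post[k, ] <- Abar[k, ] * s / q_o[k]
  }
  salience <- 0
  for (k in seq_len(n)) {
    if (q_o[k] > 0) salience <- salience + q_o[k] * .kl_cat(post[k, ], s)
  }

  if (pref$target == "outcomes") {
    # preference joint P(o, s) = C(o) Q(s | o): the state-space evidence bound
    # vanishes by construction (outcome risk stands in for state risk)
    p_o <- .pref_dist(pref, tau)
    extrinsic <- -sum(q_o * .safe_log(p_o))
    bound <- 0
  } else {
    # preference joint P(o, s) = C(s) Abar(o | s)
    p_s <- .pref_dist(pref, tau)
    p_o <- as.numeric(Abar %*% p_s)
    extrinsic <- -sum(q_o * .safe_log(p_o))
    bound <- 0
    for (k in seq_len(n)) {
      if (q_o[k] > 0 && p_o[k] > 0) {
        pref_post <- Abar[k, ] * p_s / p_o[k]
        bound <- bound + q_o[k] * .kl_cat(post[k, ], pref_post)
      }
    }
  }
  list(risk = risk_tau, ambiguity = amb, ambiguity_exact = amb_exact,
       novelty = nov, extrinsic = extrinsic, evidence_bound = bound,
       salience = salience)
}

#' Expected free energy of a policy
#'
#' Sums risk, ambiguity and (negative) novelty over the requested future
#' epochs of a policy's belief trajectory:
#' `G = sum_tau risk + ambiguity - novelty` (the novelty term is zero in
#' point mode). All named components, including the extrinsic /
#' evidence-bound / salience terms of the epistemic decomposition, are
#' recorded.
#'
#' @param model A [generative_model()].
#' @param beliefs A `policy_beliefs` object from [infer_states_all()], a
#'   single `policy_beliefs_entry`, or a T x m belief matrix for `policy`.
#' @param policy Policy row index (used to pick beliefs out of a
#'   `policy_beliefs` object).
#' @param tau_set Future epochs to sum over; defaults to every epoch after
#'   the first (callers planning mid-trial pass `(t+1):T`).
#' @return An object of class `efe_breakdown` with fields `G`, `risk`,
#'   `ambiguity`, `ambiguity_exact`, `novelty`, `extrinsic`,
#'   `evidence_bound`, `salience`, `tau_set`.
#' @export
expected_free_energy <- function(model, beliefs, policy = 1L, tau_set = NULL) {
  s_mat <- if (inherits(beliefs, "policy_beliefs")) beliefs$s[[policy]]
           else if (inherits(beliefs, "policy_beliefs_entry")) beliefs$s
           else as.matrix(beliefs)
  T_len <- nrow(s_mat)
  if (is.null(tau_set)) tau_set <- if (T_len > 1L) 2L:T_len else 1L
  if (length(tau_set) == 0L) stop("tau_set must name at least one epoch", call. = FALSE)
  if (any(tau_set < 1L) || any(tau_set > T_len)) {
    stop("tau_set outside 1..T", call. = FALSE)
  }
  acc <- list(risk = 0, ambiguity = 0, ambiguity_exact = 0, novelty = 0,
              extrinsic = 0, evidence_bound = 0, salience = 0)
  for (tau in tau_set) {
    tm <- .efe_terms(model, s_mat[tau, ], tau)
    for (f in names(acc)) acc[[f]] <- acc[[f]] + tm[[f]]
  }
  acc$G <- acc$risk + acc$ambiguity - acc$novelty
  acc$tau_set <- tau_set
  structure(acc, class = "efe_breakdown")
}

#' @export
print.efe_breakdown <- function(x, ...) {
  cat(sprintf("<efe_breakdown> G = %.4f over epochs {%s}\n",
              x$G, paste(x$tau_set, collapse = ", ")))
  cat(sprintf("  risk %.4f + ambiguity %.4f - novelty %.4f\n",
              x$risk, x$ambiguity, x$novelty))
  cat(sprintf("  = extrinsic %.4f + bound %.4f - salience %.4f - novelty %.4f (exact ambiguity %.4f)\n",
              x$extrinsic, x$evidence_bound, x$salience, x$novelty,
              x$ambiguity_exact))
  invisible(x)
}

#' Full expected-free-energy decomposition with consistency checks
#'
#' Computes every named component over `tau_set` with exact fictive
#' posteriors and reports the additive identity
#' `risk + ambiguity_exact = extrinsic + evidence_bound - salience - novelty`
#' (residual returned; it is zero up to round-off) along with the epistemic
#' lower bound `extrinsic - salience - novelty` obtained by dropping the
#' nonnegative evidence bound.
#'
#' @inheritParams expected_free_energy
#' @return An `efe_breakdown` with extra fields `identity_residual` and
#'   `lower_bound`.
#' @export
efe_decompositions <- function(model, beliefs, policy = 1L, tau_set = NULL) {
  br <- expected_free_energy(model, beliefs, policy, tau_set)
  br$identity_residual <- (br$risk + br$ambiguity_exact) -
    (br$extrinsic + br$evidence_bound - br$salience - br$novelty)
  br$lower_bound <- br$extrinsic - br$salience - br$novelty
  br
}

#' Posterior beliefs over policies
#'
#' Softmax of `log(prior) - gamma * G`: with a uniform prior and `gamma = 1`
#' this is the canonical softmax of negative expected free energy; larger
#' `gamma` sharpens selection towards the minimum-G policy (soft winner
#' take-all). Policies outside `retain` are floored at 1e-12 before
#' renormalisation.
#'
#' @param G Numeric vector of expected free energies, one per policy.
#' @param gamma Positive precision (inverse temperature).
#' @param prior Prior over policies (default uniform).
#' @param retain Optional integer vector of policy indices kept active
#'   (e.g. from [prune_policies()]); others are floored.
#' @return An object of class `policy_posterior`: `q_pi`, `G`, `retained`.
#' @export
policy_posterior <- function(G, gamma = 1, prior = NULL, retain = NULL) {
  n_pi <- length(G)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (is.null(prior)) prior <- rep(1 / n_pi, n_pi)
  if (length(prior) != n_pi || !.is_simplex(prior)) {
    stop("prior must be a probability vector over policies", call. = FALSE)
  }
  if (is.null(retain)) retain <- seq_len(n_pi)
  if (any(!is.finite(G[retain]))) {
    stop("non-finite expected free energy for a retained policy", call. = FALSE)
  }
  q <- rep(1e-12, n_pi)
  lp <- log(pmax(prior[retain], 1e-300)) - gamma * G[retain]
  q[retain] <- softmax(lp)
  q <- q / sum(q)
  structure(list(q_pi = q, G = G, retained = sort(retain)),
            class = "policy_posterior")
}

#' @export
print.policy_posterior <- function(x, ...) {
  cat(sprintf("<policy_posterior> %d policies (%d retained); max q = %.3f at policy %d\n",
              length(x$q_pi), length(x$retained), max(x$q_pi), which.max(x$q_pi)))
  invisible(x)
}

#' Occam-window pruning of policies
#'
#' Retains policies whose expected free energy lies within `window` nats of
#' the best; the rest get posterior mass floored at 1e-12 before
#' renormalisation. The argmin is always retained (ties all retained at
#' `window = 0`). The default window, `log(1000) / 2`, discards policies
#' whose posterior odds against the best exceed about 1000:1 at unit
#' precision.
#'
#' @param G Numeric vector of expected free energies.
#' @param window Nonnegative width of the Occam window (nats).
#' @param gamma,prior Passed to [policy_posterior()] for the floored
#'   posterior.
#' @return A list: `retained` (indices), `q_pi` (floored, renormalised
#'   posterior).
#' @export
prune_policies <- function(G, window = log(1000) / 2, gamma = 1, prior = NULL) {
  if (window < 0) stop("window must be nonnegative", call. = FALSE)
  retained <- which(G <= min(G) + window)
  pp <- policy_posterior(G, gamma = gamma, prior = prior, retain = retained)
  list(retained = retained, q_pi = pp$q_pi)
}
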