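#' Likelihood beliefs: point matrix or Dirichlet counts
#'
#' The agent's beliefs about the outcome likelihood mapping. In `point` mode
#' the mapping is a known column-stochastic matrix `A` (n outcomes x m states).
#' In `dirichlet` mode the agent holds independent Dirichlet beliefs over each
#' column, parameterised by a matrix of strictly positive counts; learning and
#' novelty-seeking only make sense in this mode.
#'
#' @param probs Column-stochastic n x m matrix (point mode).
#' @param counts Strictly positive n x m matrix of Dirichlet counts
#'   (dirichlet mode). Exactly one of `probs` / `counts` must be given.
#' @param counts_prior Optional prior counts (defaults to `counts`); kept
#'   alongside the posterior counts so learning updates and Bayesian model
#'   reduction can refer back to the prior.
#' @return An object of class `likelihood_belief`.
#' @export
likelihood_belief <- function(probs = NULL, counts = NULL, counts_prior = NULL) {
  if (is.null(probs) == is.null(counts)) {
    stop("supply exactly one of `probs` (point mode) or `counts` (dirichlet mode)",
         call. = FALSE)
  }
  if (!is.null(probs)) {
    probs <- as.matrix(probs)
    .check_column_stochastic(probs, "likelihood probs")
    out <- structure(list(mode = "point", probs = probs),
                     class = "likelihood_belief")
  } else {
    counts <- as.matrix(counts)
    if (any(counts <= 0)) {
      stop("dirichlet counts must be strictly positive", call. = FALSE)
    }
    if (is.null(counts_prior)) counts_prior <- counts
    counts_prior <- as.matrix(counts_prior)
    if (any(dim(counts_prior) != dim(counts)) || any(counts_prior <= 0)) {
      stop("counts_prior must be a positive matrix with the shape of counts",
           call. = FALSE)
    }
    out <- structure(list(mode = "dirichlet", counts = counts,
                          counts_prior = counts_prior),
                     class = "likelihood_belief")
  }
  out
}

#' @export
print.likelihood_belief <- function(x, ...) {
  d <- dim(if (x$mode == "point") x$probs else x$counts)
  cat(sprintf("<likelihood_belief> mode=%s, %d outcomes x %d states\n",
              x$mode, d[1L], d[2L]))
  invisible(x)
}

# number of outcomes / states implied by a likelihood belief
.lik_dim <- function(lik) {
  dim(if (lik$mode == "point") lik$probs else lik$counts)
}

#' Expected likelihood matrix under Dirichlet beliefs
#'
#' Returns the posterior mean likelihood: each column of counts normalised by
#' its sum. Point-mode beliefs are returned unchanged.
#'
#' @param lik A [likelihood_belief()].
#' @return An n x m column-stochastic matrix.
#' @export
expected_likelihood <- function(lik) {
  stopifnot(inherits(lik, "likelihood_belief"))
  if (lik$mode == "point") return(lik$probs)
  a <- lik$counts
  if (any(a <= 0)) stop("dirichlet counts must be strictly positive", call. = FALSE)
  sweep(a, 2L, colSums(a), "/")
}

#' Expected log-likelihood matrix under Dirichlet beliefs
#'
#' Returns `E[log A]` under the column-wise Dirichlet posterior:
#' `digamma(a_kj) - digamma(sum_k a_kj)`. This is not the log of
#' [expected_likelihood()]; by Jensen's inequality it is elementwise smaller
#' for finite counts. Point-mode beliefs return the elementwise (floored) log
#' of the probability matrix.
#'
#' @param lik A [likelihood_belief()].
#' @return An n x m matrix of expected log-probabilities.
#' @export
expected_log_likelihood <- function(lik) {
  stopifnot(inherits(lik, "likelihood_belief"))
  if (lik$mode == "point") return(.safe_log(lik$probs))
  a <- lik$counts
  if (any(a <= 0)) stop("dirichlet counts must be strictly positive", call. = FALSE)
  sweep(digamma(a), 2L, digamma(colSums(a)), "-")
}

#' Per-action transition model
#'
#' @param B A named list of m x m column-stochastic matrices, one per action;
#'   entry (i, j) of `B[[u]]` is the probability of moving to state i from
#'   state j under action u. Unnamed lists get actions `"u1", "u2", ...`.
#' @return An object of class `transition_model`.
#' @export
transition_model <- function(B) {
  if (is.matrix(B)) B <- list(B)
  stopifnot(is.list(B), length(B) >= 1L)
  B <- lapply(B, as.matrix)
  if (is.null(names(B)) || any(!nzchar(names(B)))) {
    names(B) <- paste0("u", seq_along(B))
  }
  m <- nrow(B[[1L]])
  for (u in seq_along(B)) {
    if (!all(dim(B[[u]]) == c(m, m))) {
      stop(sprintf("transition matrix '%s' is not %d x %d", names(B)[u], m, m),
           call. = FALSE)
    }
    .check_column_stochastic(B[[u]], sprintf("transition matrix '%s'", names(B)[u]))
  }
  structure(list(B = B, actions = names(B)), class = "transition_model")
}

#' Log-preference specification
#'
#' Preferences enter planning only through log-probability differences, so they
#' are stored in log space and softmax-normalised whenever an actual preferred
#' distribution is needed. They may concern outcomes or hidden states, and may
#' optionally vary over future timesteps.
#'
#' @param logC Numeric vector of log-preferences (length n for outcomes,
#'   m for states), or a list of such vectors, one per timestep.
#' @param target `"outcomes"` or `"states"`.
#' @return An object of class `preferences`.
#' @export
preferences <- function(logC, target = c("outcomes", "states")) {
  target <- match.arg(target)
  if (!is.list(logC)) logC <- list(logC)
  for (v in logC) {
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop("logC must contain finite numeric values", call. = FALSE)
    }
  }
  len <- unique(vapply(logC, length, 1L))
  if (length(len) != 1L) stop("all logC vectors must have equal length", call. = FALSE)
  structure(list(logC = logC, target = target, time_varying = length(logC) > 1L),
            class = "preferences")
}

# preferred distribution at future time tau (1-based within the trial)
.pref_dist <- function(pref, tau) {
  v <- if (pref$time_varying) {
    pref$logC[[min(tau, length(pref$logC))]]
  } else {
    pref$logC[[1L]]
  }
  softmax(v)
}

#' Policy space: allowable action sequences
#'
#' A trial has `horizon` observation epochs; actions are taken between epochs,
#' so each policy is a sequence of `horizon - 1` actions (the transition into
#' epoch tau is conditioned on the policy's action tau - 1).
#'
#' @param policies Integer or character matrix, one row per policy, one column
#'   per decision epoch (`horizon - 1` columns); entries are action labels or
#'   indices into the action set.
#' @param horizon Positive integer, number of observation epochs T.
#' @param prior Optional prior over policies (default uniform).
#' @param actions Character vector of allowed action labels (used to resolve
#'   integer-coded policies).
#' @return An object of class `policy_space`.
#' @export
policy_space <- function(policies, horizon, prior = NULL, actions = NULL) {
  stopifnot(is.numeric(horizon), length(horizon) == 1L, horizon >= 1L)
  horizon <- as.integer(horizon)
  policies <- as.matrix(policies)
  if (horizon == 1L) {
    if (ncol(policies) != 0L && nrow(policies) != 1L) {
      stop("with horizon 1 supply a single empty policy", call. = FALSE)
    }
  } else if (ncol(policies) != horizon - 1L) {
    stop(sprintf("policies must have horizon - 1 = %d columns, got %d",
                 horizon - 1L, ncol(policies)), call. = FALSE)
  }
  if (is.numeric(policies)) {
    if (is.null(actions)) actions <- paste0("u", seq_len(max(1, policies)))
    policies <- matrix(actions[policies], nrow = nrow(policies))
  } else if (is.null(actions)) {
    actions <- sort(unique(as.vector(policies)))
  }
  if (ncol(policies) > 0L && !all(policies %in% actions)) {
    stop("policy contains an action outside the action set", call. = FALSE)
  }
  n_pi <- nrow(policies)
  if (is.null(prior)) prior <- rep(1 / n_pi, n_pi)
  if (length(prior) != n_pi || !.is_simplex(prior)) {
    stop("policy prior must be a probability vector over the policies", call. = FALSE)
  }
  structure(list(policies = policies, horizon = horizon,
                 prior = as.numeric(prior), actions = actions),
            class = "policy_space")
}

#' Enumerate all action sequences of a given depth
#'
#' @param actions Character vector of action labels.
#' @param horizon Number of observation epochs T (policies have T - 1 actions).
#' @param prior Optional prior over policies.
#' @return A [policy_space()] containing every sequence in `actions^(T-1)`.
#' @export
all_policies <- function(actions, horizon, prior = NULL) {
  depth <- horizon - 1L
  if (depth == 0L) {
    return(policy_space(matrix(character(0), nrow = 1L, ncol = 0L),
                        horizon, prior, actions))
  }
  grid <- do.call(expand.grid,
                  c(rep(list(actions), depth), stringsAsFactors = FALSE))
  pol <- as.matrix(grid[, rev(seq_len(depth)), drop = FALSE])
  dimnames(pol) <- NULL
  policy_space(pol, horizon, prior, actions)
}

#' Assemble a generative model
#'
#' Bundles the agent's beliefs about how outcomes are generated: the likelihood
#' mapping, per-action transition dynamics, initial-state prior, preferences,
#' policy space and policy precision. Dimensions are cross-checked on
#' construction via [validate_model()].
#'
#' @param likelihood A [likelihood_belief()].
#' @param transitions A [transition_model()].
#' @param D Initial-state prior (m-simplex vector).
#' @param preferences A [preferences()] object.
#' @param policies A [policy_space()].
#' @param gamma Policy precision (inverse temperature) on expected free energy;
#'   positive, default 16 (sharply selective but finite).
#' @return An object of class `gen_model`.
#' @export
generative_model <- function(likelihood, transitions, D, preferences, policies,
                             gamma = 16) {
  model <- structure(
    list(likelihood = likelihood, transitions = transitions, D = as.numeric(D),
         preferences = preferences, policies = policies, gamma = gamma),
    class = "gen_model")
  validate_model(model)
}

#' Validate a generative model
#'
#' Checks every structural invariant: column-stochastic likelihood/transition
#' matrices (tolerance 1e-12), strictly positive Dirichlet counts, simplex
#' initial prior, mutually consistent dimensions (n, m, action set, horizon),
#' finite preferences and a positive precision. Matrices are never silently
#' renormalised; set `normalize = TRUE` to request column renormalisation of
#' near-stochastic matrices before validation.
#'
#' @param model A `gen_model`.
#' @param normalize If TRUE, renormalise likelihood/transition columns and D
#'   first (only entries within rounding of stochastic; negative entries still
#'   fail).
#' @return The validated (possibly renormalised) model, invisibly classed as
#'   before.
#' @export
validate_model <- function(model, normalize = FALSE) {
  stopifnot(inherits(model, "gen_model"))
  if (normalize) {
    if (model$likelihood$mode == "point") {
      p <- model$likelihood$probs
      if (any(p < 0)) stop("likelihood probs has negative entries", call. = FALSE)
      model$likelihood$probs <- sweep(p, 2L, colSums(p), "/")
    }
    model$transitions$B <- lapply(model$transitions$B, function(M) {
      if (any(M < 0)) stop("transition matrix has negative entries", call. = FALSE)
      sweep(M, 2L, colSums(M), "/")
    })
    if (any(model$D < 0)) stop("D has negative entries", call. = FALSE)
    model$D <- model$D / sum(model$D)
  }
  lik <- model$likelihood
  if (!inherits(lik, "likelihood_belief")) {
    stop("likelihood must be a likelihood_belief", call. = FALSE)
  }
  if (lik$mode == "point") {
    .check_column_stochastic(lik$probs, "likelihood probs")
  } else if (any(lik$counts <= 0)) {
    stop("dirichlet counts must be strictly positive", call. = FALSE)
  }
  d <- .lik_dim(lik)
  n <- d[1L]; m <- d[2L]
  tr <- model$transitions
  if (!inherits(tr, "transition_model")) {
    stop("transitions must be a transition_model", call. = FALSE)
  }
  for (u in seq_along(tr$B)) {
    if (!all(dim(tr$B[[u]]) == c(m, m))) {
      stop(sprintf("transition matrix '%s' is %d x %d but the model has %d states",
                   tr$actions[u], nrow(tr$B[[u]]), ncol(tr$B[[u]]), m),
           call. = FALSE)
    }
    .check_column_stochastic(tr$B[[u]], sprintf("transition matrix '%s'", tr$actions[u]))
  }
  if (length(model$D) != m || !.is_simplex(model$D)) {
    stop(sprintf("D must be a probability vector of length %d", m), call. = FALSE)
  }
  pref <- model$preferences
  if (!inherits(pref, "preferences")) {
    stop("preferences must be a preferences object", call. = FALSE)
  }
  want <- if (pref$target == "outcomes") n else m
  if (length(pref$logC[[1L]]) != want) {
    stop(sprintf("preferences over %s must have length %d", pref$target, want),
         call. = FALSE)
  }
  pol <- model$policies
  if (!inherits(pol, "policy_space")) {
    stop("policies must be a policy_space", call. = FALSE)
  }
  if (!all(pol$actions %in% tr$actions)) {
    stop("policy space uses actions missing from the transition model", call. = FALSE)
  }
  if (!is.numeric(model$gamma) || length(model$gamma) != 1L || model$gamma <= 0) {
    stop("gamma must be a positive scalar", call. = FALSE)
  }
  model
}

#' @export
print.gen_model <- function(x, ...) {
  d <- .lik_dim(x$likelihood)
  cat(sprintf(
    "<gen_model> %d states, %d outcomes, %d actions, horizon %d, %d policies\n",
    d[2L], d[1L], length(x$transitions$actions), x$policies$horizon,
    nrow(x$policies$policies)))
  cat(sprintf("  likelihood: %s mode; preferences over %s; gamma = %g\n",
              x$likelihood$mode, x$preferences$target, x$gamma))
  invisible(x)
}

#' @export
summary.gen_model <- function(object, ...) {
  print(object)
  cat("\nExpected likelihood (Abar):\n")
  print(round(expected_likelihood(object$likelihood), 4))
  cat("\nInitial prior D:\n")
  print(round(object$D, 4))
  invisible(object)
}

# dimensions helper used throughout
.model_dims <- function(model) {
  d <- .lik_dim(model$likelihood)
  list(n = d[1L], m = d[2L], T = model$policies$horizon,
       n_pi = nrow(model$policies$policies))
}
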