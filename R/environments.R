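# Generative processes: the world the agent acts in, deliberately distinct
# from the agent's generative model. An environment carries true
# contingencies (which the model may or may not match), a current hidden
# state and its own reproducible RNG stream.

# draw one index from a categorical distribution
.rcat <- function(p) sample.int(length(p), 1L, prob = p)

# run expr under the environment's private RNG stream, preserving the
# caller's global RNG state
.with_env_rng <- function(env, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  assign(".Random.seed", env$rng, envir = globalenv())
  value <- force(expr)
  list(value = value, rng = get(".Random.seed", globalenv()))
}

#' Construct a POMDP environment (generative process)
#'
#' @param true_A n x m column-stochastic observation matrix.
#' @param true_B Named list of m x m column-stochastic transition matrices,
#'   one per action.
#' @param true_D Initial-state distribution (m-simplex).
#' @return An object of class `pomdp_env`; call [env_reset()] before
#'   stepping.
#' @export
pomdp_environment <- function(true_A, true_B, true_D) {
  true_A <- as.matrix(true_A)
  .check_column_stochastic(true_A, "true_A")
  tr <- transition_model(true_B)
  true_D <- as.numeric(true_D)
  if (!.is_simplex(true_D) || length(true_D) != ncol(true_A)) {
    stop("true_D must be an m-simplex matching true_A", call. = FALSE)
  }
  structure(list(true_A = true_A, true_B = tr$B, actions = tr$actions,
                 true_D = true_D, state = NA_integer_, rng = NULL),
            class = "pomdp_env")
}

#' @export
print.pomdp_env <- function(x, ...) {
  cat(sprintf("<pomdp_env> %d states, %d outcomes, actions: %s; state = %s\n",
              ncol(x$true_A), nrow(x$true_A), paste(x$actions, collapse = ", "),
              ifelse(is.na(x$state), "unset", x$state)))
  invisible(x)
}

#' Reset an environment
#'
#' Samples the initial hidden state from `true_D` and an initial observation
#' from the corresponding column of `true_A`, reproducibly under `seed`.
#'
#' @param env A [pomdp_environment()].
#' @param seed Integer seed for the environment's private RNG stream.
#' @return A list: `env` (with state and RNG updated), `observation`
#'   (outcome index).
#' @export
env_reset <- function(env, seed) {
  stopifnot(inherits(env, "pomdp_env"))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed))
  env$state <- .rcat(env$true_D)
  obs <- .rcat(env$true_A[, env$state])
  env$rng <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  list(env = env, observation = obs)
}

#' Advance an environment by one action
#'
#' Samples the next hidden state from the action's true transition column and
#' an observation from the new state's likelihood column.
#'
#' @param env A reset [pomdp_environment()].
#' @param action Action label (must be in the environment's action set).
#' @return A list: `env`, `observation` (outcome index).
#' @export
env_step <- function(env, action) {
  stopifnot(inherits(env, "pomdp_env"))
  if (is.na(env$state)) stop("environment not reset", call. = FALSE)
  action <- as.character(action)
  if (!action %in% env$actions) {
    stop(sprintf("unknown action '%s'", action), call. = FALSE)
  }
  res <- .with_env_rng(env, {
    s_new <- .rcat(env$true_B[[action]][, env$state])
    o <- .rcat(env$true_A[, s_new])
    c(s_new, o)
  })
  env$state <- res$value[1L]
  env$rng <- res$rng
  list(env = env, observation = res$value[2L])
}

#' T-maze epistemic foraging task
#'
#' The canonical exploration/exploitation fixture: four locations (centre,
#' left arm, right arm, cue) crossed with two reward contexts (reward on the
#' left or on the right) give eight hidden states. The agent starts at the
#' centre with the context unknown. The cue location emits a
#' context-revealing outcome (1 bit of mutual information with context); the
#' arms emit reward with probability `reward_prob` when they match the
#' context (and with `1 - reward_prob` otherwise) and are absorbing, so
#' committing to an arm forecloses visiting the cue. Preferences weight the
#' reward outcome by `+preference_strength` and the null outcome by
#' `-preference_strength` (log scale); neutral outcomes sit at 0. Policies
#' are all 16 two-action sequences over the four movement actions; the
#' horizon is 3 observation epochs.
#'
#' @param reward_prob Probability of reward at the context-matching arm,
#'   in (0.5, 1]; default 0.98.
#' @param preference_strength Nonnegative log-preference for reward over
#'   neutral outcomes; default 4.
#' @param seed Integer seed for the environment (its true context is sampled
#'   at [env_reset()]).
#' @return A list: `model` (a [generative_model()]), `env`
#'   (a [pomdp_environment()] with the same contingencies), and index
#'   helpers `locations`, `outcomes`.
#' @export
make_tmaze <- function(reward_prob = 0.98, preference_strength = 4, seed = 1L) {
  if (reward_prob <= 0.5 || reward_prob > 1) {
    stop("reward_prob must lie in (0.5, 1]", call. = FALSE)
  }
  if (preference_strength < 0) stop("preference_strength must be nonnegative",
                                    call. = FALSE)
  locations <- c("center", "left", "right", "cue")
  outcomes <- c("center", "reward", "null", "cue-left", "cue-right")
  m <- 8L; n <- 5L
  st <- function(loc, ctx) match(loc, locations) + 4L * (ctx - 1L)
  A <- matrix(0, n, m)
  for (ctx in 1:2) {
    A[1L, st("center", ctx)] <- 1
    A[3L + ctx, st("cue", ctx)] <- 1
    for (arm in c("left", "right")) {
      p_r <- if ((arm == "left") == (ctx == 1L)) reward_prob else 1 - reward_prob
      A[2L, st(arm, ctx)] <- p_r
      A[3L, st(arm, ctx)] <- 1 - p_r
    }
  }
  B <- lapply(locations, function(dest) {
    M <- matrix(0, m, m)
    for (ctx in 1:2) {
      for (loc in locations) {
        from <- st(loc, ctx)
        # arms are absorbing; elsewhere the action moves deterministically
        to <- if (loc %in% c("left", "right")) from else st(dest, ctx)
        M[to, from] <- 1
      }
    }
    M
  })
  names(B) <- locations
  D <- numeric(m)
  D[st("center", 1L)] <- 0.5
  D[st("center", 2L)] <- 0.5
  logC <- c(0, preference_strength, -preference_strength, 0, 0)
  model <- generative_model(
    likelihood = likelihood_belief(probs = A),
    transitions = transition_model(B),
    D = D,
    preferences = preferences(logC, target = "outcomes"),
    policies = all_policies(locations, horizon = 3L),
    gamma = 16)
  env <- pomdp_environment(A, B, D)
  env$rng_seed <- as.integer(seed)
  list(model = model, env = env, locations = locations, outcomes = outcomes)
}

# Dirichlet sample: rows are draws on the (length(alpha)-1)-simplex
.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              n, length(alpha))
  g / rowSums(g)
}

#' Seeded random POMDP instance
#'
#' Draws every likelihood/transition column and the initial prior from a
#' symmetric Dirichlet with the given concentration; large concentrations
#' approach uniform columns. With `mismatch = TRUE` the environment's
#' contingencies are redrawn independently of the model's.
#'
#' @param m,n Numbers of hidden states and outcomes.
#' @param n_actions Number of actions.
#' @param horizon Number of observation epochs T (policies enumerate all
#'   action sequences of length T - 1).
#' @param concentration Positive symmetric-Dirichlet concentration
#'   (default 1, uniform over each simplex).
#' @param seed Integer seed; the same seed reproduces the instance exactly.
#' @param mismatch Draw the environment's true matrices independently.
#' @param gamma Policy precision for the model.
#' @return A list: `model`, `env`.
#' @export
make_random_pomdp <- function(m, n, n_actions, horizon, concentration = 1,
                              seed = 1L, mismatch = FALSE, gamma = 16) {
  stopifnot(m >= 1L, n >= 1L, n_actions >= 1L, horizon >= 1L, concentration > 0)
  set.seed(as.integer(seed))
  draw <- function() {
    A <- t(.rdirichlet(m, rep(concentration, n)))
    B <- lapply(seq_len(n_actions), function(u) t(.rdirichlet(m, rep(concentration, m))))
    names(B) <- paste0("u", seq_len(n_actions))
    D <- as.numeric(.rdirichlet(1L, rep(concentration, m)))
    list(A = A, B = B, D = D)
  }
  g_model <- draw()
  g_env <- if (mismatch) draw() else g_model
  actions <- paste0("u", seq_len(n_actions))
  model <- generative_model(
    likelihood = likelihood_belief(probs = g_model$A),
    transitions = transition_model(g_model$B),
    D = g_model$D,
    preferences = preferences(rep(0, n), target = "outcomes"),
    policies = all_policies(actions, horizon),
    gamma = gamma)
  env <- pomdp_environment(g_env$A, g_env$B, g_env$D)
  list(model = model, env = env)
}
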