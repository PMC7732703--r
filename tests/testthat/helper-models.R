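# Shared fixtures and independent oracles, all built in code.

# Brute-force model evidence -log P(o_{1:t} | policy) by enumeration over
# state trajectories; the independent oracle for the free-energy bound.
enum_neg_log_evidence <- function(model, obs, policy) {
  A <- expected_likelihood(model$likelihood)
  acts <- if (is.numeric(policy) && length(policy) == 1L) {
    as.character(model$policies$policies[policy, ])
  } else as.character(policy)
  B <- model$transitions$B
  m <- ncol(A)
  T_len <- model$policies$horizon
  t_obs <- length(obs)
  paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(m)), T_len)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    p <- model$D[paths[r, 1L]]
    for (tau in 2:max(2L, T_len)) {
      if (tau > T_len) break
      p <- p * B[[acts[tau - 1L]]][paths[r, tau], paths[r, tau - 1L]]
    }
    for (tau in seq_len(t_obs)) p <- p * A[obs[tau], paths[r, tau]]
    total <- total + p
  }
  -log(total)
}

# Exact Bayesian posterior over states at T = 1 given a single observation.
enum_posterior_T1 <- function(model, o) {
  A <- expected_likelihood(model$likelihood)
  post <- A[o, ] * model$D
  post / sum(post)
}

# Central finite differences of the policy free energy at epoch tau.
fd_gradient <- function(beliefs, obs, model, policy, tau, h = 1e-6) {
  vapply(seq_len(ncol(beliefs)), function(i) {
    up <- beliefs; dn <- beliefs
    up[tau, i] <- up[tau, i] + h
    dn[tau, i] <- dn[tau, i] - h
    (policy_free_energy(up, obs, model, policy) -
       policy_free_energy(dn, obs, model, policy)) / (2 * h)
  }, numeric(1L))
}

# Interior random belief matrix (rows strictly inside the simplex).
random_beliefs <- function(T_len, m) {
  t(vapply(seq_len(T_len), function(i) softmax(stats::rnorm(m)),
           numeric(m)))
}

# Monte-Carlo estimate of KL[Dir(a) || Dir(b)] from Dirichlet samples.
mc_dirichlet_kl <- function(a, b, n = 2e4, seed = 1) {
  set.seed(seed)
  g <- matrix(stats::rgamma(n * length(a), shape = rep(a, each = n)), n)
  x <- g / rowSums(g)
  lb <- function(v) sum(lgamma(v)) - lgamma(sum(v))
  vals <- log(x) %*% (a - b) - lb(a) + lb(b)
  list(est = mean(vals), se = stats::sd(vals) / sqrt(n))
}

# One uniform-Dirichlet draw on the (n-1)-simplex (uses the ambient RNG).
.rdirichlet_test <- function(n) {
  g <- stats::rgamma(n, 1)
  g / sum(g)
}

# Deterministic three-state chain where the terminal state is strongly
# preferred; identity likelihood, actions stay/advance.
make_chain_fixture <- function(strength = 6) {
  B <- list(
    stay = diag(3),
    advance = matrix(c(0, 1, 0,
                       0, 0, 1,
                       0, 0, 1), 3, 3)
  )
  generative_model(
    likelihood_belief(probs = diag(3)),
    transition_model(B),
    D = c(1, 0, 0),
    preferences = preferences(c(-strength, 0, strength), target = "states"),
    policies = all_policies(c("stay", "advance"), horizon = 3),
    gamma = 16)
}
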