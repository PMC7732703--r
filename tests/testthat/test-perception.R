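# two-state, single-policy model with a given likelihood
two_state_model <- function(A = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2),
                            D = c(0.5, 0.5), horizon = 1) {
  generative_model(likelihood_belief(probs = A), transition_model(diag(2)),
                   D, preferences(c(0, 0)), all_policies("u1", horizon))
}

test_that("free energy at the exact posterior equals the surprise", {
  mdl <- two_state_model()
  s <- matrix(c(0.9, 0.1), 1, 2)  # exact posterior for o = 1
  expect_equal(policy_free_energy(s, 1, mdl, 1), -log(0.5), tolerance = 1e-10)
  # before any observation, beliefs = prior gives F = KL = 0
  s0 <- matrix(c(0.5, 0.5), 1, 2)
  expect_equal(policy_free_energy(s0, integer(0), mdl, 1), 0, tolerance = 1e-12)
  # enumeration: at the exact posterior of random T = 1 instances F = -log P(o)
  set.seed(3)
  for (i in 1:10) {
    mp <- make_random_pomdp(3, 3, 1, 1, seed = i)$model
    o <- sample(3, 1)
    post <- enum_posterior_T1(mp, o)
    expect_equal(policy_free_energy(matrix(post, 1), o, mp, 1),
                 enum_neg_log_evidence(mp, o, character(0)), tolerance = 1e-10)
  }
  expect_error(policy_free_energy(matrix(0.5, 1, 2), c(1, 1), mdl, 1), "longer")
})

test_that("analytic gradient matches central finite differences", {
  set.seed(4)
  for (i in 1:25) {
    m <- sample(2:5, 1); n <- sample(2:5, 1); T_len <- sample(1:4, 1)
    mp <- make_random_pomdp(m, n, 2, T_len, seed = 100 + i)$model
    t_obs <- sample(0:T_len, 1)
    obs <- if (t_obs > 0) sample(n, t_obs, replace = TRUE) else integer(0)
    pol <- sample(nrow(mp$policies$policies), 1)
    s <- random_beliefs(T_len, m)
    for (tau in seq_len(T_len)) {
      g <- free_energy_gradient(s, obs, mp, pol, tau)
      expect_equal(g, fd_gradient(s, obs, mp, pol, tau), tolerance = 1e-5)
    }
  }
  mp <- make_random_pomdp(2, 2, 1, 2, seed = 1)$model
  expect_error(free_energy_gradient(random_beliefs(2, 2), 1, mp, 1, 3),
               "out of range")
})

test_that("gradient is softmax-flat at the T = 1 fixed point", {
  mdl <- two_state_model()
  s_star <- softmax(log(mdl$D) + log(mdl$likelihood$probs)[1, ])
  g <- free_energy_gradient(matrix(s_star, 1), 1, mdl, 1, 1)
  expect_equal(diff(g), 0, tolerance = 1e-10)  # constant vector
  # single-state simplex: s = [1] is always the fixed point
  m1 <- generative_model(likelihood_belief(probs = matrix(c(0.7, 0.3), 2, 1)),
                         transition_model(matrix(1, 1, 1)), 1,
                         preferences(c(0, 0)), all_policies("u1", 1))
  r <- infer_states(1, m1, 1)
  expect_equal(r$s[1, ], 1)
})

test_that("inference recovers the exact posterior at T = 1", {
  mdl <- two_state_model(D = c(0.5, 0.5))
  r <- infer_states(1, mdl, 1)
  expect_true(r$converged)
  expect_equal(r$s[1, ], c(0.9, 0.1), tolerance = 1e-6)
  expect_equal(r$s[1, ], softmax(r$v[1, ]), tolerance = 1e-12)
  # fixed-point sweeps reach the same posterior
  r2 <- infer_states(1, mdl, 1, method = "fixedpoint")
  expect_equal(r2$s[1, ], c(0.9, 0.1), tolerance = 1e-8)
})

test_that("uninformative likelihood leaves beliefs at the prior chain", {
  A <- matrix(0.5, 2, 2)
  mdl <- two_state_model(A = A, horizon = 3)
  r <- infer_states(c(1, 2, 1), mdl, 1)
  expect_equal(r$s, matrix(0.5, 3, 2), tolerance = 1e-6)
})

test_that("future beliefs follow deterministic transition propagation", {
  # 3-state cyclic chain with a deterministic shift; observation pins s1
  shift <- matrix(c(0, 1, 0,
                    0, 0, 1,
                    1, 0, 0), 3, 3)
  mdl <- generative_model(likelihood_belief(probs = diag(3)),
                          transition_model(list(u1 = shift)),
                          rep(1 / 3, 3), preferences(rep(0, 3)),
                          all_policies("u1", 3))
  r <- infer_states(1, mdl, 1, tol = 1e-10)
  expect_equal(r$s[1, ], c(1, 0, 0), tolerance = 1e-5)
  expect_equal(r$s[2, ], c(0, 1, 0), tolerance = 1e-5)  # shifted forward
  expect_equal(r$s[3, ], c(0, 0, 1), tolerance = 1e-5)
})

test_that("free energy descends monotonically under the potential dynamics", {
  set.seed(5)
  for (i in 1:10) {
    mp <- make_random_pomdp(sample(2:5, 1), sample(2:5, 1), 2,
                            sample(2:4, 1), seed = 200 + i)$model
    n <- actinfr:::.model_dims(mp)$n
    obs <- sample(n, sample(1:mp$policies$horizon, 1), replace = TRUE)
    r <- infer_states(obs, mp, 1, kappa = 0.1, track_F = TRUE)
    expect_true(all(diff(r$F_trace) <= 1e-10))
  }
})

test_that("converged free energy never beats the enumeration evidence", {
  set.seed(6)
  for (i in 1:8) {
    m <- sample(2:4, 1); n <- sample(2:4, 1); T_len <- sample(1:3, 1)
    mp <- make_random_pomdp(m, n, 2, T_len, seed = 300 + i)$model
    t_obs <- sample(1:T_len, 1)
    obs <- sample(n, t_obs, replace = TRUE)
    pol <- sample(nrow(mp$policies$policies), 1)
    r <- infer_states(obs, mp, pol)
    expect_gte(r$F, enum_neg_log_evidence(mp, obs, pol) - 1e-9)
    # rows stay normalised after every update
    expect_equal(rowSums(r$s), rep(1, T_len), tolerance = 1e-10)
  }
})

test_that("Bayesian model averaging of beliefs behaves as a mixture", {
  e1 <- matrix(c(1, 0), 1, 2); e2 <- matrix(c(0, 1), 1, 2)
  expect_equal(bma_states(list(e1), 1), e1)
  expect_equal(bma_states(list(e1, e2), c(0.5, 0.5)), matrix(0.5, 1, 2))
  expect_equal(bma_states(list(e1, e2), c(0, 1)), e2)
  expect_error(bma_states(list(e1, e2), c(0.6, 0.6)), "sum to 1")
  expect_error(bma_states(list(e1), c(0.5, 0.5)), "match")
})
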