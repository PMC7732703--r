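test_that("Dirichlet KL closed form matches its oracles", {
  expect_equal(dirichlet_kl(c(2, 3), c(2, 3)), 0)
  expect_equal(dirichlet_kl(c(2, 1), c(1, 1)), log(2) - 0.5, tolerance = 1e-12)
  # numeric integration over the 1-simplex
  for (pair in list(list(a = c(2, 1), b = c(1, 1)),
                    list(a = c(3, 2), b = c(1.5, 4)),
                    list(a = c(0.7, 1.2), b = c(2, 2)))) {
    f <- function(x) {
      da <- stats::dbeta(x, pair$a[1], pair$a[2])
      db <- stats::dbeta(x, pair$b[1], pair$b[2])
      da * (log(da) - log(db))
    }
    num <- stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
    expect_equal(dirichlet_kl(pair$a, pair$b), num, tolerance = 1e-6)
  }
  # Monte-Carlo agreement for n up to 5, and nonnegativity on random pairs
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    a <- rexp(n) + 0.2; b <- rexp(n) + 0.2
    kl <- dirichlet_kl(a, b)
    expect_gte(kl, 0)
    mc <- mc_dirichlet_kl(a, b, n = 2e4, seed = i)
    expect_lt(abs(kl - mc$est), 4 * mc$se + 1e-8)
  }
  expect_error(dirichlet_kl(c(1, -1), c(1, 1)), "positive")
})

test_that("trial updates accumulate outcome-state co-occurrence counts", {
  a0 <- matrix(1, 2, 2)
  # one-hot: a single cell increments
  a1 <- dirichlet_update_trial(a0, list(o = 1L, s = matrix(c(0, 1), 1, 2)))
  expect_equal(a1 - a0, matrix(c(0, 0, 1, 0), 2, 2))
  # graded beliefs: the outer product spreads the unit count
  a2 <- dirichlet_update_trial(a0, list(o = 1L, s = matrix(c(0.7, 0.3), 1, 2)))
  expect_equal(a2 - a0, matrix(c(0.7, 0, 0.3, 0), 2, 2))
  # empty trace leaves counts alone
  a3 <- dirichlet_update_trial(a0, list(o = integer(0), s = matrix(0, 0, 2)))
  expect_identical(a3, a0)
  # entries never decrease; each epoch adds exactly one unit of mass
  set.seed(12)
  s <- t(vapply(1:5, function(i) softmax(rnorm(2)), numeric(2)))
  a5 <- dirichlet_update_trial(a0, list(o = sample(2, 5, TRUE), s = s))
  expect_true(all(a5 >= a0))
  expect_equal(sum(a5) - sum(a0), 5)
  # one-hot beliefs over repeated trials give integer co-occurrence counts
  a <- a0
  tally <- matrix(0, 2, 2)
  for (i in 1:10) {
    o <- sample(2, 3, TRUE); st <- sample(2, 3, TRUE)
    sm <- diag(2)[st, , drop = FALSE]
    a <- dirichlet_update_trial(a, list(o = o, s = sm))
    for (k in 1:3) tally[o[k], st[k]] <- tally[o[k], st[k]] + 1
  }
  expect_equal(a - a0, tally)
  expect_error(dirichlet_update_trial(a0, list(o = 1L, s = matrix(1, 1, 3))),
               "dimensions")
})

test_that("plasticity dynamics relax to the conjugate fixed point", {
  a_prior <- matrix(c(1, 2), 2, 1)
  trace <- list(o = c(1L, 1L), s = matrix(1, 2, 1))
  target <- dirichlet_update_trial(a_prior, trace)
  # initialised at the fixed point: constant trajectory
  r0 <- plasticity_dynamics(target, a_prior, trace, step = 0.2, n_steps = 10)
  expect_equal(r0$a, target, tolerance = 1e-12)
  # closed-form exponential relaxation: a(k) = target + (1-step)^k (a0 - target)
  a_start <- matrix(c(5, 5), 2, 1)
  r <- plasticity_dynamics(a_start, a_prior, trace, step = 0.3, n_steps = 25)
  expect_equal(r$trajectory[[25]],
               target + (1 - 0.3)^25 * (a_start - target), tolerance = 1e-10)
  r_long <- plasticity_dynamics(a_start, a_prior, trace, step = 0.3,
                                n_steps = 60)
  expect_equal(r_long$a, target, tolerance = 1e-6)
  # no evidence: relaxes back to the prior
  r_empty <- plasticity_dynamics(a_start, a_prior,
                                 list(o = integer(0), s = matrix(0, 0, 1)),
                                 step = 0.3, n_steps = 80)
  expect_equal(r_empty$a, a_prior, tolerance = 1e-6)
  expect_error(plasticity_dynamics(a_start, a_prior, trace, step = 0),
               "positive")
})

test_that("accumulating evidence makes any fixed mapping less novel", {
  a <- matrix(1, 2, 2)
  nov <- numeric(6)
  for (i in 1:6) {
    nov[i] <- novelty(c(1, 0), likelihood_belief(counts = a))
    a <- dirichlet_update_trial(a, list(o = 1L, s = matrix(c(1, 0), 1, 2)))
  }
  expect_true(all(diff(nov) < 0))
})

test_that("learned likelihood converges to the true contingencies", {
  # deterministic 2-state swap chain: state sequence is known exactly, so the
  # counts tally true outcome frequencies per state
  trueA <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2)
  B <- list(u1 = matrix(c(0, 1, 1, 0), 2, 2))
  mdl <- generative_model(likelihood_belief(counts = matrix(1, 2, 2)),
                          transition_model(B), c(1, 0),
                          preferences(c(0, 0)), all_policies("u1", 8))
  env <- pomdp_environment(trueA, B, c(1, 0))
  res <- run_trials(mdl, env, n_trials = 60, seed = 99, learn = TRUE,
                    method = "fixedpoint")
  tv_60 <- colSums(abs(expected_likelihood(res$model$likelihood) - trueA)) / 2
  expect_true(all(tv_60 < 0.1))
  # counts grow by exactly one unit of mass per epoch
  expect_equal(sum(res$model$likelihood$counts) - 4, 60 * 8)
})
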