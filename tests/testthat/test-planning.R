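# minimal point-mode model over 2 states/outcomes with given A and preferences
plan_model <- function(A, logC = c(0, 0), target = "outcomes",
                       horizon = 2) {
  generative_model(likelihood_belief(probs = A), transition_model(diag(ncol(A))),
                   rep(1 / ncol(A), ncol(A)), preferences(logC, target),
                   all_policies("u1", horizon))
}

test_that("outcome prediction pushes states through the expected likelihood", {
  lik <- likelihood_belief(probs = diag(2))
  expect_equal(predict_outcomes(c(1, 0), lik), c(1, 0))
  liku <- likelihood_belief(probs = matrix(0.5, 2, 2))
  expect_equal(predict_outcomes(c(0.3, 0.7), liku), c(0.5, 0.5))
  likm <- likelihood_belief(probs = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2))
  expect_equal(predict_outcomes(c(0.5, 0.5), likm), c(0.5, 0.5))
})

test_that("risk is the KL from predicted to preferred distributions", {
  mdl <- plan_model(diag(2), logC = c(1, -1))
  pref <- softmax(c(1, -1))
  expect_equal(risk(pref, mdl), 0, tolerance = 1e-12)
  mdl_u <- plan_model(diag(2), logC = c(0, 0))
  expect_equal(risk(c(1, 0), mdl_u), log(2), tolerance = 1e-12)
  # state-form and outcome-form agree when A is the identity
  mdl_s <- plan_model(diag(2), logC = c(1, -1), target = "states")
  s <- c(0.8, 0.2)
  expect_equal(risk(s, mdl_s),
               risk(predict_outcomes(s, mdl$likelihood), mdl), tolerance = 1e-12)
})

test_that("ambiguity is the expected conditional outcome entropy", {
  det <- likelihood_belief(probs = diag(2))
  expect_equal(ambiguity(c(0.3, 0.7), det), 0)
  unif <- likelihood_belief(probs = matrix(0.5, 2, 2))
  expect_equal(ambiguity(c(0.9, 0.1), unif), log(2), tolerance = 1e-12)
  # dirichlet counts at scale 1e6 recover the point-mode value
  A <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, 2)
  lik_big <- likelihood_belief(counts = 1e6 * A)
  s <- c(0.4, 0.6)
  expect_equal(ambiguity(s, lik_big),
               ambiguity(s, likelihood_belief(probs = A)), tolerance = 1e-4)
  expect_equal(ambiguity(s, lik_big, exact = TRUE),
               ambiguity(s, likelihood_belief(probs = A)), tolerance = 1e-4)
})

test_that("novelty is the exact expected Dirichlet information gain", {
  # single state, symmetric column [1, 1]: both outcomes give the same KL
  likn <- likelihood_belief(counts = matrix(c(1, 1), 2, 1))
  expect_equal(novelty(1, likn), log(2) - 0.5, tolerance = 1e-10)
  # counts at scale: nothing left to learn
  lik_big <- likelihood_belief(counts = matrix(1e6 * c(0.3, 0.7), 2, 1))
  expect_lt(novelty(1, lik_big), 1e-5)
  # zero-mass states contribute nothing
  lik2 <- likelihood_belief(counts = matrix(c(1, 1, 5, 2), 2, 2))
  expect_equal(novelty(c(1, 0), lik2), novelty(1, likelihood_belief(
    counts = matrix(c(1, 1), 2, 1))), tolerance = 1e-12)
  expect_equal(novelty(c(0, 0), lik2), 0)
  expect_equal(novelty(0.5, likelihood_belief(probs = matrix(c(0.5, 0.5), 2, 1))), 0)
})

test_that("expected free energy reduces to risk for unambiguous likelihoods", {
  mdl <- plan_model(diag(2), logC = c(0, 0))
  s <- matrix(c(0.5, 0.5, 0.9, 0.1), 2, 2, byrow = TRUE)
  br <- expected_free_energy(mdl, s, tau_set = 2)
  expect_equal(br$ambiguity, 0)
  expect_equal(br$G, risk(predict_outcomes(s[2, ], mdl$likelihood), mdl),
               tolerance = 1e-12)
  # policies with identical predicted futures score identically
  br2 <- expected_free_energy(mdl, s[c(1, 2), ], tau_set = 2)
  expect_equal(br$G, br2$G)
  expect_error(expected_free_energy(mdl, s, tau_set = integer(0)), "tau_set")
})

test_that("the risk+ambiguity and epistemic decompositions coincide exactly", {
  set.seed(7)
  for (target in c("outcomes", "states")) {
    for (mode in c("point", "dirichlet")) {
      for (i in 1:10) {
        A <- vapply(1:2, function(j) softmax(rnorm(2)), numeric(2))
        lik <- if (mode == "point") likelihood_belief(probs = A) else
          likelihood_belief(counts = matrix(rexp(4) + 0.2, 2, 2))
        mdl <- generative_model(lik, transition_model(diag(2)), c(0.5, 0.5),
                                preferences(rnorm(2), target),
                                all_policies("u1", 2))
        s <- matrix(rep(softmax(rnorm(2)), 2), 2, 2, byrow = TRUE)
        d <- efe_decompositions(mdl, s, tau_set = 2)
        expect_lt(abs(d$identity_residual), 1e-8)
        # every KL / entropy component is nonnegative
        expect_gte(d$risk, 0); expect_gte(d$ambiguity, -1e-12)
        expect_gte(d$salience, -1e-12); expect_gte(d$novelty, 0)
        expect_gte(d$evidence_bound, -1e-12)
        # dropping the nonnegative bound leaves a lower bound on G
        G_exact <- d$risk + d$ambiguity_exact - d$novelty
        expect_gte(G_exact, d$lower_bound - d$novelty - 1e-10)
        if (mode == "point") {
          expect_equal(d$novelty, 0)
          expect_equal(d$ambiguity, d$ambiguity_exact, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("salience behaves as the fictive state information gain", {
  # uninformative likelihood: posterior = prior, no gain
  mdl_u <- plan_model(matrix(0.5, 2, 2))
  d <- efe_decompositions(mdl_u, matrix(c(0.5, 0.5, 0.3, 0.7), 2, 2,
                                        byrow = TRUE), tau_set = 2)
  expect_equal(d$salience, 0, tolerance = 1e-12)
  # identity likelihood: the outcome names the state, gain = prior entropy
  mdl_i <- plan_model(diag(2))
  s <- c(0.3, 0.7)
  d2 <- efe_decompositions(mdl_i, matrix(rep(s, 2), 2, 2, byrow = TRUE),
                           tau_set = 2)
  expect_equal(d2$salience, -sum(s * log(s)), tolerance = 1e-12)
})

test_that("with flat preferences the G-ranking is the information-gain ranking", {
  set.seed(8)
  for (i in 1:10) {
    A <- vapply(1:3, function(j) softmax(rnorm(3)), numeric(3))
    mdl <- generative_model(likelihood_belief(probs = A), transition_model(diag(3)),
                            rep(1 / 3, 3), preferences(rep(0, 3)),
                            all_policies("u1", 2))
    G <- sal <- numeric(5)
    for (p in 1:5) {
      s <- matrix(rep(softmax(rnorm(3)), 2), 2, 3, byrow = TRUE)
      d <- efe_decompositions(mdl, s, tau_set = 2)
      G[p] <- d$G; sal[p] <- d$salience
    }
    expect_equal(order(G), order(-sal))
  }
  # deterministic A in point mode: ranking equals the risk (KL-control) ranking
  set.seed(9)
  mdl_d <- plan_model(diag(3)[, c(1, 2, 3)], logC = c(2, 0, -2))
  G <- rk <- numeric(5)
  for (p in 1:5) {
    s <- matrix(rep(softmax(rnorm(3)), 2), 2, 3, byrow = TRUE)
    d <- expected_free_energy(mdl_d, s, tau_set = 2)
    G[p] <- d$G; rk[p] <- d$risk
  }
  expect_equal(order(G), order(rk))
})

test_that("policy posterior is a shifted softmax with precision", {
  pp <- policy_posterior(c(1, 1, 1))
  expect_equal(pp$q_pi, rep(1 / 3, 3))
  expect_equal(policy_posterior(c(0, log(3)))$q_pi, c(0.75, 0.25),
               tolerance = 1e-12)
  # invariance to constant shifts
  G <- c(0.2, 1.4, 0.9)
  expect_equal(policy_posterior(G)$q_pi, policy_posterior(G + 5)$q_pi,
               tolerance = 1e-12)
  # gamma -> large approaches argmin selection
  expect_equal(policy_posterior(G, gamma = 1e4)$q_pi,
               c(1, 0, 0), tolerance = 1e-10)
  expect_equal(sum(policy_posterior(G, gamma = 7)$q_pi), 1, tolerance = 1e-12)
  expect_error(policy_posterior(c(0, Inf)), "non-finite")
  expect_error(policy_posterior(G, gamma = -1), "positive")
})

test_that("Occam-window pruning always keeps the argmin", {
  pr <- prune_policies(c(1, 1, 1), window = 2)
  expect_equal(pr$retained, 1:3)
  pr0 <- prune_policies(c(0.5, 0.2, 0.2), window = 0)
  expect_equal(pr0$retained, 2:3)  # ties retained
  pr1 <- prune_policies(c(1, 2, 10), window = 3)
  expect_equal(pr1$retained, 1:2)
  expect_lt(pr1$q_pi[3], 1e-11)
  expect_equal(sum(pr1$q_pi), 1, tolerance = 1e-12)
  set.seed(10)
  for (i in 1:20) {
    G <- rnorm(6)
    expect_true(which.min(G) %in% prune_policies(G, window = runif(1, 0, 2))$retained)
  }
})
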