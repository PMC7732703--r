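# Structure learning: Bayesian model reduction over Dirichlet likelihood
# priors, and model expansion with initially unused hidden states.

# normalise count input to a matrix
.as_counts <- function(x, name) {
  x <- as.matrix(x)
  if (any(x <= 0)) stop(sprintf("%s must be strictly positive", name), call. = FALSE)
  x
}

#' Bayesian model reduction: change in log evidence
#'
#' Compares a reduced Dirichlet prior over the likelihood against the full
#' prior using only the full-model posterior counts. By conjugacy the reduced
#' posterior is `a_tilde = a_post + a_reduced_prior - a_prior` and the log
#' evidence difference is, per column,
#' `[lnB(a_tilde) - lnB(a_reduced_prior)] - [lnB(a_post) - lnB(a_prior)]`
#' with `lnB` the log multivariate beta function; columns are independent and
#' sum. Positive values favour the reduced model.
#'
#' @param a_prior,a_post,a_reduced_prior Positive count matrices (or vectors
#'   for a single column) of identical shape.
#' @return Scalar log-evidence difference `log Ptilde(o) - log P(o)`.
#' @export
bmr_delta_evidence <- function(a_prior, a_post, a_reduced_prior) {
  ap <- .as_counts(a_prior, "a_prior")
  aq <- .as_counts(a_post, "a_post")
  ar <- .as_counts(a_reduced_prior, "a_reduced_prior")
  if (any(dim(ap) != dim(aq)) || any(dim(ap) != dim(ar))) {
    stop("count matrices must share one shape", call. = FALSE)
  }
  at <- aq + ar - ap
  if (any(at <= 0)) {
    stop("invalid reduction: reduced posterior counts would be nonpositive (the reduced prior removes more mass than was ever present)",
         call. = FALSE)
  }
  delta <- 0
  for (j in seq_len(ncol(ap))) {
    delta <- delta + (.lbeta_vec(at[, j]) - .lbeta_vec(ar[, j])) -
      (.lbeta_vec(aq[, j]) - .lbeta_vec(ap[, j]))
  }
  delta
}

#' Monte-Carlo estimate of the model-reduction evidence change
#'
#' Estimates `log E_{Q(A)}[Ptilde(A) / P(A)]` by sampling likelihood columns
#' from the Dirichlet posterior and averaging density ratios; the independent
#' stochastic oracle for [bmr_delta_evidence()].
#'
#' @inheritParams bmr_delta_evidence
#' @param n_samples Samples per column (default 1e5).
#' @param seed Integer seed (required; sampling is reproducible).
#' @return A list: `estimate`, `se` (delta-method standard error of the log
#'   estimate), `n_samples`.
#' @export
bmr_monte_carlo <- function(a_prior, a_post, a_reduced_prior,
                            n_samples = 1e5, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  ap <- .as_counts(a_prior, "a_prior")
  aq <- .as_counts(a_post, "a_post")
  ar <- .as_counts(a_reduced_prior, "a_reduced_prior")
  if (any(dim(ap) != dim(aq)) || any(dim(ap) != dim(ar))) {
    stop("count matrices must share one shape", call. = FALSE)
  }
  set.seed(seed)
  estimate <- 0
  var_sum <- 0
  for (j in seq_len(ncol(ap))) {
    # Dirichlet(a_post[, j]) samples via normalised gammas
    n <- nrow(ap)
    g <- matrix(stats::rgamma(n_samples * n, shape = rep(aq[, j], each = n_samples)),
                n_samples, n)
    A <- g / rowSums(g)
    const <- .lbeta_vec(ap[, j]) - .lbeta_vec(ar[, j])
    logratio <- const + as.numeric(log(A) %*% (ar[, j] - ap[, j]))
    mx <- max(logratio)
    r <- exp(logratio - mx)
    mean_r <- mean(r)
    estimate <- estimate + mx + log(mean_r)
    # delta method: var of log(mean) ~ var(r) / (n mean^2)
    var_sum <- var_sum + stats::var(r) / (n_samples * mean_r^2)
  }
  list(estimate = estimate, se = sqrt(var_sum), n_samples = n_samples)
}

#' Expand a model with unused hidden states
#'
#' Appends `k_new` hidden states whose likelihood columns carry uniform
#' Dirichlet counts `init_count` (uninformative), extends the initial prior
#' with mass `new_state_prior` per new state (then renormalised), and makes
#' the new states absorbing under every action (identity block) so existing
#' dynamics are untouched. With negligible `new_state_prior`, inference on
#' pre-existing data is unchanged to within round-off; the new states only
#' become engaged if transitions or priors are subsequently edited, and a
#' redundant expansion can be rolled back by [bmr_delta_evidence()].
#'
#' @param model A [generative_model()] with Dirichlet likelihood beliefs
#'   (point-mode likelihoods get uniform probability columns instead).
#' @param k_new Number of states to add (0 returns the model unchanged).
#' @param init_count Positive Dirichlet count for new likelihood columns.
#' @param new_state_prior Prior mass given to each new state before
#'   renormalising D (default 1e-8).
#' @return The expanded, validated model.
#' @export
expand_states <- function(model, k_new, init_count = 1, new_state_prior = 1e-8) {
  stopifnot(inherits(model, "gen_model"))
  if (k_new == 0L) return(model)
  if (k_new < 0L) stop("k_new must be nonnegative", call. = FALSE)
  if (init_count <= 0) stop("init_count must be positive", call. = FALSE)
  dims <- .model_dims(model)
  lik <- model$likelihood
  if (lik$mode == "dirichlet") {
    pad <- matrix(init_count, dims$n, k_new)
    lik <- likelihood_belief(counts = cbind(lik$counts, pad),
                             counts_prior = cbind(lik$counts_prior, pad))
  } else {
    pad <- matrix(1 / dims$n, dims$n, k_new)
    lik <- likelihood_belief(probs = cbind(lik$probs, pad))
  }
  B_new <- lapply(model$transitions$B, function(M) {
    out <- rbind(cbind(M, matrix(0, dims$m, k_new)),
                 cbind(matrix(0, k_new, dims$m), diag(k_new)))
    out
  })
  names(B_new) <- model$transitions$actions
  D_new <- c(model$D, rep(new_state_prior, k_new))
  D_new <- D_new / sum(D_new)
  pref <- model$preferences
  if (pref$target == "states") {
    pref <- preferences(lapply(pref$logC, function(v) c(v, rep(min(v), k_new))),
                        target = "states")
  }
  generative_model(lik, transition_model(B_new), D_new, pref,
                   model$policies, model$gamma)
}
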