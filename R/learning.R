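# Dirichlet learning of the likelihood mapping.
#
# Each trial's (outcome, state-belief) pairs are accumulated as Dirichlet
# counts: a <- a_prior + sum_tau o_tau (x) s_tau, the conjugate one-step
# update. Between trials the posterior counts roll over into the next
# trial's prior. A continuous-time relaxation towards the same fixed point
# is provided for completeness.

#' KL divergence between Dirichlet distributions
#'
#' `KL[Dir(a) || Dir(b)]` in closed form:
#' `lgamma(a0) - sum lgamma(a_k) - lgamma(b0) + sum lgamma(b_k)
#'  + (a - b) . (digamma(a) - digamma(a0))`.
#'
#' @param a,b Strictly positive parameter vectors of equal length.
#' @return Nonnegative scalar, zero iff `a == b`.
#' @export
dirichlet_kl <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  if (any(a <= 0) || any(b <= 0)) {
    stop("Dirichlet parameters must be strictly positive", call. = FALSE)
  }
  a0 <- sum(a); b0 <- sum(b)
  lgamma(a0) - sum(lgamma(a)) - lgamma(b0) + sum(lgamma(b)) +
    sum((a - b) * (digamma(a) - digamma(a0)))
}

# Coerce a trace argument into list(o = one-hot matrix T x n or indices,
# s = T x m belief matrix).
.trace_pairs <- function(trace, n) {
  if (inherits(trace, "trial_record")) {
    return(list(o = trace$observations, s = trace$states))
  }
  stopifnot(is.list(trace), !is.null(trace$o), !is.null(trace$s))
  list(o = trace$o, s = trace$s)
}

#' Accumulate Dirichlet counts from a trial
#'
#' Adds the outer products of observed outcomes and policy-independent state
#' beliefs to the prior counts: `a = a_prior + sum_tau o_tau (x) s_tau`.
#' Outcomes may be indices or one-hot rows; state beliefs are simplex rows,
#' so each epoch adds exactly one unit of total count.
#'
#' @param a_prior n x m matrix of positive counts.
#' @param trace A [run_trial()] record, or a list with `o` (length-T integer
#'   vector of outcome indices, or T x n one-hot matrix) and `s` (T x m
#'   belief matrix).
#' @param rate Learning-rate multiplier on the increment (default 1, the
#'   plain conjugate update).
#' @return The updated n x m count matrix.
#' @export
dirichlet_update_trial <- function(a_prior, trace, rate = 1) {
  a_prior <- as.matrix(a_prior)
  pr <- .trace_pairs(trace, nrow(a_prior))
  o <- pr$o; s <- as.matrix(pr$s)
  if (is.null(dim(o))) {
    idx <- as.integer(o)
    o <- matrix(0, length(idx), nrow(a_prior))
    for (tt in seq_along(idx)) o[tt, idx[tt]] <- 1
  }
  o <- as.matrix(o)
  if (nrow(o) != nrow(s)) stop("observation and state traces differ in length",
                               call. = FALSE)
  if (ncol(o) != nrow(a_prior) || ncol(s) != ncol(a_prior)) {
    stop("trace dimensions do not match the count matrix", call. = FALSE)
  }
  a <- a_prior
  for (tt in seq_len(nrow(o))) {
    a <- a + rate * (o[tt, ] %o% s[tt, ])
  }
  a
}

#' Continuous-time plasticity dynamics for Dirichlet counts
#'
#' Forward-Euler integration of the linear relaxation
#' `da/dt = -a + a_prior + sum_{tau <= t} o_tau (x) s_tau`, whose global
#' attractor is the one-step conjugate update of
#' [dirichlet_update_trial()]. Entries are floored at 1e-8 (with a warning)
#' if a large step transiently drives them nonpositive.
#'
#' @param a Starting n x m count matrix.
#' @param a_prior Prior counts.
#' @param trace Evidence accumulated so far (same forms as in
#'   [dirichlet_update_trial()]); may contain fewer than T epochs.
#' @param step Positive Euler step size.
#' @param n_steps Number of steps.
#' @return A list: `a` (final counts), `trajectory` (list of count matrices,
#'   one per step), `target` (the fixed point).
#' @export
plasticity_dynamics <- function(a, a_prior, trace, step = 0.1, n_steps = 100L) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  a <- as.matrix(a)
  target <- dirichlet_update_trial(a_prior, trace)
  trajectory <- vector("list", n_steps)
  floored <- FALSE
  for (k in seq_len(n_steps)) {
    a <- a + step * (target - a)
    if (any(a <= 0)) {
      a[a <= 0] <- 1e-8
      floored <- TRUE
    }
    trajectory[[k]] <- a
  }
  if (floored) warning("count trajectory floored at 1e-8 to preserve positivity")
  list(a = a, trajectory = trajectory, target = target)
}
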