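# Internal numerical helpers shared across modules.

# Floor used for logs of structural zeros in model distributions (A, B, D).
# Entries of belief vectors use the 0*log(0) := 0 convention instead.
.LOG_FLOOR <- log(1e-16)

#' Softmax (normalised exponential)
#'
#' Numerically stable softmax of a real vector: `exp(x) / sum(exp(x))` after
#' subtracting the maximum.
#'
#' @param x Numeric vector.
#' @return A probability vector of the same length as `x`.
#' @export
softmax <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L, all(is.finite(x)))
  z <- exp(x - max(x))
  z / sum(z)
}

# log with structural zeros floored at log(1e-16); used for model probabilities
# (D, B, point-mode A) so that impossible states are strongly, finitely penalised.
.safe_log <- function(x) {
  out <- log(pmax(x, 0))
  out[!is.finite(out)] <- .LOG_FLOOR
  out
}

# sum(p * log p) with 0*log(0) := 0 (negative entropy of a belief vector)
.neg_entropy <- function(p) {
  nz <- p > 0
  sum(p[nz] * log(p[nz]))
}

# Categorical KL divergence KL[p || q] with 0*log(0) := 0.
# q entries are floored so that p-mass on a q-zero is finitely penalised.
.kl_cat <- function(p, q) {
  stopifnot(length(p) == length(q))
  nz <- p > 0
  sum(p[nz] * (log(p[nz]) - .safe_log(q[nz])))
}

# Shannon entropy of a probability vector.
.entropy <- function(p) -.neg_entropy(p)

.is_simplex <- function(x, tol = 1e-8) {
  is.numeric(x) && all(x >= -tol) && abs(sum(x) - 1) < tol
}

.check_column_stochastic <- function(M, name, tol = 1e-12) {
  if (any(M < 0)) {
    stop(sprintf("%s has negative entries", name), call. = FALSE)
  }
  cs <- colSums(M)
  bad <- which(abs(cs - 1) > tol)
  if (length(bad) > 0L) {
    stop(sprintf("%s column %d sums to %.15g, not 1", name, bad[1L], cs[bad[1L]]),
         call. = FALSE)
  }
  invisible(M)
}

# One-hot n-vector with 1 at index i.
.one_hot <- function(i, n) {
  v <- numeric(n)
  v[i] <- 1
  v
}

# log multivariate beta function of a positive vector.
.lbeta_vec <- function(a) sum(lgamma(a)) - lgamma(sum(a))
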