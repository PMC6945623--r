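# Independent oracles used across the suite.

# Global minimizer of 1/2 h'Vh + u'h over h >= 0 by active-set enumeration:
# for every support S, solve the unconstrained problem restricted to S and
# keep the feasible candidate with the smallest objective.  Exact for SPD V
# and small k.
nnqp_oracle <- function(V, u) {
  k <- length(u)
  qobj <- function(h) 0.5 * sum(h * (V %*% h)) + sum(u * h)
  best <- numeric(k)
  bestf <- qobj(best)
  for (bits in seq_len(2^k - 1)) {
    S <- which(bitwAnd(bits, 2^(seq_len(k) - 1)) > 0)
    sol <- tryCatch(solve(V[S, S, drop = FALSE], -u[S]),
                    error = function(e) NULL)
    if (is.null(sol) || any(sol < 0)) next
    h <- numeric(k)
    h[S] <- sol
    f <- qobj(h)
    if (f < bestf) {
      bestf <- f
      best <- h
    }
  }
  best
}

# Textbook multiplicative NMF rules (no penalties, no guards): one
# H-update followed by one W-update, as the alternating driver applies
# them.
lee_ref_step_mse <- function(A, W, H) {
  H <- H * crossprod(W, A) / (crossprod(W) %*% H)
  W <- W * tcrossprod(A, H) / (W %*% tcrossprod(H))
  list(W = W, H = H)
}

lee_ref_step_kl <- function(A, W, H) {
  WH <- W %*% H
  H <- H * crossprod(W, A / WH) / colSums(W)
  WH <- W %*% H
  W <- W * t(t((A / WH) %*% t(H)) / rowSums(H))
  list(W = W, H = H)
}

# Penalized KL objective over observed entries (sum convention).
kl_objective <- function(A, W, H, eps = 1e-16) {
  obs <- !is.na(A)
  a <- A[obs]
  y <- (W %*% H)[obs]
  yg <- pmax(y, eps)
  sum(ifelse(a > 0, a * log(a / yg), 0) - a + y)
}

# Random diagonally-dominant SPD quadratic instance for solver tests.
rand_nnqp <- function(k, m = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(runif((k + 4) * k), k + 4, k)
  V <- crossprod(W) + diag(runif(1, 0.1, 1), k)
  U <- matrix(rnorm(k * m, sd = 2), k, m)
  list(V = V, U = U)
}
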