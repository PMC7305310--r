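# Independent brute-force oracles, written directly from the stated
# estimator definitions. They share no code with the package internals.

# Two-traversal target-decoy q-values on a ranked list (best first):
# explicit loops, no vectorized shortcuts.
oracleQvalues <- function(isDecoy) {
  n <- length(isDecoy)
  raw <- numeric(n)
  d <- 0; t <- 0
  for (i in seq_len(n)) {
    if (isDecoy[i]) d <- d + 1 else t <- t + 1
    raw[i] <- if (t == 0) Inf else d / t
  }
  q <- numeric(n)
  m <- Inf
  for (i in rev(seq_len(n))) {
    m <- min(m, raw[i])
    q[i] <- m
  }
  pmin(q, 1)
}

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration over
# all tables with the observed margins.
oracleFisherP <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  xs <- max(0, k - n2):min(k, m)
  probs <- vapply(xs, function(x) stats::dhyper(x, m, n2, k), numeric(1))
  pObs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Circular sliding-window counts by direct enumeration.
oracleWindowCounts <- function(identified, halfWindow) {
  n <- length(identified)
  vapply(seq_len(n), function(i) {
    idx <- ((i - halfWindow - 1):(i + halfWindow - 1)) %% n + 1
    sum(identified[idx])
  }, numeric(1))
}
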