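# Independent brute-force oracles, written directly from the definitions
# with plain loops; deliberately share no code with the package internals.

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Full EWM-TOPSIS chain from the published equations, element by element.
oracle_ewm_topsis <- function(X, directions,
                              variant = c("weights-linear", "literal")) {
  variant <- match.arg(variant)
  m <- nrow(X); n <- ncol(X)
  z <- matrix(0, m, n)
  for (j in seq_len(n)) {
    lo <- min(X[, j]); hi <- max(X[, j])
    for (i in seq_len(m)) {
      z[i, j] <- if (directions[j] == "benefit")
        (X[i, j] - lo) / (hi - lo) else (hi - X[i, j]) / (hi - lo)
    }
  }
  e <- numeric(n)
  for (j in seq_len(n)) {
    s <- sum(z[, j])
    acc <- 0
    for (i in seq_len(m)) {
      p <- z[i, j] / s
      if (p > 0) acc <- acc + p * log(p)
    }
    e[j] <- -acc / log(m)
  }
  w <- (1 - e) / sum(1 - e)
  zp <- apply(z, 2, max); zn <- apply(z, 2, min)
  dp <- dn <- numeric(m)
  for (i in seq_len(m)) {
    if (variant == "weights-linear") {
      dp[i] <- sqrt(sum(w * (z[i, ] - zp)^2))
      dn[i] <- sqrt(sum(w * (z[i, ] - zn)^2))
    } else {
      dp[i] <- sqrt(sum((w * z[i, ] - w * zp)^2))
      dn[i] <- sqrt(sum((w * z[i, ] - w * zn)^2))
    }
  }
  tc <- dn / (dn + dp)
  list(z = z, e = e, w = w, d_plus = dp, d_minus = dn, closeness = tc,
       rank = order(order(-tc)))
}

random_indicator_table <- function(m, n, seed) {
  set.seed(seed)
  vals <- matrix(runif(m * n, 1, 100), m, n,
                 dimnames = list(paste0("o", 1:m), paste0("x", 1:n)))
  indicator_table(vals, "benefit")
}
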