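# Shared fixture builders. Everything is generated in code; no stored data.

# Random valid RDM over n items (Euclidean distances of a random config,
# so it is always embeddable and well-conditioned).
random_rdm <- function(n, dim = 3, seed = 1, items = NULL) {
  set.seed(seed)
  pts <- matrix(rnorm(n * dim), n, dim)
  euclidean_rdm(pts, items = items %||% sprintf("it%02d", seq_len(n)))
}

# Random RDM that is exactly embeddable when its entries are read as
# squared distances (used by planting oracles).
random_sq_rdm <- function(n, dim = 2, seed = 1, items = NULL) {
  set.seed(seed)
  pts <- matrix(rnorm(n * dim), n, dim)
  normalize_rdm(squared_euclidean_rdm(
    pts, items = items %||% sprintf("it%02d", seq_len(n))))
}

# Brute-force double-loop squared Euclidean distances.
brute_sq_euclid <- function(patterns) {
  n <- nrow(patterns)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum((patterns[i, ] - patterns[j, ])^2)
    }
  }
  d
}

# Exhaustive O(P^2) Kendall tau-a oracle: concordant minus discordant over
# all pair-of-pairs, divided by P(P-1)/2.
brute_tau_a <- function(x, y) {
  p <- length(x)
  s <- 0
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      s <- s + sign(x[i] - x[j]) * sign(y[i] - y[j])
    }
  }
  s / (p * (p - 1) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Residual after optimal translation/rotation/scaling of b onto a.
procrustes_error <- function(a, b) {
  a <- scale(a, scale = FALSE); b <- scale(b, scale = FALSE)
  s <- svd(crossprod(a, b))
  rot <- s$v %*% t(s$u)
  scl <- sum(s$d) / sum(b^2)
  sqrt(sum((a - scl * b %*% rot)^2) / sum(a^2))
}
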