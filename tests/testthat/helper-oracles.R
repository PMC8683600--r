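# Independent brute-force oracles, coded directly from the defining
# formulas and kept separate from the package implementations.

# Kruskal-Wallis H with tie correction, from the rank-sum definition.
oracle_kw <- function(x, g) {
  g <- as.character(g)
  N <- length(x)
  r <- rank(x)
  rs <- tapply(r, g, sum)
  ns <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(rs^2 / ns) - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Dunn pairwise z for groups a and b, from the defining formula.
oracle_dunn_z <- function(x, g, a, b) {
  g <- as.character(g)
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  ra <- mean(r[g == a]); rb <- mean(r[g == b])
  na <- sum(g == a); nb <- sum(g == b)
  (ra - rb) / sqrt((N * (N + 1) / 12 - tie_term) * (1 / na + 1 / nb))
}

# OLS coefficients from the normal equations.
oracle_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# Straight-line BCa interval for the mean, written independently but using
# the same documented resampling convention as the package (set.seed, one
# sample.int(n, n * B, replace = TRUE) call laid out n x B, type-7
# quantiles, half-weight for replicates tied with the observed mean).
oracle_bca_mean <- function(values, n_boot, seed, conf = 0.95) {
  n <- length(values)
  t0 <- mean(values)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  tstar <- colMeans(matrix(values[idx], nrow = n))
  z0 <- qnorm((sum(tstar < t0) + 0.5 * sum(tstar == t0)) / n_boot)
  jk <- sapply(seq_len(n), function(i) mean(values[-i]))
  d <- mean(jk) - jk
  a <- if (sum(d^2) == 0) 0 else sum(d^3) / (6 * sum(d^2)^1.5)
  zq <- qnorm(c((1 - conf) / 2, (1 + conf) / 2))
  adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  stats::quantile(tstar, adj, names = FALSE, type = 7)
}

ext_file <- function(name) {
  p <- system.file("extdata", name, package = "scaletrace")
  if (!nzchar(p)) stop("fixture not found: ", name)
  p
}
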