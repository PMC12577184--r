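# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written as plain transcriptions (explicit loops)
# so they share no code path with the package internals they check.

# Simulate one peptide block directly from the generative equations.
make_block <- function(seed, R = 4L, I = 3L, sigma_cp = 0.2, rho = 0.89,
                       delta = 0) {
  set.seed(seed)
  alpha <- rep(2, I)
  mu_p <- rnorm(1, 5, 1)
  zeta <- log10(rbeta(2, 2, 10))
  X <- matrix(NA_real_, R, 2L * I)
  for (r in seq_len(R)) {
    A <- rgamma(I, shape = rho * alpha)
    w1 <- A + rgamma(I, shape = (1 - rho) * alpha)
    w2 <- A + rgamma(I, shape = (1 - rho) * alpha)
    w1 <- w1 / sum(w1); w2 <- w2 / sum(w2)
    e <- rnorm(2, 0, sigma_cp)
    X[r, seq_len(I)] <- mu_p + zeta[1] + e[1] + log10(w1)
    X[r, I + seq_len(I)] <- mu_p + delta + zeta[2] + e[2] + log10(w2)
  }
  peptide_block(X, I, peptide = sprintf("pep_seed%d", seed))
}

# Brute-force expansion of the variance of L-hat over all (i, j, r, r')
# index combinations, applying the covariance block rules directly:
# same condition: a_ij if r = r', d otherwise; different conditions:
# b_ij (or b_ji) if r = r', 0 otherwise.
var_L_bruteforce <- function(a, b, d, R, I) {
  total <- 0
  for (i in seq_len(I)) for (j in seq_len(I)) {
    for (r1 in seq_len(R)) for (r2 in seq_len(R)) {
      # within condition 1 and within condition 2
      for (cc in 1:2) {
        total <- total + if (r1 == r2) a[i, j] else d
      }
      # cross-condition pairs, both orders, with a minus sign
      total <- total - if (r1 == r2) b[i, j] else 0
      total <- total - if (r1 == r2) b[j, i] else 0
    }
  }
  total / R^2
}

# Independent loop-wise transcription of the correlation-shrinkage intensity.
lambda_corr_oracle <- function(X) {
  R <- nrow(X); m <- ncol(X)
  xbar <- colMeans(X)
  s <- apply(X, 2, sd)
  num <- 0; den <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (s[i] == 0 || s[j] == 0) next
    w <- ((X[, i] - xbar[i]) / s[i]) * ((X[, j] - xbar[j]) / s[j])
    r_ij <- sum(w) / (R - 1)
    var_r <- R / (R - 1)^3 * sum((w - mean(w))^2)
    num <- num + var_r
    den <- den + r_ij^2
  }
  if (den <= 0) return(1)
  min(1, max(0, num / den))
}

# Independent loop-wise transcription of the variance-shrinkage intensity.
lambda_var_oracle <- function(X) {
  R <- nrow(X); m <- ncol(X)
  v_list <- lapply(seq_len(m), function(i) (X[, i] - mean(X[, i]))^2)
  s_ii <- vapply(v_list, function(v) sum(v) / (R - 1), numeric(1))
  s_med <- median(s_ii)
  num <- sum(vapply(v_list, function(v) {
    R / (R - 1)^3 * sum((v - mean(v))^2)
  }, numeric(1)))
  den <- sum((s_ii - s_med)^2)
  if (den <= 0) return(1)
  min(1, max(0, num / den))
}

# Random structured covariance satisfying the class invariants.
random_cov_structure <- function(seed, I) {
  set.seed(seed)
  d <- runif(1, 0, 0.2)
  W <- crossprod(matrix(rnorm((I + 2) * I), I + 2, I)) / (I + 2)
  b <- matrix(rnorm(I * I, 0, 0.05), I, I)
  cov_structure(a = d + W, b = b, d = d)
}
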