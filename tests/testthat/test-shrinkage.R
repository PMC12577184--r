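test_that("sample_moments: unbiased covariance, degenerate columns flagged", {
  X <- matrix(c(0, 1, 2, 0, 2, 4), 3, 2)
  m <- sample_moments(X)
  expect_equal(m$cov, matrix(c(1, 2, 2, 4), 2, 2))
  expect_equal(m$cor[1, 2], 1)
  expect_equal(m$means, c(1, 2))
  # identical columns: correlation exactly 1
  X2 <- cbind(rnorm(5), 0)
  X2[, 2] <- X2[, 1]
  expect_equal(sample_moments(X2)$cor[1, 2], 1)
  # constant column: zero variance, correlations flagged to 0
  X3 <- cbind(c(1, 2, 3, 4), 7)
  expect_warning(m3 <- sample_moments(X3), "zero-variance")
  expect_identical(m3$cov[2, 2], 0)
  expect_identical(m3$cor[1, 2], 0)
  expect_true(m3$zero_variance[2])
  expect_error(sample_moments(matrix(1:2, 1)), "replicates")
})

test_that("shrinkage intensities match the independent loop-wise oracle", {
  set.seed(5)
  for (k in 1:6) {
    bl <- make_block(k, R = c(3, 4, 6, 8, 16, 32)[k])
    expect_equal(estimate_lambda_corr(bl), lambda_corr_oracle(bl$x),
                 tolerance = 1e-12)
    expect_equal(estimate_lambda_var(bl), lambda_var_oracle(bl$x),
                 tolerance = 1e-12)
  }
})

test_that("shrinkage intensities match frozen corpcor reference values", {
  # values computed once with corpcor::cor.shrink / var.shrink (1.6.x)
  frozen <- list(
    list(seed = 1, R = 4,  l = 0.736371717021101, lv = 0.529362742066133),
    list(seed = 2, R = 3,  l = 0.487346951623556, lv = 0.569025873818731),
    list(seed = 3, R = 8,  l = 0.547798034263671, lv = 1),
    list(seed = 4, R = 16, l = 0.668489820095689, lv = 0.246268896090073),
    list(seed = 5, R = 64, l = 0.169108208298287, lv = 1)
  )
  for (f in frozen) {
    bl <- make_block(f$seed, R = f$R)
    expect_equal(estimate_lambda_corr(bl), f$l, tolerance = 1e-10)
    expect_equal(estimate_lambda_var(bl), f$lv, tolerance = 1e-10)
  }
})

test_that("lambda endpoints: zero estimator variance gives 0, noise ~1", {
  # columns whose standardized values are all +-c have constant products,
  # hence zero estimated estimator-variance and lambda = 0 exactly
  z <- c(1, 1, -1, -1)
  X <- cbind(z, 2 * z + 3, -z + 1, 0.5 * z)
  expect_equal(estimate_lambda_corr(X), 0)
  # independent N(0, 1) columns at large R: true correlations are 0 and the
  # intensity concentrates near full shrinkage (median over datasets)
  set.seed(8)
  lam <- replicate(20, estimate_lambda_corr(matrix(rnorm(64 * 6), 64, 6)))
  expect_gt(median(lam), 0.7)
  # all variances equal the median: full shrinkage, s* = s_median
  X3 <- matrix(rnorm(40), 10, 4)
  X3 <- scale(X3) * sqrt(1)   # unit variances
  fit <- shrink_covariance(peptide_block(cbind(X3), 2))
  expect_equal(fit$lambda_v, 1)
  expect_equal(diag(fit$sstar), rep(fit$s_median, 4))
})

test_that("shrink_covariance obeys the shrinkage algebra and PSD", {
  set.seed(9)
  bl <- make_block(31, R = 6)
  fit <- shrink_covariance(bl)
  m <- sample_moments(bl)
  # r* off-diagonal scaled by (1 - lambda), diagonal 1
  off <- upper.tri(fit$rstar)
  expect_equal(fit$rstar[off], (1 - fit$lambda) * m$cor[off])
  expect_equal(diag(fit$rstar), rep(1, 6))
  expect_true(all(abs(fit$rstar[off]) <= abs(m$cor[off]) + 1e-15))
  # s* recombines shrunk correlations and variances
  sd_star <- sqrt(diag(fit$sstar))
  expect_equal(fit$sstar, fit$rstar * outer(sd_star, sd_star))
  # PSD of the shrunk correlation matrix
  expect_gt(min(eigen(fit$rstar, symmetric = TRUE,
                      only.values = TRUE)$values), -1e-12)
  # lambda = lambda_v = 0 recovers the sample covariance exactly
  fit0 <- fit
  d0 <- diag(m$cov)
  expect_equal((1 - 0) * m$cor * outer(sqrt(d0), sqrt(d0)), m$cov,
               tolerance = 1e-12)
})

test_that("pool_conditions averages the within-condition blocks", {
  set.seed(12)
  bl <- make_block(55, R = 5)
  fit <- shrink_covariance(bl)
  I <- 3
  manual <- (fit$sstar[1:I, 1:I] + fit$sstar[I + 1:I, I + 1:I]) / 2
  pooled <- pool_conditions(fit)
  expect_equal(pooled, manual)
  expect_equal(pooled, t(pooled))
})

test_that("assemble_cov wires pooled, cross block and d together", {
  set.seed(13)
  bl <- make_block(77, R = 8)
  fit <- shrink_covariance(bl)
  cs <- assemble_cov(fit, d_hat = 0.1)
  expect_equal(cs$a, 0.1 + pool_conditions(fit))
  expect_equal(cs$b, fit$sstar[1:3, 4:6])
  expect_equal(cs$d, 0.1)
  expect_error(assemble_cov(fit, -0.1), "d_hat")
})

test_that("variance_of_L equals the brute-force quadruple-sum expansion", {
  k <- 0
  for (R in c(1L, 2L, 4L, 8L)) for (I in c(1L, 2L, 3L, 5L)) {
    for (rep in 1:3) {
      k <- k + 1
      cs <- random_cov_structure(1000 + k, I)
      v <- variance_of_L(cs, R, I)
      bf <- var_L_bruteforce(cs$a, cs$b, cs$d, R, I)
      expect_equal(v, bf, tolerance = 1e-12)
    }
  }
  # R = 1: the d term vanishes
  cs <- random_cov_structure(5, 3)
  expect_equal(variance_of_L(cs, 1, 3), 2 * (sum(cs$a) - sum(cs$b)),
               tolerance = 1e-12)
  # perfect cancellation floors at a positive epsilon with a warning
  a <- diag(3) * 0.5
  cs0 <- cov_structure(a = a, b = a, d = 0)
  expect_warning(v0 <- variance_of_L(cs0, 4, 3), "floored")
  expect_gt(v0, 0)
  expect_error(variance_of_L(cs, 4, 2), "mismatch")
})

test_that("shrinkage intensities decrease with R on model data (trend)", {
  set.seed(70)
  meds <- vapply(c(4L, 64L), function(R) {
    median(vapply(1:60, function(k) {
      estimate_lambda_corr(make_block(4000 + 100 * R + k, R = R))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(meds[2], meds[1])
})

test_that("d-hat is stable across disjoint halves of a large comparison", {
  p <- model_params(n_peptides = 1000L, sigma = 0)
  sim <- simulate_dataset(p, seed = 123)
  yq <- summarize_peptides(sim$table)
  peps <- unique(yq$peptide)
  d1 <- estimate_d(yq[yq$peptide %in% peps[1:500], ])$d
  d2 <- estimate_d(yq[yq$peptide %in% peps[501:1000], ])$d
  expect_lt(abs(d1 - d2) / max(d1, d2), 0.2)
})
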