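test_that("model_params validates shapes, rho and delta conventions", {
  p <- model_params()
  expect_s3_class(p, "model_params")
  expect_identical(p$alpha_dirichlet, c(2, 2, 2))
  expect_error(model_params(alpha0 = 0), "positive")
  expect_error(model_params(rho = 1.2), "rho")
  expect_error(model_params(alpha_dirichlet = c(2, -1, 2)), "positive")
  expect_error(model_params(delta_c = c(0.1, 0)), "delta_c\\[1\\]")
  # scalar effect size expands with reference condition at zero
  expect_identical(model_params(delta_c = 0.3)$delta_c, c(0, 0.3))
  # default Dirichlet shapes adapt to the fragment count
  expect_identical(model_params(n_fragments = 5L)$alpha_dirichlet, rep(2, 5))
})

test_that("logbeta_variance matches trigamma closed form, limits and MC", {
  expect_equal(logbeta_variance(2, 10), 0.1053, tolerance = 1e-3)
  expect_equal(logbeta_variance(2, 10),
               (trigamma(2) - trigamma(12)) / log(10)^2)
  # beta0 -> 0: u degenerates at 1, variance -> 0
  expect_lt(logbeta_variance(2, 1e-9), 1e-9)
  expect_error(logbeta_variance(-1, 2), "positive")
  # MC oracle for the uniform case Beta(1, 1)
  set.seed(42)
  x <- log10(runif(1e6))
  mc <- var(x)
  se <- sd((x - mean(x))^2) / sqrt(length(x))
  expect_lt(abs(logbeta_variance(1, 1) - mc), 3 * se)
})

test_that("logdirichlet_cov matches closed form, symmetry and edge cases", {
  m <- logdirichlet_cov(c(2, 2, 2))
  expect_equal(diag(m), rep(0.0874, 3), tolerance = 1e-3)
  expect_equal(m[1, 2], -0.0342, tolerance = 1e-3)
  expect_identical(m, t(m))
  expect_identical(logdirichlet_cov(5), matrix(0, 1, 1))
  expect_error(logdirichlet_cov(c(2, 0)), "positive")
  # asymmetric shapes stay symmetric as a matrix
  ma <- logdirichlet_cov(c(1, 3, 7))
  expect_identical(ma, t(ma))
  expect_equal(ma[1, 1], (trigamma(1) - trigamma(11)) / log(10)^2)
})

test_that("moment formulas agree with brute-force MC on randomized shapes", {
  set.seed(7)
  for (k in 1:5) {
    a0 <- runif(1, 0.5, 5); b0 <- runif(1, 0.5, 15)
    u <- rbeta(2e5, a0, b0)
    x <- log10(u)
    se <- sd((x - mean(x))^2) / sqrt(length(x))
    expect_lt(abs(logbeta_variance(a0, b0) - var(x)), 3 * se)
  }
  alpha <- c(0.8, 2.5, 4)
  g <- matrix(rgamma(3 * 2e5, shape = rep(alpha, each = 2e5)), ncol = 3)
  w <- g / rowSums(g)
  lx <- log10(w)
  truth <- logdirichlet_cov(alpha)
  for (i in 1:3) {
    x2 <- lx[, i]
    se <- sd((x2 - mean(x2))^2) / sqrt(length(x2))
    expect_lt(abs(truth[i, i] - var(x2)), 3 * se)
  }
})

test_that("sample_correlated_ionization: marginals, endpoints, monotonicity", {
  expect_error(sample_correlated_ionization(c(2, 2), rho = -0.1, n = 10),
               "rho")
  # rho = 1: identical weight vectors
  ws <- sample_correlated_ionization(c(2, 2, 2), 1, n = 200, seed = 1)
  expect_identical(ws$w1, ws$w2)
  # simplex conservation
  expect_equal(rowSums(ws$w1), rep(1, 200))
  # rho = 0: independence within MC error
  n <- 1e5
  ws0 <- sample_correlated_ionization(c(2, 2, 2), 0, n = n, seed = 2)
  r0 <- cor(ws0$w1[, 1], ws0$w2[, 1])
  expect_lt(abs(r0), 3 / sqrt(n))
  # marginal variance matches the closed-form Dirichlet variance (8/252)
  ws9 <- sample_correlated_ionization(c(2, 2, 2), 0.89, n = n, seed = 3)
  v <- ws9$w1[, 2]
  se <- sd((v - mean(v))^2) / sqrt(n)
  expect_lt(abs(var(v) - 8 / 252), 3 * se)
  # empirical coupling nondecreasing in rho
  cors <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(r) {
    ws <- sample_correlated_ionization(c(2, 2, 2), r, n = 2e4, seed = 4)
    cor(ws$w1[, 1], ws$w2[, 1])
  }, numeric(1))
  expect_true(all(diff(cors) > -0.02))
  expect_equal(cors[5], 1)
})

test_that("simulate_dataset reconstructs x from latents and conserves w", {
  p <- model_params(n_peptides = 30L, delta_c = 0.3)
  sim <- simulate_dataset(p, seed = 11)
  tab <- sim$table
  expect_equal(nrow(tab), 30 * 2 * 4 * 3)
  expect_true(all(tab$quantity > 0))
  expect_equal(tab$log10_quantity, log10(tab$quantity))
  # additive decomposition holds exactly
  lat <- sim$latents
  x_rebuilt <- with(tab, {
    mapply(function(cc, ii, rr, pp) {
      lat$mu_p[pp] + p$delta_c[cc] + lat$zeta_cp[cc, pp] +
        lat$e_crp[cc, rr, pp] + lat$xi_cirp[cc, ii, rr, pp]
    }, condition, fragment, replicate, as.integer(sub("pep", "", precursor)))
  })
  expect_equal(tab$log10_quantity, unname(x_rebuilt))
  # fragment shares reconstruct the simplex weights
  one <- tab[tab$precursor == "pep00001" & tab$condition == 1 &
               tab$replicate == 1, ]
  w <- one$quantity / sum(one$quantity)
  expect_equal(w, lat$w_cirp[1, , 1, 1])
  expect_equal(sum(lat$w_cirp[2, , 3, 7]), 1)
  # latent bounds
  expect_true(all(lat$u_cp > 0 & lat$u_cp <= 1))
  expect_true(all(lat$zeta_cp <= 0))
  expect_true(all(lat$mu_tilde_cp <= outer(p$delta_c, lat$mu_p, `+`)))
  # reproducibility: same seed, identical dataset
  sim2 <- simulate_dataset(p, seed = 11)
  expect_identical(sim$table, sim2$table)
})

test_that("simulated grand means and zeta variance match digamma oracles", {
  p <- model_params(n_peptides = 2000L)
  sim <- simulate_dataset(p, seed = 21)
  yq <- summarize_peptides(sim$table)
  target <- 5 + (digamma(2) - digamma(12)) / log(10)
  # y values within a peptide share mu_p and zeta: cluster by peptide for
  # an honest standard error
  pep_means <- tapply(yq$y, yq$peptide, mean)
  se <- sd(pep_means) / sqrt(length(pep_means))
  expect_lt(abs(mean(yq$y) - target), 4 * se)
  zeta <- as.numeric(sim$latents$zeta_cp)
  se_v <- sd((zeta - mean(zeta))^2) / sqrt(length(zeta))
  expect_lt(abs(var(zeta) - 0.1053), 3 * se_v + 1e-4)
})

test_that("true_cov_structure combines analytic and MC pieces", {
  cs <- true_cov_structure(model_params(), n_mc = 1e4, seed = 9)
  expect_s3_class(cs, "cov_structure")
  expect_equal(cs$d, 0.1053, tolerance = 1e-3)
  expect_equal(cs$a[1, 1] - cs$d, 0.1274, tolerance = 1e-3)
  expect_equal(cs$a[1, 2] - cs$d, 0.0058, tolerance = 1e-3)
  expect_identical(cs$b, t(cs$b))
  # rho = 0 gives a zero cross-condition block without MC
  cs0 <- true_cov_structure(model_params(rho = 0), n_mc = 1e4)
  expect_identical(cs0$b, matrix(0, 3, 3))
  expect_error(true_cov_structure(model_params(), n_mc = 100), "1e4")
})
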