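#' Construct a peptide block
#'
#' A peptide block is the complete data for one precursor in a two-condition
#' comparison: an R x 2I matrix of log10 fragment quantities whose rows are
#' replicates and whose columns are ordered (condition 1 fragments 1..I,
#' condition 2 fragments 1..I).  Replicates are paired across conditions by
#' row index.
#'
#' @param x Numeric R x 2I matrix (no missing entries, R >= 2).
#' @param n_fragments Number of fragments I (columns must equal 2I).
#' @param peptide Optional peptide identifier.
#' @return An object of class `"peptide_block"`.
#' @export
peptide_block <- function(x, n_fragments, peptide = NA_character_) {
  x <- as.matrix(x)
  I <- as.integer(n_fragments)
  if (!is.numeric(x) || anyNA(x)) stop("block matrix must be numeric, no NA")
  if (ncol(x) != 2L * I)
    stop("block must have 2 * n_fragments columns (both conditions)")
  if (nrow(x) < 2L) stop("insufficient replicates: R >= 2 required")
  structure(list(x = x, n_fragments = I, n_replicates = nrow(x),
                 peptide = peptide),
            class = "peptide_block")
}

as_block_matrix <- function(block) {
  if (inherits(block, "peptide_block")) block$x else as.matrix(block)
}

block_I <- function(block) {
  if (inherits(block, "peptide_block")) block$n_fragments
  else ncol(as.matrix(block)) %/% 2L
}

#' Sample moments of a peptide block
#'
#' Column means, unbiased (divisor R - 1) sample covariance, and sample
#' correlation over replicates.  Correlations involving a zero-variance
#' column are defined as 0 off the diagonal (1 on it) and flagged; such
#' columns are later excluded from the shrinkage-intensity sums.
#'
#' @param block A [peptide_block()] or a numeric R x 2I matrix.
#' @return List with `means`, `cov`, `cor`, and logical vector
#'   `zero_variance` marking degenerate columns.
#' @export
sample_moments <- function(block) {
  X <- as_block_matrix(block)
  R <- nrow(X)
  if (R < 2L) stop("insufficient replicates: R >= 2 required")
  means <- colMeans(X)
  Xc <- sweep(X, 2L, means)
  S <- crossprod(Xc) / (R - 1)
  s <- diag(S)
  zero <- s <= 0
  sd <- sqrt(pmax(s, 0))
  denom <- outer(sd, sd)
  Rm <- S / denom
  Rm[!is.finite(Rm)] <- 0
  diag(Rm) <- 1
  if (any(zero)) warning("zero-variance column(s) in block; correlations set to 0")
  list(means = means, cov = S, cor = Rm, zero_variance = zero)
}

# Lean internal moment/shrinkage fit used by every public entry point and by
# the bootstrap hot loop.  X is R x 2I, no validation.
shrink_fit_core <- function(X) {
  R <- nrow(X); m <- ncol(X)
  means <- colMeans(X)
  Xc <- X - rep(means, each = R)
  S <- crossprod(Xc) / (R - 1)
  s <- diag(S)
  zero <- s <= 0
  sd <- sqrt(pmax(s, 0))

  # --- correlation-shrinkage intensity (Schafer-Strimmer) ---
  ok <- !zero
  if (sum(ok) >= 2L) {
    Xs <- Xc[, ok, drop = FALSE] / rep(sd[ok], each = R)
    r_ok <- crossprod(Xs) / (R - 1)
    wbar <- r_ok * (R - 1) / R
    S2 <- crossprod(Xs * Xs)                 # sum_k xtilde_ki^2 xtilde_kj^2
    var_r <- R / (R - 1)^3 * (S2 - R * wbar^2)
    off <- upper.tri(r_ok)
    denom <- sum(r_ok[off]^2)
    lambda <- if (denom <= 0) 1 else min(1, max(0, sum(var_r[off]) / denom))
  } else {
    lambda <- 1
  }

  # --- variance-shrinkage intensity (Opgen-Rhein-Strimmer, median target) ---
  V <- Xc * Xc                               # v_ki = (x_ki - xbar_i)^2
  vbar <- colMeans(V)
  var_s <- R / (R - 1)^3 * colSums((V - rep(vbar, each = R))^2)
  s_median <- stats::median(s)
  denom_v <- sum((s - s_median)^2)
  lambda_v <- if (denom_v <= 0) 1 else min(1, max(0, sum(var_s) / denom_v))

  # --- shrunk correlations, variances, covariances ---
  Rm <- S / outer(sd, sd)
  Rm[!is.finite(Rm)] <- 0
  rstar <- (1 - lambda) * Rm
  diag(rstar) <- 1
  sstar_diag <- (1 - lambda_v) * s + lambda_v * s_median
  sstar <- rstar * sqrt(outer(sstar_diag, sstar_diag))

  list(means = means, cov = S, cor = { diag(Rm) <- 1; Rm },
       zero_variance = zero, lambda = lambda, lambda_v = lambda_v,
       s_median = s_median, rstar = rstar, sstar = sstar)
}

#' Correlation shrinkage intensity
#'
#' Analytic mean-squared-error-optimal intensity for shrinking the sample
#' correlations of a peptide block toward zero:
#' \deqn{\hat\lambda = clip\left(\frac{\sum_{i \ne j} \widehat{Var}(r_{ij})}
#' {\sum_{i \ne j} r_{ij}^2}, 0, 1\right),}
#' with \eqn{\widehat{Var}(r_{ij}) = \frac{R}{(R-1)^3} \sum_k (w_{kij} -
#' \bar w_{ij})^2} and \eqn{w_{kij} = \tilde x_{ki} \tilde x_{kj}} products of
#' standardized columns.  Zero-variance columns are excluded from both sums;
#' a zero denominator yields \eqn{\hat\lambda = 1} (full shrinkage to the
#' independence target).
#'
#' @inheritParams sample_moments
#' @return \eqn{\hat\lambda} in \[0, 1\].
#' @export
estimate_lambda_corr <- function(block) {
  X <- as_block_matrix(block)
  if (nrow(X) < 2L) stop("insufficient replicates: R >= 2 required")
  shrink_fit_core(X)$lambda
}

#' Variance shrinkage intensity
#'
#' Intensity for shrinking each sample variance toward the median of all
#' column sample variances:
#' \deqn{\hat\lambda_v = clip\left(\frac{\sum_i \widehat{Var}(s_{ii})}
#' {\sum_i (s_{ii} - s_{median})^2}, 0, 1\right),}
#' with \eqn{\widehat{Var}(s_{ii}) = \frac{R}{(R-1)^3} \sum_k (v_{ki} -
#' \bar v_i)^2}, \eqn{v_{ki} = (x_{ki} - \bar x_i)^2}.  When all variances
#' equal the median the denominator vanishes and \eqn{\hat\lambda_v = 1}.
#'
#' @inheritParams sample_moments
#' @return \eqn{\hat\lambda_v} in \[0, 1\].
#' @export
estimate_lambda_var <- function(block) {
  X <- as_block_matrix(block)
  if (nrow(X) < 2L) stop("insufficient replicates: R >= 2 required")
  shrink_fit_core(X)$lambda_v
}

#' Shrinkage estimate of the block covariance
#'
#' James-Stein-type shrinkage of the 2I x 2I covariance of a peptide block:
#' sample correlations are shrunk toward zero with intensity \eqn{\hat\lambda}
#' and sample variances toward their median with intensity
#' \eqn{\hat\lambda_v}; the shrunk covariance recombines them as
#' \eqn{s^*_{jk} = r^*_{jk} \sqrt{s^*_{jj} s^*_{kk}}}.  The shrunk correlation
#' matrix \eqn{(1-\hat\lambda) R + \hat\lambda Id} is a convex combination of
#' positive semidefinite matrices, hence positive semidefinite.
#'
#' @inheritParams sample_moments
#' @return An object of class `"shrinkage_fit"`: list with `means`, `cov`,
#'   `cor`, `zero_variance`, `lambda`, `lambda_v`, `s_median`, `rstar`,
#'   `sstar` (2I x 2I), `pooled` (I x I within-condition average), and
#'   `n_fragments`, `n_replicates`.
#' @examples
#' X <- matrix(rnorm(24), 4, 6)
#' fit <- shrink_covariance(peptide_block(X, 3))
#' fit$lambda
#' @export
shrink_covariance <- function(block) {
  X <- as_block_matrix(block)
  I <- block_I(block)
  if (nrow(X) < 2L) stop("insufficient replicates: R >= 2 required")
  if (ncol(X) != 2L * I) stop("block must have 2 * n_fragments columns")
  fit <- shrink_fit_core(X)
  if (any(fit$zero_variance))
    warning("zero-variance column(s); their correlations treated as 0")
  fit$n_fragments <- I
  fit$n_replicates <- nrow(X)
  fit$pooled <- (fit$sstar[seq_len(I), seq_len(I)] +
                   fit$sstar[I + seq_len(I), I + seq_len(I)]) / 2
  class(fit) <- "shrinkage_fit"
  fit
}

#' @export
print.shrinkage_fit <- function(x, ...) {
  cat(sprintf("Shrinkage fit: 2I = %d columns, R = %d replicates\n",
              2L * x$n_fragments, x$n_replicates))
  cat(sprintf("  lambda = %.4f (correlations), lambda_v = %.4f (variances)\n",
              x$lambda, x$lambda_v))
  invisible(x)
}

#' Pool shrunk covariances across conditions
#'
#' Under the equal-covariance assumption the two within-condition shrunk
#' covariance blocks estimate the same quantity; their elementwise average
#' is the pooled I x I block used for the `a` entries.
#'
#' @param fit A [shrink_covariance()] fit.
#' @return I x I pooled within-condition shrunk covariance.
#' @export
pool_conditions <- function(fit) {
  stopifnot(inherits(fit, "shrinkage_fit"))
  I <- fit$n_fragments
  (fit$sstar[seq_len(I), seq_len(I)] +
      fit$sstar[I + seq_len(I), I + seq_len(I)]) / 2
}

#' Assemble the structured covariance from a shrinkage fit
#'
#' Combines the pooled within-condition shrunk covariance with the globally
#' estimated cross-replicate covariance:
#' \eqn{\hat a_{i_1 i_2} = \hat d + s^*_{\cdot i_1, \cdot i_2}},
#' \eqn{\hat b_{i_1 i_2} = s^*_{1 i_1, 2 i_2}} (the cross-condition shrunk
#' block), \eqn{d = \hat d}.
#'
#' @param fit A [shrink_covariance()] fit.
#' @param d_hat Nonnegative scalar, typically from [estimate_d()].
#' @return A [cov_structure()] object.
#' @export
assemble_cov <- function(fit, d_hat) {
  stopifnot(inherits(fit, "shrinkage_fit"), is.numeric(d_hat),
            length(d_hat) == 1L, d_hat >= 0)
  I <- fit$n_fragments
  a <- d_hat + pool_conditions(fit)
  b <- fit$sstar[seq_len(I), I + seq_len(I), drop = FALSE]
  cov_structure(a = a, b = b, d = d_hat)
}

#' Variance of the shrinkage mean-difference estimate
#'
#' Closed form for the variance of \eqn{\hat L_{shrink} = \sum_i (\bar x_{1i}
#' - \bar x_{2i})} under the structured covariance:
#' \deqn{Var(\hat L) = \frac{2}{R} \sum_{ij} a_{ij} - \frac{2}{R} \sum_{ij}
#' b_{ij} + \frac{2 I^2 (R - 1)}{R} d.}
#' Because the entries are plug-in estimates the expression can be
#' nonpositive at small R; in that case it is floored at
#' \eqn{\varepsilon = 10^{-12} \cdot} (mean shrunk variance) with a warning.
#'
#' @param cov A [cov_structure()] object.
#' @param R Number of replicates per condition (>= 1).
#' @param I Number of fragments; must match the dimension of `cov`.
#' @return A strictly positive variance.
#' @export
variance_of_L <- function(cov, R, I) {
  stopifnot(inherits(cov, "cov_structure"), R >= 1)
  if (nrow(cov$a) != I) stop("dimension mismatch: cov is not I x I")
  v <- (2 / R) * (sum(cov$a) - sum(cov$b)) + (2 * I^2 * (R - 1) / R) * cov$d
  if (v <= 0) {
    eps <- max(1e-12 * mean(diag(cov$a)), .Machine$double.xmin)
    warning(sprintf("nonpositive plug-in variance (%.3g); floored at %.3g",
                    v, eps))
    v <- eps
  }
  v
}

# Fast path for the bootstrap: L-hat and Var(L-hat) from a raw R x 2I matrix
# with a fixed d; no object construction, no warnings.
shrink_L_var <- function(X, I, d_hat) {
  R <- nrow(X)
  fit <- shrink_fit_core(X)
  idx1 <- seq_len(I); idx2 <- I + idx1
  L <- sum(fit$means[idx1] - fit$means[idx2])
  pooled <- (fit$sstar[idx1, idx1] + fit$sstar[idx2, idx2]) / 2
  a <- d_hat + pooled
  b <- fit$sstar[idx1, idx2]
  v <- (2 / R) * (sum(a) - sum(b)) + (2 * I^2 * (R - 1) / R) * d_hat
  if (v <= 0) v <- max(1e-12 * mean(diag(a)), .Machine$double.xmin)
  list(L = L, var_L = v, lambda = fit$lambda, lambda_v = fit$lambda_v)
}
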