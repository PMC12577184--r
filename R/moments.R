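#' Variance of the log10 of a Beta random variable
#'
#' Closed-form variance of \eqn{\zeta = \log_{10} u} with
#' \eqn{u \sim Beta(\alpha_0, \beta_0)}.  This is the cross-replicate
#' covariance entry `d` of the structured covariance: all fragments of one
#' peptide within a condition share the acquisition-rate draw, so
#' \eqn{d = Var(\zeta_c^p)}.
#'
#' Uses the polygamma moments of the Beta law:
#' \deqn{Var(\log_{10} u) = (\psi'(\alpha_0) - \psi'(\alpha_0 + \beta_0)) /
#' (\ln 10)^2,}
#' with \eqn{\psi'} the trigamma function.  For the default Beta(2, 10) this
#' evaluates to 0.1053.
#'
#' @param alpha0,beta0 Strictly positive shape parameters.
#' @return The variance (log10-squared units), a single nonnegative number.
#' @examples
#' logbeta_variance(2, 10) # 0.1053
#' @export
logbeta_variance <- function(alpha0, beta0) {
  if (!(is.numeric(alpha0) && is.numeric(beta0) &&
        all(alpha0 > 0) && all(beta0 > 0)))
    stop("alpha0 and beta0 must be strictly positive")
  (trigamma(alpha0) - trigamma(alpha0 + beta0)) / log(10)^2
}

#' Mean of the log10 of a Beta random variable
#'
#' \eqn{E[\log_{10} u] = (\psi(\alpha_0) - \psi(\alpha_0 + \beta_0)) / \ln 10}
#' for \eqn{u \sim Beta(\alpha_0, \beta_0)}; always nonpositive.
#'
#' @inheritParams logbeta_variance
#' @return The mean (log10 units), a single nonpositive number.
#' @export
logbeta_mean <- function(alpha0, beta0) {
  if (!(is.numeric(alpha0) && is.numeric(beta0) &&
        all(alpha0 > 0) && all(beta0 > 0)))
    stop("alpha0 and beta0 must be strictly positive")
  (digamma(alpha0) - digamma(alpha0 + beta0)) / log(10)
}

#' Covariance matrix of log10 Dirichlet coordinates
#'
#' Closed-form covariance of \eqn{\xi_i = \log_{10} w_i} for
#' \eqn{(w_1, \ldots, w_I) \sim Dirichlet(\alpha_1, \ldots, \alpha_I)}:
#' \deqn{Cov(\xi_i, \xi_j) = (\psi'(\alpha_i) 1[i=j] - \psi'(\alpha_{tot}))
#' / (\ln 10)^2, \quad \alpha_{tot} = \sum_k \alpha_k.}
#' These are the within-condition, within-replicate ionization-efficiency
#' covariances of the generative model.  For Dirichlet(2, 2, 2) the diagonal
#' is 0.0874 and the off-diagonal is -0.0342.
#'
#' The I = 1 simplex is degenerate (w = 1 always) and returns the 1 x 1 zero
#' matrix.
#'
#' @param alpha Positive numeric vector of Dirichlet shapes.
#' @return An I x I symmetric covariance matrix (log10-squared units).
#' @examples
#' logdirichlet_cov(c(2, 2, 2))
#' @export
logdirichlet_cov <- function(alpha) {
  if (!(is.numeric(alpha) && length(alpha) >= 1L && all(alpha > 0)))
    stop("alpha must be a positive numeric vector")
  I <- length(alpha)
  if (I == 1L) return(matrix(0, 1L, 1L))
  atot <- sum(alpha)
  m <- matrix(-trigamma(atot), I, I)
  diag(m) <- trigamma(alpha) - trigamma(atot)
  m / log(10)^2
}

#' Structured covariance of log10 fragment quantities
#'
#' Construct the population covariance entries of the generative model for a
#' two-condition design:
#' \describe{
#'   \item{a}{within-condition, same-replicate: \eqn{a_{i_1 i_2} = Var(\zeta)
#'     + \sigma_{cp}^2 + Cov(\xi_{i_1}, \xi_{i_2})} (the sampling-error
#'     variance enters every entry because the error is shared by all
#'     fragments of one run);}
#'   \item{b}{cross-condition, same-replicate: \eqn{b_{i_1 i_2} =
#'     Cov(\xi_{1 i_1}, \xi_{2 i_2})}, estimated by Monte Carlo over
#'     [sample_correlated_ionization()] draws because the normalized
#'     cross-condition coupling has no convenient closed form;}
#'   \item{d}{within-condition, cross-replicate: \eqn{d = Var(\zeta)}, from
#'     [logbeta_variance()].}
#' }
#' Cross-condition, cross-replicate covariances are zero.
#'
#' @param params A [model_params()] object.
#' @param n_mc Number of Monte Carlo draws for the `b` block (>= 1e4).
#' @param seed Seed for the Monte Carlo draws.
#' @return An object of class `"cov_structure"`: list with `a` (I x I),
#'   `b` (I x I), `d` (scalar).
#' @examples
#' cs <- true_cov_structure(model_params(), n_mc = 1e4, seed = 1)
#' cs$a[1, 1] - cs$d # 0.1274
#' @export
true_cov_structure <- function(params = model_params(), n_mc = 1e5,
                               seed = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (n_mc < 1e4) stop("n_mc must be at least 1e4")
  I <- params$n_fragments
  d <- logbeta_variance(params$alpha0, params$beta0)
  a <- d + params$sigma_cp^2 + logdirichlet_cov(params$alpha_dirichlet)
  if (params$rho == 0) {
    b <- matrix(0, I, I)
  } else {
    ws <- sample_correlated_ionization(params$alpha_dirichlet, params$rho,
                                       n = n_mc, seed = seed)
    b <- stats::cov(log10(ws$w1), log10(ws$w2))
    # population symmetry Cov(xi_1i, xi_2j) = Cov(xi_1j, xi_2i): symmetrize MC
    b <- (b + t(b)) / 2
  }
  cov_structure(a = a, b = b, d = d)
}

#' Construct/validate a structured covariance object
#'
#' @param a I x I symmetric matrix of within-condition same-replicate
#'   covariances.
#' @param b I x I matrix of cross-condition same-replicate covariances.
#' @param d Scalar within-condition cross-replicate covariance (>= 0).
#' @return An object of class `"cov_structure"`.
#' @export
cov_structure <- function(a, b, d) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(d), length(d) == 1L)
  if (nrow(a) != ncol(a) || any(dim(b) != dim(a)))
    stop("a and b must be square matrices of equal dimension")
  if (max(abs(a - t(a))) > 1e-8 * (1 + max(abs(a))))
    stop("a must be symmetric")
  if (d < 0) stop("d must be nonnegative")
  if (any(diag(a) < d - 1e-12))
    stop("diagonal of a must be >= d")
  structure(list(a = a, b = b, d = as.numeric(d)), class = "cov_structure")
}

#' @export
print.cov_structure <- function(x, ...) {
  I <- nrow(x$a)
  cat(sprintf("Structured covariance (I = %d fragments)\n", I))
  cat(sprintf("  d = %.4f\n", x$d))
  cat(sprintf("  a - d: diag %.4f, offdiag %s\n", x$a[1, 1] - x$d,
              if (I > 1) sprintf("%.4f", x$a[1, 2] - x$d) else "-"))
  cat(sprintf("  b: diag %.4f, offdiag %s\n", x$b[1, 1],
              if (I > 1) sprintf("%.4f", x$b[1, 2]) else "-"))
  invisible(x)
}
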