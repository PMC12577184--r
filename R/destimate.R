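#' Mode of a sample by kernel density estimation
#'
#' Argmax of a Gaussian-kernel density estimate evaluated on a 512-point grid
#' spanning the data range plus/minus 3 bandwidths, with the rule-of-thumb
#' bandwidth \eqn{0.9 \min(sd, IQR/1.34) n^{-1/5}} (the defaults of
#' [stats::density()]).  Ties break toward the smallest grid point.
#'
#' @param values Numeric vector.
#' @return The mode, with attribute `degenerate = TRUE` when fewer than two
#'   distinct values are supplied (the single value is returned as-is).
#' @export
kde_mode <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values")
  if (length(unique(values)) < 2L)
    return(structure(values[1L], degenerate = TRUE))
  dens <- stats::density(values, bw = "nrd0", kernel = "gaussian",
                         n = 512L, cut = 3)
  dens$x[which.max(dens$y)]
}

#' Split-quantile standard deviation around a mode
#'
#' Robust estimate of the SD of the symmetric component of a skewed sample.
#' The values are split at the mode `M` into left deviations
#' \eqn{Z_1 = \{M - \bar z : \bar z \le M\}} and right deviations
#' \eqn{Z_2 = \{\bar z - M : \bar z > M\}}; the estimate is
#' \deqn{\min_{s, \tilde p} \; quantile(Z_s, \tilde p) \, / \,
#' \Phi^{-1}(0.5 + \tilde p / 2)}
#' over \eqn{\tilde p \in \{0.30, 0.31, \ldots, 0.99\}} (linear-interpolation
#' quantiles).  For a normal sample each ratio estimates the SD; taking the
#' minimum discounts the skewed tail.  An empty side is excluded.
#'
#' @param values Numeric vector.
#' @param mode Split point M (e.g. from [kde_mode()]).
#' @param p_grid Probability grid (default `seq(0.30, 0.99, by = 0.01)`).
#' @return Nonnegative SD estimate.
#' @export
split_quantile_sd <- function(values, mode,
                              p_grid = seq(0.30, 0.99, by = 0.01)) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values")
  z1 <- mode - values[values <= mode]
  z2 <- values[values > mode] - mode
  denom <- stats::qnorm(0.5 + p_grid / 2)
  cands <- c(
    if (length(z1)) stats::quantile(z1, p_grid, names = FALSE, type = 7) / denom,
    if (length(z2)) stats::quantile(z2, p_grid, names = FALSE, type = 7) / denom
  )
  min(cands)
}

#' Estimate the cross-replicate covariance d
#'
#' Estimates \eqn{d = Var(\zeta_c^p)}, the covariance between log10 fragment
#' quantities of different replicates within a condition, from the summarized
#' peptide quantities of a whole two-condition comparison.  Procedure:
#' median-normalize \eqn{z_{cr}^p = y_{cr}^p - m_c^y + m^y} (removes the
#' condition offset), average over replicates to \eqn{\bar z_c^p} (an
#' instance of \eqn{\mu^p + \delta + \zeta_c^p}), estimate its total variance
#' by the sample variance, estimate \eqn{Var(\mu^p)} by [kde_mode()] +
#' [split_quantile_sd()] (the \eqn{\bar z} distribution is left-skewed by
#' \eqn{\zeta \le 0} while \eqn{\mu^p} is symmetric), and subtract:
#' \eqn{\hat d = max(0, \widehat{Var}(\bar z) - \widehat{Var}(\mu^p))}.
#'
#' @param peptide_quantities `data.frame` with columns `peptide`,
#'   `condition`, `replicate`, `y` (log10 summarized peptide quantity), one
#'   row per run; e.g. from [summarize_peptides()].  At least 50 peptides
#'   recommended.
#' @return An object of class `"d_estimate"`: list with `d`, `var_total`
#'   (\eqn{\widehat{Var}(\mu^p + \delta + \zeta)}), `sd_mu`, `var_mu`,
#'   `mode`, `m_c`, `m`, `zbar` (per peptide x condition means), `n_means`.
#' @examples
#' sim <- simulate_dataset(model_params(n_peptides = 100), seed = 1)
#' yq <- summarize_peptides(sim$table)
#' estimate_d(yq)$d
#' @export
estimate_d <- function(peptide_quantities) {
  pq <- as.data.frame(peptide_quantities)
  need <- c("peptide", "condition", "replicate", "y")
  if (!all(need %in% names(pq)))
    stop("peptide_quantities must have columns ", paste(need, collapse = ", "))
  cond <- as.character(pq$condition)
  m_c <- tapply(pq$y, cond, stats::median)
  m <- stats::median(pq$y)
  z <- pq$y - m_c[cond] + m
  key <- interaction(pq$peptide, cond, drop = TRUE)
  zbar <- tapply(z, key, mean)
  if (length(zbar) < 2L)
    stop("need at least 2 peptide-condition means to estimate d")
  var_total <- stats::var(as.numeric(zbar))
  mode_z <- kde_mode(as.numeric(zbar))
  sd_mu <- split_quantile_sd(as.numeric(zbar), mode_z)
  d <- max(0, var_total - sd_mu^2)
  structure(
    list(d = d, var_total = var_total, sd_mu = sd_mu, var_mu = sd_mu^2,
         mode = as.numeric(mode_z), m_c = m_c, m = m,
         zbar = as.numeric(zbar), n_means = length(zbar)),
    class = "d_estimate"
  )
}

#' @export
print.d_estimate <- function(x, ...) {
  cat(sprintf(
    "d estimate: %.4f  (total var %.4f - mode-split var %.4f, %d means)\n",
    x$d, x$var_total, x$var_mu, x$n_means))
  invisible(x)
}
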