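#' Classification metrics for a simulated test
#'
#' Specificity = fraction of null peptides with \eqn{p \ge \alpha};
#' sensitivity = fraction of alternative peptides with \eqn{p < \alpha};
#' accuracy = 0.95 specificity + 0.05 sensitivity, the expected
#' contingency-table accuracy of a screening mixture in which 95% of
#' peptides are null.  Metrics whose class is empty are reported as `NA`.
#'
#' @param pvalues Numeric vector of p-values.
#' @param truth Logical (or 0/1) vector, `TRUE` for alternative peptides.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return Named list `specificity`, `sensitivity`, `accuracy`.
#' @export
classification_metrics <- function(pvalues, truth, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  truth <- as.logical(truth)
  if (length(truth) != length(pvalues)) stop("length mismatch")
  spec <- if (any(!truth)) mean(pvalues[!truth] >= alpha) else NA_real_
  sens <- if (any(truth)) mean(pvalues[truth] < alpha) else NA_real_
  acc <- if (!is.na(spec) && !is.na(sens)) 0.95 * spec + 0.05 * sens
         else NA_real_
  list(specificity = spec, sensitivity = sens, accuracy = acc)
}

#' Simulation experiment grid
#'
#' Axes of the simulation benchmark.  Defaults mirror the package's standard
#' evaluation setting: replicate counts 4 to 64, Beta acquisition-rate pairs
#' (2, 10), (4, 28), (11, 91) (equal means, decreasing variance), noise SDs
#' 0.05 to 0.8, and effect sizes 0, log10(2), log10(4).
#'
#' @param replicates Integer vector of replicate counts.
#' @param beta_pairs List of length-2 vectors `(alpha0, beta0)`.
#' @param sigma_cp Numeric vector of sampling-error SDs.
#' @param delta Numeric vector of effect sizes (log10 units; 0 = null cell).
#' @param methods Character subset of shrinkage / paired / independent.
#' @param n_peptides Peptides per simulated dataset.
#' @param n_datasets Simulated datasets per cell (default 1).
#' @param B Bootstrap resamples for the shrinkage method.
#' @param base_seed Base seed; per-cell seeds are derived deterministically.
#' @return An object of class `"experiment_grid"`.
#' @export
experiment_grid <- function(replicates = c(4L, 8L, 16L, 32L, 64L),
                            beta_pairs = list(c(2, 10), c(4, 28), c(11, 91)),
                            sigma_cp = seq(0.05, 0.8, by = 0.05),
                            delta = c(0, log10(2), log10(4)),
                            methods = c("shrinkage", "paired", "independent"),
                            n_peptides = 500L,
                            n_datasets = 1L,
                            B = 100L,
                            base_seed = 1L) {
  stopifnot(length(replicates) > 0, length(beta_pairs) > 0,
            length(sigma_cp) > 0, length(delta) > 0, length(methods) > 0,
            n_datasets >= 1L)
  methods <- match.arg(methods, c("shrinkage", "paired", "independent"),
                       several.ok = TRUE)
  structure(
    list(replicates = as.integer(replicates), beta_pairs = beta_pairs,
         sigma_cp = sigma_cp, delta = delta, methods = methods,
         n_peptides = as.integer(n_peptides),
         n_datasets = as.integer(n_datasets), B = as.integer(B),
         base_seed = as.integer(base_seed)),
    class = "experiment_grid"
  )
}

#' Run the simulation benchmark
#'
#' For every grid cell (replicate count x beta pair x noise SD x effect
#' size x dataset repeat), simulates a dataset of `n_peptides` peptides all
#' carrying that cell's effect size, applies each method, and computes the
#' metric the cell identifies (specificity for \eqn{\delta = 0} cells,
#' sensitivity for \eqn{\delta > 0} cells) at `alpha`.  Accuracy
#' (0.95 specificity + 0.05 sensitivity) is attached to \eqn{\delta > 0}
#' rows whose matching null cell exists.  Per-cell seeds are derived from
#' `base_seed` so cells are independent and order-insensitive; rerunning any
#' cell reproduces its metrics exactly.  Failing cells are recorded with
#' `NA` metrics rather than aborting the study.
#'
#' @param grid An [experiment_grid()].
#' @param alpha Significance level (default 0.05).
#' @return `data.frame`, one row per cell x method x dataset: grid
#'   coordinates plus `specificity`, `sensitivity`, `accuracy`, `seed`.
#' @export
run_simulation_study <- function(grid = experiment_grid(), alpha = 0.05) {
  stopifnot(inherits(grid, "experiment_grid"))
  cells <- expand.grid(
    i_rep = seq_along(grid$replicates),
    i_beta = seq_along(grid$beta_pairs),
    i_sigma = seq_along(grid$sigma_cp),
    i_delta = seq_along(grid$delta),
    dataset = seq_len(grid$n_datasets),
    KEEP.OUT.ATTRS = FALSE
  )
  rows <- vector("list", nrow(cells) * length(grid$methods))
  k <- 0L
  for (ci in seq_len(nrow(cells))) {
    cc <- cells[ci, ]
    R <- grid$replicates[cc$i_rep]
    bp <- grid$beta_pairs[[cc$i_beta]]
    sg <- grid$sigma_cp[cc$i_sigma]
    dl <- grid$delta[cc$i_delta]
    cell_index <- (cc$i_rep - 1L) +
      1000L * ((cc$i_beta - 1L) + 100L * ((cc$i_sigma - 1L) +
        100L * ((cc$i_delta - 1L) + 100L * (cc$dataset - 1L))))
    seed <- derive_seed(grid$base_seed, cell_index)
    params <- model_params(n_replicates = R, n_peptides = grid$n_peptides,
                           sigma_cp = sg, alpha0 = bp[1L], beta0 = bp[2L],
                           delta_c = dl)
    sim <- try(simulate_dataset(params, seed = seed), silent = TRUE)
    for (method in grid$methods) {
      k <- k + 1L
      met <- list(specificity = NA_real_, sensitivity = NA_real_,
                  accuracy = NA_real_)
      if (!inherits(sim, "try-error")) {
        res <- try(run_differential_tests(sim, method = method, B = grid$B,
                                          seed = derive_seed(seed, 7L)),
                   silent = TRUE)
        if (!inherits(res, "try-error")) {
          met <- classification_metrics(res$p_value,
                                        truth = rep(dl > 0, nrow(res)),
                                        alpha = alpha)
        }
      }
      rows[[k]] <- data.frame(
        R = R, alpha0 = bp[1L], beta0 = bp[2L], sigma_cp = sg, delta = dl,
        dataset = cc$dataset, method = method,
        specificity = met$specificity, sensitivity = met$sensitivity,
        accuracy = NA_real_, seed = seed, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  # accuracy: join each delta > 0 row with its matching null cell
  null_rows <- out[out$delta == 0, , drop = FALSE]
  for (r in which(out$delta > 0)) {
    m <- null_rows[null_rows$R == out$R[r] &
                     null_rows$alpha0 == out$alpha0[r] &
                     null_rows$beta0 == out$beta0[r] &
                     null_rows$sigma_cp == out$sigma_cp[r] &
                     null_rows$dataset == out$dataset[r] &
                     null_rows$method == out$method[r], , drop = FALSE]
    if (nrow(m) == 1L && !is.na(m$specificity) && !is.na(out$sensitivity[r]))
      out$accuracy[r] <- 0.95 * m$specificity + 0.05 * out$sensitivity[r]
  }
  rownames(out) <- NULL
  out
}

#' Coefficient-of-variation sweep over the bootstrap constant
#'
#' For each candidate stabilization constant \eqn{a_R}, computes the
#' per-peptide coefficient of variation \eqn{CV = sd / |mean|} of the B
#' bootstrap statistics \eqn{t^*_b} on a simulated dataset, and reports the
#' median CV across peptides.  The selection rule reports the smallest grid
#' value beyond which the CV curve changes by less than 10% of its maximum
#' (the flat region).  A shared resampling seed is used across the grid so
#' curves differ only through \eqn{a_R}.
#'
#' @param params A [model_params()] object.
#' @param a_grid Positive vector of candidate constants (increasing).
#' @param B Bootstrap resamples per peptide.
#' @param seed Seed for the dataset and the resampling.
#' @param n_peptides Number of peptides to evaluate (subset for speed).
#' @return List with `cv` (`data.frame` of `a_R`, `cv`) and `selected`
#'   (smallest admissible constant).
#' @export
cv_sweep_aR <- function(params = model_params(),
                        a_grid = c(0.05, 0.1, 0.2, 0.3, 0.5, 1, 2),
                        B = 100L, seed = 1L, n_peptides = 50L) {
  if (any(a_grid <= 0)) stop("a_R grid must be positive")
  a_grid <- sort(a_grid)
  sim <- simulate_dataset(params, seed = seed)
  blocks <- select_complete_blocks(sim$table,
                                   n_fragments = params$n_fragments)
  blocks <- blocks[seq_len(min(n_peptides, length(blocks)))]
  d_hat <- estimate_d(summarize_peptides(sim$table,
                                         params$n_fragments))$d
  R <- params$n_replicates
  cv_mat <- matrix(NA_real_, length(blocks), length(a_grid))
  for (k in seq_along(blocks)) {
    X <- blocks[[k]]$x
    I <- blocks[[k]]$n_fragments
    boot <- with_seed(derive_seed(seed, k), {
      idx <- matrix(sample.int(R, R * B, replace = TRUE), nrow = B)
      t(vapply(seq_len(B), function(b) {
        res <- shrink_L_var(X[idx[b, ], , drop = FALSE], I, d_hat)
        c(res$L, sqrt(res$var_L))
      }, numeric(2L)))
    })
    for (j in seq_along(a_grid)) {
      ts <- boot[, 1L] / (boot[, 2L] + a_grid[j])
      mu <- mean(ts)
      cv_mat[k, j] <- if (mu == 0) NA_real_ else stats::sd(ts) / abs(mu)
    }
  }
  cv <- apply(cv_mat, 2L, stats::median, na.rm = TRUE)
  # flat-region rule: smallest a beyond which successive changes stay small
  thr <- 0.1 * max(cv)
  ok <- rev(cumprod(rev(c(abs(diff(cv)) < thr, TRUE)))) > 0
  selected <- a_grid[which(ok)[1L]]
  list(cv = data.frame(a_R = a_grid, cv = cv), selected = selected)
}

#' Convergence experiment for shrinkage and covariance estimates
#'
#' For each replicate count in `R_grid`, simulates a null dataset under
#' `params`, fits the per-peptide shrinkage covariance, estimates the global
#' \eqn{\hat d}, and tabulates \eqn{\hat\lambda}, \eqn{\hat\lambda_v},
#' \eqn{\hat a_{ii} - \hat d}, \eqn{\hat a_{ij} - \hat d}, \eqn{\hat b_{ii}},
#' \eqn{\hat b_{ij}} per peptide, alongside the population values from
#' [true_cov_structure()].  Suitable for reproducing the shrinkage-intensity
#' and covariance convergence diagnostics.
#'
#' @param R_grid Integer vector of replicate counts.
#' @param params Base [model_params()] (its `n_replicates` is overridden).
#' @param seed Base seed.
#' @param n_mc Monte Carlo size for the true `b` block.
#' @return List with `per_peptide` (`data.frame`: `R`, `peptide`, `lambda`,
#'   `lambda_v`, `a_ii_minus_d`, `a_ij_minus_d`, `b_ii`, `b_ij`), `d_hat`
#'   (`data.frame`: `R`, `d_hat`), and `truth` (named list of population
#'   values).
#' @export
convergence_experiment <- function(R_grid = c(4L, 8L, 16L, 32L, 64L),
                                   params = model_params(), seed = 1L,
                                   n_mc = 1e5) {
  truth_cs <- true_cov_structure(params, n_mc = n_mc,
                                 seed = derive_seed(seed, 0L))
  I <- params$n_fragments
  truth <- list(
    a_ii_minus_d = truth_cs$a[1L, 1L] - truth_cs$d,
    a_ij_minus_d = if (I > 1) truth_cs$a[1L, 2L] - truth_cs$d else NA_real_,
    b_ii = truth_cs$b[1L, 1L],
    b_ij = if (I > 1) truth_cs$b[1L, 2L] else NA_real_,
    d = truth_cs$d
  )
  pep_rows <- list(); d_rows <- list()
  for (gi in seq_along(R_grid)) {
    R <- R_grid[gi]
    p <- params
    p$n_replicates <- as.integer(R)
    sim <- simulate_dataset(p, seed = derive_seed(seed, gi))
    blocks <- select_complete_blocks(sim$table, n_fragments = I)
    d_hat <- estimate_d(summarize_peptides(sim$table, I))$d
    d_rows[[gi]] <- data.frame(R = R, d_hat = d_hat)
    stats_k <- lapply(blocks, function(bl) {
      fit <- shrink_covariance(bl)
      cs <- assemble_cov(fit, d_hat)
      offd <- if (I > 1) upper.tri(cs$a) else matrix(FALSE, 1L, 1L)
      data.frame(
        R = R, peptide = bl$peptide,
        lambda = fit$lambda, lambda_v = fit$lambda_v,
        a_ii_minus_d = mean(diag(cs$a)) - d_hat,
        a_ij_minus_d = if (I > 1) mean(cs$a[offd]) - d_hat else NA_real_,
        b_ii = mean(diag(cs$b)),
        b_ij = if (I > 1) mean(cs$b[upper.tri(cs$b) | lower.tri(cs$b)])
               else NA_real_,
        stringsAsFactors = FALSE
      )
    })
    pep_rows[[gi]] <- do.call(rbind, stats_k)
  }
  list(per_peptide = do.call(rbind, pep_rows),
       d_hat = do.call(rbind, d_rows),
       truth = truth)
}
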