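#' Summarize fragment quantities to peptide quantities
#'
#' For one precursor, ranks fragments by their mean raw quantity across all
#' runs of the comparison (ties broken by fragment identifier), keeps the top
#' `I`, and sums them per run: \eqn{q_{cr}^p = \sum_{i=1}^I f_{cir}^p},
#' \eqn{y_{cr}^p = \log_{10} q_{cr}^p}.  Fewer than `I` available fragments
#' are summed without padding.
#'
#' @param fragments `data.frame` with columns `fragment`, `condition`,
#'   `replicate`, `quantity` for one peptide (positive quantities).
#' @param n_fragments Number of top fragments I to sum (default 3).
#' @return `data.frame` with columns `condition`, `replicate`, `q`, `y`.
#' @export
summarize_peptide <- function(fragments, n_fragments = 3L) {
  fr <- as.data.frame(fragments)
  if (!all(c("fragment", "condition", "replicate", "quantity") %in% names(fr)))
    stop("fragments must have columns fragment, condition, replicate, quantity")
  fr <- fr[is.finite(fr$quantity) & fr$quantity > 0, , drop = FALSE]
  if (nrow(fr) == 0L) stop("no positive fragment quantities")
  mean_by_frag <- tapply(fr$quantity, fr$fragment, mean)
  ord <- order(-mean_by_frag, names(mean_by_frag))
  keep <- names(mean_by_frag)[ord][seq_len(min(n_fragments, length(ord)))]
  fr <- fr[as.character(fr$fragment) %in% keep, , drop = FALSE]
  out <- stats::aggregate(list(q = fr$quantity),
                          by = list(condition = fr$condition,
                                    replicate = fr$replicate),
                          FUN = sum)
  out$y <- log10(out$q)
  out <- out[order(out$condition, out$replicate), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a whole fragment table to peptide quantities
#'
#' Applies [summarize_peptide()] to every precursor of a fragment table.
#'
#' @param table Fragment table `data.frame` (columns `precursor`, `fragment`,
#'   `condition`, `replicate`, `quantity`), e.g. `simulate_dataset()$table`
#'   or from [read_fragment_report()].
#' @param n_fragments Number of top fragments I to sum.
#' @return `data.frame` with columns `peptide`, `condition`, `replicate`,
#'   `q`, `y` (input to [estimate_d()] and the two-step t test).
#' @export
summarize_peptides <- function(table, n_fragments = 3L) {
  tab <- as.data.frame(table)
  sp <- split(tab, tab$precursor)
  out <- lapply(names(sp), function(p) {
    s <- summarize_peptide(sp[[p]], n_fragments)
    cbind(peptide = p, s, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Shrinkage estimate of the group mean difference
#'
#' \eqn{\hat L_{shrink} = \sum_{i=1}^I (\bar x_{1i} - \bar x_{2i})}, the sum
#' over fragments of the condition differences of mean log10 quantities.
#' Identity: \eqn{\hat L_{shrink} = I \hat L_{paired}} with equal replicate
#' counts.
#'
#' @inheritParams sample_moments
#' @return The estimate in log10 units.
#' @export
shrinkage_estimate_L <- function(block) {
  X <- as_block_matrix(block)
  I <- block_I(block)
  m <- colMeans(X)
  sum(m[seq_len(I)] - m[I + seq_len(I)])
}

#' Bootstrap stabilization constant schedule
#'
#' \eqn{a_R = a_4 (R/4)^{-3/2} = 2.4 R^{-3/2}}, anchored at
#' \eqn{a_4 = 0.3} for R = 4 and decaying so the bootstrap t statistics stay
#' asymptotically consistent as R grows.
#'
#' @param R Number of replicates (>= 2).
#' @return The stabilization constant (strictly positive, decreasing in R).
#' @examples
#' a_R_schedule(4) # 0.3
#' @export
a_R_schedule <- function(R) {
  if (any(R < 2)) stop("R must be >= 2")
  2.4 * R^(-3 / 2)
}

#' Bootstrap configuration
#'
#' @param B Number of bootstrap resamples (default 100, >= 2).
#' @param a_R Stabilization constant added to the bootstrap standard errors;
#'   `NULL` (default) uses [a_R_schedule()] at the block's replicate count.
#' @param seed Optional seed for the resampling.
#' @return An object of class `"bootstrap_config"`.
#' @export
bootstrap_config <- function(B = 100L, a_R = NULL, seed = NULL) {
  B <- as.integer(B)
  if (B < 2L) stop("B must be >= 2")
  if (!is.null(a_R) && !(is.numeric(a_R) && a_R > 0))
    stop("a_R must be strictly positive")
  structure(list(B = B, a_R = a_R, seed = seed), class = "bootstrap_config")
}

#' Bootstrap degrees-of-freedom for the shrinkage t statistic
#'
#' Additive bootstrap estimation: resamples the replicate vectors
#' \eqn{z_r = (x_{11r}, \ldots, x_{2Ir})} with replacement (size R), recomputes
#' \eqn{\hat L^*} and its shrinkage standard error per resample (the global
#' \eqn{\hat d} is held fixed; \eqn{\hat\lambda, \hat\lambda_v} are
#' re-estimated), and forms \eqn{t^*_b = \hat L^* / (SE^* + a_R)} where the
#' constant \eqn{a_R > 0} keeps degenerate resamples (duplicated rows) from
#' blowing up the statistic.  With \eqn{s^{*2}} the sample variance of the B
#' statistics, the Student-t variance relation gives
#' \deqn{\nu = 2 s^{*2} / (s^{*2} - 1) \textrm{ for } s^{*2} > 1, \quad
#' \nu = \infty \textrm{ otherwise.}}
#'
#' @inheritParams sample_moments
#' @param d_hat Cross-replicate covariance estimate (held fixed).
#' @param cfg A [bootstrap_config()].
#' @return List with `nu`, `s_star2`, `t_star` (length-B vector), `a_R`.
#' @export
bootstrap_df <- function(block, d_hat, cfg = bootstrap_config()) {
  X <- as_block_matrix(block)
  I <- block_I(block)
  R <- nrow(X)
  stopifnot(inherits(cfg, "bootstrap_config"))
  a_R <- if (is.null(cfg$a_R)) a_R_schedule(R) else cfg$a_R
  t_star <- with_seed(cfg$seed, {
    idx <- matrix(sample.int(R, R * cfg$B, replace = TRUE), nrow = cfg$B)
    vapply(seq_len(cfg$B), function(b) {
      res <- shrink_L_var(X[idx[b, ], , drop = FALSE], I, d_hat)
      res$L / (sqrt(res$var_L) + a_R)
    }, numeric(1L))
  })
  s_star2 <- stats::var(t_star)
  nu <- if (is.finite(s_star2) && s_star2 > 1) 2 * s_star2 / (s_star2 - 1)
        else Inf
  list(nu = nu, s_star2 = s_star2, t_star = t_star, a_R = a_R)
}

test_result <- function(peptide, method, estimate, se, statistic, df,
                        p_value, flags = character(0), diagnostics = list()) {
  structure(
    list(peptide = peptide, method = method, estimate = estimate, se = se,
         statistic = statistic, df = df, p_value = p_value, flags = flags,
         diagnostics = diagnostics),
    class = "dia_test_result"
  )
}

#' @export
print.dia_test_result <- function(x, ...) {
  cat(sprintf("%s test, peptide %s\n", x$method, x$peptide))
  cat(sprintf("  L = %.4g, SE = %.4g, t = %.4g, df = %s, p = %.4g\n",
              x$estimate, x$se, x$statistic,
              if (is.infinite(x$df)) "Inf" else sprintf("%.3g", x$df),
              x$p_value))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Shrinkage t test for one peptide block
#'
#' The feature-based shrinkage test: \eqn{t_{shrink} = \hat L_{shrink} /
#' SE(\hat L_{shrink})} with the standard error from the structured
#' covariance assembled out of the shrinkage fit ([shrink_covariance()],
#' [assemble_cov()], [variance_of_L()]) and degrees-of-freedom from
#' [bootstrap_df()].  Two-sided p-value from Student's t (standard normal
#' when \eqn{\nu = \infty}).
#'
#' @inheritParams bootstrap_df
#' @return A `"dia_test_result"` with diagnostics `lambda`, `lambda_v`,
#'   `d_hat`, `s_star2`, `a_R`.
#' @export
shrinkage_t_test <- function(block, d_hat, cfg = bootstrap_config()) {
  X <- as_block_matrix(block)
  I <- block_I(block)
  R <- nrow(X)
  fit <- shrink_covariance(peptide_block(X, I))
  cv <- assemble_cov(fit, d_hat)
  se <- sqrt(variance_of_L(cv, R, I))
  L <- shrinkage_estimate_L(block)
  bs <- bootstrap_df(block, d_hat, cfg)
  t <- L / se
  p <- 2 * stats::pt(-abs(t), df = bs$nu)
  test_result(
    peptide = if (inherits(block, "peptide_block")) block$peptide else NA,
    method = "shrinkage", estimate = L, se = se, statistic = t, df = bs$nu,
    p_value = p,
    diagnostics = list(lambda = fit$lambda, lambda_v = fit$lambda_v,
                       d_hat = d_hat, s_star2 = bs$s_star2, a_R = bs$a_R)
  )
}

#' Paired t test on fragment-level differences
#'
#' Classical feature-based baseline: treats all \eqn{I \cdot R} paired
#' differences \eqn{x_{1ir} - x_{2ir}} as i.i.d., \eqn{t = \bar d /
#' (sd(d)/\sqrt{IR})} with \eqn{IR - 1} degrees-of-freedom.  A zero sample SD
#' with a nonzero mean yields infinite \eqn{|t|} and p = 0 (flagged
#' `degenerate`); an all-zero difference vector yields t = 0, p = 1.
#'
#' @inheritParams sample_moments
#' @return A `"dia_test_result"`.
#' @export
paired_t_test <- function(block) {
  X <- as_block_matrix(block)
  I <- block_I(block)
  diffs <- as.numeric(X[, seq_len(I)] - X[, I + seq_len(I)])
  n <- length(diffs)
  if (n < 2L) stop("need at least 2 paired differences")
  m <- mean(diffs); s <- stats::sd(diffs)
  flags <- character(0)
  if (s == 0) {
    flags <- "degenerate"
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
    se <- 0
  } else {
    se <- s / sqrt(n)
    t <- m / se
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  test_result(
    peptide = if (inherits(block, "peptide_block")) block$peptide else NA,
    method = "paired", estimate = I * m, se = I * se, statistic = t,
    df = n - 1, p_value = p, flags = flags
  )
}

#' Welch two-sample t test on summarized peptide quantities
#'
#' Classical two-step baseline: Welch's unequal-variance t test on the log10
#' summarized peptide quantities \eqn{y_{cr}^p} of the two conditions, with
#' Welch-Satterthwaite degrees-of-freedom.
#'
#' @param y1,y2 Numeric vectors of summarized log10 quantities (>= 2 each).
#' @param peptide Optional peptide identifier.
#' @return A `"dia_test_result"` (estimate is `mean(y1) - mean(y2)`).
#' @export
independent_t_test <- function(y1, y2, peptide = NA_character_) {
  if (length(y1) < 2L || length(y2) < 2L)
    stop("need at least 2 summarized values per condition")
  flags <- character(0)
  if (stats::sd(y1) == 0 && stats::sd(y2) == 0) {
    m <- mean(y1) - mean(y2)
    flags <- "degenerate"
    res <- list(estimate = c(mean(y1), mean(y2)),
                statistic = if (m == 0) 0 else sign(m) * Inf,
                parameter = length(y1) + length(y2) - 2,
                p.value = if (m == 0) 1 else 0,
                stderr = 0)
  } else {
    res <- stats::t.test(y1, y2, var.equal = FALSE)
  }
  test_result(
    peptide = peptide, method = "independent",
    estimate = mean(y1) - mean(y2), se = res$stderr,
    statistic = unname(res$statistic), df = unname(res$parameter),
    p_value = res$p.value, flags = flags
  )
}

#' Run a differential test over all complete peptide blocks
#'
#' Driver that turns a fragment table (or a `fragment_sim`) into per-peptide
#' test results.  For the shrinkage method a single comparison-wide
#' \eqn{\hat d} is estimated first (from [summarize_peptides()] +
#' [estimate_d()]) and shared by all peptides; bootstrap seeds are derived
#' per peptide from `seed`.
#'
#' @param x Fragment table `data.frame` or `fragment_sim`.
#' @param method One of `"shrinkage"`, `"paired"`, `"independent"`.
#' @param conditions Length-2 vector naming the condition levels to compare
#'   (default: the first two levels in sorted order).
#' @param n_fragments Number of fragments I per block.
#' @param B Bootstrap resamples for the shrinkage method.
#' @param seed Base seed (shrinkage bootstraps).
#' @param d_hat Optional fixed d; `NULL` estimates it from the data.
#' @return `data.frame` with one row per peptide: `peptide`, `method`,
#'   `estimate`, `se`, `statistic`, `df`, `p_value`, `flags`, plus `lambda`,
#'   `lambda_v`, `d_hat` for the shrinkage method.
#' @examples
#' sim <- simulate_dataset(model_params(n_peptides = 20), seed = 3)
#' res <- run_differential_tests(sim, method = "paired")
#' head(res)
#' @export
run_differential_tests <- function(x, method = c("shrinkage", "paired",
                                                 "independent"),
                                   conditions = NULL, n_fragments = 3L,
                                   B = 100L, seed = NULL, d_hat = NULL) {
  method <- match.arg(method)
  tab <- if (inherits(x, "fragment_sim")) x$table else as.data.frame(x)
  if (inherits(x, "fragment_sim")) n_fragments <- x$params$n_fragments
  blocks <- select_complete_blocks(tab, conditions = conditions,
                                   n_fragments = n_fragments)
  if (method == "shrinkage" && is.null(d_hat)) {
    keep <- tab$precursor %in% vapply(blocks, `[[`, "", "peptide")
    d_hat <- estimate_d(summarize_peptides(tab[keep, , drop = FALSE],
                                           n_fragments))$d
  }
  rows <- lapply(seq_along(blocks), function(k) {
    bl <- blocks[[k]]
    res <- switch(method,
      shrinkage = shrinkage_t_test(
        bl, d_hat,
        bootstrap_config(B = B,
                         seed = if (is.null(seed)) NULL
                                else derive_seed(seed, k))),
      paired = paired_t_test(bl),
      independent = {
        I <- bl$n_fragments
        q1 <- rowSums(10^bl$x[, seq_len(I), drop = FALSE])
        q2 <- rowSums(10^bl$x[, I + seq_len(I), drop = FALSE])
        independent_t_test(log10(q1), log10(q2), peptide = bl$peptide)
      })
    out <- data.frame(
      peptide = res$peptide, method = res$method, estimate = res$estimate,
      se = res$se, statistic = res$statistic, df = res$df,
      p_value = res$p_value,
      flags = paste(res$flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
    if (method == "shrinkage") {
      out$lambda <- res$diagnostics$lambda
      out$lambda_v <- res$diagnostics$lambda_v
      out$d_hat <- res$diagnostics$d_hat
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
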