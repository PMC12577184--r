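#' Dose-response p-value combination
#'
#' Combines the p-values of an ordered chain of consecutive pairwise
#' comparisons (e.g. DMSO/10 nM, 10 nM/100 nM, 100 nM/100 uM) for one
#' peptide into a single dose-response significance value.  With \eqn{s_m}
#' the sign of the estimate attaining the minimum p-value (ties resolved to
#' the earliest comparison in dose order):
#' \deqn{\tilde p_{drc} = \prod_{i: s_i = s_m} \tilde p_i \;
#' \prod_{j: s_j \ne s_m} (1 - 0.5 \tilde p_j).}
#' Comparisons whose effect goes the same way as the most significant one
#' contribute their p-value as evidence; discordant ones contribute a mild
#' penalty factor in (0.5, 1].
#'
#' @param p Numeric vector of p-values in (0, 1], one per comparison, in
#'   dose order.
#' @param signs Signs of the corresponding estimates (-1 or +1; zero
#'   estimates should be coded by the user, conventionally +1).
#' @return The combined value \eqn{\tilde p_{drc}} in (0, 1].
#' @examples
#' combine_dose_response(c(0.01, 0.2, 0.5), c(1, 1, -1)) # 0.0015
#' @export
combine_dose_response <- function(p, signs) {
  if (length(p) == 0L) stop("empty comparison series")
  if (length(signs) != length(p)) stop("p and signs must have equal length")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  if (!all(signs %in% c(-1, 1))) stop("signs must be -1 or +1")
  s_m <- signs[which.min(p)]   # which.min takes the earliest tie
  same <- signs == s_m
  prod(p[same]) * prod(1 - 0.5 * p[!same])
}

#' Local false discovery rate scores from signed p-values
#'
#' Empirical-Bayes lfdr on signed z-scores \eqn{z = s \cdot \Phi^{-1}(1 -
#' p/2)}: with a theoretical N(0, 1) null, a Gaussian-kernel density estimate
#' \eqn{\hat f} of all z, and a Storey-type null proportion
#' \eqn{\hat\pi_0 = \min(1, \#\{p > 0.5\} / (0.5 m))},
#' \deqn{lfdr(z) = clip(\hat\pi_0 \, \phi(z) / \hat f(z), 0, 1).}
#' Isotonic regression is applied on each tail so the score is monotone
#' nonincreasing in \eqn{|z|}.  The estimator is a simple, dependency-free
#' approximation; fewer than 50 p-values trigger a warning but scores are
#' still returned.
#'
#' @param p Numeric vector of two-sided p-values in (0, 1].
#' @param signs Signs of the corresponding estimates (-1 or +1).
#' @return Numeric vector of lfdr scores in \[0, 1\], aligned with `p`.
#' @export
local_fdr <- function(p, signs) {
  m <- length(p)
  if (m == 0L) stop("no p-values")
  if (length(signs) != m) stop("p and signs must have equal length")
  if (m < 50L) warning("fewer than 50 p-values; lfdr estimates are unstable")
  p <- pmin(pmax(p, 1e-300), 1)
  z <- sign(signs) * stats::qnorm(p / 2, lower.tail = FALSE)
  pi0 <- min(1, sum(p > 0.5) / (0.5 * m))
  zf <- z[is.finite(z)]
  dens <- stats::density(zf, bw = "nrd0", kernel = "gaussian", n = 512L,
                         cut = 3)
  fhat <- stats::approx(dens$x, dens$y, xout = z, rule = 2)$y
  fhat <- pmax(fhat, .Machine$double.xmin)
  lfdr <- pmin(pmax(pi0 * stats::dnorm(z) / fhat, 0), 1)

  # enforce monotonicity in |z| on each tail
  for (side in c(-1, 1)) {
    sel <- which(if (side > 0) z >= 0 else z < 0)
    if (length(sel) > 1L) {
      ord <- sel[order(z[sel] * side)]    # increasing |z|
      v <- lfdr[ord]
      # antitonic fit: reverse, isotonic (nondecreasing), reverse back
      lfdr[ord] <- rev(stats::isoreg(rev(v))$yf)
    }
  }
  lfdr
}

#' Aggregate peptide scores to protein scores
#'
#' Protein score = minimum score over its member peptides (a protein is as
#' significant as its most significant peptide).  Proteins with no scored
#' peptide are omitted with a warning.
#'
#' @param scores Named numeric vector of peptide-level scores (lfdr or
#'   \eqn{\tilde p_{drc}}), names are peptide ids.
#' @param map `data.frame` with columns `peptide`, `protein` mapping every
#'   scored peptide to a protein.
#' @return `data.frame` with columns `protein`, `score`, `n_peptides`,
#'   `best_peptide`, sorted by score.
#' @export
aggregate_protein <- function(scores, map) {
  map <- as.data.frame(map)
  if (!all(c("peptide", "protein") %in% names(map)))
    stop("map must have columns peptide, protein")
  if (is.null(names(scores))) stop("scores must be named by peptide id")
  unmapped <- setdiff(names(scores), map$peptide)
  if (length(unmapped))
    stop("unmapped peptide(s): ", paste(utils::head(unmapped, 5L),
                                        collapse = ", "))
  all_proteins <- unique(map$protein)
  map <- map[map$peptide %in% names(scores), , drop = FALSE]
  dropped <- setdiff(all_proteins, unique(map$protein))
  if (length(dropped))
    warning("protein(s) with no scored peptides omitted: ",
            paste(dropped, collapse = ", "))
  sp <- split(map$peptide, map$protein)
  out <- do.call(rbind, lapply(names(sp), function(pr) {
    vals <- scores[sp[[pr]]]
    data.frame(protein = pr, score = min(vals), n_peptides = length(vals),
               best_peptide = sp[[pr]][which.min(vals)],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$score, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Volcano table
#'
#' Converts per-peptide (or per-protein) results into volcano-plot
#' coordinates: log2 fold change \eqn{= \hat L / \log_{10} 2} and
#' \eqn{-\log_{10}} of the lfdr score, with a significance flag for
#' `lfdr <= 0.01` and `|log2 FC| >= 1`.
#'
#' @param results `data.frame` with columns `peptide` and `estimate` (log10
#'   units), e.g. from [run_differential_tests()].
#' @param scores lfdr scores aligned with the rows of `results` (or named by
#'   peptide id).
#' @param lfdr_cutoff,fc_cutoff Selection thresholds (defaults 0.01 and 1).
#' @return `data.frame` with columns `id`, `log2_fc`, `lfdr`,
#'   `neg_log10_lfdr`, `significant`.
#' @export
volcano_table <- function(results, scores, lfdr_cutoff = 0.01,
                          fc_cutoff = 1) {
  res <- as.data.frame(results)
  if (!all(c("peptide", "estimate") %in% names(res)))
    stop("results must have columns peptide, estimate")
  s <- if (!is.null(names(scores))) unname(scores[res$peptide]) else scores
  if (length(s) != nrow(res)) stop("scores not aligned with results")
  log2_fc <- res$estimate / log10(2)
  data.frame(
    id = res$peptide,
    log2_fc = log2_fc,
    lfdr = s,
    neg_log10_lfdr = -log10(pmax(s, 1e-300)),
    significant = s <= lfdr_cutoff & abs(log2_fc) >= fc_cutoff,
    stringsAsFactors = FALSE
  )
}
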