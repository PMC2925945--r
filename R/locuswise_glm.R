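#' Quasi-binomial test of one locus against invasive status
#'
#' Fits a generalized linear model with logit link, binomial variance and a
#' free (Pearson) scale parameter to the per-sample average-beta values at a
#' single locus, with invasive status as the only covariate. Because the
#' covariate is binary the fit is saturated: the slope equals the difference
#' of group-mean logits. The two-sided p-value uses a t reference with n - 2
#' degrees of freedom and the Pearson dispersion estimate.
#'
#' Degenerate inputs: a locus whose values are all identical gets slope 0,
#' dispersion 0, p = 1. A locus with two distinct constant groups (zero
#' Pearson dispersion but nonzero slope) is perfectly separated; it is
#' flagged and assigned p = 0.
#'
#' @param beta_j Numeric vector of average-beta values in \[0, 1\]; values
#'   are clamped to \[1e-6, 1 - 1e-6\] before the logit.
#' @param invasive Logical (or 0/1) vector of the same length; both groups
#'   must be nonempty.
#' @param eps Boundary clamp, default 1e-6.
#' @return List with `slope` (logit scale, invasive minus non-invasive),
#'   `dispersion` (Pearson chi-square / (n - 2)), `p` (two-sided), and
#'   `degenerate` flag.
#' @export
fit_quasibinomial <- function(beta_j, invasive, eps = 1e-6) {
  invasive <- as.logical(invasive)
  stopifnot(length(beta_j) == length(invasive), !anyNA(beta_j),
            !anyNA(invasive))
  if (!any(invasive) || all(invasive)) {
    stop("both invasive and non-invasive groups must be nonempty",
         call. = FALSE)
  }
  y <- pmin(pmax(beta_j, eps), 1 - eps)
  if (stats::var(y) == 0) {
    return(list(slope = 0, dispersion = 0, p = 1, degenerate = TRUE))
  }
  fit <- stats::glm(y ~ invasive, family = stats::quasibinomial(),
                    control = stats::glm.control(epsilon = 1e-14,
                                                 maxit = 100))
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  dispersion <- sm$dispersion
  if (!is.finite(dispersion) || dispersion <= 1e-12) {
    # two constant groups at different levels: perfect separation
    return(list(slope = slope, dispersion = 0, p = 0, degenerate = TRUE))
  }
  p <- sm$coefficients[2, "Pr(>|t|)"]
  list(slope = slope, dispersion = dispersion, p = unname(p),
       degenerate = FALSE)
}

#' Locus-by-locus quasi-binomial screen
#'
#' Applies [fit_quasibinomial()] to every locus and attaches Storey q-values.
#'
#' @param m A [meth_matrix()].
#' @param sheet Sample sheet with `sample_id` and logical `invasive`.
#' @param pi0 Passed to [compute_qvalues()]: `"smoother"` (default) or
#'   `"fixed1"` (Benjamini-Hochberg).
#' @return A `locus_results` data frame: locus, slope, dispersion, p, q,
#'   direction ("+"/"-").
#' @export
glm_screen <- function(m, sheet, pi0 = c("smoother", "fixed1")) {
  stopifnot(inherits(m, "meth_matrix"))
  pi0 <- match.arg(pi0)
  idx <- match(rownames(m$beta), sheet$sample_id)
  if (anyNA(idx)) stop("sample sheet missing samples present in the matrix",
                       call. = FALSE)
  invasive <- as.logical(sheet$invasive[idx])
  res <- lapply(seq_len(ncol(m$beta)), function(j) {
    fit_quasibinomial(m$beta[, j], invasive)
  })
  out <- data.frame(
    locus = colnames(m$beta),
    slope = vapply(res, `[[`, numeric(1), "slope"),
    dispersion = vapply(res, `[[`, numeric(1), "dispersion"),
    p = vapply(res, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE)
  out$q <- compute_qvalues(out$p, pi0 = pi0)
  out$direction <- ifelse(out$slope >= 0, "+", "-")
  class(out) <- c("locus_results", "data.frame")
  out
}

#' Storey q-values
#'
#' False discovery rate q-values with the proportion of true nulls pi0
#' estimated over a lambda grid (0.05 to 0.95 in steps of 0.05) and
#' extrapolated with a cubic smoothing spline (df = 3), clipped to (0, 1\].
#' With `pi0 = "fixed1"` the procedure reduces exactly to
#' Benjamini-Hochberg.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param pi0 `"smoother"` (default) or `"fixed1"`.
#' @return Vector of q-values, same order as `p`.
#' @export
compute_qvalues <- function(p, pi0 = c("smoother", "fixed1")) {
  pi0 <- match.arg(pi0)
  if (length(p) == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0,1]", call. = FALSE)
  }
  m <- length(p)
  if (pi0 == "fixed1" || m < 30) {
    # too few p-values to estimate pi0 stably; fall back to pi0 = 1
    pi0_hat <- 1
  } else {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0_hat <- stats::predict(sp, x = max(lambda))$y
    pi0_hat <- min(max(pi0_hat, 1e-4), 1)
  }
  o <- order(p)
  ro <- order(o)
  q <- pi0_hat * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[ro]
}

#' Count significant loci by direction
#'
#' @param results A `locus_results` table from [glm_screen()].
#' @param q_cut q-value cutoff, default 0.05.
#' @return Named integer vector `c(n_up, n_down)`: loci with q < q_cut split
#'   by slope sign.
#' @export
count_significant <- function(results, q_cut = 0.05) {
  sig <- results$q < q_cut
  c(n_up = sum(sig & results$slope > 0),
    n_down = sum(sig & results$slope < 0))
}

#' Exploratory hierarchical clustering of samples
#'
#' Manhattan distance between sample beta profiles with average linkage.
#'
#' @param m A [meth_matrix()].
#' @return An [stats::hclust] dendrogram over samples.
#' @export
hcluster <- function(m) {
  stopifnot(inherits(m, "meth_matrix"))
  if (nrow(m$beta) < 2) stop("need at least 2 samples", call. = FALSE)
  stats::hclust(stats::dist(m$beta, method = "manhattan"),
                method = "average")
}
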