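#' Spearman correlations between a gene's CpG sites
#'
#' @param t A `pyro_table` (long format: sample_id, gene, site, pct_meth).
#' @param gene Gene name.
#' @return Site x site Spearman correlation matrix.
#' @export
site_correlations <- function(t, gene) {
  sub <- t[t$gene == gene, ]
  if (nrow(sub) == 0L) stop(sprintf("no rows for gene '%s'", gene),
                            call. = FALSE)
  wide <- stats::reshape(sub[, c("sample_id", "site", "pct_meth")],
                         idvar = "sample_id", timevar = "site",
                         direction = "wide")
  m <- as.matrix(wide[, -1, drop = FALSE])
  colnames(m) <- sub("^pct_meth\\.", "site", colnames(m))
  stats::cor(m, method = "spearman", use = "pairwise.complete.obs")
}

#' Per-sample mean percent methylation across a gene's CpG sites
#'
#' Missing sites are averaged over the observed sites; the number of sites
#' contributing is reported alongside.
#'
#' @inheritParams site_correlations
#' @return Data frame: sample_id, mean_pct, n_sites.
#' @export
gene_mean <- function(t, gene) {
  sub <- t[t$gene == gene & !is.na(t$pct_meth), ]
  if (nrow(sub) == 0L) stop(sprintf("no rows for gene '%s'", gene),
                            call. = FALSE)
  agg <- stats::aggregate(pct_meth ~ sample_id, data = sub,
                          FUN = function(v) c(mean(v), length(v)))
  data.frame(sample_id = agg$sample_id,
             mean_pct = agg$pct_meth[, 1],
             n_sites = as.integer(agg$pct_meth[, 2]),
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis one-way analysis of variance
#'
#' Tie-corrected H statistic with a chi-square reference on
#' (number of groups - 1) degrees of freedom.
#'
#' @param groups List of >= 2 numeric vectors.
#' @return List: `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Wilcoxon rank-sum test, optionally protected by a Kruskal-Wallis gate
#'
#' Two-sided. Uses the exact enumeration distribution when the smaller
#' group has at most 8 observations and there are no ties, otherwise the
#' normal approximation with tie correction (no continuity correction).
#' When `protected_by` is supplied, the comparison is only carried out if
#' that (Kruskal-Wallis) p-value is below `alpha`; otherwise the result is
#' flagged `tested = FALSE` with `p = NA`.
#'
#' @param a,b Numeric vectors.
#' @param protected_by Optional p-value from a preceding omnibus test.
#' @param alpha Protection level, default 0.05.
#' @return List: `W`, `p`, `tested`, `exact`.
#' @export
ranksum <- function(a, b, protected_by = NULL, alpha = 0.05) {
  if (!is.null(protected_by) && protected_by >= alpha) {
    return(list(W = NA_real_, p = NA_real_, tested = FALSE, exact = NA))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE,
                       alternative = "two.sided"))
  list(W = unname(wt$statistic), p = wt$p.value, tested = TRUE,
       exact = exact)
}

#' Dichotomize at the median
#'
#' Values at or below the median of the analyzed series are negative
#' (FALSE); values strictly above are positive (TRUE).
#'
#' @param values Numeric vector.
#' @return Logical vector (TRUE = positive / methylated).
#' @export
dichotomize_median <- function(values) {
  values > stats::median(values, na.rm = TRUE)
}

#' Odds ratio from a 2x2 table
#'
#' Cross-product odds ratio with a Woolf (log-scale) 95\% confidence
#' interval. When any cell is zero, 0.5 is added to every cell (Haldane
#' correction) and the result flagged.
#'
#' @param t 2x2 numeric matrix: rows = exposure (negative, positive),
#'   columns = outcome (control, case); or a length-4 vector
#'   (a, b, c, d) = (neg-control, neg-case, pos-control, pos-case).
#' @return List: `or`, `ci` (length 2), `corrected` flag.
#' @export
or_from_2x2 <- function(t) {
  if (is.matrix(t)) {
    stopifnot(identical(dim(t), c(2L, 2L)))
    cells <- c(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
  } else {
    stopifnot(length(t) == 4)
    cells <- as.numeric(t)
  }
  if (any(cells < 0)) stop("counts must be nonnegative", call. = FALSE)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * cc)
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  list(or = or, ci = ci, corrected = corrected)
}

#' Multivariable unconditional logistic regression
#'
#' Maximum likelihood via iteratively reweighted least squares
#' (`glm(binomial)`, convergence 1e-8, up to 100 iterations), Wald 95\%
#' confidence intervals. Perfect separation (diverging coefficients or
#' exploding standard errors) raises an explicit error.
#'
#' @param outcome Logical/0-1 response vector.
#' @param covariates Data frame of exposures and adjustment covariates.
#' @return A `logistic_fit` data frame: term, coef, se, or, ci_low,
#'   ci_high, p.
#' @export
logistic_fit <- function(outcome, covariates) {
  dat <- data.frame(.y = as.numeric(as.logical(outcome)), covariates)
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  cf <- summary(fit)$coefficients
  if (!fit$converged || any(abs(cf[, "Estimate"]) > 15) ||
      any(cf[, "Std. Error"] > 100)) {
    stop("logistic model did not converge (possible perfect separation)",
         call. = FALSE)
  }
  out <- data.frame(term = rownames(cf),
                    coef = cf[, "Estimate"],
                    se = cf[, "Std. Error"],
                    or = exp(cf[, "Estimate"]),
                    ci_low = exp(cf[, "Estimate"] - 1.96 * cf[, "Std. Error"]),
                    ci_high = exp(cf[, "Estimate"] + 1.96 * cf[, "Std. Error"]),
                    p = cf[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("logistic_fit", "data.frame")
  out
}

#' All-three-genes additive methylation indicator
#'
#' Indicator that all three gene promoters are methylated above their
#' medians, for the additive (panel) model contrasting all-3 against
#' none/1/2.
#'
#' @param gene_dichotomies List or data frame of exactly 3 logical vectors
#'   (TRUE = above median).
#' @return Logical vector: TRUE when all three are positive.
#' @export
additive_score <- function(gene_dichotomies) {
  gd <- as.data.frame(gene_dichotomies)
  stopifnot(ncol(gd) == 3)
  Reduce(`&`, lapply(gd, as.logical))
}

#' Tumor-cell-fraction sensitivity check
#'
#' Refits a logistic model with a percent-tumor-cells covariate added and
#' reports the change in each original coefficient. A covariate collinear
#' with an existing exposure is flagged instead of silently refit.
#'
#' @param outcome,covariates As in [logistic_fit()].
#' @param tumor_percent Numeric vector (percent tumor cells per sample).
#' @return List: `base`, `adjusted` (both `logistic_fit`s), `delta` (named
#'   coefficient changes for the shared terms), `collinear` flag.
#' @export
tumor_fraction_sensitivity <- function(outcome, covariates, tumor_percent) {
  stopifnot(length(tumor_percent) == length(outcome))
  num <- covariates[vapply(covariates, is.numeric, logical(1))]
  collinear <- FALSE
  for (v in num) {
    if (stats::sd(v) > 0 && stats::sd(tumor_percent) > 0 &&
        abs(stats::cor(v, tumor_percent)) > 0.99) collinear <- TRUE
  }
  base <- logistic_fit(outcome, covariates)
  if (collinear) {
    return(list(base = base, adjusted = NULL, delta = NULL,
                collinear = TRUE))
  }
  adjusted <- logistic_fit(outcome, cbind(covariates,
                                          tumor_percent = tumor_percent))
  shared <- intersect(base$term, adjusted$term)
  delta <- adjusted$coef[match(shared, adjusted$term)] -
    base$coef[match(shared, base$term)]
  names(delta) <- shared
  list(base = base, adjusted = adjusted, delta = delta, collinear = FALSE)
}

#' Pfaffl efficiency-corrected fold change
#'
#' `fold = E_target^dCt_target / E_ref^dCt_ref`, with
#' `dCt = Ct(control) - Ct(treated)` for each amplicon and E the PCR
#' efficiency (2 = perfect doubling).
#'
#' @param E_target,E_ref Amplification efficiencies.
#' @param dCt_target,dCt_ref Ct differences (control minus treated).
#' @return Fold change (numeric).
#' @export
pfaffl_fold_change <- function(E_target, dCt_target, E_ref, dCt_ref) {
  stopifnot(E_target > 0, E_ref > 0)
  E_target^dCt_target / E_ref^dCt_ref
}

#' Percentage cells of a printed contingency table
#'
#' Computes the displayed percentage for each count given its denominator,
#' rounding half to even (the R `round()` convention) at the requested
#' number of digits — the convention that reproduces the printed tables.
#'
#' @param n Numeric vector of counts.
#' @param denom Matching vector of denominators.
#' @param digits Displayed digits (vectorized), default 0.
#' @return Numeric vector of display percentages.
#' @export
table_percent <- function(n, denom, digits = 0) {
  stopifnot(length(n) == length(denom), all(denom > 0))
  round(100 * n / denom, digits)
}
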