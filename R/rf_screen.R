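#' Random-forest screen configuration
#'
#' @param n_trees Trees per forest. Default 500.
#' @param m_grid Integer vector of candidate mtry values; `NULL` means the
#'   full [mtry_grid()] range for the locus count at fit time.
#' @param n_perm Label permutations for the OOB null. Default 100.
#' @param importance_cut Percent-change-in-MSE selection threshold (strict
#'   >). Default 6; the companion screening threshold 5 is equally valid
#'   config.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = 500, m_grid = NULL, n_perm = 100,
                      importance_cut = 6) {
  stopifnot(n_trees >= 1, n_perm >= 1)
  if (!is.null(m_grid)) stopifnot(all(m_grid >= 1))
  structure(list(n_trees = as.integer(n_trees), m_grid = m_grid,
                 n_perm = as.integer(n_perm),
                 importance_cut = importance_cut),
            class = "rf_config")
}

#' mtry candidate range
#'
#' The tuning grid runs from half of sqrt(M) to twice sqrt(M), rounded
#' inward to integers and clipped to \[1, M\].
#'
#' @param M Total number of loci (features), >= 1.
#' @return Integer vector `c(lo, hi)`, `lo <= hi`.
#' @export
mtry_grid <- function(M) {
  stopifnot(M >= 1)
  r <- sqrt(M)
  lo <- max(1L, as.integer(ceiling(r / 2)))
  hi <- min(as.integer(M), as.integer(floor(2 * r)))
  if (hi < lo) hi <- lo
  c(lo, hi)
}

#' Tune mtry by out-of-bag error
#'
#' Fits one classification forest per candidate mtry and returns the value
#' with the lowest OOB misclassification rate; ties break toward the
#' smallest mtry. Each forest is grown from a deterministic per-m seed
#' derived from `seed`.
#'
#' @param X Numeric matrix, samples x loci.
#' @param y Two-level factor (or coercible) of sample types.
#' @param config An [rf_config()]. When `config$m_grid` is `NULL`, every
#'   integer in [mtry_grid()] is evaluated.
#' @param seed Integer master seed for this tuning run.
#' @return List: `best_m`, `oob` (named numeric vector of OOB error per m).
#' @export
tune_mtry <- function(X, y, config = rf_config(), seed = 1L) {
  y <- as.factor(y)
  if (nlevels(y) < 2) stop("y must have two classes", call. = FALSE)
  grid <- config$m_grid
  if (is.null(grid)) {
    g <- mtry_grid(ncol(X))
    grid <- seq.int(g[1], g[2])
  }
  grid <- sort(unique(pmin(as.integer(grid), ncol(X))))
  oob <- vapply(seq_along(grid), function(i) {
    set.seed(seed + i)
    rf <- randomForest::randomForest(X, y, ntree = config$n_trees,
                                     mtry = grid[i])
    unname(rf$err.rate[config$n_trees, "OOB"])
  }, numeric(1))
  names(oob) <- grid
  list(best_m = grid[which.min(oob)], oob = oob)
}

#' OOB permutation test of the methylation-phenotype association
#'
#' Compares the forest's out-of-bag error on the observed labels with the
#' null distribution of OOB errors from forests grown on permuted labels.
#' The p-value is `(1 + #{null OOB <= observed OOB}) / (1 + n_perm)`, so its
#' floor is `1 / (n_perm + 1)`.
#'
#' @inheritParams tune_mtry
#' @param mtry mtry used for all forests (observed and null); typically the
#'   tuned value.
#' @return List: `observed` OOB error, `null` vector (length n_perm), `p`.
#' @export
oob_permutation_test <- function(X, y, config = rf_config(), mtry = NULL,
                                 seed = 1L) {
  y <- as.factor(y)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  set.seed(seed)
  rf <- randomForest::randomForest(X, y, ntree = config$n_trees, mtry = mtry)
  observed <- unname(rf$err.rate[config$n_trees, "OOB"])
  null <- vapply(seq_len(config$n_perm), function(b) {
    set.seed(seed + 1000L + b)
    yb <- sample(y)
    rfb <- randomForest::randomForest(X, yb, ntree = config$n_trees,
                                      mtry = mtry)
    unname(rfb$err.rate[config$n_trees, "OOB"])
  }, numeric(1))
  p <- (1 + sum(null <= observed)) / (1 + config$n_perm)
  list(observed = observed, null = null, p = p)
}

#' Percent-change-in-MSE variable importance
#'
#' Grows a regression forest on the phenotype coded 0/1 and reports, per
#' locus, the permutation increase in out-of-bag MSE as a percentage of the
#' forest's OOB MSE. Using the regression (MSE) form of importance for a
#' binary phenotype keeps the importance scale continuous.
#'
#' @inheritParams tune_mtry
#' @param mtry mtry for the importance forest; default sqrt of locus count.
#' @return Named numeric vector: percent change in MSE per locus.
#' @export
rf_importance <- function(X, y, config = rf_config(), mtry = NULL,
                          seed = 1L) {
  y01 <- as.numeric(as.factor(y)) - 1
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  set.seed(seed)
  # y is 0/1 by construction; the regression-mode warning is expected
  rf <- suppressWarnings(
    randomForest::randomForest(X, y01, ntree = config$n_trees,
                               mtry = mtry, importance = TRUE))
  raw <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  mse <- rf$mse[config$n_trees]
  100 * raw / mse
}

#' Select loci by importance threshold
#'
#' @param importances Named numeric vector of percent-change-in-MSE values.
#' @param cut Threshold in percent; selection is strict (`> cut`).
#' @return Character vector of selected locus ids (possibly empty).
#' @export
select_important <- function(importances, cut = 6) {
  names(importances)[importances > cut]
}

#' Error on an external validation series
#'
#' @param forest A fitted classification `randomForest`.
#' @param X2 Held-out sample x locus matrix (same loci as training).
#' @param y2 Held-out labels.
#' @return Misclassification proportion.
#' @export
external_error <- function(forest, X2, y2) {
  pred <- stats::predict(forest, X2)
  mean(as.character(pred) != as.character(y2))
}

#' Full random-forest screen for one series
#'
#' Tunes mtry, runs the OOB permutation test at the tuned mtry, computes
#' percent-change-in-MSE importances and applies the selection threshold.
#'
#' @param m A [meth_matrix()].
#' @param sheet Sample sheet with `sample_id` and logical `invasive`.
#' @param config An [rf_config()].
#' @param seed Integer master seed for the screen.
#' @param permutation Run the OOB permutation test (slowest part)?
#'   Default TRUE.
#' @return List: `best_m`, `oob_by_m`, `observed_oob`, `perm` (NULL or the
#'   [oob_permutation_test()] result), `importance`, `selected`, `forest`
#'   (the tuned classification forest, for external validation).
#' @export
rf_screen <- function(m, sheet, config = rf_config(), seed = 1L,
                      permutation = TRUE) {
  stopifnot(inherits(m, "meth_matrix"))
  idx <- match(rownames(m$beta), sheet$sample_id)
  if (anyNA(idx)) stop("sample sheet missing samples present in the matrix",
                       call. = FALSE)
  y <- factor(ifelse(as.logical(sheet$invasive[idx]),
                     "invasive", "noninvasive"))
  X <- m$beta
  tuned <- tune_mtry(X, y, config, seed = seed)
  set.seed(seed + 1L)
  forest <- randomForest::randomForest(X, y, ntree = config$n_trees,
                                       mtry = tuned$best_m)
  observed <- unname(forest$err.rate[config$n_trees, "OOB"])
  perm <- NULL
  if (permutation) {
    perm <- oob_permutation_test(X, y, config, mtry = tuned$best_m,
                                 seed = seed + 2L)
  }
  imp <- rf_importance(X, y, config, mtry = tuned$best_m, seed = seed + 3L)
  list(best_m = tuned$best_m, oob_by_m = tuned$oob, observed_oob = observed,
       perm = perm, importance = imp,
       selected = select_important(imp, config$importance_cut),
       forest = forest)
}
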