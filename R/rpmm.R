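#' @name rpmm
#' @title Recursively partitioned beta-mixture models
#'
#' @description
#' Model-based clustering of methylation profiles. Each latent class k gives
#' locus j a beta distribution with parameters (a_jk, b_jk); loci are
#' independent given class. The profile population is split recursively with
#' 2-class mixtures fitted by EM, a split being retained only when the
#' 2-class BIC improves on the 1-class BIC at that node. Recursion passes
#' fractional sample weights (the responsibilities), so no sample is hard-
#' assigned until the tree is final.
NULL

clamp_beta_values <- function(X, eps = 1e-6) pmin(pmax(X, eps), 1 - eps)

# trapezoidal rule on an equally spaced grid
trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

# Weighted beta maximum likelihood, vectorized over loci.
# u: n-vector of nonnegative weights; returns list(a, b, obj) where obj is
# the per-locus weighted log-likelihood divided by sum(u).
beta_ml <- function(X, logX, log1mX, u, floor_par = 1e-3, cap_par = 1e7,
                    max_iter = 50, tol = 1e-10) {
  U <- sum(u)
  if (U <= 1e-10) stop("effective weight collapsed to zero", call. = FALSE)
  s1 <- as.vector(crossprod(u, logX)) / U
  s2 <- as.vector(crossprod(u, log1mX)) / U
  m <- as.vector(crossprod(u, X)) / U
  v <- as.vector(crossprod(u, X^2)) / U - m^2
  v <- pmax(v, 1e-9)
  phi <- pmax(m * (1 - m) / v - 1, 1e-2)
  a <- pmin(pmax(m * phi, floor_par), cap_par)
  b <- pmin(pmax((1 - m) * phi, floor_par), cap_par)

  obj_fun <- function(a, b) (a - 1) * s1 + (b - 1) * s2 - lbeta(a, b)
  obj <- obj_fun(a, b)
  for (it in seq_len(max_iter)) {
    g1 <- s1 - (digamma(a) - digamma(a + b))
    g2 <- s2 - (digamma(b) - digamma(a + b))
    if (max(abs(c(g1, g2))) < tol) break
    tab <- trigamma(a + b)
    haa <- -(trigamma(a) - tab)
    hbb <- -(trigamma(b) - tab)
    hab <- tab
    det <- haa * hbb - hab^2
    det[abs(det) < 1e-300] <- 1e-300
    da <- (hbb * g1 - hab * g2) / det
    db <- (haa * g2 - hab * g1) / det
    # damped step: halve until inside the box and not worse
    step <- rep(1, length(a))
    for (h in 1:30) {
      an <- a - step * da
      bn <- b - step * db
      bad <- an < floor_par | bn < floor_par | an > cap_par | bn > cap_par
      if (!any(bad)) {
        on <- obj_fun(an, bn)
        bad <- on < obj - 1e-12
        if (!any(bad)) break
      }
      step[bad] <- step[bad] / 2
      if (all(step < 1e-9)) break
    }
    an <- pmin(pmax(a - step * da, floor_par), cap_par)
    bn <- pmin(pmax(b - step * db, floor_par), cap_par)
    on <- obj_fun(an, bn)
    keep <- on >= obj          # never accept a worse point
    a[keep] <- an[keep]
    b[keep] <- bn[keep]
    obj[keep] <- on[keep]
  }
  list(a = a, b = b, obj = obj)
}

# per-sample log density under one class: sum_j log dbeta(x_ij; a_j, b_j)
class_logdens <- function(logX, log1mX, a, b) {
  as.vector(logX %*% (a - 1) + log1mX %*% (b - 1)) - sum(lbeta(a, b))
}

# single-class weighted fit with BIC
fit_one_class <- function(X, logX, log1mX, w) {
  fit <- beta_ml(X, logX, log1mX, w)
  ll <- sum(w * class_logdens(logX, log1mX, fit$a, fit$b))
  n_eff <- sum(w)
  list(a = fit$a, b = fit$b, loglik = ll,
       bic = -2 * ll + 2 * ncol(X) * log(n_eff))
}

#' Fit a weighted 2-class beta mixture by EM
#'
#' EM with the M-step solving the weighted beta likelihood equations by a
#' damped Newton iteration on the digamma equations (initialized at weighted
#' method-of-moments, parameters floored at 1e-3). Initial responsibilities
#' come from a deterministic split of the samples at the weighted median of
#' their scores on the first principal direction of the logit-beta matrix.
#' The weighted log-likelihood is nondecreasing over iterations (the M-step
#' never accepts a worse parameter point).
#'
#' @param X Numeric matrix, samples x loci, values clamped internally to
#'   \[1e-6, 1 - 1e-6\]. Needs at least 4 samples.
#' @param w Optional nonnegative sample weights (default all 1).
#' @param max_iter Maximum EM iterations, default 1000.
#' @param tol Relative log-likelihood convergence tolerance, default 1e-6.
#' @return A `beta_mixture_node`: list with `eta` (class weights), `a`, `b`
#'   (loci x 2 parameter matrices), `resp` (n x 2 responsibilities),
#'   `loglik`, `loglik_trace`, `bic`, `converged`, `n_iter`.
#' @export
fit_two_class <- function(X, w = NULL, max_iter = 1000, tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  J <- ncol(X)
  if (n < 4) stop("need at least 4 samples to fit a 2-class mixture",
                  call. = FALSE)
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(w) == n, all(w >= 0))
  X <- clamp_beta_values(X)
  logX <- log(X)
  log1mX <- log1p(-X)

  # deterministic init: split at weighted median of first PC of logit(X)
  L <- stats::qlogis(X)
  wc <- w / sum(w)
  ctr <- sweep(L, 2, colSums(L * wc))
  sv <- svd(ctr * sqrt(wc), nu = 0, nv = 1)
  score <- as.vector(ctr %*% sv$v[, 1])
  # weighted median: zero-weight samples must not influence the split point
  o <- order(score)
  med <- score[o][which(cumsum(wc[o]) >= 0.5)[1]]
  r <- cbind(ifelse(score <= med, 0.95, 0.05),
             ifelse(score <= med, 0.05, 0.95))

  a <- b <- matrix(NA_real_, J, 2)
  eta <- c(0.5, 0.5)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # M-step
    eta <- as.vector(crossprod(w, r)) / sum(w)
    eta <- pmax(eta, 1e-8)
    eta <- eta / sum(eta)
    for (k in 1:2) {
      u <- w * r[, k]
      if (sum(u) > 1e-8) {
        fit <- beta_ml(X, logX, log1mX, u)
        if (!anyNA(a[, k])) {
          # keep the better of old/new per locus (M-step monotonicity)
          U <- sum(u)
          s1 <- as.vector(crossprod(u, logX)) / U
          s2 <- as.vector(crossprod(u, log1mX)) / U
          obj_old <- (a[, k] - 1) * s1 + (b[, k] - 1) * s2 -
            lbeta(a[, k], b[, k])
          worse <- fit$obj < obj_old
          fit$a[worse] <- a[worse, k]
          fit$b[worse] <- b[worse, k]
        }
        a[, k] <- fit$a
        b[, k] <- fit$b
      }
    }
    # E-step
    lg <- cbind(log(eta[1]) + class_logdens(logX, log1mX, a[, 1], b[, 1]),
                log(eta[2]) + class_logdens(logX, log1mX, a[, 2], b[, 2]))
    mx <- pmax(lg[, 1], lg[, 2])
    se <- exp(lg - mx)
    ll <- sum(w * (mx + log(rowSums(se))))
    r <- se / rowSums(se)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) {
    warning(sprintf(
      "2-class EM did not converge in %d iterations (last loglik %.6g)",
      max_iter, ll_trace[length(ll_trace)]))
  }
  n_eff <- sum(w)
  structure(list(eta = eta, a = a, b = b, resp = r,
                 loglik = ll_trace[length(ll_trace)],
                 loglik_trace = ll_trace,
                 bic = -2 * ll_trace[length(ll_trace)] +
                   (4 * J + 1) * log(n_eff),
                 converged = converged, n_iter = length(ll_trace)),
            class = "beta_mixture_node")
}

#' Recursively partition a methylation matrix
#'
#' Starting from all samples, repeatedly fits weighted 2-class beta mixtures
#' and accepts a split when the 2-class BIC at the node beats the 1-class
#' BIC (both computed with the node's effective sample size, the sum of its
#' fractional weights). Children receive weights `w * responsibility`.
#' Nodes with effective mass below `min_node` are not split.
#'
#' @param X Numeric matrix (samples x loci) or a [meth_matrix()].
#' @param min_node Minimum effective samples to attempt a split, default 8.
#' @param max_depth Maximum recursion depth, default 6.
#' @param max_iter,tol Passed to [fit_two_class()].
#' @return An `rpmm_tree`: list with `root` (nested nodes), `leaves` (list of
#'   leaf records: `path`, `a`, `b`, `weight`), `loci`, `n_samples`.
#'   Leaf paths are strings like "rLR" (root, left, right).
#' @export
recursive_partition <- function(X, min_node = 8, max_depth = 6,
                                max_iter = 1000, tol = 1e-6) {
  if (inherits(X, "meth_matrix")) X <- X$beta
  X <- clamp_beta_values(as.matrix(X))
  logX <- log(X)
  log1mX <- log1p(-X)
  n <- nrow(X)

  build <- function(w, path, depth) {
    one <- fit_one_class(X, logX, log1mX, w)
    make_leaf <- function() {
      list(type = "leaf", path = path, a = one$a, b = one$b,
           weight = sum(w), loglik = one$loglik, bic = one$bic)
    }
    if (sum(w) < min_node || depth >= max_depth) return(make_leaf())
    two <- tryCatch(
      suppressWarnings(fit_two_class(X, w, max_iter = max_iter, tol = tol)),
      error = function(e) NULL)
    if (is.null(two) || two$bic >= one$bic) return(make_leaf())
    list(type = "split", path = path,
         eta = two$eta, a = two$a, b = two$b,
         bic_split = two$bic, bic_leaf = one$bic,
         left = build(w * two$resp[, 1], paste0(path, "L"), depth + 1),
         right = build(w * two$resp[, 2], paste0(path, "R"), depth + 1))
  }
  root <- build(rep(1, n), "r", 0)

  leaves <- list()
  collect <- function(node) {
    if (node$type == "leaf") {
      leaves[[length(leaves) + 1]] <<- node[c("path", "a", "b", "weight")]
    } else {
      collect(node$left)
      collect(node$right)
    }
  }
  collect(root)
  structure(list(root = root, leaves = leaves,
                 loci = colnames(X), n_samples = n),
            class = "rpmm_tree")
}

#' @export
print.rpmm_tree <- function(x, ...) {
  cat(sprintf("rpmm_tree: %d leaves over %d samples x %d loci\n",
              length(x$leaves), x$n_samples, length(x$loci)))
  for (lf in x$leaves) {
    cat(sprintf("  leaf %-6s effective n = %.1f\n", lf$path, lf$weight))
  }
  invisible(x)
}

#' Empirical-Bayes class membership
#'
#' Posterior probability of each leaf for each sample: the product of the
#' branch responsibilities along the path from the root, computed from the
#' fitted node parameters. Rows sum to 1.
#'
#' @param tree An [recursive_partition()] tree.
#' @param X Matrix or [meth_matrix()] with the tree's loci.
#' @return n x n_leaves matrix of posterior probabilities; columns named by
#'   leaf path.
#' @export
eb_membership <- function(tree, X) {
  stopifnot(inherits(tree, "rpmm_tree"))
  if (inherits(X, "meth_matrix")) X <- X$beta
  X <- clamp_beta_values(as.matrix(X))
  if (!is.null(colnames(X)) && !is.null(tree$loci)) {
    stopifnot(identical(colnames(X), tree$loci))
  }
  logX <- log(X)
  log1mX <- log1p(-X)
  walk <- function(node) {
    if (node$type == "leaf") {
      m <- matrix(1, nrow(X), 1)
      colnames(m) <- node$path
      return(m)
    }
    lg <- cbind(log(node$eta[1]) +
                  class_logdens(logX, log1mX, node$a[, 1], node$b[, 1]),
                log(node$eta[2]) +
                  class_logdens(logX, log1mX, node$a[, 2], node$b[, 2]))
    mx <- pmax(lg[, 1], lg[, 2])
    se <- exp(lg - mx)
    r <- se / rowSums(se)
    cbind(walk(node$left) * r[, 1], walk(node$right) * r[, 2])
  }
  post <- walk(tree$root)
  rownames(post) <- rownames(X)
  post
}

#' Hard class assignment from the tree
#'
#' @inheritParams eb_membership
#' @return Factor of leaf paths, one per sample (argmax posterior).
#' @export
rpmm_classes <- function(tree, X) {
  post <- eb_membership(tree, X)
  factor(colnames(post)[max.col(post, ties.method = "first")],
         levels = colnames(post))
}

#' Permutation chi-square test of class vs phenotype
#'
#' Pearson chi-square statistic on the class x phenotype contingency table,
#' with significance from permuting the phenotype labels. The p-value is
#' `(1 + #{null >= observed}) / (1 + B)`, so its floor is `1 / (B + 1)`.
#'
#' @param classes Vector/factor of class labels (>= 2 levels present).
#' @param phenotype Vector/factor of phenotype labels (>= 2 levels present).
#' @param B Number of permutations, default 10000.
#' @return List: `statistic`, `p`, `B`, `table` (observed table).
#' @export
permutation_chisq <- function(classes, phenotype, B = 10000) {
  cf <- factor(classes)
  pf <- factor(phenotype)
  cf <- droplevels(cf)
  pf <- droplevels(pf)
  if (nlevels(pf) < 2) stop("phenotype is constant: degenerate table",
                            call. = FALSE)
  if (nlevels(cf) < 2) stop("need at least 2 classes", call. = FALSE)
  stopifnot(length(cf) == length(pf), B >= 1)
  C <- nlevels(cf)
  P <- nlevels(pf)
  ci <- as.integer(cf)
  pi_ <- as.integer(pf)
  n <- length(ci)
  # expected counts depend only on the margins, invariant under permutation
  E <- as.vector(outer(tabulate(ci, C), tabulate(pi_, P))) / n
  stat_of <- function(pv) {
    counts <- tabulate((pv - 1L) * C + ci, C * P)
    sum((counts - E)^2 / E)
  }
  observed <- stat_of(pi_)
  null <- vapply(seq_len(B), function(b) stat_of(sample(pi_)), numeric(1))
  p <- (1 + sum(null >= observed - 1e-12)) / (1 + B)
  list(statistic = observed, p = p, B = B,
       table = table(class = cf, phenotype = pf))
}

#' Class-versus-rest AUC for one locus
#'
#' How well locus j separates leaf class k from all other classes pooled.
#' The pooled complement is approximated by a normal distribution G moment-
#' matched to the prevalence-weighted mixture of the other leaves' beta
#' distributions at locus j (truncated to \[0, 1\] and renormalized). The
#' AUC is P(X_k > X_other), computed by trapezoidal integration of
#' the beta survival function against the normal density on a 10,001-point
#' grid over \[0, 1\], then folded to `max(AUC, 1 - AUC)` so that whichever
#' direction dominates is reported.
#'
#' @param tree An [recursive_partition()] tree with at least 2 leaves.
#' @param j Locus index or locus id.
#' @param k Leaf index or leaf path.
#' @param grid_n Number of integration grid points, default 10001.
#' @return AUC in \[0.5, 1\].
#' @export
class_auc <- function(tree, j, k, grid_n = 10001) {
  stopifnot(inherits(tree, "rpmm_tree"))
  if (length(tree$leaves) < 2) {
    stop("class-vs-rest AUC is undefined for a single-leaf tree",
         call. = FALSE)
  }
  if (is.character(j)) j <- match(j, tree$loci)
  paths <- vapply(tree$leaves, `[[`, character(1), "path")
  if (is.character(k)) k <- match(k, paths)
  stopifnot(!is.na(j), !is.na(k))
  lf <- tree$leaves[[k]]
  a <- lf$a[j]
  b <- lf$b[j]
  others <- tree$leaves[-k]
  wts <- vapply(others, `[[`, numeric(1), "weight")
  wts <- wts / sum(wts)
  ma <- vapply(others, function(o) o$a[j], numeric(1))
  mb <- vapply(others, function(o) o$b[j], numeric(1))
  mns <- ma / (ma + mb)
  vrs <- ma * mb / ((ma + mb)^2 * (ma + mb + 1))
  mu <- sum(wts * mns)
  sig2 <- sum(wts * (vrs + mns^2)) - mu^2
  sig <- sqrt(max(sig2, 0))
  if (sig < 1e-8) {
    auc <- 1 - stats::pbeta(mu, a, b)
  } else {
    g <- seq(0, 1, length.out = grid_n)
    dens <- stats::dnorm(g, mu, sig)
    Z <- trapz(g, dens)
    auc <- trapz(g, (1 - stats::pbeta(g, a, b)) * dens) / Z
  }
  max(auc, 1 - auc)
}

#' Rank loci by their best class-versus-rest AUC
#'
#' @inheritParams class_auc
#' @return An `auc_ranking` data frame: `locus`, one `auc_<path>` column per
#'   leaf, and `max_auc` (the per-locus maximum over leaves), sorted by
#'   decreasing `max_auc`.
#' @export
rank_loci_by_auc <- function(tree, grid_n = 10001) {
  stopifnot(inherits(tree, "rpmm_tree"))
  J <- length(tree$loci)
  K <- length(tree$leaves)
  paths <- vapply(tree$leaves, `[[`, character(1), "path")
  aucs <- matrix(NA_real_, J, K,
                 dimnames = list(tree$loci, paste0("auc_", paths)))
  for (k in seq_len(K)) {
    for (j in seq_len(J)) {
      aucs[j, k] <- class_auc(tree, j, k, grid_n = grid_n)
    }
  }
  out <- data.frame(locus = tree$loci, aucs, max_auc = apply(aucs, 1, max),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$max_auc), ]
  rownames(out) <- NULL
  class(out) <- c("auc_ranking", "data.frame")
  out
}
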