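make_two_class_data <- function(n = 200, J = 50, m1 = 0.2, m2 = 0.8,
                                prec = 10, seed = 1) {
  set.seed(seed)
  cls <- rep(1:2, each = n / 2)
  mu <- ifelse(cls == 1, m1, m2)
  X <- matrix(rbeta(n * J, rep(mu * prec, J), rep((1 - mu) * prec, J)),
              n, J, dimnames = list(paste0("s", 1:n), paste0("L", 1:J)))
  list(X = X, cls = cls)
}

test_that("two-class EM recovers parameters with monotone log-likelihood", {
  d <- make_two_class_data(seed = 61)
  fit <- fit_two_class(d$X)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  expect_true(fit$converged)

  means <- colMeans(fit$a / (fit$a + fit$b))
  expect_equal(sort(means), c(0.2, 0.8), tolerance = 0.05)

  hard <- max.col(fit$resp)
  ari <- mclust::adjustedRandIndex(hard, d$cls)
  expect_gt(ari, 0.95)

  # parameter recovery across seeds: median |fitted mean - truth| < 0.02
  errs <- vapply(1:10, function(s) {
    dd <- make_two_class_data(n = 200, J = 30, seed = 100 + s)
    f <- fit_two_class(dd$X)
    m <- f$a / (f$a + f$b)
    lo <- which.min(colMeans(m))
    median(abs(c(m[, lo] - 0.2, m[, -lo] - 0.8)))
  }, numeric(1))
  expect_lt(median(errs), 0.02)

  expect_error(fit_two_class(d$X[1:3, ]), "at least 4")
})

test_that("EM log-likelihood is nondecreasing on varied fixtures", {
  for (s in 1:5) {
    set.seed(70 + s)
    X <- matrix(rbeta(40 * 10, 2, 5), 40, 10)
    fit <- suppressWarnings(fit_two_class(X))
    expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  }
})

test_that("BIC rejects splitting homogeneous data and accepts real structure", {
  # single beta per locus: 2-class BIC worse than 1-class, tree has 1 leaf
  set.seed(81)
  X0 <- matrix(rbeta(100 * 30, 2, 8), 100, 30)
  tree0 <- recursive_partition(X0)
  expect_length(tree0$leaves, 1)

  # two clear classes: exactly 2 leaves
  d <- make_two_class_data(seed = 82)
  tree2 <- recursive_partition(d$X)
  expect_length(tree2$leaves, 2)
})

test_that("four well-separated classes give a 4-leaf tree with true means", {
  coh <- generate_cohort(cohort_config(n_samples = 240, n_loci = 100,
                                       n_classes = 4,
                                       class_means = c(0.15, 0.35, 0.60,
                                                       0.85),
                                       frac_sex_loci = 0, seed = 91))
  tree <- recursive_partition(coh$matrix)
  expect_length(tree$leaves, 4)
  fitted <- sort(vapply(tree$leaves,
                        function(l) mean(l$a / (l$a + l$b)), numeric(1)))
  expect_equal(fitted, c(0.15, 0.35, 0.60, 0.85), tolerance = 0.05)

  cls <- rpmm_classes(tree, coh$matrix)
  expect_gt(mclust::adjustedRandIndex(cls, coh$truth$class), 0.9)
})

test_that("refitting two merged leaves reproduces the parent split", {
  coh <- generate_cohort(cohort_config(n_samples = 240, n_loci = 100,
                                       n_classes = 4,
                                       class_means = c(0.15, 0.35, 0.60,
                                                       0.85),
                                       frac_sex_loci = 0, seed = 92))
  tree <- recursive_partition(coh$matrix)
  expect_length(tree$leaves, 4)
  # take the two leaves under one side of the root and refit their samples
  paths <- vapply(tree$leaves, `[[`, character(1), "path")
  side <- paths[startsWith(paths, "rL")]
  if (length(side) == 2) {
    cls <- rpmm_classes(tree, coh$matrix)
    sub <- coh$matrix$beta[cls %in% side, ]
    refit <- fit_two_class(sub)
    ref_means <- sort(colMeans(refit$a / (refit$a + refit$b)))
    node_means <- sort(vapply(tree$leaves[paths %in% side],
                              function(l) mean(l$a / (l$a + l$b)),
                              numeric(1)))
    expect_equal(ref_means, node_means, tolerance = 0.05)
  } else {
    succeed("root split did not isolate a two-leaf side; covered by seeds")
  }
})

test_that("empirical-Bayes membership is row-stochastic and sharp when separated", {
  d <- make_two_class_data(n = 100, J = 40, prec = 20, seed = 93)
  tree <- recursive_partition(d$X)
  post <- eb_membership(tree, d$X)
  expect_equal(unname(rowSums(post)), rep(1, nrow(post)), tolerance = 1e-12)
  expect_gt(min(apply(post, 1, max)), 0.99)

  # symmetric two-leaf tree, sample at the likelihood midpoint -> (0.5, 0.5)
  sym <- structure(list(
    root = list(type = "split", path = "r", eta = c(0.5, 0.5),
                a = matrix(c(2, 8), 1, 2), b = matrix(c(8, 2), 1, 2),
                left = list(type = "leaf", path = "rL", a = 2, b = 8,
                            weight = 1),
                right = list(type = "leaf", path = "rR", a = 8, b = 2,
                             weight = 1)),
    leaves = list(list(path = "rL", a = 2, b = 8, weight = 1),
                  list(path = "rR", a = 8, b = 2, weight = 1)),
    loci = "L1", n_samples = 2), class = "rpmm_tree")
  p <- eb_membership(sym, matrix(0.5, 1, 1, dimnames = list("s", "L1")))
  expect_equal(unname(p[1, ]), c(0.5, 0.5))
})

test_that("permutation chi-square has the right floor, nulls, and errors", {
  # perfectly aligned classes and phenotype: p at the permutation floor
  cls <- rep(c("A", "B"), each = 30)
  ph <- rep(c(0, 1), each = 30)
  res <- permutation_chisq(cls, ph, B = 10000)
  expect_equal(res$p, 1 / 10001)
  expect_lt(res$p, 1e-4)

  # observed statistic 0 (class-conditional distributions identical): p = 1
  cls2 <- c(1, 1, 2, 2)
  ph2 <- c("a", "b", "a", "b")
  res2 <- permutation_chisq(cls2, ph2, B = 200)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p, 1)

  expect_error(permutation_chisq(cls, rep(1, 60)), "constant")
  expect_error(permutation_chisq(rep("A", 60), ph), "2 classes")
})

test_that("class-vs-rest AUC matches oracles and folds correctly", {
  two_leaf_tree <- function(a1, b1, a2, b2, w = c(1, 1)) {
    structure(list(
      root = NULL,
      leaves = list(list(path = "rL", a = a1, b = b1, weight = w[1]),
                    list(path = "rR", a = a2, b = b2, weight = w[2])),
      loci = "L1", n_samples = sum(w)), class = "rpmm_tree")
  }
  # identical symmetric class distributions: AUC = 0.5 (exact by symmetry)
  t_sym <- two_leaf_tree(8, 8, 8, 8)
  expect_lt(abs(class_auc(t_sym, 1, 1) - 0.5), 1e-3)
  # identical skewed distributions: near 0.5, with a small gap from the
  # normal approximation of the complement
  t_eq <- two_leaf_tree(2, 8, 2, 8)
  expect_lt(abs(class_auc(t_eq, 1, 1) - 0.5), 0.05)

  # effectively disjoint supports
  t_dis <- two_leaf_tree(50, 2, 2, 50)
  expect_gte(class_auc(t_dis, 1, 1), 0.999)

  # Beta(2,8) vs a complement moment-matched to mean 0.6, sd 0.1:
  # numeric integral within 0.005 of a 10^6-draw MC oracle
  oa <- 0.6 * 23; ob <- 0.4 * 23   # Beta with mean .6, var ~ 0.01
  t_mc <- two_leaf_tree(2, 8, oa, ob)
  mu <- oa / (oa + ob)
  sig <- sqrt(oa * ob / ((oa + ob)^2 * (oa + ob + 1)))
  set.seed(17)
  xs <- rbeta(2e6, 2, 8)
  ys <- rnorm(2e6, mu, sig)
  keep <- which(ys >= 0 & ys <= 1)[1:1e6]
  mc <- mean(xs[keep] > ys[keep])
  mc <- max(mc, 1 - mc)
  expect_lt(abs(class_auc(t_mc, 1, 1) - mc), 0.005)

  # folding invariance: swapping which class is "of interest"
  expect_equal(class_auc(t_mc, 1, 1), class_auc(t_mc, 1, 2),
               tolerance = 0.02)

  single <- structure(list(root = NULL,
                           leaves = list(list(path = "r", a = 1, b = 1,
                                              weight = 1)),
                           loci = "L1", n_samples = 1),
                      class = "rpmm_tree")
  expect_error(class_auc(single, 1, 1), "single-leaf")
})

test_that("AUC ranking surfaces loci that differ in one class only", {
  coh <- generate_cohort(cohort_config(
    n_samples = 200, n_loci = 30, n_classes = 2,
    class_means = rbind(rep(0.3, 30), c(rep(0.3, 25), rep(0.8, 5))),
    frac_sex_loci = 0, seed = 94))
  tree <- recursive_partition(coh$matrix)
  expect_length(tree$leaves, 2)
  rk <- rank_loci_by_auc(tree)
  spiked <- coh$matrix$annotation$locus[26:30]
  expect_true(all(rk$max_auc[match(spiked, rk$locus)] > 0.9))
  expect_true(all(rk$max_auc[!rk$locus %in% spiked] < 0.75))
  # exchangeable loci sit near 0.5
  expect_lt(max(rk$max_auc[!rk$locus %in% spiked]), 0.65)
})
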