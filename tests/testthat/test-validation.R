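make_pyro <- function(values_by_site, gene = "HOXB2") {
  n <- length(values_by_site[[1]])
  do.call(rbind, lapply(seq_along(values_by_site), function(s) {
    data.frame(sample_id = paste0("s", 1:n), gene = gene, site = s,
               pct_meth = values_by_site[[s]], stringsAsFactors = FALSE)
  }))
}

test_that("site correlations are Spearman on ranks", {
  v <- c(10, 30, 20, 50, 40, 60)
  t1 <- make_pyro(list(v, v))
  expect_equal(site_correlations(t1, "HOXB2")[1, 2], 1)

  t2 <- make_pyro(list(v, rev(sort(v))[rank(v)]))  # reversed ranks
  expect_equal(site_correlations(t2, "HOXB2")[1, 2], -1)

  # 6-sample fixture vs hand-ranked oracle
  a <- c(12, 45, 23, 67, 34, 51)
  b <- c(15, 40, 30, 60, 28, 55)
  t3 <- make_pyro(list(a, b))
  expect_equal(site_correlations(t3, "HOXB2")[1, 2],
               cor(rank(a), rank(b)))
})

test_that("gene means average observed sites and report the count", {
  t1 <- make_pyro(list(c(10, 20), c(20, 40), c(30, 60)))
  m <- gene_mean(t1, "HOXB2")
  expect_equal(m$mean_pct, c(20, 40))
  expect_equal(m$n_sites, c(3L, 3L))

  # single site: identity
  t2 <- make_pyro(list(c(11, 22)))
  expect_equal(gene_mean(t2, "HOXB2")$mean_pct, c(11, 22))

  # a missing site is averaged over the observed ones
  t3 <- t1
  t3$pct_meth[t3$sample_id == "s1" & t3$site == 3] <- NA
  m3 <- gene_mean(t3, "HOXB2")
  expect_equal(m3$mean_pct[m3$sample_id == "s1"], 15)
  expect_equal(m3$n_sites[m3$sample_id == "s1"], 2L)
})

test_that("Kruskal-Wallis H matches hand computation and handles ties", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0)

  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$H, 7.2)
  expect_equal(r$df, 2)
  expect_equal(r$p, pchisq(7.2, 2, lower.tail = FALSE))

  ties <- list(c(1, 1, 2, 2), c(2, 3, 3, 4), c(4, 4, 5, 5))
  expect_equal(kruskal_wallis(ties)$H, oracle_kw(ties))

  # invariance under monotone transforms
  g <- list(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  expect_equal(kruskal_wallis(g)$H,
               kruskal_wallis(lapply(g, function(v) exp(v)))$H)
})

test_that("rank-sum p matches exhaustive enumeration and honors protection", {
  set.seed(23)
  for (i in 1:5) {
    a <- round(runif(4, 0, 100), 3)
    b <- round(runif(4, 0, 100), 3)
    mine <- ranksum(a, b)
    expect_true(mine$exact)
    expect_equal(mine$p, oracle_ranksum_exact(a, b))
  }
  # symmetric singleton swap
  expect_equal(ranksum(1, 2)$p, 1)

  gated <- ranksum(1:5, 6:10, protected_by = 0.2)
  expect_false(gated$tested)
  expect_true(is.na(gated$p))
  open <- ranksum(1:5, 6:10, protected_by = 0.01)
  expect_true(open$tested)
})

test_that("median dichotomization uses the <= rule", {
  expect_equal(dichotomize_median(c(1, 2, 3, 4)),
               c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(dichotomize_median(rep(5, 4)), rep(FALSE, 4))
  expect_equal(dichotomize_median(c(1, 2, 3)), c(FALSE, FALSE, TRUE))
  # idempotent on duplicated boundary samples
  v <- c(1, 2, 2, 3)
  expect_equal(dichotomize_median(v), c(FALSE, FALSE, FALSE, TRUE))
})

test_that("2x2 odds ratios reproduce printed counts and flag corrections", {
  # printed HOXB2 counts: (110, 8) negative, (61, 53) positive
  r <- or_from_2x2(c(110, 8, 61, 53))
  expect_equal(r$or, (53 * 110) / (8 * 61), tolerance = 1e-12)
  expect_equal(r$or, 11.95, tolerance = 0.001)
  expect_false(r$corrected)
  expect_lt(r$ci[1], r$or)
  expect_gt(r$ci[2], r$or)

  expect_equal(or_from_2x2(c(10, 10, 10, 10))$or, 1)

  z <- or_from_2x2(c(10, 0, 5, 5))
  expect_true(z$corrected)
  expect_true(is.finite(z$or))
  expect_error(or_from_2x2(c(-1, 2, 3, 4)), "nonnegative")
})

test_that("logistic single-exposure fit equals the 2x2 cross-product OR", {
  set.seed(29)
  for (i in 1:5) {
    n <- 150
    x <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(-1 + 1.5 * x))
    tab <- c(sum(x == 0 & y == 0), sum(x == 0 & y == 1),
             sum(x == 1 & y == 0), sum(x == 1 & y == 1))
    if (any(tab == 0)) next
    fit <- logistic_fit(y, data.frame(x = x))
    expect_equal(fit$or[fit$term == "x"], or_from_2x2(tab)$or,
                 tolerance = 1e-6)
  }
  # CI contains the OR by construction
  fit <- logistic_fit(rbinom(100, 1, 0.3), data.frame(x = rnorm(100)))
  expect_true(all(fit$ci_low <= fit$or & fit$or <= fit$ci_high))
})

test_that("perfect separation raises an explicit error", {
  x <- c(rep(0, 20), rep(1, 20))
  y <- x
  expect_error(logistic_fit(y, data.frame(x = x)), "separation|converge")
})

test_that("the all-three-genes score matches the printed panel margins", {
  expect_true(additive_score(list(TRUE, TRUE, TRUE)))
  expect_false(additive_score(list(TRUE, TRUE, FALSE)))

  # printed panel counts: all-3 = 18 + 11 = 29, fewer = 125 + 8 = 133
  tab <- read.csv(system.file("extdata", "printed_tables.csv",
                              package = "methmark"))
  panel <- tab[tab$table == 3 & tab$model == "panel", ]
  all3 <- sum(panel$count[panel$row %in% c("all3_low", "all3_high")])
  fewer <- sum(panel$count[panel$row %in% c("fewer_low", "fewer_high")])
  expect_equal(all3, 29)
  expect_equal(fewer, 133)
})

test_that("tumor-fraction sensitivity reports near-zero deltas under the null", {
  set.seed(31)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.5 + 1 * x))
  tumor <- runif(n, 75, 100)          # independent of outcome and exposure
  res <- tumor_fraction_sensitivity(y, data.frame(x = x), tumor)
  expect_false(res$collinear)
  expect_lt(max(abs(res$delta[names(res$delta) != "(Intercept)"])), 0.3)

  # collinear covariate is flagged, not refit
  res2 <- tumor_fraction_sensitivity(y, data.frame(x = x),
                                     x * 10 + 50)
  expect_true(res2$collinear)
  expect_null(res2$adjusted)
})

test_that("Pfaffl fold change follows the efficiency-corrected ratio", {
  expect_equal(pfaffl_fold_change(2, 0, 2, 0), 1)
  expect_equal(pfaffl_fold_change(2, 1, 2, 0), 2)
  expect_equal(pfaffl_fold_change(1.95, 7, 2, 0.5),
               1.95^7 / 2^0.5, tolerance = 1e-12)
  expect_equal(pfaffl_fold_change(1.95, 7, 2, 0.5), 75.88, tolerance = 0.01)
})
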