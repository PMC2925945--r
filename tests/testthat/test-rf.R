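test_that("mtry grid spans half to twice sqrt(M), clipped", {
  expect_equal(mtry_grid(1413), c(19, 75))
  expect_equal(mtry_grid(100), c(5, 20))
  expect_equal(mtry_grid(1), c(1, 1))
  expect_equal(mtry_grid(2), c(1, 2))
})

test_that("mtry tuning is seeded, tie-broken small, and finds signal", {
  pair <- generate_cohort(cohort_config(n_samples = 80, n_loci = 20,
                                        frac_differential = 0.25,
                                        diff_mean = 0.75, frac_sex_loci = 0,
                                        seed = 31))
  y <- pair$sheet$invasive
  cfg <- rf_config(n_trees = 200, m_grid = c(2, 4, 8))
  t1 <- tune_mtry(pair$matrix$beta, y, cfg, seed = 5)
  t2 <- tune_mtry(pair$matrix$beta, y, cfg, seed = 5)
  expect_identical(t1, t2)
  expect_true(t1$best_m %in% c(2, 4, 8))
  # strongly separable data: OOB near zero at the tuned m
  expect_lt(min(t1$oob), 0.1)
  # tie-break toward smallest m
  fake <- c(`2` = 0.2, `4` = 0.2, `8` = 0.3)
  expect_equal(c(2, 4, 8)[which.min(fake)], 2)
  expect_error(tune_mtry(pair$matrix$beta, rep(TRUE, 80), cfg),
               "two classes")
})

test_that("OOB permutation p-values hit the floor on separable data", {
  pair <- generate_cohort(cohort_config(n_samples = 40, n_loci = 10,
                                        frac_differential = 0.5,
                                        diff_mean = 0.85, precision = 30,
                                        frac_sex_loci = 0, seed = 41))
  res <- oob_permutation_test(pair$matrix$beta, pair$sheet$invasive,
                              rf_config(n_trees = 100, n_perm = 100),
                              seed = 2)
  expect_equal(res$p, 1 / 101)
  expect_length(res$null, 100)
  # invariance to relabeling the two classes
  res2 <- oob_permutation_test(pair$matrix$beta, !pair$sheet$invasive,
                               rf_config(n_trees = 100, n_perm = 100),
                               seed = 2)
  expect_equal(res2$p, res$p)
  # p always within its defined range
  expect_gte(res$p, 1 / 101)
  expect_lte(res$p, 1)
})

test_that("importance selection is strict and monotone in the cut", {
  imp <- c(a = 7, b = 6, c = 5.5, d = 1)
  expect_identical(select_important(imp, 6), "a")
  expect_identical(select_important(c(x = 0, y = 0), 6), character(0))
  s5 <- select_important(imp, 5)
  s6 <- select_important(imp, 6)
  expect_true(all(s6 %in% s5))
})

test_that("spiked loci dominate percent-change-in-MSE importance", {
  hits <- 0
  fp_frac <- numeric(0)
  for (s in 1:5) {
    pair <- generate_cohort(cohort_config(n_samples = 100, n_loci = 40,
                                          frac_differential = 0.125,
                                          diff_mean = 0.6,
                                          frac_sex_loci = 0,
                                          seed = 600 + s))
    imp <- rf_importance(pair$matrix$beta, pair$sheet$invasive,
                         rf_config(n_trees = 300), seed = s)
    sel <- select_important(imp, 6)
    spiked <- pair$truth$differential_loci
    hits <- hits + all(spiked %in% sel)
    fp_frac <- c(fp_frac, sum(!sel %in% spiked) / max(1, length(sel)))
  }
  expect_equal(hits, 5)
  expect_lte(mean(fp_frac), 0.10)
})

test_that("external-series error is deterministic and near 0/baseline as expected", {
  pair <- generate_series_pair(
    cohort_config(n_samples = 60, n_loci = 20, frac_differential = 0.25,
                  diff_mean = 0.8, frac_sex_loci = 0, seed = 51),
    cohort_config(n_samples = 80, n_loci = 20, frac_differential = 0.25,
                  diff_mean = 0.8, frac_sex_loci = 0, seed = 52))
  y1 <- factor(pair$series1$sheet$invasive)
  set.seed(1)
  forest <- randomForest::randomForest(pair$series1$matrix$beta, y1,
                                       ntree = 200)
  # training data back through the forest: near-zero error
  expect_lt(external_error(forest, pair$series1$matrix$beta, y1), 0.05)
  # true external series: still strongly better than chance
  y2 <- factor(pair$series2$sheet$invasive)
  e2 <- external_error(forest, pair$series2$matrix$beta, y2)
  expect_lt(e2, 0.2)
  # label-shuffled external series: error near the 50% mixing baseline
  set.seed(9)
  e_null <- external_error(forest, pair$series2$matrix$beta, sample(y2))
  expect_gt(e_null, 0.3)
  # deterministic given the fixed forest
  expect_identical(external_error(forest, pair$series2$matrix$beta, y2), e2)
})
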