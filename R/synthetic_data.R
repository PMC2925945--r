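#' Configuration for a synthetic array cohort
#'
#' Describes a GoldenGate-style methylation cohort: per-locus beta-distributed
#' average-beta values, optional latent methylation classes, a subset of loci
#' differentially methylated (shifted upward) in invasive tumors, detection
#' p-values with a configurable failure rate, and phenotype covariates (age,
#' gender, grade, TP53 IHC intensity) linked to invasive status.
#'
#' Methylation at locus j in a sample of class k is drawn as
#' `Beta(m * s, (1 - m) * s)` where `m` is the class/locus mean and
#' `s = precision` (so the default mean 0.2 with precision 10 is Beta(2, 8)).
#'
#' @param n_samples Number of samples. Default 73 (a Series-1-sized cohort).
#' @param n_loci Number of array loci. Default 500.
#' @param n_classes Number of latent methylation classes (>= 1). Default 1.
#' @param class_weights Simplex vector of class prevalences, length
#'   `n_classes`. Default uniform.
#' @param class_means Either `NULL` (all classes at `baseline_mean`), a vector
#'   of length `n_classes` (one mean per class, applied to every locus), or an
#'   `n_classes x n_loci` matrix of per-class per-locus means.
#' @param baseline_mean Baseline locus mean in (0,1). Default 0.2.
#' @param precision Beta precision a + b (> 0). Default 10.
#' @param invasive_fraction Marginal probability a sample is invasive, used
#'   when `invasive_by_class` is `NULL`. Default 0.42.
#' @param invasive_by_class Optional vector of per-class invasive
#'   probabilities (ties invasiveness to the latent classes).
#' @param frac_differential Fraction of loci differentially methylated by
#'   invasive status. Default 0.
#' @param diff_mean Mean of differential loci in invasive samples (shifted
#'   upward from `baseline_mean`). Default 0.6.
#' @param detect_fail_rate Per-measurement probability of a detection
#'   failure. Passing measurements get p ~ U(0, 1e-6), failing ones
#'   p ~ U(1e-5, 1), matching the operating points of the two QC thresholds.
#'   Default 0.
#' @param frac_sex_loci Fraction of loci annotated on X/Y. Default 0.056
#'   (84/1505, the GoldenGate panel proportion).
#' @param tp53_baseline Probability of high (3+) TP53 IHC staining in
#'   non-invasive samples. Default 0.10.
#' @param tp53_or Odds ratio of high TP53 staining given invasive status.
#'   Default 12 (the crude association seen in validation-series tables).
#' @param age_mean,age_sd Age distribution, default 62 (9.3).
#' @param male_prob Probability male, default 0.73.
#' @param grade_high_prob Probability of high grade (3) given non-invasive /
#'   invasive, length 2. Default c(0.17, 0.85).
#' @param series Series label stored in the sample sheet. Default "S1".
#' @param seed Integer seed; the same config generates byte-identical output.
#'
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_samples = 73, n_loci = 500, n_classes = 1,
                          class_weights = NULL, class_means = NULL,
                          baseline_mean = 0.2, precision = 10,
                          invasive_fraction = 0.42, invasive_by_class = NULL,
                          frac_differential = 0, diff_mean = 0.6,
                          detect_fail_rate = 0, frac_sex_loci = 0.056,
                          tp53_baseline = 0.10, tp53_or = 12,
                          age_mean = 62, age_sd = 9.3, male_prob = 0.73,
                          grade_high_prob = c(0.17, 0.85),
                          series = "S1", seed = 1L) {
  stopifnot(n_samples >= 2, n_loci >= 1, n_classes >= 1)
  if (is.null(class_weights)) class_weights <- rep(1 / n_classes, n_classes)
  if (length(class_weights) != n_classes || any(class_weights < 0) ||
      abs(sum(class_weights) - 1) > 1e-8) {
    stop("class_weights must be a length-n_classes simplex vector",
         call. = FALSE)
  }
  if (!is.null(class_means)) {
    if (is.matrix(class_means)) {
      stopifnot(nrow(class_means) == n_classes, ncol(class_means) == n_loci)
    } else {
      stopifnot(length(class_means) == n_classes)
      class_means <- matrix(class_means, n_classes, n_loci)
    }
    if (any(class_means <= 0 | class_means >= 1)) {
      stop("class means must lie strictly inside (0,1)", call. = FALSE)
    }
  }
  if (precision <= 0) stop("precision must be positive", call. = FALSE)
  stopifnot(baseline_mean > 0, baseline_mean < 1,
            diff_mean > 0, diff_mean < 1,
            frac_differential >= 0, frac_differential <= 1,
            invasive_fraction >= 0, invasive_fraction <= 1,
            detect_fail_rate >= 0, detect_fail_rate <= 1)
  if (!is.null(invasive_by_class)) {
    stopifnot(length(invasive_by_class) == n_classes,
              all(invasive_by_class >= 0), all(invasive_by_class <= 1))
  }
  structure(
    list(n_samples = as.integer(n_samples), n_loci = as.integer(n_loci),
         n_classes = as.integer(n_classes), class_weights = class_weights,
         class_means = class_means, baseline_mean = baseline_mean,
         precision = precision, invasive_fraction = invasive_fraction,
         invasive_by_class = invasive_by_class,
         frac_differential = frac_differential, diff_mean = diff_mean,
         detect_fail_rate = detect_fail_rate, frac_sex_loci = frac_sex_loci,
         tp53_baseline = tp53_baseline, tp53_or = tp53_or,
         age_mean = age_mean, age_sd = age_sd, male_prob = male_prob,
         grade_high_prob = grade_high_prob, series = series,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' Generate a synthetic array cohort
#'
#' Draws a sample x locus average-beta matrix, matching detection p-values,
#' locus annotation, and a phenotype sample sheet from a [cohort_config()].
#' The hidden generative truth (latent class per sample, ids of differential
#' loci) is returned in `truth` for testing only; the analysis pipeline never
#' reads it.
#'
#' @param config A [cohort_config()].
#' @param annotation Optional locus annotation data frame (locus, gene,
#'   chromosome) from a previous cohort, so that a second series shares the
#'   same array panel. Must have `n_loci` rows.
#' @param differential_loci Optional character vector of locus ids to use as
#'   the differential set (overrides the random draw), so that the same loci
#'   are differential in every series of a study.
#' @return A list with elements `matrix` (a [meth_matrix()]), `sheet` (sample
#'   sheet data frame with columns sample_id, age, gender, invasive, grade,
#'   tp53_high, series), and `truth` (list: `class`, `differential_loci`).
#' @export
generate_cohort <- function(config, annotation = NULL,
                            differential_loci = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  J <- config$n_loci

  if (is.null(annotation)) {
    gene <- sprintf("GENE%04d", seq_len(J))
    locus <- sprintf("%s_P%03d", gene, sample(1:999, J, replace = TRUE))
    n_sex <- round(config$frac_sex_loci * J)
    chrom <- sample(as.character(1:22), J, replace = TRUE)
    if (n_sex > 0) {
      sex_idx <- sample.int(J, n_sex)
      chrom[sex_idx] <- sample(c("X", "Y"), n_sex, replace = TRUE)
    }
    annotation <- data.frame(locus = locus, gene = gene, chromosome = chrom,
                             stringsAsFactors = FALSE)
  } else {
    stopifnot(nrow(annotation) == J)
    locus <- annotation$locus
  }

  cls <- sample.int(config$n_classes, n, replace = TRUE,
                    prob = config$class_weights)
  if (!is.null(config$invasive_by_class)) {
    invasive <- stats::rbinom(n, 1, config$invasive_by_class[cls]) == 1
  } else {
    invasive <- stats::rbinom(n, 1, config$invasive_fraction) == 1
  }

  # per-sample per-locus mean: class structure, then invasive shift
  if (is.null(config$class_means)) {
    mu <- matrix(config$baseline_mean, n, J)
  } else {
    mu <- config$class_means[cls, , drop = FALSE]
  }
  if (is.null(differential_loci)) {
    n_diff <- floor(config$frac_differential * J)
    diff_loci <- if (n_diff > 0) locus[sample.int(J, n_diff)] else character(0)
  } else {
    stopifnot(all(differential_loci %in% locus))
    diff_loci <- differential_loci
  }
  if (length(diff_loci) > 0) {
    mu[invasive, match(diff_loci, locus)] <- config$diff_mean
  }
  s <- config$precision
  beta <- matrix(stats::rbeta(n * J, mu * s, (1 - mu) * s), n, J)
  sample_id <- sprintf("%s_T%03d", config$series, seq_len(n))
  dimnames(beta) <- list(sample_id, locus)

  fail <- matrix(stats::rbinom(n * J, 1, config$detect_fail_rate) == 1, n, J)
  detp <- matrix(stats::runif(n * J, 0, 1e-6), n, J)
  detp[fail] <- stats::runif(sum(fail), 1e-5, 1)
  dimnames(detp) <- dimnames(beta)

  lo <- stats::qlogis(config$tp53_baseline)
  tp53 <- stats::rbinom(n, 1, stats::plogis(lo + log(config$tp53_or) *
                                              invasive)) == 1
  grade_p <- ifelse(invasive, config$grade_high_prob[2],
                    config$grade_high_prob[1])
  grade <- ifelse(stats::rbinom(n, 1, grade_p) == 1, "high", "low")
  sheet <- data.frame(
    sample_id = sample_id,
    age = round(stats::rnorm(n, config$age_mean, config$age_sd), 1),
    gender = ifelse(stats::rbinom(n, 1, config$male_prob) == 1,
                    "male", "female"),
    invasive = invasive,
    grade = grade,
    tp53_high = tp53,
    series = config$series,
    stringsAsFactors = FALSE)

  list(matrix = meth_matrix(beta, detp, annotation),
       sheet = sheet,
       truth = list(class = cls, differential_loci = diff_loci))
}

#' Generate two series sharing one array panel and differential locus set
#'
#' Series 2 reuses series 1's locus annotation and differential loci, as two
#' patient series profiled on the same array would.
#'
#' @param config1,config2 [cohort_config()]s with equal `n_loci`.
#' @return List with elements `series1`, `series2` (each a
#'   [generate_cohort()] result).
#' @export
generate_series_pair <- function(config1, config2) {
  stopifnot(config1$n_loci == config2$n_loci)
  s1 <- generate_cohort(config1)
  s2 <- generate_cohort(config2,
                        annotation = s1$matrix$annotation,
                        differential_loci = s1$truth$differential_loci)
  list(series1 = s1, series2 = s2)
}

#' Configuration for a synthetic pyrosequencing table
#'
#' Describes per-gene percent-methylation (0-100) readouts over a few
#' adjacent CpG sites per gene, with group-specific means keyed to a sample
#' sheet column and correlated sites generated through a Gaussian copula with
#' truncated-normal marginals (support kept in \[0, 100\] with a tunable
#' between-site Spearman structure).
#'
#' @param genes Named integer vector: CpG site count per gene, e.g.
#'   `c(HOXB2 = 5, KRT13 = 4, FRZB = 3)`.
#' @param group_var Sample-sheet column defining the groups (e.g. "invasive"
#'   or "grade").
#' @param group_means Named list, one entry per gene; each entry a named
#'   numeric vector of mean percent methylation (0-100) per group level.
#' @param rho Between-site latent Gaussian correlation, strictly inside
#'   (-1, 1). Default 0.8.
#' @param noise_sd Site-level noise scale on the percent scale. Default 10.
#' @param seed Integer seed.
#' @return A `pyro_config` list, validated.
#' @export
pyro_config <- function(genes = c(HOXB2 = 5, KRT13 = 4, FRZB = 3),
                        group_var = "invasive",
                        group_means = list(
                          HOXB2 = c(`FALSE` = 15, `TRUE` = 45),
                          KRT13 = c(`FALSE` = 20, `TRUE` = 35),
                          FRZB = c(`FALSE` = 20, `TRUE` = 32)),
                        rho = 0.8, noise_sd = 10, seed = 1L) {
  stopifnot(length(genes) >= 1, !is.null(names(genes)), all(genes >= 1))
  if (!(rho > -1 && rho < 1)) {
    stop("between-site correlation must lie strictly inside (-1, 1)",
         call. = FALSE)
  }
  if (!setequal(names(genes), names(group_means))) {
    stop("group_means must name every gene", call. = FALSE)
  }
  rng <- range(unlist(group_means))
  if (rng[1] < 0 || rng[2] > 100) {
    stop("group means must lie in [0, 100]", call. = FALSE)
  }
  stopifnot(noise_sd >= 0)
  structure(list(genes = genes, group_var = group_var,
                 group_means = group_means, rho = rho, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "pyro_config")
}

#' Generate a synthetic pyrosequencing table
#'
#' For each sample and gene, draws a latent equicorrelated Gaussian vector
#' across the gene's CpG sites (correlation `rho`), maps it through the
#' normal quantile (a Gaussian copula with truncated-normal marginals) onto
#' `group mean + noise_sd * z`, and clips to \[0, 100\]. With `noise_sd = 0`
#' every site equals its group mean exactly.
#'
#' @param config A [pyro_config()].
#' @param sheet Sample sheet with `sample_id` and the `group_var` column.
#' @return A long-format `pyro_table` data frame with columns `sample_id`,
#'   `gene`, `site`, `pct_meth`; one row per (sample, gene, site).
#' @export
generate_pyro_table <- function(config, sheet) {
  stopifnot(inherits(config, "pyro_config"))
  if (!config$group_var %in% names(sheet)) {
    stop(sprintf("sample sheet lacks group column '%s'", config$group_var),
         call. = FALSE)
  }
  set.seed(config$seed)
  n <- nrow(sheet)
  grp <- as.character(sheet[[config$group_var]])
  out <- vector("list", length(config$genes))
  for (g in seq_along(config$genes)) {
    gene <- names(config$genes)[g]
    S <- config$genes[[g]]
    means <- config$group_means[[gene]]
    if (!all(unique(grp) %in% names(means))) {
      stop(sprintf("group_means for %s lack level(s): %s", gene,
                   paste(setdiff(unique(grp), names(means)), collapse = ", ")),
           call. = FALSE)
    }
    # equicorrelated Gaussian: z = sqrt(rho) * common + sqrt(1-rho) * e
    rho <- config$rho
    common <- stats::rnorm(n)
    e <- matrix(stats::rnorm(n * S), n, S)
    if (rho >= 0) {
      z <- sqrt(rho) * matrix(common, n, S) + sqrt(1 - rho) * e
    } else {
      # negative rho: alternate sign of the shared factor between sites
      sgn <- rep(c(1, -1), length.out = S)
      z <- sqrt(-rho) * matrix(common, n, S) %*% diag(sgn) +
        sqrt(1 + rho) * e
    }
    val <- means[grp] + config$noise_sd * z
    val <- pmin(pmax(val, 0), 100)
    out[[g]] <- data.frame(sample_id = rep(sheet$sample_id, S),
                           gene = gene,
                           site = rep(seq_len(S), each = n),
                           pct_meth = as.vector(val),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pyro_table", "data.frame")
  res
}
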