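#' Read a methylation matrix from TSV files
#'
#' The beta and detection-p files are TSV with sample ids in the first
#' column and locus ids as the header; the annotation file is TSV with
#' columns locus, gene, chromosome. Validation errors name the first
#' offending cell.
#'
#' @param beta_path,detp_path,annot_path File paths.
#' @return A [meth_matrix()].
#' @export
read_beta_matrix <- function(beta_path, detp_path, annot_path) {
  for (p in c(beta_path, detp_path, annot_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p),
                              call. = FALSE)
  }
  read_num <- function(path, what) {
    d <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- as.character(d[[1]])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                     !is.na(m), arr.ind = TRUE)
      cell <- if (nrow(bad)) sprintf(" at sample '%s', locus '%s'",
                                     rownames(m)[bad[1, 1]],
                                     colnames(m)[bad[1, 2]]) else ""
      stop(sprintf("non-numeric %s value%s in %s", what, cell, path),
           call. = FALSE)
    }
    m
  }
  beta <- read_num(beta_path, "beta")
  detp <- read_num(detp_path, "detection p")
  if (!identical(dim(beta), dim(detp))) {
    stop(sprintf("shape mismatch: beta is %dx%d but detection p is %dx%d",
                 nrow(beta), ncol(beta), nrow(detp), ncol(detp)),
         call. = FALSE)
  }
  annot <- utils::read.delim(annot_path, stringsAsFactors = FALSE,
                             colClasses = c(chromosome = "character"))
  meth_matrix(beta, detp, annot)
}

#' Write a methylation cohort to the standard pipeline input files
#'
#' Writes beta.tsv, detp.tsv, annotation.tsv, sheet.csv, and (when a truth
#' element is present) truth.json — a sidecar the pipeline never reads.
#'
#' @param cohort A [generate_cohort()] result (or a list with `matrix` and
#'   `sheet`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- cohort$matrix
  paths <- c(beta = file.path(dir, "beta.tsv"),
             detp = file.path(dir, "detp.tsv"),
             annot = file.path(dir, "annotation.tsv"),
             sheet = file.path(dir, "sheet.csv"))
  write_mat <- function(x, path) {
    df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_mat(m$beta, paths["beta"])
  write_mat(m$detection_p, paths["detp"])
  utils::write.table(m$annotation, paths["annot"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(cohort$sheet, paths["sheet"], row.names = FALSE)
  if (!is.null(cohort$truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.json"))
    jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE)
  }
  invisible(paths)
}

#' Read a pyrosequencing table from CSV
#'
#' @param path CSV with columns sample_id, gene, site, pct_meth.
#' @return A `pyro_table` data frame.
#' @export
read_pyro_table <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "site", "pct_meth")
  if (!all(need %in% names(t))) {
    stop(sprintf("pyro table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (any(t$pct_meth < 0 | t$pct_meth > 100, na.rm = TRUE)) {
    stop("percent methylation outside [0, 100]", call. = FALSE)
  }
  if (anyDuplicated(t[, c("sample_id", "gene", "site")])) {
    stop("duplicate (sample, gene, site) rows", call. = FALSE)
  }
  class(t) <- c("pyro_table", "data.frame")
  t
}

#' Run the full two-series discovery pipeline on synthetic or file inputs
#'
#' Stages, in order: array QC per series, then the three locus-selection
#' procedures (quasi-binomial GLM + q-values, random-forest screen,
#' recursively partitioned beta-mixture model + AUC ranking) per series,
#' then the cross-series candidate intersection. All randomness derives
#' from `seed` via fixed per-stage offsets (series i RF screen uses
#' `seed + 100 * i`). A manifest with the seed and all thresholds is
#' written alongside the outputs.
#'
#' @param series1,series2 Cohorts: each either a [generate_cohort()] result
#'   or a list with `matrix` ([meth_matrix()]) and `sheet`.
#' @param out_dir Output directory; created if needed.
#' @param thresholds A [selection_thresholds()].
#' @param rf_cfg An [rf_config()]. The slow OOB permutation test is skipped
#'   inside the pipeline (it is a significance report, not a selection
#'   step); run [oob_permutation_test()] directly when needed.
#' @param qc Named list of QC cutoffs: `fail_p`, `frac`, `med_p`.
#' @param seed Master seed.
#' @return A `pipeline_result` list: per-series `qc`, `glm`, `rf`, `tree`,
#'   `auc`, `auc_leaf`, plus `candidates` (a `candidate_set`) and
#'   `manifest`.
#' @export
run_pipeline <- function(series1, series2, out_dir = NULL,
                         thresholds = selection_thresholds(),
                         rf_cfg = rf_config(),
                         qc = list(fail_p = 1e-5, frac = 0.75, med_p = 0.05),
                         seed = 1L) {
  stage <- "qc"
  result <- tryCatch({
    run_series <- function(cohort, i) {
      stage <<- sprintf("qc (series %d)", i)
      if (is.null(cohort$matrix) || is.null(cohort$sheet)) {
        stop("cohort must provide `matrix` and `sheet`", call. = FALSE)
      }
      qcres <- run_qc(cohort$matrix, fail_p = qc$fail_p, frac = qc$frac,
                      med_p = qc$med_p)
      m <- qcres$matrix
      stage <<- sprintf("glm (series %d)", i)
      glm_res <- glm_screen(m, cohort$sheet)
      stage <<- sprintf("rf (series %d)", i)
      rf_res <- rf_screen(m, cohort$sheet, config = rf_cfg,
                          seed = seed + 100L * i, permutation = FALSE)
      stage <<- sprintf("rpmm (series %d)", i)
      tree <- recursive_partition(m)
      if (length(tree$leaves) >= 2) {
        auc <- rank_loci_by_auc(tree)
        leaf <- invasive_enriched_leaf(tree, m, cohort$sheet)
      } else {
        # single-leaf tree: AUC undefined; no locus can pass the AUC cut
        auc <- data.frame(locus = colnames(m$beta), auc_r = 0.5,
                          max_auc = 0.5, stringsAsFactors = FALSE)
        leaf <- "r"
      }
      list(qc = qcres$report, matrix = m, glm = glm_res, rf = rf_res,
           tree = tree, auc = auc, auc_leaf = leaf)
    }
    s1 <- run_series(series1, 1L)
    s2 <- run_series(series2, 2L)
    stage <- "select"
    cand <- intersect_candidates(
      series_results(s1$glm, s1$rf$importance, s1$auc, s1$auc_leaf),
      series_results(s2$glm, s2$rf$importance, s2$auc, s2$auc_leaf),
      thresholds)
    manifest <- list(
      package = "methmark",
      version = as.character(utils::packageVersion("methmark")),
      seed = seed,
      thresholds = unclass(thresholds),
      qc = qc,
      rf = list(n_trees = rf_cfg$n_trees, n_perm = rf_cfg$n_perm,
                importance_cut = rf_cfg$importance_cut))
    list(series1 = s1, series2 = s2, candidates = cand,
         manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(result$candidates$audit,
                       file.path(out_dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (i in 1:2) {
      s <- result[[paste0("series", i)]]
      utils::write.table(s$glm,
                         file.path(out_dir,
                                   sprintf("locus_results_s%d.tsv", i)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(result$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  class(result) <- "pipeline_result"
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("methmark pipeline result\n")
  print(x$candidates)
  invisible(x)
}
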