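#' Selection thresholds for the three-method intersection
#'
#' @param q_cut GLM q-value cutoff (pass iff q < q_cut). Default 0.05.
#' @param importance_cut RF percent-change-in-MSE cutoff (strict >).
#'   Default 6.
#' @param auc_cut Class-vs-rest AUC cutoff (strict >). Default 0.75.
#' @return A `selection_thresholds` list.
#' @export
selection_thresholds <- function(q_cut = 0.05, importance_cut = 6,
                                 auc_cut = 0.75) {
  structure(list(q_cut = q_cut, importance_cut = importance_cut,
                 auc_cut = auc_cut),
            class = "selection_thresholds")
}

#' Identify the invasive-enriched leaf of a tree
#'
#' The "class of interest" for the AUC criterion: the leaf whose members
#' have the highest prevalence of invasive tumors (posterior-weighted).
#'
#' @param tree An [recursive_partition()] tree.
#' @param m A [meth_matrix()] (or beta matrix) for the same samples.
#' @param sheet Sample sheet with `sample_id` and logical `invasive`.
#' @return Leaf path string.
#' @export
invasive_enriched_leaf <- function(tree, m, sheet) {
  X <- if (inherits(m, "meth_matrix")) m$beta else m
  post <- eb_membership(tree, X)
  idx <- match(rownames(X), sheet$sample_id)
  invasive <- as.logical(sheet$invasive[idx])
  prev <- colSums(post * invasive) / colSums(post)
  names(prev)[which.max(prev)]
}

#' Per-series method results for the intersection rule
#'
#' @param glm_results A `locus_results` table ([glm_screen()]).
#' @param rf_importance Named numeric vector of percent-change-in-MSE values
#'   ([rf_importance()]), covering the same loci.
#' @param auc_ranking An `auc_ranking` ([rank_loci_by_auc()]).
#' @param auc_leaf Leaf path of the class of interest (the invasive-enriched
#'   leaf, [invasive_enriched_leaf()]); its `auc_<path>` column is the one
#'   thresholded.
#' @return A `series_results` list, universe-checked.
#' @export
series_results <- function(glm_results, rf_importance, auc_ranking,
                           auc_leaf) {
  u1 <- sort(glm_results$locus)
  u2 <- sort(names(rf_importance))
  u3 <- sort(auc_ranking$locus)
  if (!identical(u1, u2) || !identical(u1, u3)) {
    diff <- unique(c(setdiff(u1, u2), setdiff(u2, u1),
                     setdiff(u1, u3), setdiff(u3, u1)))
    stop(sprintf("locus universes disagree across methods: %s",
                 paste(utils::head(diff, 10), collapse = ", ")),
         call. = FALSE)
  }
  col <- paste0("auc_", auc_leaf)
  if (!col %in% names(auc_ranking)) {
    stop(sprintf("auc ranking has no column '%s'", col), call. = FALSE)
  }
  structure(list(glm = glm_results, rf = rf_importance, auc = auc_ranking,
                 auc_leaf = auc_leaf),
            class = "series_results")
}

#' Three-method, two-series candidate intersection
#'
#' A locus is a candidate iff, in each series independently, it passes the
#' GLM significance cut, the RF importance cut, and the class-vs-rest AUC
#' cut for that series' invasive-enriched leaf; the per-series survivor sets
#' are then intersected across the two series.
#'
#' @param series1,series2 [series_results()] objects; their locus universes
#'   must agree.
#' @param thresholds A [selection_thresholds()].
#' @return A `candidate_set` list: `candidates` (character vector) and
#'   `audit` (data frame of per-series per-method pass/fail, one row per
#'   locus).
#' @export
intersect_candidates <- function(series1, series2,
                                 thresholds = selection_thresholds()) {
  stopifnot(inherits(series1, "series_results"),
            inherits(series2, "series_results"))
  u1 <- sort(series1$glm$locus)
  u2 <- sort(series2$glm$locus)
  if (!identical(u1, u2)) {
    diff <- c(setdiff(u1, u2), setdiff(u2, u1))
    stop(sprintf("series locus universes disagree: %s",
                 paste(utils::head(diff, 10), collapse = ", ")),
         call. = FALSE)
  }
  pass_one <- function(s) {
    loci <- s$glm$locus
    glm_pass <- s$glm$q < thresholds$q_cut
    rf_pass <- s$rf[loci] > thresholds$importance_cut
    auc <- s$auc[[paste0("auc_", s$auc_leaf)]][match(loci, s$auc$locus)]
    auc_pass <- auc > thresholds$auc_cut
    data.frame(locus = loci, glm = glm_pass, rf = unname(rf_pass),
               auc = auc_pass, stringsAsFactors = FALSE)
  }
  p1 <- pass_one(series1)
  p2 <- pass_one(series2)
  p2 <- p2[match(p1$locus, p2$locus), ]
  audit <- data.frame(locus = p1$locus,
                      s1_glm = p1$glm, s1_rf = p1$rf, s1_auc = p1$auc,
                      s2_glm = p2$glm, s2_rf = p2$rf, s2_auc = p2$auc,
                      stringsAsFactors = FALSE)
  audit$candidate <- audit$s1_glm & audit$s1_rf & audit$s1_auc &
    audit$s2_glm & audit$s2_rf & audit$s2_auc
  structure(list(candidates = audit$locus[audit$candidate], audit = audit),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d candidate loci of %d tested\n",
              length(x$candidates), nrow(x$audit)))
  if (length(x$candidates)) {
    cat(" ", paste(x$candidates, collapse = ", "), "\n")
  }
  invisible(x)
}
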