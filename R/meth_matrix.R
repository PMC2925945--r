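#' Methylation matrix container
#'
#' Bundles a samples x loci average-beta matrix with its matching detection
#' p-value matrix and a per-locus annotation table. Average beta is the
#' array-level methylation estimate for one CpG locus, a proportion in
#' \[0, 1\] (methylated signal over total signal); the detection p-value is
#' the per-measurement probability that the signal is indistinguishable from
#' background, and drives the QC filters.
#'
#' @param beta Numeric matrix, samples in rows and loci in columns, values in
#'   \[0, 1\]. Must carry row and column names (sample and locus ids).
#' @param detection_p Numeric matrix of the same shape as `beta`, values in
#'   \[0, 1\].
#' @param annotation Data frame with columns `locus`, `gene`, `chromosome`,
#'   one row per column of `beta` (any order; matched by `locus`).
#'
#' @return An object of class `meth_matrix`: a list with elements `beta`,
#'   `detection_p` and `annotation` (annotation re-ordered to match the
#'   column order of `beta`).
#' @export
meth_matrix <- function(beta, detection_p, annotation) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop("`beta` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("`beta` must have sample row names and locus column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(beta)) || anyDuplicated(colnames(beta))) {
    stop("sample and locus ids must be unique", call. = FALSE)
  }
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("beta value out of [0,1] at sample '%s', locus '%s'",
                 rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]]),
         call. = FALSE)
  }
  if (!is.matrix(detection_p) || !identical(dim(detection_p), dim(beta))) {
    stop("`detection_p` must be a matrix with the same shape as `beta`",
         call. = FALSE)
  }
  if (!is.null(rownames(detection_p)) &&
      !identical(rownames(detection_p), rownames(beta))) {
    stop("detection_p row names disagree with beta", call. = FALSE)
  }
  dimnames(detection_p) <- dimnames(beta)
  if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE)) {
    stop("detection p-values must lie in [0,1]", call. = FALSE)
  }
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  need <- c("locus", "gene", "chromosome")
  if (!all(need %in% names(annotation))) {
    stop("annotation must have columns locus, gene, chromosome", call. = FALSE)
  }
  if (!setequal(annotation$locus, colnames(beta))) {
    stop("annotation loci do not match beta columns", call. = FALSE)
  }
  annotation <- annotation[match(colnames(beta), annotation$locus), ,
                           drop = FALSE]
  rownames(annotation) <- NULL
  structure(list(beta = beta, detection_p = detection_p,
                 annotation = annotation),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d samples x %d loci\n",
              nrow(x$beta), ncol(x$beta)))
  cat(sprintf("  beta range: [%.3f, %.3f]\n",
              min(x$beta), max(x$beta)))
  chr <- chrom_normalize(x$annotation$chromosome)
  cat(sprintf("  autosomal loci: %d, X/Y loci: %d\n",
              sum(!chr %in% c("X", "Y")), sum(chr %in% c("X", "Y"))))
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) dim(x$beta)

# subset keeping all three slots aligned
subset_meth <- function(m, samples = NULL, loci = NULL) {
  if (is.null(samples)) samples <- rownames(m$beta)
  if (is.null(loci)) loci <- colnames(m$beta)
  beta <- m$beta[samples, loci, drop = FALSE]
  detp <- m$detection_p[samples, loci, drop = FALSE]
  ann <- m$annotation[match(loci, m$annotation$locus), , drop = FALSE]
  rownames(ann) <- NULL
  structure(list(beta = beta, detection_p = detp, annotation = ann),
            class = "meth_matrix")
}

# accept 1..22 / X / Y with or without "chr" prefix; error names the locus
chrom_normalize <- function(chrom, locus = NULL) {
  out <- toupper(sub("^chr", "", as.character(chrom), ignore.case = TRUE))
  ok <- out %in% c(as.character(1:22), "X", "Y")
  if (!all(ok)) {
    offender <- if (!is.null(locus)) locus[!ok][1] else which(!ok)[1]
    stop(sprintf("unknown chromosome label '%s' for locus '%s'",
                 chrom[!ok][1], offender), call. = FALSE)
  }
  out
}
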