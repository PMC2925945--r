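#' Drop samples that fail detection across most loci
#'
#' A sample is removed when strictly more than `frac` of its loci have a
#' detection p-value above `fail_p`, i.e. most of its measurements are
#' indistinguishable from background. Defaults mirror the GoldenGate QC
#' convention (p > 1e-5 at > 75\% of loci).
#'
#' @param m A [meth_matrix()].
#' @param fail_p Detection p-value above which a single measurement counts as
#'   failed. Default `1e-5`.
#' @param frac Fraction of failed loci above which (strictly) the sample is
#'   dropped. Default `0.75`.
#' @return A list with `matrix` (the filtered [meth_matrix()]) and `report`
#'   (a `qc_report`; see [qc_report()]).
#' @export
filter_samples <- function(m, fail_p = 1e-5, frac = 0.75) {
  stopifnot(inherits(m, "meth_matrix"))
  if (nrow(m$beta) == 0L || ncol(m$beta) == 0L) {
    stop("empty methylation matrix", call. = FALSE)
  }
  stopifnot(fail_p > 0, fail_p < 1, frac > 0, frac < 1)
  fail_frac <- rowMeans(m$detection_p > fail_p)
  drop <- fail_frac > frac            # strict: exactly 75% failing is retained
  keep <- rownames(m$beta)[!drop]
  out <- subset_meth(m, samples = keep)
  rep <- qc_report(dropped_samples = fail_frac[drop],
                   retained_samples = length(keep),
                   retained_loci = ncol(out$beta))
  list(matrix = out, report = rep)
}

#' Drop loci whose median detection p-value is poor
#'
#' A locus is removed when its median detection p-value across the (already
#' sample-filtered) samples exceeds `med_p` strictly. For an even number of
#' samples the median is the mean of the central pair.
#'
#' @param m A [meth_matrix()].
#' @param med_p Median detection p-value cutoff, default 0.05.
#' @inherit filter_samples return
#' @export
filter_loci <- function(m, med_p = 0.05) {
  stopifnot(inherits(m, "meth_matrix"))
  if (nrow(m$beta) == 0L || ncol(m$beta) == 0L) {
    stop("empty methylation matrix", call. = FALSE)
  }
  stopifnot(med_p > 0, med_p < 1)
  med <- apply(m$detection_p, 2, stats::median)
  drop <- med > med_p
  keep <- colnames(m$beta)[!drop]
  out <- subset_meth(m, loci = keep)
  rep <- qc_report(dropped_loci = med[drop],
                   retained_samples = nrow(out$beta),
                   retained_loci = length(keep))
  list(matrix = out, report = rep)
}

#' Restrict to autosomal loci
#'
#' Removes loci annotated on the X or Y chromosome. Chromosome labels
#' 1..22/X/Y are accepted with or without a "chr" prefix; any other label is
#' an error naming the offending locus.
#'
#' @param m A [meth_matrix()].
#' @return A [meth_matrix()] with only autosomal loci. Warns when nothing
#'   remains.
#' @export
restrict_autosomal <- function(m) {
  stopifnot(inherits(m, "meth_matrix"))
  chr <- chrom_normalize(m$annotation$chromosome, m$annotation$locus)
  keep <- m$annotation$locus[!chr %in% c("X", "Y")]
  if (length(keep) == 0L) {
    warning("no autosomal loci remain after sex-chromosome restriction")
  }
  subset_meth(m, loci = keep)
}

#' Full array QC: samples, then loci, then autosomal restriction
#'
#' @inheritParams filter_samples
#' @inheritParams filter_loci
#' @return A list with `matrix` and a combined `report`.
#' @export
run_qc <- function(m, fail_p = 1e-5, frac = 0.75, med_p = 0.05) {
  s <- filter_samples(m, fail_p = fail_p, frac = frac)
  l <- filter_loci(s$matrix, med_p = med_p)
  a <- restrict_autosomal(l$matrix)
  rep <- qc_report(dropped_samples = s$report$dropped_samples,
                   dropped_loci = l$report$dropped_loci,
                   retained_samples = nrow(a$beta),
                   retained_loci = ncol(a$beta))
  list(matrix = a, report = rep)
}

#' QC report constructor
#'
#' @param dropped_samples Named numeric vector: failing fraction per dropped
#'   sample.
#' @param dropped_loci Named numeric vector: median detection p per dropped
#'   locus.
#' @param retained_samples,retained_loci Counts after filtering.
#' @return A `qc_report` list.
#' @export
qc_report <- function(dropped_samples = numeric(0),
                      dropped_loci = numeric(0),
                      retained_samples = NA_integer_,
                      retained_loci = NA_integer_) {
  structure(list(dropped_samples = dropped_samples,
                 dropped_loci = dropped_loci,
                 retained_samples = retained_samples,
                 retained_loci = retained_loci),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("array QC report\n")
  cat(sprintf("  dropped samples: %d\n", length(x$dropped_samples)))
  cat(sprintf("  dropped loci:    %d\n", length(x$dropped_loci)))
  cat(sprintf("  retained: %s samples x %s loci\n",
              x$retained_samples, x$retained_loci))
  invisible(x)
}
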