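#' Filter undetected probes
#'
#' Removes probes that are undetected in every sample, i.e. whose detection
#' p-value exceeds `alpha` in all samples. A probe is retained as soon as it
#' is detected (p <= alpha) in at least one sample. Probe order is preserved.
#'
#' @param x an `ExpressionMatrix` carrying detection p-values.
#' @param alpha detection significance level (default 0.01).
#' @return the filtered `ExpressionMatrix`.
#' @export
detection_filter <- function(x, alpha = 0.01) {
  if (is.null(x$detection_p))
    stop("no detection p-values present; skip the detection-filter stage ",
         "explicitly if your matrix was deposited pre-filtered")
  keep <- rowSums(x$detection_p <= alpha) >= 1
  x[keep, ]
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample onto the mean sorted profile (ties averaged), via
#' [limma::normalizeQuantiles()]. Used as the normalization stage of the
#' pipeline; matrices carrying already-normalized deposited values can skip
#' it.
#'
#' @param x an `ExpressionMatrix`.
#' @return the normalized `ExpressionMatrix` (detection p-values untouched).
#' @export
quantile_normalize <- function(x) {
  if (ncol(x$values) < 2) {
    warning("single sample: quantile normalization is the identity")
    return(x)
  }
  vals <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(vals) <- dimnames(x$values)
  expression_matrix(vals, symbols = x$symbols, detection_p = x$detection_p)
}

#' Per-probe interquartile range
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7, the usual statistical-environment default).
#'
#' @param x an `ExpressionMatrix`.
#' @return named numeric vector of IQRs, one per probe.
#' @export
probe_iqr <- function(x) {
  q <- matrixStats_rowQuantiles(x$values, probs = c(0.25, 0.75))
  stats::setNames(q[, 2] - q[, 1], rownames(x$values))
}

# row-wise type-7 quantiles without a matrixStats dependency
matrixStats_rowQuantiles <- function(m, probs) {
  t(apply(m, 1, stats::quantile, probs = probs, type = 7, names = FALSE))
}

#' Filter probes by interquartile range
#'
#' Retains probes whose IQR across all samples exceeds `threshold` (strict
#' inequality), selecting the most variable probes without any biological
#' preselection. Probe order is preserved; the filter is idempotent.
#'
#' @param x an `ExpressionMatrix`.
#' @param threshold IQR threshold in log2 units (default 0.5).
#' @return the filtered `ExpressionMatrix` (possibly with zero probes).
#' @export
iqr_filter <- function(x, threshold = 0.5) {
  if (ncol(x$values) < 4)
    warning("IQR filtering with fewer than 4 samples is unreliable")
  keep <- probe_iqr(x) > threshold
  x[keep, ]
}

#' Count variantly expressed probes within a pair
#'
#' A probe is variant between the two members of a pair when its fold change
#' exceeds `fc_threshold` in either direction; on the log2 scale this is
#' `|x_m1 - x_m2| > log2(fc_threshold)`. Symmetric in member order and
#' invariant to adding a constant to both members.
#'
#' @param x an `ExpressionMatrix` (log2 values).
#' @param pair character vector of two sample ids.
#' @param fc_threshold linear-scale fold-change threshold (default 2, i.e.
#'   fold change > 2 or < 0.5).
#' @return integer count of variant probes.
#' @export
count_variant_probes <- function(x, pair, fc_threshold = 2) {
  if (length(pair) != 2) stop("`pair` must name exactly two samples")
  miss <- setdiff(pair, sample_ids(x))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  d <- abs(x$values[, pair[1]] - x$values[, pair[2]])
  sum(d > log2(fc_threshold))
}

#' Collapse probes to genes by maximal IQR
#'
#' Keeps, for each gene symbol, the single probe with the largest IQR across
#' samples; probes without a symbol are kept as they are. Used when summaries
#' should count genes rather than probes.
#'
#' @param x an `ExpressionMatrix` with symbol annotation.
#' @return the collapsed `ExpressionMatrix`, probe order preserved.
#' @export
collapse_to_genes <- function(x) {
  if (is.null(x$symbols)) stop("collapse requires symbol annotation")
  iqr <- probe_iqr(x)
  keep <- rep(TRUE, nrow(x$values))
  ann <- which(!is.na(x$symbols))
  by_sym <- split(ann, x$symbols[ann])
  for (idx in by_sym) {
    if (length(idx) > 1) keep[idx[-which.max(iqr[idx])]] <- FALSE
  }
  x[keep, ]
}
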