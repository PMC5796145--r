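#' Two-way ANOVA variance components for paired samples
#'
#' Decomposes an n-pairs x 2-members table into between-patients, member and
#' residual mean squares by a two-way crossed ANOVA, and converts them to
#' method-of-moments variance-component estimates. With grand mean g, patient
#' means r_i and member means c_j (k = 2 members):
#'
#' \deqn{MS_{patients} = k \sum_i (r_i - g)^2 / (n - 1)}
#' \deqn{MS_{members}  = n \sum_j (c_j - g)^2 / (k - 1)}
#' \deqn{MS_{residual} = \sum_{ij} (x_{ij} - r_i - c_j + g)^2 / ((n-1)(k-1))}
#'
#' and \eqn{\hat\sigma^2_{patients} = (MS_{patients} - MS_{residual}) / k},
#' \eqn{\hat\sigma^2_{members} = (MS_{members} - MS_{residual}) / n},
#' \eqn{\hat\sigma^2_{residual} = MS_{residual}}. Components are deliberately
#' not truncated at zero, matching the convention of classical agreement-ICC
#' implementations, so downstream ICC values can be negative.
#'
#' @param pairs_matrix numeric n x 2 matrix, one row per patient, one column
#'   per pair member; n >= 2, no missing values.
#' @return a `VarianceComponents` list with elements `ms_patients`,
#'   `ms_members`, `ms_residual`, `sigma2_patients`, `sigma2_members`,
#'   `sigma2_residual`, `n_pairs`, `k_members`.
#' @export
anova_decompose <- function(pairs_matrix) {
  m <- as.matrix(pairs_matrix)
  if (ncol(m) != 2) stop("pairs_matrix must have exactly 2 columns (members)")
  n <- nrow(m)
  if (n < 2) stop("at least 2 pairs are required")
  if (anyNA(m) || any(!is.finite(m))) stop("missing or non-finite values in pairs_matrix")
  k <- 2
  g <- mean(m)
  r <- rowMeans(m)
  cj <- colMeans(m)
  ms_p <- k * sum((r - g)^2) / (n - 1)
  ms_m <- n * sum((cj - g)^2) / (k - 1)
  resid <- m - outer(r, rep(1, k)) - outer(rep(1, n), cj) + g
  ms_e <- sum(resid^2) / ((n - 1) * (k - 1))
  comp <- list(
    ms_patients = ms_p, ms_members = ms_m, ms_residual = ms_e,
    sigma2_patients = (ms_p - ms_e) / k,
    sigma2_members = (ms_m - ms_e) / n,
    sigma2_residual = ms_e,
    n_pairs = n, k_members = k)
  class(comp) <- "VarianceComponents"
  comp
}

#' @export
print.VarianceComponents <- function(x, ...) {
  cat(sprintf("VarianceComponents (n = %d pairs)\n", x$n_pairs))
  cat(sprintf("  MS: patients %.4g, members %.4g, residual %.4g\n",
              x$ms_patients, x$ms_members, x$ms_residual))
  cat(sprintf("  sigma2: patients %.4g, members %.4g, residual %.4g\n",
              x$sigma2_patients, x$sigma2_members, x$sigma2_residual))
  invisible(x)
}

#' Agreement intraclass correlation from variance components
#'
#' The agreement ICC is the between-patients variance divided by the sum of
#' the between-patients, member (within-patients) and residual variances.
#' Keeping the member effect in the denominator makes systematic differences
#' between pair members count against agreement. Because components are not
#' truncated, the ICC can be negative; it equals 1 only when member and
#' residual components vanish with positive between-patient spread.
#'
#' @param components a `VarianceComponents` object.
#' @param tol denominators smaller than `tol` in absolute value (a constant
#'   gene) yield `NA` — flagged undefined and excluded from downstream
#'   distribution summaries.
#' @return the ICC (scalar), or `NA_real_` when undefined.
#' @export
icc_agreement <- function(components, tol = 1e-12) {
  den <- components$sigma2_patients + components$sigma2_members +
    components$sigma2_residual
  if (!is.finite(den) || abs(den) < tol) return(NA_real_)
  components$sigma2_patients / den
}

#' Per-gene agreement ICC for one pair group
#'
#' Computes the agreement ICC for every probe using only the pairs of the
#' requested group, via a vectorized two-way ANOVA decomposition (identical,
#' to numerical precision, to looping [anova_decompose()] +
#' [icc_agreement()] over probes).
#'
#' @param x an `ExpressionMatrix`.
#' @param design a `PairDesign`.
#' @param group one of `"SBC"`, `"MBC"`, `"LRC"`.
#' @return an `ICCTable`: data frame with columns `probe_id`, `symbol`,
#'   `group`, `icc`, `ms_patients`, `ms_members`, `ms_residual`,
#'   `sigma2_patients`, `sigma2_members`, `sigma2_residual`. Constant probes
#'   have `icc = NA`; their number is stored in the `n_undefined` attribute.
#' @export
icc_per_gene <- function(x, design, group) {
  d <- design[design$group == group, , drop = FALSE]
  if (nrow(d) < 2)
    stop(sprintf("group %s has %d pair(s); at least 2 required", group, nrow(d)))
  validate_design(design, x, groups = group)
  m1 <- x$values[, d$member1_sample, drop = FALSE]
  m2 <- x$values[, d$member2_sample, drop = FALSE]
  n <- nrow(d); k <- 2
  g <- (rowSums(m1) + rowSums(m2)) / (n * k)   # grand mean per probe
  r <- (m1 + m2) / 2                           # patient means, probes x n
  c1 <- rowMeans(m1); c2 <- rowMeans(m2)       # member means
  ms_p <- k * rowSums((r - g)^2) / (n - 1)
  ms_m <- n * ((c1 - g)^2 + (c2 - g)^2) / (k - 1)
  res1 <- m1 - r - c1 + g
  res2 <- m2 - r - c2 + g
  ms_e <- (rowSums(res1^2) + rowSums(res2^2)) / ((n - 1) * (k - 1))
  s2p <- (ms_p - ms_e) / k
  s2m <- (ms_m - ms_e) / n
  den <- s2p + s2m + ms_e
  icc <- ifelse(abs(den) < 1e-12, NA_real_, s2p / den)
  out <- data.frame(
    probe_id = probe_ids(x),
    symbol = if (is.null(x$symbols)) NA_character_ else x$symbols,
    group = group, icc = icc,
    ms_patients = ms_p, ms_members = ms_m, ms_residual = ms_e,
    sigma2_patients = s2p, sigma2_members = s2m, sigma2_residual = ms_e,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_undefined") <- sum(is.na(icc))
  class(out) <- c("ICCTable", "data.frame")
  out
}

#' Write an ICC table as TSV
#' @param tab an `ICCTable` (or rbind of several).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_icc_table <- function(tab, path) {
  cols <- c("probe_id", "symbol", "group", "icc",
            "ms_patients", "ms_members", "ms_residual")
  utils::write.table(as.data.frame(tab)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
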