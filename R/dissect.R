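#' Compare per-gene ICC distributions across pair groups
#'
#' Treats each gene's ICC as one observation and the pair group (SBC, MBC,
#' LRC) as a factor: reports per-group medians, counts of genes above an ICC
#' cutoff, a one-way ANOVA across groups and pairwise two-sided t-tests.
#' Undefined (NA) ICC values are excluded from all summaries; negative ICCs
#' are kept. Per-gene ICC values are correlated across groups through the
#' genes themselves; the ANOVA ignores that, as is conventional for these
#' distribution comparisons, so its p-values are descriptive.
#'
#' @param icc_tables a named list of `ICCTable`s (one per group) or a single
#'   table covering several groups.
#' @param cutoff ICC cutoff for the above-threshold gene counts
#'   (default 0.5).
#' @param t_method `"welch"` (default, unequal variances) or `"student"` for
#'   the pairwise t-tests.
#' @param variant_counts optional data frame (`patient_id`, `group`,
#'   `n_variant`) of per-pair variant-probe counts, summarized per group.
#' @param probe_set label for the probe set being compared.
#' @return a `GroupComparison`: list with `probe_set`, `n_probes`,
#'   `median_icc`, `n_above_cutoff`, `cutoff`, `anova` (`F`, `p`),
#'   `pairwise_p` (named vector), `variant_counts`,
#'   `median_variant_count`, `n_undefined`.
#' @export
compare_groups <- function(icc_tables, cutoff = 0.5,
                           t_method = c("welch", "student"),
                           variant_counts = NULL, probe_set = "probe_set") {
  t_method <- match.arg(t_method)
  tab <- if (is.data.frame(icc_tables)) icc_tables
  else do.call(rbind, lapply(icc_tables, as.data.frame))
  groups <- unique(tab$group)
  if (length(groups) < 2) stop("need at least 2 groups to compare")
  ok <- !is.na(tab$icc)
  n_def <- tapply(ok, tab$group, sum)
  dead <- names(n_def)[n_def < 2]
  if (length(dead))
    stop("group(s) without enough defined ICC values: ",
         paste(dead, collapse = ", "))
  def <- tab[ok, , drop = FALSE]

  med <- tapply(def$icc, def$group, stats::median)[groups]
  n_above <- tapply(def$icc > cutoff, def$group, sum)[groups]

  fit <- stats::lm(icc ~ group, data = transform(def, group = factor(group)))
  an <- stats::anova(fit)
  pairs <- utils::combn(groups, 2)
  pw <- apply(pairs, 2, function(p) {
    stats::t.test(def$icc[def$group == p[1]], def$icc[def$group == p[2]],
                  var.equal = (t_method == "student"))$p.value
  })
  names(pw) <- apply(pairs, 2, paste, collapse = "_vs_")

  mvc <- NULL
  if (!is.null(variant_counts))
    mvc <- tapply(variant_counts$n_variant, variant_counts$group,
                  stats::median)[intersect(groups, variant_counts$group)]

  structure(list(
    probe_set = probe_set,
    n_probes = length(unique(tab$probe_id)),
    median_icc = med,
    n_above_cutoff = n_above,
    cutoff = cutoff,
    anova = c(F = an$`F value`[1], p = an$`Pr(>F)`[1]),
    pairwise_p = pw,
    t_method = t_method,
    variant_counts = variant_counts,
    median_variant_count = mvc,
    n_undefined = sum(!ok)),
    class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("GroupComparison [%s]: %d probes\n", x$probe_set, x$n_probes))
  cat("  median ICC: ",
      paste(sprintf("%s=%.3f", names(x$median_icc), x$median_icc),
            collapse = ", "), "\n")
  cat(sprintf("  genes with ICC > %.2g: %s\n", x$cutoff,
              paste(sprintf("%s=%d", names(x$n_above_cutoff),
                            x$n_above_cutoff), collapse = ", ")))
  cat(sprintf("  ANOVA: F = %.3g, p = %.3g\n", x$anova[["F"]], x$anova[["p"]]))
  invisible(x)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full intra-pair variability dissection
#'
#' Orchestrates the pipeline: detection filtering (when detection p-values
#' are present), optional quantile normalization, optional probe-to-gene
#' collapsing, then per-gene agreement ICC per pair group on several probe
#' panels, each summarized with [compare_groups()]:
#' * `unselected_IQR` — all probes passing the IQR filter (most variable,
#'   biologically unselected genes);
#' * one panel per supplied signature — all probes mapping to the
#'   signature's symbols (not IQR-filtered by default, since a curated list
#'   is already a selection; `iqr_filter_signatures` forces the filter).
#'
#' Per-pair variant-probe counts (fold change beyond `fc_threshold`) are
#' computed on each panel's probes by default, or on the full detected set
#' with `variant_on = "detected"`.
#'
#' @param x an `ExpressionMatrix` (raw with detection p-values, or deposited
#'   pre-normalized values).
#' @param design a `PairDesign`.
#' @param signatures list of `GeneSignature` objects (possibly empty).
#' @param iqr_threshold IQR filter threshold (default 0.5 log2 units).
#' @param icc_cutoff ICC cutoff for above-threshold counts (default 0.5).
#' @param fc_threshold fold-change threshold for variant probes (default 2).
#' @param detection_alpha detection p-value threshold (default 0.01).
#' @param normalize `"none"` or `"quantile"`.
#' @param collapse_genes `"none"` or `"max-iqr"` (one probe per gene).
#' @param iqr_filter_signatures apply the IQR filter to signature panels too?
#' @param variant_on `"panel"` or `"detected"`.
#' @param t_method passed to [compare_groups()].
#' @return a `DissectionReport`: list with `panels` (per panel: `comparison`,
#'   `icc` table, `mapping` counts), `log` (stage-level probe counts) and
#'   `metadata`.
#' @export
run_dissection <- function(x, design, signatures = list(),
                           iqr_threshold = 0.5, icc_cutoff = 0.5,
                           fc_threshold = 2, detection_alpha = 0.01,
                           normalize = c("none", "quantile"),
                           collapse_genes = c("none", "max-iqr"),
                           iqr_filter_signatures = FALSE,
                           variant_on = c("panel", "detected"),
                           t_method = c("welch", "student")) {
  normalize <- match.arg(normalize)
  collapse_genes <- match.arg(collapse_genes)
  variant_on <- match.arg(variant_on)
  t_method <- match.arg(t_method)
  if (inherits(signatures, "GeneSignature")) signatures <- list(signatures)

  log <- list(input_probes = nrow(x$values))
  groups <- names(which(table(design$group) >= 2))
  groups <- intersect(c("SBC", "MBC", "LRC"), groups)
  stage("design", validate_design(design, x, groups))

  if (!is.null(x$detection_p)) {
    x <- stage("detection_filter", detection_filter(x, detection_alpha))
  }
  log$detected_probes <- nrow(x$values)
  if (normalize == "quantile")
    x <- stage("normalize", quantile_normalize(x))
  if (collapse_genes == "max-iqr")
    x <- stage("collapse", collapse_to_genes(x))
  log$analysis_probes <- nrow(x$values)

  panels <- list()
  panels$unselected_IQR <- list(
    matrix = stage("iqr_filter", iqr_filter(x, iqr_threshold)),
    mapping = NULL)
  for (sig in signatures) {
    mp <- stage(paste0("signature:", sig$name), map_symbols_to_probes(sig, x))
    m <- x[mp$probe_ids, ]
    if (iqr_filter_signatures) m <- iqr_filter(m, iqr_threshold)
    panels[[sig$name]] <- list(matrix = m, mapping = mp$counts)
  }

  out_panels <- list()
  for (pn in names(panels)) {
    pm <- panels[[pn]]$matrix
    if (nrow(pm$values) == 0) stop("[stage panel:", pn, "] empty probe set")
    icc <- do.call(rbind, lapply(groups, function(g)
      stage(paste0("icc:", pn, ":", g), icc_per_gene(pm, design, g))))
    vm <- if (variant_on == "panel") pm else x
    d <- design[design$group %in% groups, ]
    vc <- data.frame(
      patient_id = d$patient_id, group = d$group,
      n_variant = vapply(seq_len(nrow(d)), function(i)
        count_variant_probes(vm, c(d$member1_sample[i], d$member2_sample[i]),
                             fc_threshold), 0L))
    cmp <- stage(paste0("compare:", pn),
                 compare_groups(icc, cutoff = icc_cutoff, t_method = t_method,
                                variant_counts = vc, probe_set = pn))
    out_panels[[pn]] <- list(comparison = cmp, icc = icc,
                             mapping = panels[[pn]]$mapping)
    log[[paste0("panel_", pn, "_probes")]] <- nrow(pm$values)
    log[[paste0("panel_", pn, "_undefined_icc")]] <- cmp$n_undefined
  }

  structure(list(
    panels = out_panels,
    log = log,
    metadata = list(
      groups = groups,
      n_pairs = as.list(table(design$group)[groups]),
      iqr_threshold = iqr_threshold, icc_cutoff = icc_cutoff,
      fc_threshold = fc_threshold, detection_alpha = detection_alpha,
      normalize = normalize, collapse_genes = collapse_genes,
      iqr_filter_signatures = iqr_filter_signatures,
      variant_on = variant_on, t_method = t_method,
      package_version = as.character(utils::packageVersion("iccdissect")))),
    class = "DissectionReport")
}

#' @export
print.DissectionReport <- function(x, ...) {
  cat("DissectionReport\n")
  for (pn in names(x$panels)) print(x$panels[[pn]]$comparison)
  invisible(x)
}

#' Write a dissection report to a directory
#'
#' Emits `report.json` (panel summaries and run metadata), one
#' `icc_<panel>.tsv` per panel, `variant_counts_<panel>.tsv`, and
#' `run_log.txt` with stage-level probe counts.
#'
#' @param report a `DissectionReport`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dissection_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- lapply(report$panels, function(p) {
    cmp <- p$comparison
    list(probe_set = cmp$probe_set, n_probes = cmp$n_probes,
         median_icc = as.list(cmp$median_icc),
         n_above_cutoff = as.list(cmp$n_above_cutoff),
         cutoff = cmp$cutoff,
         anova_F = cmp$anova[["F"]], anova_p = cmp$anova[["p"]],
         pairwise_p = as.list(cmp$pairwise_p),
         median_variant_count = as.list(cmp$median_variant_count),
         n_undefined = cmp$n_undefined,
         mapping = as.list(p$mapping))
  })
  jsonlite::write_json(list(panels = summ, metadata = report$metadata),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (pn in names(report$panels)) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", pn)
    write_icc_table(report$panels[[pn]]$icc,
                    file.path(dir, paste0("icc_", safe, ".tsv")))
    utils::write.table(report$panels[[pn]]$comparison$variant_counts,
                       file.path(dir, paste0("variant_counts_", safe, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(paste(names(report$log), unlist(report$log), sep = "\t"),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Plot ICC distributions per group
#'
#' A density plot of per-gene ICC values, one curve per pair group, for one
#' panel of a report (or any ICC table).
#'
#' @param icc an `ICCTable` (multi-group) or a `DissectionReport`.
#' @param panel when a report is given, which panel to plot.
#' @return a ggplot object.
#' @export
plot_icc_distributions <- function(icc, panel = NULL) {
  if (inherits(icc, "DissectionReport")) {
    if (is.null(panel)) panel <- names(icc$panels)[1]
    icc <- icc$panels[[panel]]$icc
  }
  df <- as.data.frame(icc)
  df <- df[!is.na(df$icc), ]
  ggplot2::ggplot(df, ggplot2::aes(x = icc, colour = group)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "agreement ICC", y = "density",
                  title = if (is.null(panel)) NULL else panel) +
    ggplot2::theme_minimal()
}
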