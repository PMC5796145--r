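icc_table_stub <- function(group, icc) {
  data.frame(probe_id = paste0("p", seq_along(icc)), symbol = NA_character_,
             group = group, icc = icc, stringsAsFactors = FALSE)
}

test_that("group comparison: identical distributions give F = 0 and equal medians", {
  icc <- seq(-0.2, 0.9, length.out = 25)
  tab <- rbind(icc_table_stub("SBC", icc), icc_table_stub("MBC", icc),
               icc_table_stub("LRC", icc))
  cmp <- compare_groups(tab)
  expect_equal(unname(cmp$anova[["F"]]), 0, tolerance = 1e-12)
  expect_equal(unname(cmp$anova[["p"]]), 1, tolerance = 1e-12)
  expect_true(all(abs(cmp$median_icc - median(icc)) < 1e-12))
  # every median lies within the observed range; counts bounded by set size
  expect_true(all(cmp$median_icc >= min(icc) & cmp$median_icc <= max(icc)))
  expect_true(all(cmp$n_above_cutoff <= 25))
  # a cutoff below every value counts the full probe set
  cmp2 <- compare_groups(tab, cutoff = -Inf)
  expect_true(all(cmp2$n_above_cutoff == 25))
})

test_that("group comparison detects well-separated ICC distributions", {
  set.seed(12)
  tab <- rbind(icc_table_stub("LRC", rnorm(1000, 0.60, 0.1)),
               icc_table_stub("SBC", rnorm(1000, 0.35, 0.1)),
               icc_table_stub("MBC", rnorm(1000, 0.10, 0.1)))
  cmp <- compare_groups(tab)
  expect_lt(cmp$anova[["p"]], 1e-10)
  expect_true(cmp$median_icc[["LRC"]] > cmp$median_icc[["SBC"]])
  expect_true(cmp$median_icc[["SBC"]] > cmp$median_icc[["MBC"]])
  expect_true(all(cmp$pairwise_p < 1e-10))
  expect_true(all(cmp$pairwise_p >= 0 & cmp$pairwise_p <= 1))
  # matches a direct one-way ANOVA on the same vectors
  ref <- stats::anova(stats::lm(icc ~ group, data = tab))
  expect_equal(unname(cmp$anova[["F"]]), ref$`F value`[1], tolerance = 1e-12)

  # a group with no defined values is named in the error
  bad <- rbind(icc_table_stub("SBC", rnorm(10)),
               icc_table_stub("MBC", rep(NA_real_, 10)))
  expect_error(compare_groups(bad), "MBC")
})

test_that("full dissection reproduces the three qualitative patterns", {
  co <- small_cohort(seed = 42, n_genes = 400)
  rep <- run_dissection(
    co$matrix, co$design,
    signatures = list(class_signature(co, "intrinsic-like"),
                      class_signature(co, "stromal-like")))
  expect_s3_class(rep, "DissectionReport")
  expect_named(rep$panels, c("unselected_IQR", "intrinsic-like", "stromal-like"))

  un <- rep$panels$unselected_IQR$comparison
  expect_true(un$median_icc[["LRC"]] > un$median_icc[["SBC"]])
  expect_true(un$median_icc[["SBC"]] > un$median_icc[["MBC"]])
  expect_lt(un$anova[["p"]], 0.01)

  intr <- rep$panels$`intrinsic-like`$comparison
  expect_lt(abs(intr$median_icc[["SBC"]] - intr$median_icc[["MBC"]]), 0.05)
  expect_true(intr$median_icc[["LRC"]] > intr$median_icc[["SBC"]])

  str <- rep$panels$`stromal-like`$comparison
  expect_lt(str$median_icc[["MBC"]], str$median_icc[["SBC"]])
  expect_lt(str$median_icc[["LRC"]], un$median_icc[["LRC"]])

  # variant-probe medians exist for every group
  expect_true(all(c("SBC", "MBC", "LRC") %in%
                    names(un$median_variant_count)))
})

test_that("dissection is deterministic and its report is self-consistent on disk", {
  co <- small_cohort(seed = 6, n_genes = 120)
  sigs <- list(class_signature(co, "intrinsic-like"))
  r1 <- run_dissection(co$matrix, co$design, signatures = sigs)
  r2 <- run_dissection(co$matrix, co$design, signatures = sigs)
  expect_identical(r1$panels$unselected_IQR$icc$icc,
                   r2$panels$unselected_IQR$icc$icc)
  expect_identical(r1$panels$unselected_IQR$comparison$median_icc,
                   r2$panels$unselected_IQR$comparison$median_icc)

  dir <- withr::local_tempdir()
  write_dissection_report(r1, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  js <- jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
  # medians and counts recomputable from the emitted ICC TSV
  tsv <- utils::read.delim(file.path(dir, "icc_unselected_IQR.tsv"))
  for (g in c("SBC", "MBC", "LRC")) {
    icc_g <- tsv$icc[tsv$group == g & !is.na(tsv$icc)]
    expect_equal(js$panels$unselected_IQR$median_icc[[g]], median(icc_g),
                 tolerance = 1e-9)
    expect_equal(js$panels$unselected_IQR$n_above_cutoff[[g]],
                 sum(icc_g > 0.5))
  }
})

test_that("signature panels skip the IQR filter unless forced", {
  # low-variance signature genes would not survive an IQR filter
  quiet <- simulate_cohort(simulation_config(
    list(gene_class("background", 0.1, 0.5, 0.3, 0.2, 80),
         gene_class("quiet", 0.005, 0.0, 0.0, 0.005, 40)), seed = 30))
  sig <- class_signature(quiet, "quiet")
  rep <- run_dissection(quiet$matrix, quiet$design, signatures = list(sig))
  expect_equal(rep$panels$quiet$comparison$n_probes, 40)
  expect_error(
    run_dissection(quiet$matrix, quiet$design, signatures = list(sig),
                   iqr_filter_signatures = TRUE),
    "empty probe set")
})
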