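#!/usr/bin/env Rscript
# Step 2 — ingest and preprocess the cohort like a deposited array dataset.
#
# Reads the TSV cohort from step 1 back through the expression-matrix reader
# (exactly the path a GEO-deposited dataset would take), applies the
# detection filter (detection p <= 0.01 in at least one sample), quantile
# normalization, and the IQR > 0.5 variability filter, then counts
# variantly expressed probes (fold change > 2 or < 0.5) within every pair.

library(iccdissect)

mat <- read_expression("results/cohort/expression.tsv",
                       annotation = "results/cohort/annotation.tsv",
                       detection_path = "results/cohort/detection_p.tsv")
design <- read_pair_design("results/cohort/design.tsv")
print(mat)

mat <- detection_filter(mat, alpha = 0.01)
cat("after detection filter:", nrow(mat$values), "probes\n")

mat <- quantile_normalize(mat)
filtered <- iqr_filter(mat, threshold = 0.5)
cat("after IQR > 0.5 filter:", nrow(filtered$values), "probes\n")

vc <- data.frame(
  patient_id = design$patient_id, group = design$group,
  n_variant = vapply(seq_len(nrow(design)), function(i)
    count_variant_probes(filtered,
                         c(design$member1_sample[i], design$member2_sample[i]),
                         fc_threshold = 2), 0L))
cat("median variant probes per pair:\n")
print(tapply(vc$n_variant, vc$group, median))

dir.create("results", showWarnings = FALSE)
write.table(vc, "results/variant_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_expression(filtered, "results/expression_filtered.tsv")
cat("filtered matrix and per-pair variant counts written under results/\n")
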