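# Shared fixtures and independent oracles, all built in code.

# Independent agreement-ICC oracle: two-way ANOVA mean squares via stats::aov,
# converted to variance components by hand. Deliberately does not touch the
# package's own decomposition path.
aov_icc_oracle <- function(m) {
  n <- nrow(m)
  d <- data.frame(y = as.vector(m),
                  patient = factor(rep(seq_len(n), 2)),
                  member = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ patient + member, data = d))[[1]][["Mean Sq"]]
  s2p <- (ms[1] - ms[3]) / 2
  s2m <- (ms[2] - ms[3]) / n
  list(ms_patients = ms[1], ms_members = ms[2], ms_residual = ms[3],
       sigma2 = c(s2p, s2m, ms[3]),
       icc = s2p / (s2p + s2m + ms[3]))
}

# A tiny annotated 4-probe x 4-sample matrix with detection p-values.
tiny_matrix <- function() {
  v <- matrix(c(1, 2, 3, 4,
                5, 5, 5, 5,
                2, 4, 6, 8,
                7, 6, 9, 8), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("p", 1:4), paste0("s", 1:4)))
  dp <- matrix(0, 4, 4, dimnames = dimnames(v))
  expression_matrix(v, symbols = c("A", "A", "B", NA), detection_p = dp)
}

tiny_design <- function() {
  pair_design(data.frame(
    patient_id = c("pt1", "pt2"),
    group = c("SBC", "SBC"),
    member1_sample = c("s1", "s3"),
    member2_sample = c("s2", "s4")))
}

# Small cohort used by several dissection tests (kept modest for speed).
small_cohort <- function(seed = 42, n_genes = 400) {
  simulate_cohort(default_config(seed = seed, n_genes = n_genes))
}
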