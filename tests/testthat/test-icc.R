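test_that("two-way decomposition matches hand-computed mean squares", {
  # perfectly agreeing pairs: all variance between patients
  c1 <- anova_decompose(cbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(c(c1$ms_patients, c1$ms_members, c1$ms_residual), c(2, 0, 0),
               tolerance = 1e-12)
  expect_equal(c(c1$sigma2_patients, c1$sigma2_members, c1$sigma2_residual),
               c(1, 0, 0), tolerance = 1e-12)
  expect_equal(icc_agreement(c1), 1, tolerance = 1e-12)

  # pure disagreement: all variance residual, components go negative
  c2 <- anova_decompose(cbind(c(0, 2, 1), c(2, 0, 1)))
  expect_equal(c(c2$ms_patients, c2$ms_members, c2$ms_residual), c(0, 0, 2),
               tolerance = 1e-12)
  expect_equal(c(c2$sigma2_patients, c2$sigma2_members, c2$sigma2_residual),
               c(-1, -2 / 3, 2), tolerance = 1e-12)
  expect_equal(icc_agreement(c2), -3, tolerance = 1e-12)

  # constant member offset: member variance enters the denominator
  c3 <- anova_decompose(cbind(c(1, 3, 5), c(2, 4, 6)))
  expect_equal(c(c3$ms_patients, c3$ms_members, c3$ms_residual), c(8, 1.5, 0),
               tolerance = 1e-12)
  expect_equal(c(c3$sigma2_patients, c3$sigma2_members, c3$sigma2_residual),
               c(4, 0.5, 0), tolerance = 1e-12)
  expect_equal(icc_agreement(c3), 4 / 4.5, tolerance = 1e-12)
})

test_that("decomposition agrees with an independent aov oracle", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(5:30, 1)
    m <- cbind(rnorm(n, sd = runif(1, 0.5, 3)), rnorm(n))
    m[, 2] <- m[, 2] + 0.8 * m[, 1]   # induce some agreement
    comp <- anova_decompose(m)
    orc <- aov_icc_oracle(m)
    expect_equal(comp$ms_patients, orc$ms_patients, tolerance = 1e-10)
    expect_equal(comp$ms_members, orc$ms_members, tolerance = 1e-10)
    expect_equal(comp$ms_residual, orc$ms_residual, tolerance = 1e-10)
    expect_equal(icc_agreement(comp), orc$icc, tolerance = 1e-10)
  }
})

test_that("degenerate inputs are rejected or flagged", {
  expect_error(anova_decompose(cbind(1, 2)), "at least 2 pairs")
  expect_error(anova_decompose(cbind(c(1, NA), c(2, 3))), "missing")
  expect_error(anova_decompose(matrix(1:9, 3)), "2 columns")
  # constant gene: zero total variance -> undefined ICC
  expect_true(is.na(icc_agreement(anova_decompose(cbind(c(5, 5, 5), c(5, 5, 5))))))
})

test_that("per-gene ICC is location/scale invariant and matches the loop", {
  co <- small_cohort(seed = 5, n_genes = 60)
  tab <- icc_per_gene(co$matrix, co$design, "SBC")
  expect_s3_class(tab, "ICCTable")
  expect_equal(nrow(tab), nrow(co$matrix$values))

  # batched result identical to probe-by-probe decomposition
  d <- co$design[co$design$group == "SBC", ]
  for (i in sample(nrow(tab), 10)) {
    m <- cbind(co$matrix$values[i, d$member1_sample],
               co$matrix$values[i, d$member2_sample])
    expect_equal(tab$icc[i], icc_agreement(anova_decompose(m)),
                 tolerance = 1e-10)
  }

  # affine transform of the whole matrix leaves every ICC unchanged
  shifted <- co$matrix
  shifted$values <- 3.7 * shifted$values + 11
  tab2 <- icc_per_gene(shifted, co$design, "SBC")
  expect_equal(tab2$icc, tab$icc, tolerance = 1e-9)

  # permuting patient order within the group changes nothing
  perm <- co$design[sample(nrow(co$design)), ]
  attr(perm, "member_order") <- attr(co$design, "member_order")
  class(perm) <- class(co$design)
  tab3 <- icc_per_gene(co$matrix, perm, "SBC")
  expect_equal(tab3$icc, tab$icc, tolerance = 1e-12)
})

test_that("noise-free recurrence pairs reach ICC ~ 1, and ICC is capped at 1", {
  cfg <- simulation_config(
    gene_class("pure", 0.1, 0.5, 0, 1e-10, 50), seed = 3)
  co <- simulate_cohort(cfg)
  tab <- icc_per_gene(co$matrix, co$design, "LRC")
  expect_true(all(tab$icc > 0.999))
  expect_true(all(tab$icc <= 1 + 1e-12))
})

test_that("groups with fewer than 2 pairs and constant genes are handled", {
  co <- small_cohort(seed = 9, n_genes = 20)
  d1 <- co$design[co$design$group != "SBC" |
                    co$design$patient_id == "SBC_p001", ]
  class(d1) <- class(co$design)
  expect_error(icc_per_gene(co$matrix, d1, "SBC"), "at least 2")

  flat <- co$matrix
  flat$values[1, ] <- 4.2
  tab <- icc_per_gene(flat, co$design, "MBC")
  expect_true(is.na(tab$icc[1]))
  expect_identical(attr(tab, "n_undefined"), 1L)
})
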