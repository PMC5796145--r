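test_that("closed-form population ICC follows the sharing structure", {
  cl <- gene_class("x", 0.1, 0.5, 0.3, 0.2, 10)
  expect_equal(population_icc(cl, TRUE, FALSE), 0.6 / 1.1, tolerance = 1e-12)
  expect_equal(population_icc(cl, FALSE, TRUE), 0.4 / 1.1, tolerance = 1e-12)
  expect_equal(population_icc(cl, FALSE, FALSE), 0.1 / 1.1, tolerance = 1e-12)
  # all variance in the shared host component
  host <- gene_class("h", 1, 0, 0, 1e-12, 1)
  expect_equal(population_icc(host, FALSE, FALSE), 1, tolerance = 1e-6)
  expect_equal(unname(population_icc_by_group(cl)),
               c(0.4 / 1.1, 0.1 / 1.1, 0.6 / 1.1), tolerance = 1e-12)
})

test_that("invalid class/config parameters are rejected", {
  expect_error(gene_class("x", -0.1, 0, 0, 0.2, 5), "non-negative")
  expect_error(gene_class("x", 0.1, 0, 0, 0, 5), "strictly positive")
  # zero total variance cannot be built through gene_class (var_noise > 0);
  # forge it to exercise the population_icc guard
  zl <- gene_class("x", 0, 0, 0, 1, 5)
  zl$var_noise <- 0
  expect_error(population_icc(zl, TRUE, TRUE), "positive")
  expect_error(simulation_config(gene_class("x", 0, 0, 0, 1, 5),
                                 n_pairs = c(SBC = 1, MBC = 5, LRC = 5)),
               "n_pairs >= 2")
  expect_error(simulation_config(gene_class("x", 0, 0, 0, 1, 5),
                                 n_pairs = c(SBC = 5, MBC = 5)),
               "must name")
})

test_that("simulated cohorts have the declared shape and are seed-reproducible", {
  cfg <- simulation_config(
    list(gene_class("a", 0.1, 0.5, 0.3, 0.2, 30),
         gene_class("b", 0.1, 0, 0.5, 0.2, 20, prop_undetected = 0.1)),
    n_pairs = c(SBC = 4, MBC = 3, LRC = 5), seed = 77)
  co <- simulate_cohort(cfg)
  expect_equal(dim(co$matrix$values), c(50, 2 * (4 + 3 + 5)))
  expect_equal(sort(unique(co$truth$class)), c("a", "b"))
  expect_equal(nrow(co$design), 12)
  expect_equal(sum(co$truth$undetected), 2)   # floor(0.1 * 20)
  # simple detection rule: undetected genes get p = 0.5 everywhere, others 0
  expect_true(all(co$matrix$detection_p[co$truth$undetected, ] == 0.5))
  expect_true(all(co$matrix$detection_p[!co$truth$undetected, ] == 0))

  co2 <- simulate_cohort(cfg)
  expect_identical(co$matrix$values, co2$matrix$values)

  # per-gene substreams: early genes unchanged when the class grows
  cfg3 <- simulation_config(
    list(gene_class("a", 0.1, 0.5, 0.3, 0.2, 45)),
    n_pairs = c(SBC = 4, MBC = 3, LRC = 5), seed = 77)
  co3 <- simulate_cohort(cfg3)
  expect_identical(co$matrix$values[1:30, ], co3$matrix$values[1:30, ])
})

test_that("no shared variance means ICC centered at zero; shared-only means one", {
  cfg0 <- simulation_config(gene_class("noise", 0, 0, 0, 1, 300), seed = 21)
  co0 <- simulate_cohort(cfg0)
  expect_equal(unique(co0$truth$pop_icc_SBC), 0)
  for (g in c("SBC", "MBC", "LRC")) {
    med <- median(icc_per_gene(co0$matrix, co0$design, g)$icc, na.rm = TRUE)
    expect_lt(abs(med), 0.1)
  }
})

test_that("population ordering LRC > SBC > MBC holds and is recovered empirically", {
  cl <- gene_class("bg", 0.1, 0.5, 0.3, 0.2, 1000)
  pop <- population_icc_by_group(cl)
  expect_true(pop[["LRC"]] > pop[["SBC"]] && pop[["SBC"]] > pop[["MBC"]])

  co <- simulate_cohort(simulation_config(cl, seed = 13))
  med <- vapply(c("LRC", "SBC", "MBC"), function(g)
    median(icc_per_gene(co$matrix, co$design, g)$icc, na.rm = TRUE), 0)
  expect_true(med[["LRC"]] > med[["SBC"]] && med[["SBC"]] > med[["MBC"]])
  expect_equal(unname(med), unname(pop[c("LRC", "SBC", "MBC")]),
               tolerance = 0.05)
})

test_that("intrinsic-like genes: SBC and MBC distributions are indistinguishable", {
  # zero time variance makes SBC and MBC population ICCs equal; across seeded
  # replicates a t-test between their estimated ICC distributions should stay
  # non-significant in the vast majority of runs
  cl <- gene_class("intr", 0.1, 0.5, 0, 0.2, 300)
  expect_equal(population_icc(cl, FALSE, TRUE), population_icc(cl, FALSE, FALSE))
  n_sig <- 0L
  for (s in 1:100) {
    co <- simulate_cohort(simulation_config(cl, seed = 1000 + s))
    sbc <- icc_per_gene(co$matrix, co$design, "SBC")$icc
    mbc <- icc_per_gene(co$matrix, co$design, "MBC")$icc
    if (t.test(sbc, mbc)$p.value < 0.01) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 5)
})

test_that("stromal-like genes: MBC drops below SBC; LRC equals MBC in population", {
  cl <- gene_class("strom", 0.1, 0, 0.5, 0.2, 500)
  expect_equal(population_icc(cl, TRUE, FALSE), population_icc(cl, FALSE, FALSE))
  co <- simulate_cohort(simulation_config(cl, seed = 31))
  med <- vapply(c("SBC", "MBC"), function(g)
    median(icc_per_gene(co$matrix, co$design, g)$icc, na.rm = TRUE), 0)
  expect_lt(med[["MBC"]], med[["SBC"]])
})

test_that("the heavy-tailed noise hook is honored", {
  cfg <- simulation_config(gene_class("bg", 0.1, 0.5, 0.3, 0.2, 40), seed = 4)
  heavy <- function(n, sd) sd * stats::rt(n, df = 3) / sqrt(3)
  co_t <- simulate_cohort(cfg, noise_fn = heavy)
  co_n <- simulate_cohort(cfg)
  expect_false(identical(co_t$matrix$values, co_n$matrix$values))
  expect_equal(dim(co_t$matrix$values), dim(co_n$matrix$values))
})

test_that("cohorts round-trip through the TSV dialect and config files load", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(gene_class("a", 0.1, 0.5, 0.3, 0.2, 12),
                           n_pairs = c(SBC = 3, MBC = 2, LRC = 2), seed = 8)
  co <- simulate_cohort(cfg)
  write_cohort(co, dir)
  back <- read_expression(file.path(dir, "expression.tsv"),
                          annotation = file.path(dir, "annotation.tsv"),
                          detection_path = file.path(dir, "detection_p.tsv"))
  expect_equal(back$values, co$matrix$values, tolerance = 1e-9)
  expect_identical(back$symbols, co$matrix$symbols)
  d <- read_pair_design(file.path(dir, "design.tsv"))
  expect_equal(as.data.frame(d), as.data.frame(co$design))

  yml <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(
    seed = 8, n_pairs = list(SBC = 3, MBC = 2, LRC = 2),
    gene_classes = list(list(name = "a", var_host = 0.1, var_genetic = 0.5,
                             var_time = 0.3, var_noise = 0.2, n_genes = 12))),
    yml)
  cfg2 <- read_simulation_config(yml)
  expect_identical(simulate_cohort(cfg2)$matrix$values, co$matrix$values)
})
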