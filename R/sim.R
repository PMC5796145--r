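#' Parameters for one simulated gene class
#'
#' The generative model decomposes each gene's log2 expression in member j of
#' pair i into four independent Gaussian sources:
#' \deqn{x_{gij} = \mu_g + h_{gi} + g_{gi[j]} + t_{gi[j]} + \epsilon_{gij}}
#' where `h` is a host component always shared by both members of a pair,
#' the genetic-background component `g` is shared within a pair only when the
#' two lesions have a common clonal origin, the time/microenvironment
#' component `t` is shared only when the two lesions arise at the same time,
#' and `eps` is technical noise, always independent.
#'
#' Two stereotyped classes mirror the biology: "intrinsic-like" genes carry
#' high genetic and near-zero time variance (tumor-genotype readouts, like
#' the PAM50 intrinsic genes), "stromal-like" genes the reverse
#' (host/microenvironment readouts).
#'
#' @param name class label.
#' @param var_host host variance shared by both members of every pair
#'   (log2 units squared, >= 0).
#' @param var_genetic genetic-background variance (>= 0).
#' @param var_time time/microenvironment variance (>= 0).
#' @param var_noise technical noise variance (> 0).
#' @param n_genes number of genes in the class (>= 1).
#' @param mean_range baseline expression `mu_g` is drawn once per gene from
#'   `runif(mean_range)`; default \[6, 12\] log2 units emulates an array's
#'   dynamic range (location does not affect the ICC).
#' @param prop_undetected fraction of the class flagged "undetected": those
#'   genes get detection p = 0.5 in every sample (all others 0), a simple
#'   rule that lets the detection filter be exercised.
#' @return a `GeneClassParams` list.
#' @export
gene_class <- function(name, var_host, var_genetic, var_time, var_noise,
                       n_genes, mean_range = c(6, 12), prop_undetected = 0) {
  v <- c(var_host = var_host, var_genetic = var_genetic,
         var_time = var_time, var_noise = var_noise)
  if (any(!is.finite(v)) || any(v < 0))
    stop("variances must be finite and non-negative")
  if (var_noise <= 0) stop("var_noise must be strictly positive")
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (prop_undetected < 0 || prop_undetected > 1)
    stop("prop_undetected must lie in [0, 1]")
  structure(list(name = name, var_host = var_host, var_genetic = var_genetic,
                 var_time = var_time, var_noise = var_noise,
                 n_genes = as.integer(n_genes), mean_range = mean_range,
                 prop_undetected = prop_undetected),
            class = "GeneClassParams")
}

#' The fixed sharing structure of the three pair groups
#'
#' Locally recurrent pairs (LRC) share their genetic background but not their
#' time of occurrence; synchronous bilateral pairs (SBC) share time but not
#' genetic background; metachronous bilateral pairs (MBC) share neither. The
#' host component is shared in all groups (same patient).
#'
#' @return data frame with columns `group`, `genetic_shared`, `time_shared`.
#' @export
sharing_map <- function() {
  data.frame(group = c("SBC", "MBC", "LRC"),
             genetic_shared = c(FALSE, FALSE, TRUE),
             time_shared = c(TRUE, FALSE, FALSE),
             stringsAsFactors = FALSE)
}

#' Simulation configuration for a paired-tumor cohort
#'
#' @param gene_classes list of [gene_class()] objects.
#' @param n_pairs named integer vector of pair counts per group; the default
#'   matches the study cohort (SBC = 18, MBC = 11, LRC = 10 pairs). Every
#'   group needs at least 2 pairs.
#' @param seed integer seed; together with the per-gene substream rule it
#'   makes cohorts bitwise reproducible (see [simulate_cohort()]).
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(gene_classes,
                              n_pairs = c(SBC = 18, MBC = 11, LRC = 10),
                              seed = 1L) {
  if (inherits(gene_classes, "GeneClassParams"))
    gene_classes <- list(gene_classes)
  if (!length(gene_classes) ||
      !all(vapply(gene_classes, inherits, TRUE, "GeneClassParams")))
    stop("gene_classes must be a list of gene_class() objects")
  if (!all(c("SBC", "MBC", "LRC") %in% names(n_pairs)))
    stop("n_pairs must name all of SBC, MBC, LRC")
  n_pairs <- n_pairs[c("SBC", "MBC", "LRC")]
  if (any(n_pairs < 2)) stop("every group needs n_pairs >= 2 (ICC undefined below)")
  structure(list(gene_classes = gene_classes,
                 n_pairs = stats::setNames(as.integer(n_pairs), names(n_pairs)),
                 seed = as.integer(seed), sharing = sharing_map()),
            class = "SimulationConfig")
}

#' Default cohort configuration
#'
#' Three gene classes of 2000 genes each at the study's pair counts: a
#' `background` class with both genetic and time variance (genetic dominant),
#' an `intrinsic-like` class with zero time variance, and a `stromal-like`
#' class with zero genetic variance. Variance defaults (host 0.1, genetic
#' 0.5, time 0.3, noise 0.2) are illustrative magnitudes, not calibrated to
#' any dataset.
#'
#' @param seed integer seed.
#' @param n_genes genes per class.
#' @return a `SimulationConfig`.
#' @export
default_config <- function(seed = 1L, n_genes = 2000) {
  simulation_config(
    gene_classes = list(
      gene_class("background",     0.1, 0.5, 0.3, 0.2, n_genes),
      gene_class("intrinsic-like", 0.1, 0.5, 0.0, 0.2, n_genes),
      gene_class("stromal-like",   0.1, 0.0, 0.5, 0.2, n_genes)),
    seed = seed)
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' The file mirrors [simulation_config()]: top-level `seed`, `n_pairs`
#' (map group -> count) and `gene_classes` (list of maps with the
#' [gene_class()] fields).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `SimulationConfig`.
#' @export
read_simulation_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  classes <- lapply(cfg$gene_classes, function(gc) {
    do.call(gene_class, gc[intersect(names(gc), names(formals(gene_class)))])
  })
  simulation_config(classes,
                    n_pairs = unlist(cfg$n_pairs),
                    seed = if (is.null(cfg$seed)) 1L else cfg$seed)
}

#' Closed-form population ICC of the generative model
#'
#' Under the variance-source model the agreement ICC a gene converges to is
#' the variance shared by both members of a pair over the total:
#' \deqn{ICC = (\sigma^2_H + [\sigma^2_G] + [\sigma^2_T]) /
#'       (\sigma^2_H + \sigma^2_G + \sigma^2_T + \sigma^2_E)}
#' with the genetic and time terms entering the numerator only when shared in
#' the group at hand.
#'
#' @param params a [gene_class()] object.
#' @param genetic_shared is the genetic component shared within pairs?
#' @param time_shared is the time component shared within pairs?
#' @return the population ICC (scalar in \[0, 1\]).
#' @export
population_icc <- function(params, genetic_shared, time_shared) {
  tot <- params$var_host + params$var_genetic + params$var_time + params$var_noise
  if (tot <= 0) stop("total variance must be positive for a population ICC")
  num <- params$var_host +
    (if (genetic_shared) params$var_genetic else 0) +
    (if (time_shared) params$var_time else 0)
  num / tot
}

#' Population ICC per group for a gene class
#' @param params a [gene_class()] object.
#' @return named vector of population ICCs for SBC, MBC, LRC.
#' @export
population_icc_by_group <- function(params) {
  sh <- sharing_map()
  stats::setNames(
    vapply(seq_len(nrow(sh)), function(i)
      population_icc(params, sh$genetic_shared[i], sh$time_shared[i]), 0),
    sh$group)
}

#' Simulate a paired-tumor expression cohort
#'
#' Draws, for every gene and pair, the host, genetic, time and noise
#' components of the variance-source model (see [gene_class()]) with the
#' sharing structure of [sharing_map()]. When a component is unshared it is
#' drawn independently for each member — members stay exchangeable, which
#' keeps the closed-form population ICC exact.
#'
#' Reproducibility: gene `i` (global index across classes) uses its own RNG
#' substream seeded with `(seed + 1000003 * i) mod (2^31 - 1)`, so cohorts
#' are bitwise reproducible and a gene's values do not change when the total
#' gene count does.
#'
#' @param config a [simulation_config()].
#' @param noise_fn optional alternative noise generator, a
#'   `function(n, sd)` returning `n` deviates with standard deviation `sd`
#'   (e.g. scaled Student-t for a heavy-tail robustness check). Default:
#'   Gaussian. The closed-form population ICC assumes the default.
#' @return a `SimulatedCohort`: list with `matrix` (an `ExpressionMatrix`
#'   with detection p-values), `design` (a `PairDesign`) and `truth` (data
#'   frame: `probe_id`, `symbol`, `class`, `undetected`, `pop_icc_SBC`,
#'   `pop_icc_MBC`, `pop_icc_LRC`).
#' @export
simulate_cohort <- function(config, noise_fn = NULL) {
  if (!inherits(config, "SimulationConfig"))
    stop("config must be a simulation_config()")
  if (is.null(noise_fn)) noise_fn <- function(n, sd) stats::rnorm(n, 0, sd)
  groups <- c("SBC", "MBC", "LRC")
  np <- config$n_pairs
  sh <- config$sharing
  rownames(sh) <- sh$group

  patient_ids <- unlist(lapply(groups, function(g)
    sprintf("%s_p%03d", g, seq_len(np[[g]]))))
  design <- pair_design(data.frame(
    patient_id = patient_ids,
    group = rep(groups, np[groups]),
    member1_sample = paste0(patient_ids, "_m1"),
    member2_sample = paste0(patient_ids, "_m2"),
    stringsAsFactors = FALSE))
  samples <- as.vector(rbind(design$member1_sample, design$member2_sample))
  # column block (m1, m2 interleaved per pair) for each group
  col_of <- stats::setNames(seq_along(samples), samples)

  n_total <- sum(vapply(config$gene_classes, `[[`, 1L, "n_genes"))
  vals <- matrix(NA_real_, n_total, length(samples),
                 dimnames = list(sprintf("P%06d", seq_len(n_total)), samples))
  truth <- data.frame(
    probe_id = rownames(vals),
    symbol = sprintf("G%06d", seq_len(n_total)),
    class = NA_character_, undetected = FALSE,
    pop_icc_SBC = NA_real_, pop_icc_MBC = NA_real_, pop_icc_LRC = NA_real_,
    stringsAsFactors = FALSE)

  gi <- 0L
  for (cl in config$gene_classes) {
    pop <- population_icc_by_group(cl)
    n_und <- floor(cl$prop_undetected * cl$n_genes)
    for (j in seq_len(cl$n_genes)) {
      gi <- gi + 1L
      truth$class[gi] <- cl$name
      truth$pop_icc_SBC[gi] <- pop[["SBC"]]
      truth$pop_icc_MBC[gi] <- pop[["MBC"]]
      truth$pop_icc_LRC[gi] <- pop[["LRC"]]
      if (j <= n_und) truth$undetected[gi] <- TRUE
      set.seed((config$seed + 1000003 * gi) %% 2147483647L)
      mu <- stats::runif(1, cl$mean_range[1], cl$mean_range[2])
      for (g in groups) {
        n <- np[[g]]
        h <- stats::rnorm(n, 0, sqrt(cl$var_host))
        if (sh[g, "genetic_shared"]) {
          gm1 <- gm2 <- stats::rnorm(n, 0, sqrt(cl$var_genetic))
        } else {
          gm1 <- stats::rnorm(n, 0, sqrt(cl$var_genetic))
          gm2 <- stats::rnorm(n, 0, sqrt(cl$var_genetic))
        }
        if (sh[g, "time_shared"]) {
          tm1 <- tm2 <- stats::rnorm(n, 0, sqrt(cl$var_time))
        } else {
          tm1 <- stats::rnorm(n, 0, sqrt(cl$var_time))
          tm2 <- stats::rnorm(n, 0, sqrt(cl$var_time))
        }
        e1 <- noise_fn(n, sqrt(cl$var_noise))
        e2 <- noise_fn(n, sqrt(cl$var_noise))
        d <- design[design$group == g, ]
        vals[gi, col_of[d$member1_sample]] <- mu + h + gm1 + tm1 + e1
        vals[gi, col_of[d$member2_sample]] <- mu + h + gm2 + tm2 + e2
      }
    }
  }

  detp <- matrix(0, n_total, length(samples), dimnames = dimnames(vals))
  detp[truth$undetected, ] <- 0.5
  mat <- expression_matrix(vals, symbols = truth$symbol, detection_p = detp)
  structure(list(matrix = mat, design = design, truth = truth),
            class = "SimulatedCohort")
}

#' @export
print.SimulatedCohort <- function(x, ...) {
  cat(sprintf("SimulatedCohort: %d genes, %d pairs (%s)\n",
              nrow(x$matrix$values), nrow(x$design),
              paste(sprintf("%s=%d", names(table(x$design$group)),
                            as.integer(table(x$design$group))), collapse = ", ")))
  cat("  classes:", paste(unique(x$truth$class), collapse = ", "), "\n")
  invisible(x)
}

#' Gene signature of one simulated class
#'
#' Turns the symbols of a simulated gene class into a [gene_signature()] so
#' signature-stratified analyses can be run on synthetic cohorts exactly as
#' on real ones.
#'
#' @param cohort a `SimulatedCohort`.
#' @param class_name one of the class labels in the cohort's truth table.
#' @return a `GeneSignature`.
#' @export
class_signature <- function(cohort, class_name) {
  sym <- cohort$truth$symbol[cohort$truth$class == class_name]
  if (!length(sym)) stop("no genes of class ", class_name)
  gene_signature(class_name, sym, source = "simulated gene class")
}

#' Write a simulated cohort to a directory
#'
#' Emits `expression.tsv`, `detection_p.tsv`, `annotation.tsv`,
#' `design.tsv` and `truth.tsv` in the TSV dialects used by
#' [read_expression()] and [read_pair_design()].
#'
#' @param cohort a `SimulatedCohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$matrix, file.path(dir, "expression.tsv"),
                   detection_path = file.path(dir, "detection_p.tsv"),
                   annotation_path = file.path(dir, "annotation.tsv"))
  write_pair_design(cohort$design, file.path(dir, "design.tsv"))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
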