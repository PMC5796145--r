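#' Pair design: which samples form a tumor pair, and in which group
#'
#' Each record maps a patient to her two paired samples and a clinical group:
#' `SBC` (synchronous bilateral: contralateral tumors diagnosed within six
#' months), `MBC` (metachronous bilateral: beyond six months) or `LRC`
#' (primary tumor with its ipsilateral local recurrence).
#'
#' The member-order convention matters because the agreement ICC keeps a
#' member (column) effect: for SBC, member 1 and 2 are as recorded
#' (right/left); for MBC and LRC, member 1 is the earlier lesion. The
#' convention is stored as the `member_order` attribute.
#'
#' @param df data frame with columns `patient_id`, `group`, `member1_sample`,
#'   `member2_sample`.
#' @param member_order free-text note recording the member-order convention.
#' @return a `PairDesign` (a validated data frame).
#' @export
pair_design <- function(df, member_order =
                          "SBC: as recorded (right, left); MBC/LRC: earlier lesion first") {
  need <- c("patient_id", "group", "member1_sample", "member2_sample")
  if (!all(need %in% names(df)))
    stop("design must have columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[, need]
  df$group <- as.character(df$group)
  bad <- setdiff(unique(df$group), c("SBC", "MBC", "LRC"))
  if (length(bad))
    stop("unknown group(s): ", paste(bad, collapse = ", "),
         " (expected SBC, MBC, LRC)")
  samp <- c(df$member1_sample, df$member2_sample)
  if (anyDuplicated(samp))
    stop("each sample may appear in exactly one pair; duplicated: ",
         paste(unique(samp[duplicated(samp)]), collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicated patient_id in design")
  attr(df, "member_order") <- member_order
  class(df) <- c("PairDesign", "data.frame")
  df
}

#' Read a pair-design TSV
#'
#' Expected columns: patient_id, group, member1_sample, member2_sample.
#'
#' @param path path to the TSV file.
#' @return a `PairDesign`.
#' @export
read_pair_design <- function(path) {
  pair_design(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a pair design as TSV
#' @param design a `PairDesign`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check a design against a matrix for ICC analysis
#'
#' Verifies that every sample of the requested groups is present in the
#' matrix and that each group retained has at least two pairs (the ICC is
#' undefined for a single pair).
#'
#' @param design a `PairDesign`.
#' @param x an `ExpressionMatrix`.
#' @param groups groups to check (default: all present in the design).
#' @return the design restricted to `groups`, invisibly.
#' @export
validate_design <- function(design, x, groups = unique(design$group)) {
  d <- design[design$group %in% groups, , drop = FALSE]
  missing <- setdiff(c(d$member1_sample, d$member2_sample), sample_ids(x))
  if (length(missing))
    stop("samples in design but not in matrix: ",
         paste(missing, collapse = ", "))
  n <- table(d$group)
  if (any(n < 2))
    stop("group(s) with fewer than 2 pairs (ICC undefined): ",
         paste(names(n)[n < 2], collapse = ", "))
  invisible(d)
}
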