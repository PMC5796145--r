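#' Construct an ExpressionMatrix
#'
#' A lightweight container for a probes x samples log2 expression matrix with
#' optional probe-level gene-symbol annotation and a detection p-value matrix
#' (Illumina bead arrays report, per probe and sample, the probability that
#' the signal is indistinguishable from background).
#'
#' @param values numeric matrix, probes in rows, samples in columns. Row names
#'   are probe ids, column names are sample ids; both must be unique.
#' @param symbols optional character vector of gene symbols, one per probe
#'   (`NA` for unannotated probes). Symbols are stored case-folded to upper
#'   case with surrounding whitespace stripped, so signature matching is
#'   case-insensitive.
#' @param detection_p optional numeric matrix of detection p-values in
#'   \[0, 1\], same dimensions and dimnames as `values`.
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, symbols = NULL, detection_p = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  # ids are only enforceable on nonzero extents: R drops the dimnames of an
  # empty margin, and an empty filter result is legal
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("`values` must have probe ids as row names and sample ids as column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("`values` contains non-finite entries after ingest")
  if (!is.null(symbols)) {
    if (length(symbols) != nrow(values))
      stop("`symbols` must have one entry per probe")
    symbols <- clean_symbols(symbols)
  }
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !all(dim(detection_p) == dim(values)))
      stop("`detection_p` must be a matrix with the same shape as `values`")
    if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE))
      stop("`detection_p` values must lie in [0, 1]")
    dimnames(detection_p) <- dimnames(values)
  }
  structure(
    list(values = values, symbols = symbols, detection_p = detection_p),
    class = "ExpressionMatrix"
  )
}

clean_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[!nzchar(x) | x %in% c("NA", "")] <- NA_character_
  x
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$symbols))
    cat(sprintf("  annotated probes: %d\n", sum(!is.na(x$symbols))))
  if (!is.null(x$detection_p))
    cat("  detection p-values: present\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Probe and sample identifiers
#' @param x an `ExpressionMatrix`.
#' @return character vector of ids.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname probe_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an ExpressionMatrix
#'
#' @param x an `ExpressionMatrix`.
#' @param i probe index (integer, logical or probe-id character).
#' @param j sample index.
#' @param ... ignored.
#' @return the subsetted `ExpressionMatrix`.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(i)) i <- match(i, rownames(x$values))
  if (anyNA(i)) stop("unknown probe id in subset")
  vals <- x$values[i, j, drop = FALSE]
  expression_matrix(
    vals,
    symbols = if (!is.null(x$symbols)) x$symbols[i],
    detection_p = if (!is.null(x$detection_p)) x$detection_p[i, j, drop = FALSE]
  )
}

#' Read an expression matrix from disk
#'
#' Supports two dialects: a plain TSV (first row sample ids, first column
#' probe ids) and the GEO series-matrix text format, whose data block sits
#' between `!series_matrix_table_begin` and `!series_matrix_table_end`
#' markers (all other `!`-prefixed lines are ignored).
#'
#' @param path path to the file.
#' @param dialect `"tsv"` or `"geo_series_matrix"`.
#' @param log2_transform if `TRUE`, values are log2-transformed after reading
#'   (a pseudo-count of 1 is NOT added; supply already-offset intensities).
#'   Default `FALSE`: values are taken to be on the log2 scale already.
#' @param na_action policy for missing cells: `"error"` (default) rejects the
#'   file, `"impute_median"` replaces each missing cell with its probe's
#'   median across samples.
#' @param annotation optional probe annotation: a path to a two-column TSV
#'   (probe_id, symbol; with header) or a data frame with those columns.
#' @param detection_path optional path to a companion detection p-value TSV
#'   with the identical probe x sample layout.
#' @return an `ExpressionMatrix`.
#' @export
read_expression <- function(path,
                            dialect = c("tsv", "geo_series_matrix"),
                            log2_transform = FALSE,
                            na_action = c("error", "impute_median"),
                            annotation = NULL,
                            detection_path = NULL) {
  dialect <- match.arg(dialect)
  na_action <- match.arg(na_action)
  vals <- switch(dialect,
    tsv = read_value_tsv(path),
    geo_series_matrix = read_series_matrix(path)
  )
  if (anyNA(vals)) {
    if (na_action == "error") {
      bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop(sprintf("missing value at probe '%s', sample '%s' (na_action = \"error\")",
                   rownames(vals)[bad[1]], colnames(vals)[bad[2]]))
    }
    med <- apply(vals, 1, stats::median, na.rm = TRUE)
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- med[idx[, 1]]
  }
  if (log2_transform) {
    if (any(vals <= 0))
      stop("log2 transform requested but non-positive values present")
    vals <- log2(vals)
  }
  symbols <- NULL
  if (!is.null(annotation)) {
    ann <- if (is.character(annotation))
      utils::read.delim(annotation, stringsAsFactors = FALSE) else annotation
    if (ncol(ann) < 2) stop("annotation must have columns probe_id, symbol")
    symbols <- ann[[2]][match(rownames(vals), ann[[1]])]
  }
  detection_p <- NULL
  if (!is.null(detection_path)) {
    detection_p <- read_value_tsv(detection_path)
    if (!identical(dim(detection_p), dim(vals)) ||
        !identical(rownames(detection_p), rownames(vals)) ||
        !identical(colnames(detection_p), colnames(vals)))
      stop("detection p-value table does not match the expression table layout")
  }
  expression_matrix(vals, symbols = symbols, detection_p = detection_p)
}

read_value_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate probe ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- tab[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) &
                     !toupper(trimws(col)) %in% c("NA", ""))
      if (length(bad))
        stop(sprintf("non-numeric cell at probe '%s', sample '%s': \"%s\"",
                     ids[bad[1]], colnames(body)[j], col[bad[1]]))
      body[[j]] <- num
    }
  }
  vals <- as.matrix(body)
  rownames(vals) <- ids
  vals
}

read_series_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1 || length(end) != 1 || end <= beg + 1)
    stop("no series-matrix data block (begin/end markers) found in ", path)
  block <- lines[(beg + 1):(end - 1)]
  tab <- utils::read.delim(text = paste(block, collapse = "\n"),
                           header = TRUE, check.names = FALSE,
                           quote = "\"", stringsAsFactors = FALSE)
  ids <- gsub("\"", "", as.character(tab[[1]]))
  if (anyDuplicated(ids))
    stop("duplicate probe ids in series matrix: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  colnames(vals) <- gsub("\"", "", colnames(vals))
  vals
}

#' Write an expression matrix (and companions) as TSV
#'
#' @param x an `ExpressionMatrix`.
#' @param path output path for the value matrix (probe_id column first).
#' @param detection_path optional path for the detection p-value companion.
#' @param annotation_path optional path for the probe_id/symbol table.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, detection_path = NULL,
                             annotation_path = NULL) {
  write_value_tsv(x$values, path)
  if (!is.null(detection_path)) {
    if (is.null(x$detection_p)) stop("no detection p-values to write")
    write_value_tsv(x$detection_p, detection_path)
  }
  if (!is.null(annotation_path)) {
    if (is.null(x$symbols)) stop("no symbol annotation to write")
    utils::write.table(
      data.frame(probe_id = probe_ids(x), symbol = x$symbols),
      annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

write_value_tsv <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
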