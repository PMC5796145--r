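#' Construct a gene signature
#'
#' @param name signature name.
#' @param symbols character vector of gene symbols; case-folded, whitespace
#'   stripped and deduplicated (with a warning when duplicates are dropped).
#' @param source provenance note.
#' @return a `GeneSignature`.
#' @export
gene_signature <- function(name, symbols, source = "user") {
  symbols <- clean_symbols(symbols)
  symbols <- symbols[!is.na(symbols)]
  if (!length(symbols)) stop("signature '", name, "' has no symbols")
  if (anyDuplicated(symbols)) {
    warning("signature '", name, "': duplicate symbols removed")
    symbols <- unique(symbols)
  }
  structure(list(name = name, symbols = symbols, source = source),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature '%s': %d symbols (%s)\n",
              x$name, length(x$symbols), x$source))
  invisible(x)
}

#' Load a gene signature from a file or by packaged name
#'
#' Accepts a plain-text file (one symbol per line; blank lines and `#`
#' comments ignored) or a GMT file (first line's set is used unless `set`
#' names another). The intrinsic breast-cancer list is packaged: pass
#' `"PAM50"` to load its 50 gene symbols.
#'
#' @param path_or_name file path, or `"PAM50"`.
#' @param name optional signature name (default: file base name).
#' @param set for GMT files, which gene set to load (default: first).
#' @return a `GeneSignature`.
#' @export
load_signature <- function(path_or_name, name = NULL, set = NULL) {
  if (identical(toupper(path_or_name), "PAM50")) {
    path <- system.file("extdata", "pam50_symbols.txt", package = "iccdissect")
    return(load_signature(path, name = "PAM50"))
  }
  if (!file.exists(path_or_name)) stop("file not found: ", path_or_name)
  lines <- readLines(path_or_name, warn = FALSE)
  if (grepl("\\.gmt$", path_or_name, ignore.case = TRUE)) {
    fields <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
    if (!length(fields)) stop("empty signature file: ", path_or_name)
    sets <- vapply(fields, `[[`, "", 1)
    pick <- if (is.null(set)) 1L else match(set, sets)
    if (is.na(pick)) stop("gene set '", set, "' not found in ", path_or_name)
    f <- fields[[pick]]
    if (length(f) < 3) stop("GMT set '", sets[pick], "' has no genes")
    return(gene_signature(if (is.null(name)) sets[pick] else name,
                          f[-(1:2)], source = path_or_name))
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty signature file: ", path_or_name)
  gene_signature(
    if (is.null(name)) sub("\\.[^.]*$", "", basename(path_or_name)) else name,
    lines, source = path_or_name)
}

#' Realize a signature as a probe set on a platform
#'
#' Matches signature symbols against the matrix's probe annotation,
#' case-insensitively, and reports which symbols were found and by how many
#' probes. One symbol may be detected by several probes; all are returned,
#' in the matrix's probe order.
#'
#' @param signature a `GeneSignature`.
#' @param x an `ExpressionMatrix` with symbol annotation.
#' @return a `SignatureMapping`: list with `signature` (name),
#'   `matched_symbols`, `probe_ids`, and `counts`
#'   (`n_symbols_input`, `n_symbols_matched`, `n_probes`).
#' @export
map_symbols_to_probes <- function(signature, x) {
  if (is.null(x$symbols))
    stop("matrix has no symbol annotation; cannot map a signature")
  hit <- !is.na(x$symbols) & x$symbols %in% signature$symbols
  matched <- intersect(signature$symbols, x$symbols[hit])
  structure(list(
    signature = signature$name,
    matched_symbols = matched,
    probe_ids = probe_ids(x)[hit],
    counts = c(n_symbols_input = length(signature$symbols),
               n_symbols_matched = length(matched),
               n_probes = sum(hit))),
    class = "SignatureMapping")
}

#' @export
print.SignatureMapping <- function(x, ...) {
  cat(sprintf("SignatureMapping '%s': %d/%d symbols matched by %d probes\n",
              x$signature, x$counts[["n_symbols_matched"]],
              x$counts[["n_symbols_input"]], x$counts[["n_probes"]]))
  invisible(x)
}

#' Write a signature-mapping report as TSV
#' @param mapping a `SignatureMapping`.
#' @param x the `ExpressionMatrix` it was mapped on (for probe symbols).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_mapping <- function(mapping, x, path) {
  idx <- match(mapping$probe_ids, probe_ids(x))
  utils::write.table(
    data.frame(signature = mapping$signature,
               probe_id = mapping$probe_ids,
               symbol = x$symbols[idx]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
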