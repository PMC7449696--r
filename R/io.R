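# Plain-text readers and writers for the pipeline's interchange formats:
# event tables as CSV with a sidecar manifest, expression matrices as TSV
# (genes x samples), gene sets as GMT.

#' Read / write a tpm expression matrix as TSV
#'
#' Genes in rows (first column `gene`), samples in columns.
#'
#' @param path file path.
#' @return `read_tpm` returns a numeric gene x sample matrix.
#' @export
read_tpm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stop("first column of a tpm table must be 'gene'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop("tpm values must be non-negative")
  m
}

#' @rdname read_tpm
#' @param tpm gene x sample matrix.
#' @export
write_tpm <- function(tpm, path) {
  df <- data.frame(gene = rownames(tpm), tpm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids,
#' tab-separated.
#'
#' @param path file path.
#' @return named list of gene-id character vectors; descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty gene-set file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) stop("GMT lines need name, description and >= 1 gene")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene-id vectors.
#' @param description optional per-set description strings.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an event table to CSV
#'
#' Numeric columns are written at full precision so that re-runs are
#' byte-identical.
#'
#' @param events event table.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  num <- vapply(events, is.numeric, logical(1))
  out <- events
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event table written by [write_events()]
#'
#' @param path file path.
#' @return data frame.
#' @export
read_events <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
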