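#' Read and write the pipeline's plain-text interchange formats
#'
#' Matrices are written as TSV with samples in rows and aptamer IDs in
#' columns (first column \code{sample_id}); networks as 3-column TSV
#' (source, target, sign in +/-); gene sets as GMT (term, description,
#' members); cell-type markers as 2-column TSV (cell_type, protein).
#' All writers produce byte-stable output for a given object.
#'
#' @param x matrix / data frame / object to write.
#' @param path file path.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname pipeline_io
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname pipeline_io
#' @export
read_network_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("source", "target", "sign")
  signed_digraph(df)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file: one term per line, tab-separated — term ID,
#'   description, then member genes.
#' @return named list of character vectors; each element carries its
#'   description as the \code{"description"} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) next
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    attr(members, "description") <- parts[2]
    sets[[parts[1]]] <- members
  }
  sets
}

#' @rdname pipeline_io
#' @export
read_marker_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("cell_type", "protein")
  split(df$protein, df$cell_type)
}

#' Write a ground-truth object as JSON
#' @param truth a \code{ground_truth} list from \code{\link{simulate_cohorts}}.
#' @param path file path.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a QC report as JSON
#' @param report a \code{qc_report}.
#' @param path file path.
#' @export
write_qc_report_json <- function(report, path) {
  jsonlite::write_json(
    list(removed_aptamers = report$removed_aptamers,
         removed_samples = report$removed_samples,
         counts = as.list(report$counts),
         surviving = as.list(report$surviving),
         input = as.list(report$input)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
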