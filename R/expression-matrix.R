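#' Expression matrix with sample annotations
#'
#' Container for a normalized log2 expression matrix (genes x samples) plus a
#' sample sheet giving, for every column, the experimental condition
#' (`treated` or `control`), the timepoint in minutes after stimulation, and
#' the replicate number. All downstream statistics (per-timepoint regularized
#' t-tests, the nested polynomial time-course ANOVA, the subset-dynamics
#' distance) consume this container.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row names
#'   (or `gene_ids`) supply the gene identifiers; column names must match the
#'   sample sheet's `sample_id`.
#' @param samples data.frame with columns `sample_id`, `condition`
#'   (`"treated"`/`"control"`), `timepoint_min` (non-negative integer minutes),
#'   `replicate` (positive integer).
#' @param gene_ids optional character vector of gene identifiers overriding
#'   the row names of `values`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (numeric matrix with dimnames), `gene_ids`, and `samples`.
#' @details Gene identifiers are opaque case-sensitive strings; no identifier
#'   normalization is attempted. All values must be finite: missing values are
#'   rejected at construction (the arrays this models are fully observed after
#'   normalization, and silent imputation hides data problems).
#' @examples
#' v <- matrix(rnorm(8), 2, 4, dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
#' sheet <- data.frame(sample_id = paste0("s", 1:4),
#'                     condition = rep(c("treated", "control"), 2),
#'                     timepoint_min = c(30, 30, 60, 60), replicate = c(1, 1, 1, 1))
#' em <- expression_matrix(v, sheet)
#' @export
expression_matrix <- function(values, samples, gene_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    abort("`values` must be a numeric matrix", "abatime_format_error")
  gene_ids <- gene_ids %||% rownames(values)
  if (is.null(gene_ids))
    abort("gene identifiers missing (no rownames and no `gene_ids`)",
          "abatime_format_error")
  gene_ids <- as.character(gene_ids)
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    abort(sprintf("duplicated gene id(s): %s",
                  paste(unique(dup), collapse = ", ")),
          "abatime_format_error")
  if (anyNA(values) || any(!is.finite(values)))
    abort("expression values must all be finite (no missing values)",
          "abatime_format_error")
  samples <- validate_sample_sheet(samples)
  sid <- colnames(values) %||% samples$sample_id
  if (length(sid) != nrow(samples) ||
      !setequal(sid, samples$sample_id))
    abort("sample columns and sample sheet disagree", "abatime_consistency_error")
  # column order follows the sample sheet
  values <- values[, match(samples$sample_id, sid), drop = FALSE]
  dimnames(values) <- list(gene_ids, samples$sample_id)
  structure(list(values = values, gene_ids = gene_ids, samples = samples),
            class = "expression_matrix")
}

validate_sample_sheet <- function(samples) {
  need <- c("sample_id", "condition", "timepoint_min", "replicate")
  if (!is.data.frame(samples) || !all(need %in% names(samples)))
    abort(sprintf("sample sheet must have columns %s",
                  paste(need, collapse = ", ")), "abatime_format_error")
  samples <- as.data.frame(samples)[need]
  samples$sample_id <- as.character(samples$sample_id)
  samples$condition <- as.character(samples$condition)
  if (!all(samples$condition %in% c("treated", "control")))
    abort("condition must be 'treated' or 'control'", "abatime_format_error")
  samples$timepoint_min <- as.integer(samples$timepoint_min)
  samples$replicate <- as.integer(samples$replicate)
  if (anyNA(samples$timepoint_min) || any(samples$timepoint_min < 0))
    abort("timepoint_min must be a non-negative integer", "abatime_format_error")
  if (anyNA(samples$replicate) || any(samples$replicate < 1))
    abort("replicate must be a positive integer", "abatime_format_error")
  if (anyDuplicated(samples$sample_id))
    abort("duplicated sample_id in sample sheet", "abatime_format_error")
  key <- paste(samples$condition, samples$timepoint_min, samples$replicate)
  if (anyDuplicated(key))
    abort("duplicated (condition, timepoint, replicate) triple",
          "abatime_format_error")
  rownames(samples) <- NULL
  samples
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$samples$condition, x$samples$timepoint_min)
  cat("replicates per condition x timepoint (min):\n")
  print(tab)
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Distinct timepoints of an expression matrix
#' @param em an `expression_matrix`.
#' @return sorted integer vector of distinct timepoints (minutes).
#' @export
timepoints <- function(em) sort(unique(em$samples$timepoint_min))

#' Read an expression matrix and its sample sheet from TSV files
#'
#' The matrix file is tab-delimited with a header row of sample ids and first
#' column `gene_id`; the sample sheet has columns `sample_id`, `condition`,
#' `timepoint_min`, `replicate`. Sample order is taken from the sample sheet.
#' CRLF line endings are tolerated; the canonical dialect is tab-delimited
#' UTF-8 with Unix line endings.
#'
#' @param matrix_path path to the expression TSV.
#' @param samplesheet_path path to the sample-sheet TSV.
#' @return a validated [expression_matrix()].
#' @export
read_expression <- function(matrix_path, samplesheet_path) {
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L || names(raw)[1] != "gene_id")
    abort("matrix file must start with a 'gene_id' column", "abatime_format_error")
  gene_ids <- as.character(raw[[1]])
  num <- raw[-1]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad))
    abort(sprintf("non-numeric expression column(s): %s",
                  paste(names(num)[bad], collapse = ", ")),
          "abatime_format_error")
  values <- as.matrix(num)
  rownames(values) <- gene_ids
  sheet <- utils::read.delim(samplesheet_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  expression_matrix(values, sheet)
}

#' Write an expression matrix and its sample sheet to TSV files
#'
#' Inverse of [read_expression()]: `write_expression` followed by
#' `read_expression` reproduces the values bit-identically (full-precision
#' decimal serialization via \code{format(..., digits = 17)}).
#'
#' @param em an `expression_matrix`.
#' @param matrix_path,samplesheet_path output paths.
#' @return invisibly, the paths written.
#' @export
write_expression <- function(em, matrix_path, samplesheet_path) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(gene_id = em$gene_ids,
                   format(em$values, digits = 17, trim = TRUE,
                          scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(em$samples, samplesheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, samplesheet_path))
}

#' Read a gene set from a plain-text file
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' ignored. The result is deduplicated and order-independent.
#'
#' @param path input file.
#' @return character vector of unique gene ids (possibly empty; an empty file
#'   yields an empty set with a warning, not an error).
#' @export
read_gene_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- unique(lines)
  if (!length(out)) warning("gene set file '", path, "' is empty")
  out
}

#' Write a gene set to a plain-text file (one id per line)
#' @param genes character vector of gene ids.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(unique(as.character(genes)), path)
  invisible(path)
}
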