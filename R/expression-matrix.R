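#' Gene-by-sample expression matrix with an explicit scale flag
#'
#' Light container pairing a numeric genes x samples matrix with a flag saying
#' whether values are normalized TPM or log2(TPM + 1). Downstream operations
#' check the flag so that, for example, differential expression can refuse a
#' raw-TPM input.
#'
#' @param values Numeric matrix, genes in rows (unique rownames) and samples in
#'   columns (unique colnames). No missing values allowed; TPM values must be
#'   non-negative.
#' @param scale `"tpm"` for normalized transcripts-per-million, `"log2"` for
#'   log2(TPM + 1).
#' @return An object of class `expr_matrix`.
#' @seealso [log_transform()], [read_expression_tsv()]
#' @export
expression_matrix <- function(values, scale = c("tpm", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) field_stop("values", "must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    field_stop("values", "must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    field_stop("gene ids", sprintf("duplicated id '%s'", dup))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1L]
    field_stop("sample ids", sprintf("duplicated id '%s'", dup))
  }
  if (anyNA(values)) field_stop("values", "missing values are not allowed")
  if (scale == "tpm" && any(values < 0)) {
    field_stop("values", "TPM-scale values must be non-negative")
  }
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Extract the numeric matrix or scale flag from an `expr_matrix`
#' @param m An [expression_matrix()].
#' @return `expr_values()` the genes x samples numeric matrix;
#'   `expr_scale()` the scale flag (`"tpm"` or `"log2"`).
#' @export
expr_values <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  m$values
}

#' @rdname expr_values
#' @export
expr_scale <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  m$scale
}

#' Read an expression matrix from TSV
#'
#' Expected layout: header row of sample ids, first column of gene ids,
#' tab-separated numeric cells. Duplicated gene ids and non-numeric cells are
#' rejected with the offending coordinates in the error message.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param scale Declared scale of the stored values (default `"tpm"`).
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, scale = c("tpm", "log2")) {
  scale <- match.arg(scale)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(raw) < 2L) field_stop("file", "needs a gene id column plus >=1 sample column")
  genes <- raw[[1L]]
  if (anyDuplicated(genes)) {
    dup <- genes[duplicated(genes)][1L]
    stop(sprintf("duplicate gene id '%s' in %s", dup, path), call. = FALSE)
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at gene row %d ('%s'), sample column %d ('%s')",
                 bad[1L], genes[bad[1L]], bad[2L], colnames(cells)[bad[2L]]),
         call. = FALSE)
  }
  dimnames(num) <- list(genes, colnames(cells))
  expression_matrix(num, scale = scale)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_tsv()]: first column `gene`, header row of
#' sample ids. Values are written at full double precision so a write/read
#' round trip is exact.
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  v <- expr_values(m)
  df <- data.frame(gene = rownames(v),
                   format(v, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table from TSV
#'
#' Requires columns `sample_id`, `patient_id`, `site`. Site labels define the
#' contrasts: the study design uses `stricture`, `proximal`, `distal`.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with character columns `sample_id`, `patient_id`,
#'   `site`.
#' @export
read_sample_metadata_tsv <- function(path) {
  meta <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     colClasses = "character", quote = "")
  need <- c("sample_id", "patient_id", "site")
  miss <- setdiff(need, names(meta))
  if (length(miss)) field_stop("metadata", paste("missing column(s):",
                                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(meta$sample_id)) field_stop("sample_id", "duplicated ids")
  meta[need]
}

#' @noRd
write_metadata_tsv <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## check that metadata covers exactly the matrix columns
check_meta <- function(m, meta) {
  v <- expr_values(m)
  if (!setequal(colnames(v), meta$sample_id)) {
    field_stop("metadata", "sample ids do not match the expression matrix columns")
  }
  meta[match(colnames(v), meta$sample_id), , drop = FALSE]
}
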