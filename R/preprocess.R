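#' Log-transform a TPM expression matrix
#'
#' Replaces every value v by log2(v + 1), the transform under which a two-fold
#' expression change equals a mean difference of one unit. Shape and ids are
#' unchanged; the round trip `2^v - 1` recovers TPM exactly.
#'
#' @param m A TPM-scale [expression_matrix()].
#' @return A log2-scale [expression_matrix()].
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_scale(m) != "tpm") {
    field_stop("scale", "input is already log-transformed")
  }
  v <- expr_values(m)
  if (any(v < 0)) field_stop("values", "negative TPM value")
  expression_matrix(log2(v + 1), "log2")
}

#' Filter low-count and low-variance genes
#'
#' Applies the two study filters in order: (a) remove genes whose transformed
#' value falls below 1 in any sample; (b) among the survivors, remove genes in
#' the lowest `variance_quantile` of per-gene variance. A zero-variance
#' (constant) gene is always removed by (b) whenever `variance_quantile > 0`;
#' at `variance_quantile = 0` the variance filter is a no-op, making the
#' operation idempotent.
#'
#' @param m A log2-scale [expression_matrix()].
#' @param variance_quantile Fraction of lowest-variance survivors to drop
#'   (default 0.10).
#' @return List with `matrix` (the filtered [expression_matrix()]) and
#'   `report`: counts of input genes, genes removed by each rule, and the
#'   retained gene ids.
#' @export
filter_genes <- function(m, variance_quantile = 0.10) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_scale(m) != "log2") field_stop("scale", "input must be log2-transformed")
  if (variance_quantile < 0 || variance_quantile >= 1) {
    field_stop("variance_quantile", "must lie in [0, 1)")
  }
  v <- expr_values(m)
  n_input <- nrow(v)

  keep_count <- apply(v, 1L, function(row) all(row >= 1))
  n_low_count <- sum(!keep_count)
  v1 <- v[keep_count, , drop = FALSE]
  if (nrow(v1) == 0L) stop("empty matrix: every gene failed the low-count filter",
                           call. = FALSE)

  gene_var <- apply(v1, 1L, var)
  thr <- quantile(gene_var, variance_quantile, names = FALSE)
  drop_var <- gene_var < thr
  if (variance_quantile > 0) drop_var <- drop_var | gene_var == 0
  keep_var <- !drop_var
  n_low_var <- sum(!keep_var)
  v2 <- v1[keep_var, , drop = FALSE]
  if (nrow(v2) == 0L) stop("empty matrix: every gene failed the variance filter",
                           call. = FALSE)

  report <- list(n_input_genes = n_input,
                 n_removed_low_count = n_low_count,
                 n_removed_low_variance = n_low_var,
                 retained = rownames(v2))
  list(matrix = expression_matrix(v2, "log2"), report = report)
}
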