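#' Area under the ROC curve from continuous scores
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) sample
#' pairs in which the positive sample scores higher, ties counted one half.
#' Invariant under any strictly monotone transform of the scores.
#'
#' @param scores Numeric vector of classifier scores.
#' @param labels Logical (or two-level) vector, `TRUE`/positive meaning the
#'   target class; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_from_scores(c(1, 2, 4, 3, 5), c(FALSE, FALSE, FALSE, TRUE, TRUE))
#' @export
auc_from_scores <- function(scores, labels) {
  if (is.factor(labels) || is.character(labels)) {
    lab <- factor(labels)
    if (nlevels(lab) != 2L) field_stop("labels", "need exactly two classes")
    labels <- lab == levels(lab)[2L]
  }
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) field_stop("labels", "length mismatch")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) field_stop("labels", "one class is absent")
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

## stratified fold assignment, seeded by the caller's RNG state
stratified_folds <- function(lab, folds) {
  fold_id <- integer(length(lab))
  for (cl in levels(lab)) {
    idx <- sample(which(lab == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Random-forest AUC of a gene panel
#'
#' Trains a bagged random forest on the panel's expression columns and scores
#' stricture versus non-stricture by AUC. Out-of-sample class probabilities
#' come from pooled stratified k-fold cross-validation (default, the least
#' optimistic common choice at small n), from out-of-bag votes
#' (`scheme = "oob"`), or from resubstitution (`scheme = "resub"`, optimistic
#' and flagged as such). The confidence interval is a percentile bootstrap
#' over score/label pairs, resampled within class.
#'
#' @param m A log2-scale [expression_matrix()].
#' @param labels Per-sample class labels (two classes, >= 3 samples each).
#' @param panel Character vector of gene ids (all present in `m`).
#' @param n_trees Trees per forest (default 500).
#' @param scheme Scoring scheme: `"cv"`, `"oob"` or `"resub"`.
#' @param folds CV fold count (default 5); reduced automatically, with a
#'   warning, when a class has fewer samples than folds.
#' @param n_boot Bootstrap resamples for the CI (default 2000).
#' @param conf_level CI level (default 0.95).
#' @param seed Seed for fold assignment, forests and bootstrap.
#' @param panel_name Optional display name.
#' @return List of class `auc_result`: `panel_name`, `genes`, `auc`,
#'   `ci_low`, `ci_high`, `n_pos`, `n_neg`, `scheme`, `scores`.
#' @export
rf_panel_auc <- function(m, labels, panel, n_trees = 500,
                         scheme = c("cv", "oob", "resub"), folds = 5,
                         n_boot = 2000, conf_level = 0.95, seed = 1,
                         panel_name = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(m, "expr_matrix"))
  v <- expr_values(m)
  miss <- setdiff(panel, rownames(v))
  if (length(miss)) field_stop("panel", sprintf("gene '%s' absent from the matrix", miss[1L]))
  if (length(panel) < 1L) field_stop("panel", "must contain at least one gene")
  lab <- factor(labels)
  if (nlevels(lab) != 2L) field_stop("labels", "need exactly two classes")
  if (any(table(lab) < 3L)) field_stop("labels", "need at least 3 samples per class")
  positive <- if ("stricture" %in% levels(lab)) "stricture" else levels(lab)[2L]
  x <- t(v[panel, , drop = FALSE])
  colnames(x) <- make.names(colnames(x))
  n <- nrow(x)

  set.seed(stream_seed(seed, "rf"))
  scores <- switch(
    scheme,
    cv = {
      k <- min(folds, min(table(lab)))
      if (k < folds) warning(sprintf("fold count reduced to %d (smallest class size)", k))
      fold_id <- stratified_folds(lab, k)
      sc <- numeric(n)
      for (f in seq_len(k)) {
        test <- fold_id == f
        rf <- randomForest(x[!test, , drop = FALSE], lab[!test], ntree = n_trees)
        sc[test] <- predict(rf, x[test, , drop = FALSE], type = "prob")[, positive]
      }
      sc
    },
    oob = {
      rf <- randomForest(x, lab, ntree = n_trees)
      rf$votes[, positive]
    },
    resub = {
      rf <- randomForest(x, lab, ntree = n_trees)
      predict(rf, x, type = "prob")[, positive]
    }
  )

  is_pos <- lab == positive
  auc <- auc_from_scores(scores, is_pos)
  pos_idx <- which(is_pos)
  neg_idx <- which(!is_pos)
  boot <- vapply(seq_len(n_boot), function(b) {
    i <- c(sample(pos_idx, replace = TRUE), sample(neg_idx, replace = TRUE))
    auc_from_scores(scores[i], is_pos[i])
  }, numeric(1))
  alpha2 <- (1 - conf_level) / 2
  ci <- quantile(boot, c(alpha2, 1 - alpha2), names = FALSE)

  structure(list(panel_name = panel_name %||% paste(panel, collapse = "+"),
                 genes = panel, auc = auc,
                 ci_low = ci[1L], ci_high = ci[2L],
                 n_pos = length(pos_idx), n_neg = length(neg_idx),
                 scheme = scheme, conf_level = conf_level,
                 scores = setNames(scores, rownames(x))),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("<auc_result> %s: AUC %.3f (%d%% CI %.3f-%.3f), %s scoring, %d pos / %d neg\n",
              x$panel_name, x$auc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$scheme, x$n_pos, x$n_neg))
  invisible(x)
}
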