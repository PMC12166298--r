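## Core NIPALS PLS1 on a samples x genes matrix and a numeric response.
## x must already be centered/scaled, y centered. Deterministic: with a single
## response the weight vector is X'y directly (no iterative start needed).
pls1_core <- function(x, y, n_components) {
  p <- ncol(x)
  W <- P <- matrix(0, p, 0)
  TT <- matrix(0, nrow(x), 0)
  q <- numeric(0)
  ss <- numeric(0)
  xd <- x
  yd <- y
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tvec <- drop(xd %*% w)
    tt <- sum(tvec^2)
    if (tt < 1e-12) break
    pvec <- drop(crossprod(xd, tvec)) / tt
    qa <- sum(yd * tvec) / tt
    W <- cbind(W, w)
    P <- cbind(P, pvec)
    TT <- cbind(TT, tvec)
    q <- c(q, qa)
    ss <- c(ss, qa^2 * tt)
    xd <- xd - tcrossprod(tvec, pvec)
    yd <- yd - qa * tvec
  }
  list(W = W, P = P, scores = TT, q = q, ss = ss)
}

vip_from_fit <- function(W, ss) {
  p <- nrow(W)
  if (ncol(W) == 0L || sum(ss) <= 0) {
    warning("response carries no projected variance; VIP defined as zero")
    return(rep(0, p))
  }
  ## W columns have unit norm by construction
  sqrt(p * drop(W^2 %*% ss) / sum(ss))
}

#' Fit a PLS-DA model for stricture versus non-stricture
#'
#' NIPALS partial least squares with a single binary response (class indicator
#' centered), genes autoscaled to zero mean and unit variance - the
#' convention under which a VIP threshold of 1 is interpretable. Deflation
#' makes the component scores mutually orthogonal; the fit is deterministic
#' (no random initialization). Zero-variance genes are excluded with a
#' warning before scaling.
#'
#' @param m A log2-scale [expression_matrix()].
#' @param labels Per-sample class labels with exactly two levels and at least
#'   two samples per class.
#' @param n_components Maximum number of latent components (default 2; the
#'   fit stops early if the response is exhausted).
#' @param positive Label treated as the positive class (default `"stricture"`
#'   if present, else the last factor level).
#' @return An object of class `plsda_model` with weights, scores, loadings,
#'   per-component explained response sum of squares `ss`, cumulative `r2`,
#'   and per-gene `vip` scores (whose squares average to 1).
#' @export
fit_plsda <- function(m, labels, n_components = 2, positive = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  lab <- factor(labels)
  if (nlevels(lab) != 2L) field_stop("labels", "need exactly two classes")
  if (any(table(lab) < 2L)) field_stop("labels", "need at least 2 samples per class")
  x <- t(expr_values(m))
  if (nrow(x) != length(lab)) field_stop("labels", "length must equal the sample count")
  if (is.null(positive)) {
    positive <- if ("stricture" %in% levels(lab)) "stricture" else levels(lab)[2L]
  }
  y <- as.numeric(lab == positive)

  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance gene(s) excluded before scaling", sum(sds == 0)))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(x) == 0L) field_stop("m", "no genes with positive variance")
  ctr <- colMeans(x)
  xs <- scale(x, center = ctr, scale = sds)
  ymean <- mean(y)
  yc <- y - ymean
  tss <- sum(yc^2)

  fit <- pls1_core(xs, yc, n_components)
  vip <- vip_from_fit(fit$W, fit$ss)
  names(vip) <- colnames(x)
  structure(list(genes = colnames(x), weights = fit$W, loadings = fit$P,
                 scores = fit$scores, y_loadings = fit$q, ss = fit$ss,
                 r2_cum = cumsum(fit$ss) / tss, vip = vip,
                 center = ctr, scale = sds, y_mean = ymean, tss = tss,
                 positive = positive, levels = levels(lab),
                 n_components = length(fit$q)),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d genes, %d component(s); R2_cum = %s\n",
              length(x$genes), x$n_components,
              paste(sprintf("%.3f", x$r2_cum), collapse = ", ")))
  invisible(x)
}

#' Predict continuous class scores from a fitted PLS-DA model
#'
#' @param object A `plsda_model`.
#' @param newdata An [expression_matrix()] or a samples x genes matrix
#'   containing the model's genes.
#' @param n_components Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return Numeric vector of predicted scores on the 0/1 class-indicator
#'   scale (larger means more like the positive class).
#' @export
predict.plsda_model <- function(object, newdata, n_components = NULL, ...) {
  a <- n_components %||% object$n_components
  if (a < 1L || a > object$n_components) field_stop("n_components", "out of range")
  x <- if (inherits(newdata, "expr_matrix")) t(expr_values(newdata)) else as.matrix(newdata)
  miss <- setdiff(object$genes, colnames(x))
  if (length(miss)) field_stop("newdata", sprintf("missing gene '%s'", miss[1L]))
  xs <- scale(x[, object$genes, drop = FALSE], object$center, object$scale)
  Wa <- object$weights[, seq_len(a), drop = FALSE]
  Pa <- object$loadings[, seq_len(a), drop = FALSE]
  Wstar <- Wa %*% solve(crossprod(Pa, Wa))
  drop(object$y_mean + xs %*% Wstar %*% object$y_loadings[seq_len(a)])
}

#' Per-gene VIP scores of a fitted PLS-DA model
#'
#' Variable importance in projection:
#' `vip_j = sqrt( p * sum_a SS_a w_ja^2 / sum_a SS_a )` with unit-norm weight
#' vectors and `p` the gene count, so the VIP squares always average to 1.
#'
#' @param model A fitted `plsda_model`.
#' @return Named numeric vector of non-negative VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  model$vip
}

#' Cross-validated R2/Q2 of the PLS-DA model
#'
#' R2 per component count comes from the full fit; Q2 from out-of-fold
#' predictions, `Q2_a = 1 - PRESS_a / TSS`. Folds are stratified by class
#' where fold count allows (leave-one-out, the default given the small
#' matched cohorts, cannot stratify but every training fold retains both
#' classes). The recommended component count maximizes Q2.
#'
#' @inheritParams fit_plsda
#' @param folds Number of folds; `NULL` (default) means leave-one-out.
#' @return Data.frame with one row per component count: `n_components`,
#'   `r2_cum`, `q2_cum`; the Q2-maximizing count is attached as attribute
#'   `recommended`.
#' @export
cross_validate_plsda <- function(m, labels, n_components = 2, folds = NULL,
                                 positive = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- expr_values(m)
  n <- ncol(v)
  lab <- factor(labels)
  if (nlevels(lab) != 2L) field_stop("labels", "need exactly two classes")
  folds <- folds %||% n
  if (folds > n) field_stop("folds", "cannot exceed the sample count")
  if (folds < 2L) field_stop("folds", "need at least 2 folds")
  if (is.null(positive)) {
    positive <- if ("stricture" %in% levels(lab)) "stricture" else levels(lab)[2L]
  }
  y <- as.numeric(lab == positive)

  ## deterministic stratified assignment: round-robin within class
  fold_id <- integer(n)
  for (cl in levels(lab)) {
    idx <- which(lab == cl)
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  if (folds < n) {
    tab <- table(fold_id, lab)
    if (any(tab == 0) && min(table(lab)) >= folds) {
      stop("internal: stratified folding failed", call. = FALSE)  # nocov
    }
  }

  full <- fit_plsda(m, lab, n_components, positive = positive)
  A <- full$n_components
  press <- numeric(A)
  tss <- sum((y - mean(y))^2)
  for (f in seq_len(folds)) {
    test <- which(fold_id == f)
    train <- setdiff(seq_len(n), test)
    if (length(unique(lab[train])) < 2L) {
      stop("a training fold lost a class; reduce the fold count", call. = FALSE)
    }
    mtr <- expression_matrix(v[, train, drop = FALSE], expr_scale(m))
    fit <- suppressWarnings(fit_plsda(mtr, lab[train],
                                      n_components = n_components,
                                      positive = positive))
    for (a in seq_len(A)) {
      a_use <- min(a, fit$n_components)
      pred <- predict(fit, t(v[, test, drop = FALSE]), n_components = a_use)
      press[a] <- press[a] + sum((y[test] - pred)^2)
    }
  }
  out <- data.frame(n_components = seq_len(A),
                    r2_cum = full$r2_cum,
                    q2_cum = 1 - press / tss)
  attr(out, "recommended") <- out$n_components[which.max(out$q2_cum)]
  out
}

#' Select genes by VIP threshold
#'
#' Genes whose VIP score strictly exceeds the threshold, sorted by descending
#' VIP. The study convention is VIP > 1: genes contributing more than an
#' average share to the class separation.
#'
#' @param model A fitted `plsda_model`.
#' @param threshold VIP cutoff (default 1.0, strict inequality).
#' @return List of class `selection_result`: `genes` (data.frame `gene`,
#'   `vip`) and `threshold`.
#' @export
select_genes <- function(model, threshold = 1.0) {
  stopifnot(inherits(model, "plsda_model"))
  vip <- sort(model$vip[model$vip > threshold], decreasing = TRUE)
  structure(list(genes = data.frame(gene = names(vip), vip = unname(vip),
                                    row.names = NULL, stringsAsFactors = FALSE),
                 threshold = threshold),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d gene(s) with VIP > %g\n",
              nrow(x$genes), x$threshold))
  invisible(x)
}
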