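# Small in-code fixtures shared across the suite.

# A reduced matched cohort: fast to generate, same structure as the default.
small_design <- function(seed = 1, ...) {
  cohort_design(n_patients = 6, n_genes = 200, n_deg_up = 10, n_deg_down = 4,
                block_size = 20, seed = seed, ...)
}

# Tiny expression matrix with named genes/samples from a plain numeric matrix.
toy_expr <- function(values, scale = "log2", genes = NULL, samples = NULL) {
  values <- as.matrix(values)
  rownames(values) <- genes %||% sprintf("g%02d", seq_len(nrow(values)))
  colnames(values) <- samples %||% sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values, scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force BH step-up: adjusted p_i = min over j with p_j >= p_i of
# min(1, m * p_j / rank_j), computed by direct enumeration.
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ranked[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Brute-force AUC: enumerate every (positive, negative) pair.
auc_brute_force <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (sp in pos) for (sn in neg) {
    total <- total + (sp > sn) + 0.5 * (sp == sn)
  }
  total / (length(pos) * length(neg))
}

# Independently coded one-component PLS1 regression on an autoscaled matrix:
# weight proportional to X'y, score t = Xw, prediction ybar + q * t.
pls1_oracle_predict <- function(x, y) {
  xs <- scale(x)
  yc <- y - mean(y)
  w <- drop(crossprod(xs, yc))
  w <- w / sqrt(sum(w^2))
  tvec <- drop(xs %*% w)
  q <- sum(yc * tvec) / sum(tvec^2)
  mean(y) + q * tvec
}
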