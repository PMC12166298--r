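#' Validated configuration for the end-to-end pipeline
#'
#' Collects paths (or in-memory objects) and every stage parameter, checking
#' ranges up front so a malformed configuration fails before any stage runs.
#'
#' @param expression A TPM-scale [expression_matrix()] or path to its TSV.
#' @param metadata A metadata data.frame or path to its TSV.
#' @param out_dir Output directory (created if missing).
#' @param alpha DEG significance level in (0, 1) (default 0.05).
#' @param fc_threshold DEG fold-change gate > 1 (default 2).
#' @param variance_quantile Low-variance filter quantile in `[0, 1)`
#'   (default 0.10).
#' @param vip_threshold VIP selection cutoff >= 0 (default 1.0).
#' @param n_components PLS-DA components (default 2).
#' @param rf_trees,rf_scheme Random-forest size and scoring scheme.
#' @param panel_size Genes in the combined panel (default 8, the signature
#'   size).
#' @param power_grid,power_reps,power_genes Power-curve grid, Monte-Carlo
#'   replicates, and how many top panel genes to run curves for.
#' @param qpcr_calibrator Calibrator site for any qPCR stage run separately.
#' @param seed Master seed; each stage derives its own stream.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, metadata, out_dir,
                            alpha = 0.05, fc_threshold = 2,
                            variance_quantile = 0.10, vip_threshold = 1.0,
                            n_components = 2, rf_trees = 500,
                            rf_scheme = "cv", panel_size = 8,
                            power_grid = c(5, 10, 15, 20, 50, 100),
                            power_reps = 200, power_genes = 3,
                            qpcr_calibrator = "proximal", seed = 1L) {
  if (alpha <= 0 || alpha >= 1) field_stop("alpha", "must lie in (0, 1)")
  if (fc_threshold <= 1) field_stop("fc_threshold", "must exceed 1")
  if (variance_quantile < 0 || variance_quantile >= 1) {
    field_stop("variance_quantile", "must lie in [0, 1)")
  }
  if (vip_threshold < 0) field_stop("vip_threshold", "must be non-negative")
  if (!rf_scheme %in% c("cv", "oob", "resub")) {
    field_stop("rf_scheme", "must be one of cv, oob, resub")
  }
  if (any(diff(power_grid) <= 0) || any(power_grid < 2)) {
    field_stop("power_grid", "must be strictly increasing group sizes >= 2")
  }
  if (power_reps < 100) field_stop("power_reps", "need at least 100 replicates")
  structure(list(expression = expression, metadata = metadata,
                 out_dir = out_dir, alpha = alpha,
                 fc_threshold = fc_threshold,
                 variance_quantile = variance_quantile,
                 vip_threshold = vip_threshold, n_components = n_components,
                 rf_trees = rf_trees, rf_scheme = rf_scheme,
                 panel_size = panel_size, power_grid = power_grid,
                 power_reps = power_reps, power_genes = power_genes,
                 qpcr_calibrator = qpcr_calibrator, seed = seed),
            class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
    }),
    warning = function(w) {
      message(sprintf("[%s] warning: %s", stage, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
}

#' Run the full stricture-signature pipeline
#'
#' Chains the analysis stages in study order: log-transform and filter the
#' TPM matrix; moderated-t differential expression for the three pairwise
#' site contrasts; sign-consistent overlap of the two stricture contrasts;
#' PLS-DA with VIP selection and cross-validated R2/Q2; random-forest AUC of
#' the combined top-VIP panel and of each panel gene individually; and
#' simulated power curves for the leading panel genes at their estimated
#' Cohen's d. All stage outputs (TSV tables, JSON summaries) plus a run
#' manifest are written under `config$out_dir`; any stage failure halts with
#' a stage-tagged error.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (also written as `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  checksums <- list()

  m <- with_stage("load", {
    if (is.character(config$expression)) {
      checksums$expression <- unname(tools::md5sum(config$expression))
      read_expression_tsv(config$expression, scale = "tpm")
    } else config$expression
  })
  meta <- with_stage("load", {
    if (is.character(config$metadata)) {
      checksums$metadata <- unname(tools::md5sum(config$metadata))
      read_sample_metadata_tsv(config$metadata)
    } else config$metadata
  })
  meta <- with_stage("load", check_meta(m, meta))

  filt <- with_stage("preprocess", {
    f <- filter_genes(log_transform(m), config$variance_quantile)
    write_expression_tsv(f$matrix, out("expression_filtered.tsv"))
    f
  })
  mlog <- filt$matrix

  contrasts <- list(contrast_spec("stricture", "proximal"),
                    contrast_spec("stricture", "distal"),
                    contrast_spec("proximal", "distal"))
  deg <- with_stage("deg", {
    lapply(contrasts, function(ct) {
      res <- moderated_t(mlog, meta, ct, alpha = config$alpha,
                         fc_threshold = config$fc_threshold)
      write.table(res, out(paste0("deg_", ct$name, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      res
    })
  })

  overlap <- with_stage("overlap", {
    ov <- overlap_deg(deg[[1L]], deg[[2L]])
    write.table(ov$genes, out("overlap_degs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    ov
  })

  labels <- ifelse(meta$site == "stricture", "stricture", "margin")
  plsda <- with_stage("plsda", {
    model <- fit_plsda(mlog, labels, n_components = config$n_components)
    cv <- cross_validate_plsda(mlog, labels, n_components = config$n_components)
    sel <- select_genes(model, config$vip_threshold)
    ranked <- data.frame(gene = names(model$vip), vip = unname(model$vip),
                         selected = model$vip > config$vip_threshold)
    ranked <- ranked[order(-ranked$vip), ]
    write.table(ranked, out("vip_ranked.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(list(r2_cum = cv$r2_cum, q2_cum = cv$q2_cum,
                              recommended = attr(cv, "recommended")),
                         out("plsda_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    list(model = model, cv = cv, selection = sel)
  })

  panel <- head(plsda$selection$genes$gene, config$panel_size)
  rf <- with_stage("classify", {
    if (length(panel) < 1L) stop("VIP selection is empty; no panel to score")
    combined <- rf_panel_auc(mlog, labels, panel, n_trees = config$rf_trees,
                             scheme = config$rf_scheme,
                             seed = stream_seed(config$seed, "classify"),
                             panel_name = "combined")
    singles <- lapply(panel, function(g) {
      rf_panel_auc(mlog, labels, g, n_trees = config$rf_trees,
                   scheme = config$rf_scheme,
                   seed = stream_seed(config$seed, paste0("classify-", g)),
                   panel_name = g)
    })
    summ <- list(combined = combined[c("auc", "ci_low", "ci_high", "scheme")],
                 individual = lapply(singles, function(s)
                   s[c("panel_name", "auc", "ci_low", "ci_high")]))
    jsonlite::write_json(summ, out("panel_auc.json"), auto_unbox = TRUE,
                         digits = NA)
    write.table(data.frame(sample_id = names(combined$scores),
                           score = unname(combined$scores)),
                out("panel_scores.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(combined = combined, singles = singles)
  })

  power <- with_stage("power", {
    genes_pw <- head(panel, config$power_genes)
    stric <- meta$sample_id[meta$site == "stricture"]
    marg <- meta$sample_id[meta$site != "stricture"]
    vlog <- expr_values(mlog)
    model <- fit_lognormal(
      expression_matrix(expr_values(m)[rownames(vlog), marg, drop = FALSE], "tpm"),
      genes = panel)
    curves <- lapply(genes_pw, function(g) {
      d_hat <- cohens_d(vlog[g, stric], vlog[g, marg])
      power_curve(model, effect_spec(g, d_hat),
                  n_grid = config$power_grid, n_reps = config$power_reps,
                  alpha = config$alpha,
                  seed = stream_seed(config$seed, paste0("power-", g)))
    })
    tab <- do.call(rbind, lapply(curves, function(cv)
      cbind(gene = cv$target, d = cv$d, cv$curve)))
    write.table(tab, out("power_curves.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    curves
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("fibrosign")),
    seed = config$seed,
    stage_seeds = list(classify = stream_seed(config$seed, "classify"),
                       power = vapply(power, function(cv) cv$seed, numeric(1))),
    parameters = config[setdiff(names(config), c("expression", "metadata"))],
    input_checksums = checksums,
    filter_report = filt$report[c("n_input_genes", "n_removed_low_count",
                                  "n_removed_low_variance")],
    n_deg = vapply(deg, function(d) sum(d$is_deg), numeric(1)),
    n_overlap = nrow(overlap$genes),
    n_selected = nrow(plsda$selection$genes),
    panel = panel,
    combined_auc = rf$combined$auc,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
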