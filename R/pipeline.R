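#' Pipeline configuration
#'
#' Collects every tunable threshold of the predictor-extraction pipeline.
#' Differential-screening cutoffs follow the conventional values for
#' two-class log2 microarray studies (|log2 FC| >= 1 at FDR <= 0.01 for
#' expression and miRNA; raw p <= 0.01 with |mean beta difference| >= 0.35
#' for methylation). The feature-gene degree cut is data-density dependent
#' and therefore has no default: `NULL` keeps every diff-gene as a feature
#' gene; alternatively give `feature_degree_cut` (strict) or
#' `feature_top_k`.
#'
#' @param logfc_cut,fdr_cut expression (and miRNA) selection thresholds.
#' @param meth_p_cut,diffmean_cut methylation selection thresholds.
#' @param target_degree_cut strict differential-miRNA indegree cut for
#'   target genes (default 2).
#' @param feature_degree_cut,feature_top_k feature-gene degree filter (at
#'   most one; both `NULL` keeps all diff-genes).
#' @param causality a [causality_config()].
#' @param epsilon stepwise-selection tolerance (default 0.005).
#' @param n_trees,k_folds,n_repeats random-forest CV settings.
#' @param max_iterations stepwise outer-loop cap.
#' @param removal_semantics `"prose"` or `"pseudocode"` (see
#'   [stepwise_select()]).
#' @param include_isolated treat feature genes without causal edges as
#'   isolated (hence independent) nodes.
#' @param seed base seed for every stochastic step.
#' @export
pipeline_config <- function(logfc_cut = 1, fdr_cut = 0.01,
                            meth_p_cut = 0.01, diffmean_cut = 0.35,
                            target_degree_cut = 2L,
                            feature_degree_cut = NULL, feature_top_k = NULL,
                            causality = causality_config(),
                            epsilon = 0.005, n_trees = 500L, k_folds = 5L,
                            n_repeats = 10L, max_iterations = 50L,
                            removal_semantics = c("prose", "pseudocode"),
                            include_isolated = TRUE, seed = 1L) {
  stopifnot(fdr_cut > 0, fdr_cut < 1, meth_p_cut > 0, meth_p_cut < 1,
            epsilon >= 0, n_trees >= 1L, k_folds >= 2L, n_repeats >= 1L,
            max_iterations >= 1L)
  if (!is.null(feature_degree_cut) && !is.null(feature_top_k))
    stop("give at most one of feature_degree_cut and feature_top_k")
  structure(list(logfc_cut = logfc_cut, fdr_cut = fdr_cut,
                 meth_p_cut = meth_p_cut, diffmean_cut = diffmean_cut,
                 target_degree_cut = as.integer(target_degree_cut),
                 feature_degree_cut = feature_degree_cut,
                 feature_top_k = feature_top_k, causality = causality,
                 epsilon = epsilon, n_trees = as.integer(n_trees),
                 k_folds = as.integer(k_folds),
                 n_repeats = as.integer(n_repeats),
                 max_iterations = as.integer(max_iterations),
                 removal_semantics = match.arg(removal_semantics),
                 include_isolated = isTRUE(include_isolated),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; keys under
#' `causality:` mirror [causality_config()]. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  ca <- y$causality
  y$causality <- NULL
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(ca)) {
    badc <- setdiff(names(ca), names(formals(causality_config)))
    if (length(badc))
      stop("unknown causality key(s): ", paste(badc, collapse = ", "))
    y$causality <- do.call(causality_config, ca)
  }
  do.call(pipeline_config, y)
}

#' Extract a minimal predictor gene panel from multi-omics inputs
#'
#' The end-to-end fitting function. Stages: (1) differential screening of
#' the expression matrix (Welch t + BH FDR + log2 FC), and of the optional
#' methylation and miRNA matrices, with differential-miRNA target genes
#' taken by regulator indegree; (2) union into the diff-gene set; (3) the
#' multi-interaction network induced on diff-genes, with feature genes
#' picked by degree; (4) the Granger cascade directing every interacting
#' feature-gene pair on the time series; (5) topological screening of
#' globally independent genes (sources, isolated nodes, feedback
#' components); (6) stepwise random-forest selection of the predictor
#' panel; (7) final cross-validated metrics and ROC of the panel, plus a
#' forest trained on all samples for [predict.granger_select()].
#'
#' @param expression log2 expression matrix ([expression_matrix()]).
#' @param labels sample labels for `expression` columns.
#' @param timeseries time-series matrix ([timeseries_matrix()]) used by the
#'   causality cascade.
#' @param interactions [typed_edges()] holding the undirected gene-gene
#'   interactions (and any `mirna_target` edges).
#' @param methylation optional list(matrix, labels) of beta values.
#' @param mirna optional list(matrix, labels) of miRNA log2 expression; its
#'   differential miRNAs are mapped to target genes through the
#'   `mirna_target` edges of `interactions`.
#' @param config a [pipeline_config()].
#' @return an object of class `granger_select`; see
#'   [summary.granger_select()]. Key elements: `predictors`, `metrics`,
#'   `roc`, `auc`, `selection`, `screening`, `directing`, `diff_gene_set`.
#' @export
granger_select <- function(expression, labels, timeseries, interactions,
                           methylation = NULL, mirna = NULL,
                           config = pipeline_config()) {
  cl <- match.call()
  labels <- .align_labels(labels, colnames(expression))

  dea_expr <- dea_expression(expression, labels,
                             config$logfc_cut, config$fdr_cut)
  degs <- dea_expr$feature_id[dea_expr$selected]

  dea_meth <- NULL; dmet_genes <- character()
  if (!is.null(methylation)) {
    dea_meth <- dea_methylation(methylation$matrix, methylation$labels,
                                config$meth_p_cut, config$diffmean_cut)
    dmet_genes <- dea_meth$feature_id[dea_meth$selected]
  }

  dea_mirna <- NULL; target_genes <- character()
  if (!is.null(mirna)) {
    dea_mirna <- dea_expression(mirna$matrix, mirna$labels,
                                config$logfc_cut, config$fdr_cut)
    demirnas <- dea_mirna$feature_id[dea_mirna$selected]
    target_genes <- mirna_target_genes(demirnas, interactions,
                                       config$target_degree_cut)
  }

  dgs <- union_diff_genes(degs, dmet_genes, target_genes)
  if (length(dgs$diff_genes) == 0L)
    stop("differential screening selected no genes")

  net <- build_network(dgs$diff_genes, interactions)
  feature_genes <-
    if (!is.null(config$feature_degree_cut))
      select_by_degree(net, degree_cut = config$feature_degree_cut)
    else if (!is.null(config$feature_top_k))
      select_by_degree(net, top_k = config$feature_top_k)
    else net$nodes
  if (length(feature_genes) == 0L)
    stop("degree filter removed every feature gene")
  feature_net <- induced_subnetwork(net, feature_genes)

  directing <- direct_network(feature_net, timeseries, config$causality)
  screening <- screen_independent(directing$network,
                                  all_genes = feature_genes,
                                  include_isolated = config$include_isolated)
  candidates <- intersect(screening$independent_genes, rownames(expression))
  if (length(candidates) == 0L)
    stop("no globally independent gene is present in the expression matrix")

  cv_cfg <- cv_config(config$k_folds, config$n_trees, config$n_repeats,
                      config$seed)
  selection <- stepwise_select(candidates, expression, labels,
                               epsilon = config$epsilon, cfg = cv_cfg,
                               removal_semantics = config$removal_semantics,
                               max_iterations = config$max_iterations)
  metrics <- cv_score(selection$P, expression, labels, cv_cfg,
                      return_scores = TRUE)
  roc <- roc_auc(metrics$scores, labels)
  set.seed(config$seed)
  rf <- randomForest::randomForest(
    x = t(expression[selection$P, , drop = FALSE]), y = labels,
    ntree = config$n_trees,
    mtry = max(1L, floor(sqrt(length(selection$P)))))

  structure(list(call = cl, config = config, dea_expression = dea_expr,
                 dea_methylation = dea_meth, dea_mirna = dea_mirna,
                 diff_gene_set = dgs, network = net,
                 feature_genes = feature_genes, feature_net = feature_net,
                 directing = directing, screening = screening,
                 selection = selection, predictors = selection$P,
                 metrics = metrics, roc = roc$roc, auc = roc$auc,
                 rf_model = rf, labels = labels),
            class = "granger_select")
}

#' @export
print.granger_select <- function(x, ...) {
  cat("Granger-directed predictor selection\n")
  cat(sprintf("  predictors (%d): %s\n", length(x$predictors),
              paste(x$predictors, collapse = ", ")))
  cat(sprintf("  CV accuracy %.3f, MCC %.3f, AUC %.3f\n",
              x$metrics$acc, x$metrics$mcc, x$auc))
  invisible(x)
}

#' Summarise a fitted predictor-selection pipeline
#'
#' @param object a `granger_select` fit.
#' @param ... unused.
#' @export
summary.granger_select <- function(object, ...) {
  x <- object
  n_diff <- length(x$diff_gene_set$diff_genes)
  cat("Granger-directed predictor selection\n")
  cat(sprintf("  diff-genes: %d (DEG %d, methylation %d, miRNA-target %d)\n",
              n_diff, length(x$diff_gene_set$degs),
              length(x$diff_gene_set$dmet_genes),
              length(x$diff_gene_set$demirna_target_genes)))
  cat(sprintf("  feature genes: %d; interaction edges: %d\n",
              length(x$feature_genes), nrow(x$feature_net$edges)))
  cat(sprintf("  directed causal edges: %d (of %d pairs tested)\n",
              nrow(x$directing$network), length(x$directing$pair_results)))
  cat(sprintf("  globally independent genes: %d\n",
              length(x$screening$independent_genes)))
  cat(sprintf("  predictors (%d): %s\n", length(x$predictors),
              paste(x$predictors, collapse = ", ")))
  cat(sprintf("  CV: ACC %.3f  SN %.3f  SP %.3f  MCC %.3f  AUC %.3f\n",
              x$metrics$acc, x$metrics$sn, x$metrics$sp, x$metrics$mcc,
              x$auc))
  invisible(x)
}

#' @export
coef.granger_select <- function(object, ...) object$predictors

#' Predict class or tumour probability for new samples
#'
#' Applies the forest trained on the full discovery data (predictor genes
#' only) to a new genes-x-samples matrix, which must contain all predictor
#' genes.
#'
#' @param object a `granger_select` fit.
#' @param newdata expression matrix with genes in rows.
#' @param type `"class"` or `"prob"` (positive-class probability).
#' @param ... unused.
#' @export
predict.granger_select <- function(object, newdata,
                                   type = c("class", "prob"), ...) {
  type <- match.arg(type)
  miss <- setdiff(object$predictors, rownames(newdata))
  if (length(miss))
    stop("newdata lacks predictor gene(s): ", paste(miss, collapse = ", "))
  X <- t(newdata[object$predictors, , drop = FALSE])
  if (type == "class") predict(object$rf_model, X)
  else predict(object$rf_model, X, type = "prob")[, "TP"]
}

#' Plot the ROC curve of the selected panel
#'
#' @param x a `granger_select` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.granger_select <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("Predictor panel ROC (AUC %.3f)", x$auc),
                 ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Run the pipeline from files to an artifact directory
#'
#' Reads every input from disk, runs [granger_select()], and writes all
#' intermediates (differential tables, diff-gene list, network degrees,
#' feature-gene edges, causal network, per-type causal summary, independent
#' genes, predictor list, selection trace, metrics and ROC points) plus a
#' provenance JSON recording the configuration, seed and package version.
#' Reruns with identical inputs and config are byte-identical.
#'
#' @param config a [pipeline_config()] (or a YAML path for [read_config()]).
#' @param inputs named list of paths: `expression`, `labels`, `timeseries`,
#'   `interactions`; optional `methylation`, `methylation_labels`, `mirna`,
#'   `mirna_labels`.
#' @param out_dir artifact directory (created if needed).
#' @return the `granger_select` fit, invisibly.
#' @export
run_pipeline <- function(config, inputs, out_dir) {
  if (is.character(config)) config <- read_config(config)
  need <- c("expression", "labels", "timeseries", "interactions")
  miss <- setdiff(need, names(inputs))
  if (length(miss))
    stop("missing input path(s): ", paste(miss, collapse = ", "))
  expression <- read_expression(inputs$expression)
  labels <- read_labels(inputs$labels)
  timeseries <- read_timeseries(inputs$timeseries)
  interactions <- read_edge_list(inputs$interactions)
  methylation <- NULL
  if (!is.null(inputs$methylation))
    methylation <- list(matrix = read_expression(inputs$methylation),
                        labels = read_labels(inputs$methylation_labels))
  mirna <- NULL
  if (!is.null(inputs$mirna))
    mirna <- list(matrix = read_expression(inputs$mirna),
                  labels = read_labels(inputs$mirna_labels))

  fit <- granger_select(expression, labels, timeseries, interactions,
                        methylation = methylation, mirna = mirna,
                        config = config)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_diff_table(fit$dea_expression, p("dea_expression.tsv"))
  if (!is.null(fit$dea_methylation))
    write_diff_table(fit$dea_methylation, p("dea_methylation.tsv"))
  if (!is.null(fit$dea_mirna))
    write_diff_table(fit$dea_mirna, p("dea_mirna.tsv"))
  writeLines(c("gene", fit$diff_gene_set$diff_genes), p("diff_genes.tsv"))
  write.table(data.frame(gene = names(fit$network$degree),
                         degree = as.integer(fit$network$degree)),
              p("network_degree.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_edge_list(fit$feature_net$edges, p("feature_edges.tsv"))
  write_causal_network(fit$directing$network, p("causal_network.tsv"))
  write.table(fit$directing$type_summary, p("causal_type_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = names(fit$screening$category),
                         category = fit$screening$category,
                         independent = names(fit$screening$category) %in%
                           fit$screening$independent_genes),
              p("independent_genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(c("gene", fit$predictors), p("predictors.tsv"))
  write.table(fit$selection$trace, p("selection_trace.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(acc = fit$metrics$acc, sn = fit$metrics$sn, sp = fit$metrics$sp,
         mcc = fit$metrics$mcc, auc = fit$auc),
    p("metrics.json"), auto_unbox = TRUE, digits = NA)
  write.table(fit$roc, p("roc_points.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  prov <- list(
    package = "grangersift",
    version = as.character(utils::packageVersion("grangersift")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stages = c("dea", "union", "network", "direct", "screen", "select",
               "evaluate"),
    config = .config_as_list(config))
  jsonlite::write_json(prov, p("provenance.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(fit)
}

.config_as_list <- function(config) {
  out <- unclass(config)
  out$causality <- unclass(out$causality)
  out
}

#' Write a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(.config_as_list(config), path)
  invisible(path)
}
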