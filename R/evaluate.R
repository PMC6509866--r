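#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values (ties grouped)
#' and records (FPR, TPR) at each, from (0, 0) to (1, 1); the area under the
#' curve is computed by the trapezoid rule. Scores are positive-class
#' probabilities or votes, higher meaning more tumour-like.
#'
#' @param scores numeric vector of positive-class scores.
#' @param labels sample labels ([sample_labels()]); if `scores` is named the
#'   labels are aligned by name.
#' @return list with `roc` (data frame fpr, tpr, threshold) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (!is.null(names(scores)))
    labels <- .align_labels(labels, names(scores))
  if (length(scores) != length(labels))
    stop("scores and labels lengths differ")
  pos <- labels == "TP"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present for ROC analysis")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / n_neg, 0)
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, thr))
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1)
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1, threshold = -Inf))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  list(roc = roc, auc = auc)
}

#' Validate a predictor panel on independent datasets
#'
#' Re-evaluates a fixed predictor gene set on each dataset by stratified
#' k-fold random-forest cross-validation within that dataset (the model is
#' refit per dataset, so the panel -- not a transferred fit -- is what is
#' validated). Set `transfer` to instead train once on a reference dataset
#' and apply the frozen forest to every other one.
#'
#' @param predictors character gene set.
#' @param datasets named list; each element a list with `matrix`
#'   (expression) and `labels`.
#' @param cfg a [cv_config()].
#' @param on_missing `"error"` (default) to fail when a dataset lacks a
#'   predictor gene, or `"drop"` to evaluate on the genes present and flag
#'   the drop.
#' @param transfer optional name of the dataset to train on; remaining
#'   datasets are scored with that single model instead of per-dataset CV.
#' @return named list of validation reports: per dataset `metrics`, `roc`,
#'   `auc`, `dropped_genes`.
#' @export
cross_validate_predictors <- function(predictors, datasets,
                                      cfg = cv_config(),
                                      on_missing = c("error", "drop"),
                                      transfer = NULL) {
  on_missing <- match.arg(on_missing)
  predictors <- as.character(predictors)
  prep <- lapply(names(datasets), function(id) {
    d <- datasets[[id]]
    miss <- setdiff(predictors, rownames(d$matrix))
    if (length(miss) && on_missing == "error")
      stop(sprintf("predictor gene(s) %s absent from dataset %s",
                   paste(miss, collapse = ", "), id))
    list(id = id, genes = setdiff(predictors, miss), dropped = miss, d = d)
  })
  if (!is.null(transfer)) {
    if (!transfer %in% names(datasets)) stop("unknown transfer dataset")
    ref <- prep[[match(transfer, names(datasets))]]
    set.seed(cfg$seed)
    rf <- randomForest::randomForest(
      x = t(ref$d$matrix[ref$genes, , drop = FALSE]),
      y = .align_labels(ref$d$labels, colnames(ref$d$matrix)),
      ntree = cfg$n_trees)
  }
  out <- lapply(prep, function(p) {
    if (length(p$genes) == 0L)
      return(list(metrics = NULL, roc = NULL, auc = NA_real_,
                  dropped_genes = p$dropped, skipped = TRUE))
    labels <- .align_labels(p$d$labels, colnames(p$d$matrix))
    if (is.null(transfer) || p$id == transfer) {
      m <- cv_score(p$genes, p$d$matrix, labels, cfg, return_scores = TRUE)
      scores <- m$scores
    } else {
      genes <- intersect(rownames(ref$d$matrix), p$genes)
      pr <- predict(rf, t(p$d$matrix[genes, , drop = FALSE]), type = "prob")
      scores <- setNames(pr[, "TP"], colnames(p$d$matrix))
      pred <- factor(ifelse(scores >= 0.5, "TP", "NT"),
                     levels = c("NT", "TP"))
      m <- confusion_metrics(confusion_matrix(
        tp = sum(pred == "TP" & labels == "TP"),
        fp = sum(pred == "TP" & labels == "NT"),
        tn = sum(pred == "NT" & labels == "NT"),
        fn = sum(pred == "NT" & labels == "TP")))
    }
    r <- roc_auc(scores, labels)
    list(metrics = m, roc = r$roc, auc = r$auc,
         dropped_genes = p$dropped, skipped = FALSE)
  })
  names(out) <- names(datasets)
  out
}
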