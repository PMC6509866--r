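#' Confusion matrix constructor
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(TP = tp, FP = fp, TN = tn, FN = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion matrix counts must be non-negative integers")
  structure(as.list(counts), class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Computes the four standard indexes of a binary confusion matrix:
#' \deqn{ACC = (TP+TN)/(TP+FP+FN+TN)}
#' \deqn{SN = TP/(TP+FN)}
#' \deqn{SP = TN/(FP+TN)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(FP+TN)(TN+FN)}}
#' MCC is defined as 0 whenever a marginal factor is 0 (the usual convention
#' for degenerate margins); SN and SP are NA when their denominator is 0.
#'
#' @param cm a [confusion_matrix()].
#' @return a `metrics_report` list with `acc`, `sn`, `sp`, `mcc`.
#' @export
confusion_metrics <- function(cm) {
  tp <- as.numeric(cm$TP); fp <- as.numeric(cm$FP)
  tn <- as.numeric(cm$TN); fn <- as.numeric(cm$FN)
  total <- tp + fp + tn + fn
  if (total <= 0) stop("empty confusion matrix")
  denom2 <- (tp + fp) * (tp + fn) * (fp + tn) * (tn + fn)
  structure(list(
    acc = (tp + tn) / total,
    sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    sp = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
    mcc = if (denom2 > 0) (tp * tn - fp * fn) / sqrt(denom2) else 0,
    cm = cm), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("ACC %.3f  SN %.3f  SP %.3f  MCC %.3f%s\n", x$acc, x$sn, x$sp,
              x$mcc,
              if (!is.null(x$auc)) sprintf("  AUC %.3f", x$auc) else ""))
  invisible(x)
}

#' Cross-validation configuration for the random-forest wrapper
#'
#' @param k_folds folds of the stratified cross-validation (default 5).
#' @param n_trees trees per forest (default 500).
#' @param n_repeats repetitions of the whole CV, averaged (default 10).
#' @param seed base seed; repeat r uses seed + r so the whole evaluation is
#'   deterministic for a given gene set.
#' @export
cv_config <- function(k_folds = 5L, n_trees = 500L, n_repeats = 10L,
                      seed = 1L) {
  stopifnot(k_folds >= 2L, n_trees >= 1L, n_repeats >= 1L)
  structure(list(k_folds = as.integer(k_folds), n_trees = as.integer(n_trees),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "cv_config")
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into k folds.
.make_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  set.seed(seed)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop(sprintf(
        "class %s has %d samples, fewer than %d folds; use a smaller k",
        cl, length(idx), k))
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated random-forest score of a gene set
#'
#' Fits a random forest (ntree trees, mtry = floor(sqrt(p))) on the given
#' genes under stratified k-fold cross-validation, pools the out-of-fold
#' predictions of each repetition into one confusion matrix, computes
#' ACC/SN/SP/MCC, and averages the metrics over `n_repeats` seeded
#' repetitions. Fully deterministic for fixed inputs and config.
#'
#' @param genes character subset of `rownames(mat)`.
#' @param mat expression matrix (genes x samples).
#' @param labels sample labels aligned to `mat` columns.
#' @param cfg a [cv_config()].
#' @param return_scores also attach per-sample positive-class vote fractions
#'   (averaged over repeats) as `$scores`, for ROC analysis.
#' @return a `metrics_report` with `acc`, `sn`, `sp`, `mcc`, `auc` and the
#'   pooled confusion matrix of the first repetition.
#' @export
cv_score <- function(genes, mat, labels, cfg = cv_config(),
                     return_scores = FALSE) {
  genes <- as.character(genes)
  missing <- setdiff(genes, rownames(mat))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(head(missing, 5L), collapse = ", "))
  if (length(genes) == 0L) stop("empty gene set")
  labels <- .align_labels(labels, colnames(mat))
  if (nlevels(droplevels(labels)) < 2L)
    stop("both classes must be present")
  X <- t(mat[genes, , drop = FALSE])
  mtry <- max(1L, floor(sqrt(length(genes))))
  acc <- sn <- sp <- mcc <- numeric(cfg$n_repeats)
  votes <- matrix(0, nrow = nrow(X), ncol = cfg$n_repeats)
  cm1 <- NULL
  for (r in seq_len(cfg$n_repeats)) {
    fold <- .make_folds(labels, cfg$k_folds, seed = cfg$seed + r)
    pred <- factor(rep(NA_character_, nrow(X)), levels = levels(labels))
    for (f in seq_len(cfg$k_folds)) {
      tr <- fold != f; te <- !tr
      set.seed(cfg$seed + 1000L * r + f)
      rf <- randomForest::randomForest(
        x = X[tr, , drop = FALSE], y = labels[tr],
        ntree = cfg$n_trees, mtry = mtry)
      pr <- predict(rf, X[te, , drop = FALSE], type = "prob")
      votes[te, r] <- pr[, "TP"]
      pred[te] <- factor(ifelse(pr[, "TP"] >= 0.5, "TP", "NT"),
                         levels = levels(labels))
    }
    cm <- confusion_matrix(tp = sum(pred == "TP" & labels == "TP"),
                           fp = sum(pred == "TP" & labels == "NT"),
                           tn = sum(pred == "NT" & labels == "NT"),
                           fn = sum(pred == "NT" & labels == "TP"))
    if (r == 1L) cm1 <- cm
    m <- confusion_metrics(cm)
    acc[r] <- m$acc; sn[r] <- m$sn; sp[r] <- m$sp; mcc[r] <- m$mcc
  }
  score <- rowMeans(votes)
  names(score) <- rownames(X)
  out <- structure(list(acc = mean(acc), sn = mean(sn), sp = mean(sp),
                        mcc = mean(mcc),
                        auc = roc_auc(score, labels)$auc,
                        cm = cm1, acc_sd = sd(acc)),
                   class = "metrics_report")
  if (return_scores) out$scores <- score
  out
}

#' Rank candidate genes by single-gene classification accuracy
#'
#' Scores every gene as a lone predictor (by `score_fn`, default the
#' cross-validated random forest of [cv_score()]) and sorts by accuracy,
#' breaking ties by MCC and then by gene identifier.
#'
#' @param G character gene list.
#' @param mat,labels,cfg passed to [cv_score()] by the default scorer.
#' @param score_fn optional `function(genes) -> list(acc=, mcc=)` replacing
#'   the random-forest scorer (used for deterministic algorithm testing).
#' @return data frame with columns gene, acc, sn, sp, mcc, ordered best
#'   first.
#' @export
rank_candidates <- function(G, mat = NULL, labels = NULL, cfg = cv_config(),
                            score_fn = NULL) {
  G <- as.character(G)
  if (length(G) == 0L) stop("empty candidate list")
  if (is.null(score_fn))
    score_fn <- function(genes) cv_score(genes, mat, labels, cfg)
  reports <- lapply(G, function(g) score_fn(g))
  num <- function(field) vapply(reports, function(r) {
    v <- r[[field]]; if (is.null(v)) NA_real_ else v
  }, numeric(1L))
  out <- data.frame(gene = G, acc = num("acc"), sn = num("sn"),
                    sp = num("sp"), mcc = num("mcc"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$acc, -out$mcc, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# argmax with the package tie rule: accuracy, then MCC, then candidate order
.pick_best <- function(accs, mccs) {
  best <- 1L
  for (i in seq_along(accs)[-1L]) {
    if (accs[i] > accs[best] ||
        (accs[i] == accs[best] && mccs[i] > mccs[best]))
      best <- i
  }
  best
}

#' Stepwise character selection
#'
#' Reduces a candidate gene list to a minimal predictor set by a stepwise
#' wrapper around cross-validated random-forest accuracy:
#'
#' 1. *Initialisation*: every candidate is scored as a single predictor; the
#'    best one seeds the predictor set `P`.
#' 2. *Loop* (while `P_ACC - ACC_max > -epsilon` and candidates remain):
#'    snapshot `ACC_max <- P_ACC`; **add** the candidate whose inclusion
#'    gives the highest accuracy; then, if the tolerance condition still
#'    holds, **remove**: each member's leave-one-out accuracy is evaluated
#'    against the current `P_ACC`, and (default `"prose"` semantics) every
#'    member whose removal strictly improves accuracy is returned to the
#'    candidate pool. The `"pseudocode"` variant instead *keeps only* the
#'    members whose removal would improve accuracy (and restores `P`
#'    unchanged when that set is empty, which would otherwise discard the
#'    whole set). Accuracy is recomputed after removal.
#'
#' Scores are memoised per gene set, so the loop is deterministic; a state
#' that repeats exactly (an add immediately undone by the removal step)
#' cannot make further progress and stops the loop, as does the iteration
#' cap, in both cases returning the best-scoring predictor set seen. Ties in
#' every argmax are broken by higher MCC, then earlier candidate rank, then
#' gene identifier.
#'
#' @param G character candidate gene list (ranked internally).
#' @param mat,labels,cfg passed to [cv_score()] by the default scorer.
#' @param epsilon tolerance: accuracy may drop by at most `epsilon` per
#'   outer iteration before the loop stops (default 0.005).
#' @param removal_semantics `"prose"` (default: drop members whose removal
#'   improves accuracy) or `"pseudocode"` (keep only such members).
#' @param max_iterations outer-loop cap (default 50).
#' @param score_fn optional deterministic scorer replacing the random
#'   forest, `function(genes) -> list(acc=, mcc=)`.
#' @return list of class `stepwise_selection`: `P` (the returned predictor
#'   set), `P_ACC`, `trace` (data frame: step, action, gene, acc_before,
#'   acc_after), `ranking`, `final_state`, `stopped_by` (one of
#'   `tolerance`, `exhausted`, `cycle`, `iteration_cap`).
#' @export
stepwise_select <- function(G, mat = NULL, labels = NULL, epsilon = 0.005,
                            cfg = cv_config(),
                            removal_semantics = c("prose", "pseudocode"),
                            max_iterations = 50L, score_fn = NULL) {
  removal_semantics <- match.arg(removal_semantics)
  stopifnot(epsilon >= 0, max_iterations >= 1L)
  G <- as.character(G)
  if (length(G) == 0L) stop("empty candidate list")
  if (is.null(score_fn))
    score_fn <- function(genes) cv_score(genes, mat, labels, cfg)
  memo <- new.env(parent = emptyenv())
  score <- function(genes) {
    key <- paste(sort(genes), collapse = "\r")
    if (!is.null(memo[[key]])) return(memo[[key]])
    s <- score_fn(genes)
    if (!is.finite(s$acc)) stop("non-finite accuracy for gene set")
    val <- list(acc = s$acc, mcc = if (is.null(s$mcc)) NA_real_ else s$mcc)
    memo[[key]] <- val
    val
  }
  ranking <- rank_candidates(G, score_fn = score)
  P <- ranking$gene[1L]
  P_ACC <- ranking$acc[1L]
  C <- ranking$gene[-1L]                     # kept in rank order
  trace <- list(data.frame(step = 0L, action = "init", gene = P,
                           acc_before = NA_real_, acc_after = P_ACC,
                           stringsAsFactors = FALSE))
  best_P <- P; best_ACC <- P_ACC
  note_best <- function() {
    if (P_ACC > best_ACC ||
        (P_ACC == best_ACC && length(P) < length(best_P))) {
      best_P <<- P; best_ACC <<- P_ACC
    }
  }
  ACC_max <- -Inf
  seen <- character()
  stopped_by <- "tolerance"
  step <- 0L
  while (P_ACC - ACC_max > -epsilon && length(C) > 0L) {
    step <- step + 1L
    if (step > max_iterations) {
      warning("stepwise selection reached the iteration cap; ",
              "returning the best set seen")
      stopped_by <- "iteration_cap"
      break
    }
    key <- paste(paste(sort(P), collapse = ","),
                 paste(sort(C), collapse = ","), sep = ";")
    if (key %in% seen) { stopped_by <- "cycle"; break }
    seen <- c(seen, key)
    ACC_max <- P_ACC

    add_scores <- lapply(C, function(cand) score(c(P, cand)))
    i_add <- .pick_best(vapply(add_scores, `[[`, 0, "acc"),
                        vapply(add_scores, `[[`, 0, "mcc"))
    g_add <- C[i_add]
    acc_before <- P_ACC
    P <- c(P, g_add)
    C <- C[-i_add]
    P_ACC <- add_scores[[i_add]]$acc
    trace[[length(trace) + 1L]] <-
      data.frame(step = step, action = "add", gene = g_add,
                 acc_before = acc_before, acc_after = P_ACC,
                 stringsAsFactors = FALSE)
    note_best()

    if (P_ACC - ACC_max > -epsilon && length(P) >= 2L) {
      rem_acc <- vapply(P, function(p) score(setdiff(P, p))$acc, 0)
      improves <- rem_acc > P_ACC
      removed <- if (removal_semantics == "prose") {
        P[improves]
      } else {
        keep <- P[improves]           # literal Step 2.3 assignment
        if (length(keep) == 0L) character() else P[!improves]
      }
      if (length(removed)) {
        for (g in removed)
          trace[[length(trace) + 1L]] <-
            data.frame(step = step, action = "remove", gene = g,
                       acc_before = P_ACC,
                       acc_after = rem_acc[match(g, P)],
                       stringsAsFactors = FALSE)
        P <- setdiff(P, removed)
        C <- c(C, removed)
        P_ACC <- score(P)$acc
        note_best()
      }
    }
    if (length(C) == 0L) stopped_by <- "exhausted"
  }
  final_state <- list(P = P, P_ACC = P_ACC)
  if (stopped_by %in% c("cycle", "iteration_cap")) {
    P <- best_P; P_ACC <- best_ACC
  }
  trace <- do.call(rbind, trace)
  rownames(trace) <- NULL
  structure(list(P = P, P_ACC = P_ACC,
                 trace = trace, ranking = ranking,
                 final_state = final_state, best_P = best_P,
                 best_ACC = best_ACC, stopped_by = stopped_by,
                 epsilon = epsilon,
                 removal_semantics = removal_semantics),
            class = "stepwise_selection")
}

#' @export
print.stepwise_selection <- function(x, ...) {
  cat(sprintf("stepwise selection: %d predictor(s), ACC %.3f (stopped: %s)\n",
              length(x$P), x$P_ACC, x$stopped_by))
  cat("  P:", paste(x$P, collapse = ", "), "\n")
  invisible(x)
}
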