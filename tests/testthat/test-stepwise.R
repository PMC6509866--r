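test_that("confusion metrics reproduce the four index formulas", {
  perfect <- confusion_metrics(confusion_matrix(10, 0, 10, 0))
  expect_equal(unlist(perfect[c("acc", "sn", "sp", "mcc")]),
               c(acc = 1, sn = 1, sp = 1, mcc = 1))
  m <- confusion_metrics(confusion_matrix(3, 1, 4, 2))
  expect_equal(m$acc, 0.7)
  expect_equal(m$sn, 0.6)
  expect_equal(m$sp, 0.8)
  expect_equal(m$mcc, 10 / sqrt(4 * 5 * 5 * 6))
  degen <- confusion_metrics(confusion_matrix(0, 0, 5, 5))
  expect_equal(degen$sn, 0)
  expect_equal(degen$sp, 1)
  expect_equal(degen$mcc, 0)
  expect_error(confusion_matrix(-1, 0, 0, 1), "non-negative")
})

test_that("cross-validated RF scores separable and chance-level genes correctly", {
  cfg <- cv_config(n_trees = 100L, n_repeats = 2L, seed = 1L)
  fx <- two_class_fixture(c(strong = 10, noise = 0), n_per_class = 60L,
                          seed = 51)
  m <- cv_score("strong", fx$matrix, fx$labels, cfg)
  expect_gte(m$acc, 0.98)
  set.seed(52)
  shuffled <- fx$labels
  names(shuffled) <- sample(names(shuffled))
  shuffled <- shuffled[colnames(fx$matrix)]
  m0 <- cv_score("strong", fx$matrix, shuffled, cfg)
  expect_true(m0$acc > 0.3 && m0$acc < 0.7)
  # determinism: identical config gives an identical report
  expect_identical(cv_score("strong", fx$matrix, fx$labels, cfg),
                   cv_score("strong", fx$matrix, fx$labels, cfg))
  few <- c(1:3, 61:63)    # 3 samples per class, fewer than 5 folds
  expect_error(cv_score("strong", fx$matrix[, few], fx$labels[few],
                        cv_config(k_folds = 5)), "folds")
})

test_that("repeating the cross-validation stabilises the accuracy estimate", {
  fx <- two_class_fixture(c(g = 1.5), n_per_class = 20L, seed = 53)
  acc_of <- function(reps, seed)
    cv_score("g", fx$matrix, fx$labels,
             cv_config(n_trees = 50L, n_repeats = reps, seed = seed))$acc
  acc1 <- vapply(1:12, function(s) acc_of(1L, s * 100L), 0)
  acc10 <- vapply(1:12, function(s) acc_of(10L, s * 100L), 0)
  expect_lt(sd(acc10), sd(acc1))
})

test_that("candidate ranking orders by accuracy with deterministic ties", {
  cfg <- cv_config(n_trees = 100L, n_repeats = 1L, seed = 2L)
  fx <- two_class_fixture(c(info = 10, junk = 0), n_per_class = 30L,
                          seed = 54)
  rk <- rank_candidates(c("junk", "info"), fx$matrix, fx$labels, cfg)
  expect_identical(rk$gene[1], "info")
  expect_identical(rank_candidates("info", fx$matrix, fx$labels, cfg)$gene,
                   "info")
  # equal scores fall back to lexicographic order
  sc <- table_scorer(list(b = 0.8, a = 0.8))
  rk2 <- rank_candidates(c("b", "a"), score_fn = sc)
  expect_identical(rk2$gene, c("a", "b"))
})

test_that("stepwise selection recovers jointly informative genes", {
  set.seed(55)
  n <- 60L
  samples <- sprintf("s%03d", 1:(2 * n))
  labels <- sample_labels(samples, rep(c("TP", "NT"), each = n))
  # two latent class axes, each read out by one informative gene
  ax1 <- ifelse(labels == "TP", 1.6, -1.6) + rnorm(2 * n, 0, 1)
  ax2 <- ifelse(labels == "TP", 1.6, -1.6) + rnorm(2 * n, 0, 1)
  vals <- rbind(inf1 = ax1, inf2 = ax2,
                matrix(rnorm(8 * 2 * n), 8, 2 * n,
                       dimnames = list(sprintf("n%02d", 1:8), NULL)))
  mat <- expression_matrix(vals, sample_ids = samples)
  cfg <- cv_config(n_trees = 100L, n_repeats = 2L, seed = 3L)
  sel <- stepwise_select(rownames(mat), mat, labels, epsilon = 0.01,
                         cfg = cfg)
  expect_true(all(c("inf1", "inf2") %in% sel$P))
  expect_lte(sum(!sel$P %in% c("inf1", "inf2")), 1L)
  expect_gte(sel$P_ACC, cv_score(c("inf1", "inf2"), mat, labels, cfg)$acc
             - 0.03)
})

test_that("a single candidate exits immediately with itself as the panel", {
  sel <- stepwise_select("only", score_fn = table_scorer(list(only = 0.9)))
  expect_identical(sel$P, "only")
  expect_equal(sel$P_ACC, 0.9)
  expect_identical(sel$trace$action, "init")
})

test_that("with epsilon 0 a strictly worsening add stops the loop", {
  # three genes; every addition lowers accuracy
  tab <- list(a = 0.9, b = 0.8, c = 0.7,
              ab = 0.85, ac = 0.84, abc = 0.5, bc = 0.6)
  sel <- stepwise_select(c("a", "b", "c"), epsilon = 0,
                         score_fn = table_scorer(tab))
  # trace: init a, one failed add of b, loop condition false
  expect_identical(sel$trace$action, c("init", "add"))
  expect_identical(sel$final_state$P, c("a", "b"))
  expect_equal(sel$final_state$P_ACC, 0.85)
  expect_identical(sel$stopped_by, "tolerance")
})

test_that("the selection state invariants hold along the trace", {
  tab <- list(a = 0.80, b = 0.75, c = 0.70, d = 0.50,
              ab = 0.85, ac = 0.82, ad = 0.78,
              abc = 0.90, abd = 0.84, bc = 0.91, bcd = 0.88,
              bd = 0.6, cd = 0.6, abcd = 0.8, acd = 0.7)
  sel <- stepwise_select(c("a", "b", "c", "d"), epsilon = 0.005,
                         score_fn = table_scorer(tab))
  # no duplicates, P bounded by G
  expect_identical(anyDuplicated(sel$P), 0L)
  expect_lte(length(sel$P), 4L)
  # trace reconstructs P exactly
  p <- character()
  for (i in seq_len(nrow(sel$trace))) {
    row <- sel$trace[i, ]
    if (row$action %in% c("init", "add")) p <- c(p, row$gene)
    if (row$action == "remove") p <- setdiff(p, row$gene)
  }
  expect_identical(p, sel$final_state$P)
})

test_that("removal semantics differ exactly as documented", {
  tab <- list(a = 0.80, b = 0.75, c = 0.70, d = 0.50,
              ab = 0.85, ac = 0.82, ad = 0.78,
              abc = 0.90, abd = 0.84, bc = 0.91, bcd = 0.88,
              bd = 0.6, cd = 0.6, abcd = 0.8, acd = 0.7)
  prose <- stepwise_select(c("a", "b", "c", "d"), epsilon = 0.005,
                           score_fn = table_scorer(tab),
                           removal_semantics = "prose")
  pseudo <- stepwise_select(c("a", "b", "c", "d"), epsilon = 0.005,
                            score_fn = table_scorer(tab),
                            removal_semantics = "pseudocode")
  # prose drops the member whose removal improves accuracy (a), keeps b,c
  expect_true("a" %in% prose$trace$gene[prose$trace$action == "remove"])
  expect_true(all(c("b", "c") %in% prose$P))
  # the literal pseudocode assignment instead keeps only the improver
  expect_identical(sort(pseudo$final_state$P), "a")
})
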