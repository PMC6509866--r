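# Independent oracles and fixture builders shared across the test files.
# Each oracle is a deliberately naive implementation (closed form, brute
# force or enumeration) kept separate from the code paths it checks.

# Benjamini-Hochberg by hand: p(i) * m / i, then cumulative min from the
# largest rank down.
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Eqs of the four confusion-matrix indexes, written out directly.
metrics_by_hand <- function(tp, fp, tn, fn) {
  denom2 <- (tp + fp) * (tp + fn) * (fp + tn) * (tn + fn)
  list(acc = (tp + tn) / (tp + fp + fn + tn),
       sn = tp / (tp + fn),
       sp = tn / (fp + tn),
       mcc = if (denom2 > 0) (tp * tn - fp * fn) / sqrt(denom2) else 0)
}

# AUC as the tie-corrected Mann-Whitney U statistic: mean pairwise win
# probability of positive over negative scores, ties counting 1/2.
auc_by_hand <- function(scores, pos) {
  s1 <- scores[pos]; s0 <- scores[!pos]
  total <- 0
  for (a in s1) total <- total + sum(a > s0) + 0.5 * sum(a == s0)
  total / (length(s1) * length(s0))
}

# Brute-force strongly connected components by boolean reachability
# closure (Floyd-Warshall); feedback components are classes of mutually
# reachable vertices of size >= 2, or self-reaching singletons.
feedback_by_hand <- function(edges, nodes) {
  n <- length(nodes)
  R <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) R[cbind(edges$source, edges$target)] <- TRUE
  for (k in seq_len(n))
    for (i in seq_len(n))
      if (R[i, k]) R[i, ] <- R[i, ] | R[k, ]
  comps <- list()
  assigned <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (assigned[i]) next
    mutual <- which((R[i, ] & R[, i]) | seq_len(n) == i)
    if (length(mutual) >= 2L || R[i, i]) {
      comps[[length(comps) + 1L]] <- sort(nodes[mutual])
      assigned[mutual] <- TRUE
    }
  }
  comps[order(vapply(comps, `[`, "", 1L))]
}

# Literal independence rule: indegree 0, or on a directed cycle (reaches
# itself through at least one edge).
independent_by_hand <- function(edges, nodes) {
  n <- length(nodes)
  R <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) R[cbind(edges$source, edges$target)] <- TRUE
  for (k in seq_len(n))
    for (i in seq_len(n))
      if (R[i, k]) R[i, ] <- R[i, ] | R[k, ]
  indeg0 <- !(nodes %in% edges$target)
  on_cycle <- diag(R)
  sort(nodes[indeg0 | on_cycle])
}

# Minimal causal-network table around a source->target arc list, with
# placeholder diagnostics (screening only reads source/target).
arcs_as_network <- function(source, target) {
  n <- length(source)
  causal_network(data.frame(
    source = source, target = target,
    interaction_type = rep("physical", n), pearson_r = rep(0.9, n),
    pearson_p = rep(1e-4, n), cointegration_p = rep(NA_real_, n),
    granger_p_forward = rep(0.01, n), granger_p_reverse = rep(0.5, n),
    lag_used = rep(1L, n), stringsAsFactors = FALSE))
}

# Random digraph on `n` nodes with edge probability `p`.
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  grid <- expand.grid(source = nodes, target = nodes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, ]
  grid <- grid[runif(nrow(grid)) < p, ]
  list(nodes = nodes, edges = grid,
       net = arcs_as_network(grid$source, grid$target))
}

# Deterministic memoised scorer over an explicit subset -> accuracy table;
# errors on an unlisted subset so tests see exactly which sets are queried.
table_scorer <- function(tab) {
  function(genes) {
    key <- paste(sort(genes), collapse = "")
    if (is.null(tab[[key]])) stop("unscored gene set: ", key)
    list(acc = tab[[key]], mcc = 0)
  }
}

# Small two-class expression fixture: `shifts` gives the tumour-class mean
# shift per gene (in units of the noise sd).
two_class_fixture <- function(shifts, n_per_class = 30L, sd = 1, seed = 42L) {
  set.seed(seed)
  genes <- names(shifts)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_along(shifts))
  n <- 2L * n_per_class
  samples <- sprintf("s%03d", seq_len(n))
  labels <- sample_labels(samples, rep(c("TP", "NT"), each = n_per_class))
  vals <- matrix(rnorm(length(shifts) * n, 0, sd), length(shifts), n)
  vals[, labels == "TP"] <- vals[, labels == "TP"] + shifts
  list(matrix = expression_matrix(vals, genes, samples), labels = labels)
}
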