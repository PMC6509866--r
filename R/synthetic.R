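#' Specification of a synthetic two-class multi-omics study
#'
#' Defines the generative conditions shared by all fixture generators: a
#' gene universe, a two-class expression study with planted discriminative
#' genes, a VAR(1) time course with planted directed couplings whose sources
#' are those same genes, and a random typed interaction network guaranteed
#' to contain the planted pairs. Defaults describe a compact study -- 40
#' genes, 60 tumour and 60 normal samples, 150 time points, three planted
#' genes separated by 3 noise-sd between classes -- suitable for end-to-end
#' recovery experiments on a single CPU.
#'
#' @param n_genes gene universe size (identifiers `G01`, `G02`, ...).
#' @param n_tumor,n_normal samples per class.
#' @param n_timepoints length of the simulated time course.
#' @param n_planted number of planted discriminative genes (the first
#'   `n_planted` gene identifiers), which also act as causal sources.
#' @param effect_size tumour-class shift of planted genes, in log2 units
#'   (noise sd is 1, so this is also the separation in sd units).
#' @param noise_sd residual sd of expression values.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline log2
#'   expression.
#' @param causal_coef VAR(1) cross-coupling coefficient of planted directed
#'   edges.
#' @param self_coef VAR(1) autoregressive coefficient shared by all genes.
#' @param targets_per_source planted targets per causal source gene.
#' @param innovation_sd sd of the VAR innovations.
#' @param burn_in discarded initial VAR steps.
#' @param edge_density probability that a random unordered gene pair is
#'   linked in the interaction network.
#' @param seed base seed; all generators are pure functions of the spec.
#' @return a list of class `synthetic_spec`, including `planted_genes` and
#'   `planted_causal_edges` (data frame source/target/coef).
#' @export
synthetic_spec <- function(n_genes = 40L, n_tumor = 60L, n_normal = 60L,
                           n_timepoints = 150L, n_planted = 3L,
                           effect_size = 3, noise_sd = 1,
                           baseline_mean = 7, baseline_sd = 1,
                           causal_coef = 0.8, self_coef = 0.5,
                           targets_per_source = 2L, innovation_sd = 1,
                           burn_in = 50L, edge_density = 0.10, seed = 1L) {
  stopifnot(n_genes >= 2L, n_planted >= 0L, n_planted <= n_genes,
            n_timepoints >= 8L, edge_density > 0, edge_density <= 1)
  genes <- sprintf("G%02d", seq_len(n_genes))
  planted <- genes[seq_len(n_planted)]
  free <- setdiff(genes, planted)
  edges <- NULL
  if (n_planted > 0L && targets_per_source > 0L) {
    need <- n_planted * targets_per_source
    if (need > length(free))
      stop("not enough non-planted genes for the requested causal targets")
    tgt <- free[seq_len(need)]
    edges <- data.frame(
      source = rep(planted, each = targets_per_source),
      target = tgt, coef = causal_coef, stringsAsFactors = FALSE)
  }
  spec <- list(n_genes = as.integer(n_genes), n_tumor = as.integer(n_tumor),
               n_normal = as.integer(n_normal),
               n_timepoints = as.integer(n_timepoints),
               genes = genes, planted_genes = planted,
               planted_causal_edges = edges,
               effect_size = effect_size, noise_sd = noise_sd,
               baseline_mean = baseline_mean, baseline_sd = baseline_sd,
               causal_coef = causal_coef, self_coef = self_coef,
               innovation_sd = innovation_sd, burn_in = as.integer(burn_in),
               edge_density = edge_density, seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  spec
}

#' Simulate a two-class expression matrix with planted discriminative genes
#'
#' Gaussian class-conditional model: each gene has a baseline drawn once
#' from N(baseline_mean, baseline_sd); samples add N(0, noise_sd) noise; the
#' planted genes are shifted by `effect_size` in the tumour class.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `matrix` ([expression_matrix()]), `labels` and `truth`
#'   (planted gene identifiers).
#' @export
simulate_expression <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_tumor + spec$n_normal
  samples <- sprintf("S%03d", seq_len(n))
  labels <- sample_labels(samples, rep(c("TP", "NT"),
                                       c(spec$n_tumor, spec$n_normal)))
  base <- rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)
  vals <- base + matrix(rnorm(spec$n_genes * n, 0, spec$noise_sd),
                        spec$n_genes, n)
  planted <- match(spec$planted_genes, spec$genes)
  if (length(planted))
    vals[planted, labels == "TP"] <-
      vals[planted, labels == "TP"] + spec$effect_size
  list(matrix = expression_matrix(vals, spec$genes, samples),
       labels = labels,
       truth = list(planted_discriminative = spec$planted_genes))
}

# coupling matrix of the VAR(1): x_t = A x_{t-1} + eps_t
.var_coupling <- function(spec) {
  A <- diag(spec$self_coef, spec$n_genes)
  dimnames(A) <- list(spec$genes, spec$genes)
  ed <- spec$planted_causal_edges
  if (!is.null(ed) && nrow(ed))
    A[cbind(ed$target, ed$source)] <- ed$coef
  A
}

#' Simulate a VAR(1) time course with planted directed couplings
#'
#' Generates `x_t = A x_{t-1} + eps_t` where `A` has the spec's
#' autoregressive diagonal and one off-diagonal entry per planted directed
#' edge (target row, source column). The burn-in is discarded; an unstable
#' coupling matrix (spectral radius >= 1) is an error.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `matrix` ([timeseries_matrix()], time points 0, 1, ...
#'   hours) and `truth` (the planted directed edge data frame).
#' @export
simulate_var_timeseries <- function(spec) {
  A <- .var_coupling(spec)
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf("unstable VAR coupling matrix (spectral radius %.3f)", rho))
  set.seed(spec$seed + 1L)
  total <- spec$burn_in + spec$n_timepoints
  x <- rnorm(spec$n_genes, 0, spec$innovation_sd)
  out <- matrix(0, spec$n_genes, spec$n_timepoints)
  for (t in seq_len(total)) {
    x <- drop(A %*% x) + rnorm(spec$n_genes, 0, spec$innovation_sd)
    if (t > spec$burn_in) out[, t - spec$burn_in] <- x
  }
  list(matrix = timeseries_matrix(out, spec$genes,
                                  time_points = seq_len(spec$n_timepoints) - 1),
       truth = list(planted_causal_edges = spec$planted_causal_edges))
}

#' Simulate a random typed interaction network
#'
#' Each unordered gene pair is linked independently with probability
#' `edge_density` and given one of the three undirected interaction types at
#' random; the unordered versions of all planted causal pairs are always
#' included, so the causality cascade can reach them.
#'
#' @param spec a [synthetic_spec()].
#' @param edge_density overrides `spec$edge_density` when given.
#' @return a [typed_edges()] data frame.
#' @export
simulate_interactions <- function(spec, edge_density = spec$edge_density) {
  set.seed(spec$seed + 2L)
  pairs <- utils::combn(spec$genes, 2L)
  keep <- runif(ncol(pairs)) < edge_density
  ed <- spec$planted_causal_edges
  if (!is.null(ed) && nrow(ed)) {
    a <- pmin(ed$source, ed$target); b <- pmax(ed$source, ed$target)
    keep <- keep | (pairs[1L, ] %in% a &
                      paste(pairs[1L, ], pairs[2L, ]) %in% paste(a, b))
  }
  ga <- pairs[1L, keep]; gb <- pairs[2L, keep]
  typed_edges(ga, gb, sample(UNDIRECTED_TYPES, length(ga), replace = TRUE))
}

#' Simulate a methylation beta-value matrix
#'
#' Per-gene baseline beta values (logistic-transformed normals) with
#' independent sample noise; the genes in `planted` gain `effect` beta in
#' the tumour class (clamped to \[0, 1\]).
#'
#' @param spec a [synthetic_spec()].
#' @param planted character genes to make differentially methylated
#'   (default none).
#' @param effect beta shift of planted genes (default 0.4).
#' @return list with `matrix`, `labels`, `truth`.
#' @export
simulate_methylation <- function(spec, planted = character(), effect = 0.4) {
  set.seed(spec$seed + 3L)
  n <- spec$n_tumor + spec$n_normal
  samples <- sprintf("S%03d", seq_len(n))
  labels <- sample_labels(samples, rep(c("TP", "NT"),
                                       c(spec$n_tumor, spec$n_normal)))
  base <- stats::plogis(rnorm(spec$n_genes, -1, 0.8))
  vals <- base + matrix(rnorm(spec$n_genes * n, 0, 0.03), spec$n_genes, n)
  idx <- match(intersect(planted, spec$genes), spec$genes)
  if (length(idx))
    vals[idx, labels == "TP"] <- vals[idx, labels == "TP"] + effect
  vals <- pmin(pmax(vals, 0), 1)
  list(matrix = expression_matrix(vals, spec$genes, samples),
       labels = labels, truth = list(planted_dmet = spec$genes[idx]))
}

#' Simulate a miRNA study: expression, labels and target edges
#'
#' Generates `n_mirna` miRNAs of which `n_diff` are differentially expressed
#' (log2 shift `effect` in tumours), plus a random miRNA-to-gene target edge
#' list in which each gene of `hub_targets` is targeted by at least
#' `hub_indegree` differential miRNAs.
#'
#' @param spec a [synthetic_spec()].
#' @param n_mirna,n_diff number of miRNAs and of differential ones.
#' @param effect log2 shift of differential miRNAs.
#' @param hub_targets character genes guaranteed a high differential
#'   indegree (default: the spec's planted genes).
#' @param hub_indegree differential-miRNA indegree given to hub targets.
#' @param target_density probability of any miRNA -> gene edge.
#' @return list with `matrix`, `labels`, `target_edges` ([typed_edges()]
#'   rows of type `mirna_target`) and `truth`.
#' @export
simulate_mirna <- function(spec, n_mirna = 20L, n_diff = 5L, effect = 2,
                           hub_targets = spec$planted_genes,
                           hub_indegree = 3L, target_density = 0.05) {
  stopifnot(n_diff <= n_mirna, hub_indegree <= n_diff)
  set.seed(spec$seed + 4L)
  mirnas <- sprintf("mir%02d", seq_len(n_mirna))
  diff_mirnas <- mirnas[seq_len(n_diff)]
  n <- spec$n_tumor + spec$n_normal
  samples <- sprintf("S%03d", seq_len(n))
  labels <- sample_labels(samples, rep(c("TP", "NT"),
                                       c(spec$n_tumor, spec$n_normal)))
  vals <- 5 + matrix(rnorm(n_mirna * n, 0, spec$noise_sd), n_mirna, n)
  vals[seq_len(n_diff), labels == "TP"] <-
    vals[seq_len(n_diff), labels == "TP"] + effect
  grid <- expand.grid(mirna = mirnas, gene = spec$genes,
                      stringsAsFactors = FALSE)
  keep <- runif(nrow(grid)) < target_density
  ga <- grid$mirna[keep]; gb <- grid$gene[keep]
  for (g in hub_targets) {
    ga <- c(ga, diff_mirnas[seq_len(hub_indegree)])
    gb <- c(gb, rep(g, hub_indegree))
  }
  list(matrix = expression_matrix(vals, mirnas, samples), labels = labels,
       target_edges = typed_edges(ga, gb, rep("mirna_target", length(ga))),
       truth = list(diff_mirnas = diff_mirnas, hub_targets = hub_targets))
}

#' Simulate the full input set of a synthetic study
#'
#' Convenience wrapper producing every pipeline input from one spec:
#' expression + labels, VAR time series, interaction edge list (with the
#' miRNA target edges appended when requested), and optionally methylation
#' and miRNA matrices. All draws derive from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param with_methylation,with_mirna include the extra omics layers
#'   (default `FALSE`; the expression + time-series core is enough for
#'   recovery experiments).
#' @return list with elements `expression`, `labels`, `timeseries`,
#'   `interactions`, `truth`, and optionally `methylation`, `mirna`.
#' @export
simulate_study <- function(spec, with_methylation = FALSE,
                           with_mirna = FALSE) {
  expr <- simulate_expression(spec)
  ts <- simulate_var_timeseries(spec)
  inter <- simulate_interactions(spec)
  out <- list(expression = expr$matrix, labels = expr$labels,
              timeseries = ts$matrix, interactions = inter,
              truth = c(expr$truth, ts$truth))
  if (with_methylation) {
    out$methylation <- simulate_methylation(spec, planted = spec$planted_genes)
    out$truth$planted_dmet <- out$methylation$truth$planted_dmet
  }
  if (with_mirna) {
    mi <- simulate_mirna(spec)
    out$mirna <- mi
    out$interactions <- typed_edges(
      c(inter$gene_a, mi$target_edges$gene_a),
      c(inter$gene_b, mi$target_edges$gene_b),
      c(inter$interaction_type, mi$target_edges$interaction_type))
    out$truth$diff_mirnas <- mi$truth$diff_mirnas
  }
  out
}
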