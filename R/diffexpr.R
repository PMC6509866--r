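#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector, clipped to 1
#' and monotone in rank. Thin validated wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("p_values must be numeric")
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1] with no NA")
  stats::p.adjust(p_values, method = "BH")
}

# Vectorised two-sided Welch t-test of tumour vs normal rows.
# Returns per-gene mean difference, t, df, p and a zero-variance flag.
.welch_rows <- function(mat, labels) {
  tp <- labels == "TP"
  nt <- !tp
  n1 <- sum(tp); n0 <- sum(nt)
  if (n1 < 2L || n0 < 2L)
    stop("need at least 2 samples per class (got ", n1, " TP / ", n0, " NT)")
  x1 <- mat[, tp, drop = FALSE]; x0 <- mat[, nt, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  diff <- m1 - m0
  zero_var <- se2 == 0
  t_stat <- ifelse(zero_var, NA_real_, diff / sqrt(se2))
  df <- ifelse(zero_var, NA_real_,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1)))
  p <- ifelse(zero_var, ifelse(diff == 0, 1, 0),
              2 * pt(-abs(t_stat), df))
  list(diff = diff, t = t_stat, df = df, p = p, zero_var = zero_var)
}

#' Differential expression analysis
#'
#' Per-gene Welch (unequal-variance) two-sided t-test of tumour versus normal
#' samples on log2-scale values, with Benjamini-Hochberg FDR adjustment.
#' The log2 fold change is the difference of class means of the already-log2
#' values. A gene is selected when `|log2_fc| >= logfc_cut` and
#' `fdr <= fdr_cut` (inclusive boundaries). Genes with zero variance in both
#' classes get p = 1 (0 if the means still differ) and are flagged.
#'
#' @param mat log2 expression matrix ([expression_matrix()]).
#' @param labels sample labels aligned to `mat` columns.
#' @param logfc_cut absolute log2-fold-change threshold (default 1).
#' @param fdr_cut FDR threshold (default 0.01).
#' @return a `diff_table` data frame: feature_id, log2_fc, t_stat, p_value,
#'   fdr, zero_variance, selected.
#' @export
dea_expression <- function(mat, labels, logfc_cut = 1, fdr_cut = 0.01) {
  labels <- .align_labels(labels, colnames(mat))
  w <- .welch_rows(mat, labels)
  fdr <- bh_adjust(w$p)
  out <- data.frame(feature_id = rownames(mat), log2_fc = unname(w$diff),
                    t_stat = unname(w$t), p_value = unname(w$p),
                    fdr = unname(fdr), zero_variance = unname(w$zero_var),
                    selected = unname(abs(w$diff) >= logfc_cut & fdr <= fdr_cut),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("diff_table", "data.frame")
  out
}

#' Differential methylation analysis
#'
#' Per-gene Welch t-test on beta values plus the mean beta difference
#' `diff_mean = mean(tumour) - mean(normal)`. A gene is selected when
#' `p_value <= p_cut` and `|diff_mean| >= diffmean_cut` (raw p, matching the
#' usual methylation screen; boundaries inclusive).
#'
#' @param mat beta-value matrix, values in \[0, 1\].
#' @param labels sample labels aligned to `mat` columns.
#' @param p_cut p-value threshold (default 0.01).
#' @param diffmean_cut absolute mean-difference threshold (default 0.35).
#' @return a `diff_table` data frame with a `diff_mean` column.
#' @export
dea_methylation <- function(mat, labels, p_cut = 0.01, diffmean_cut = 0.35) {
  if (any(mat < 0 | mat > 1))
    stop("methylation beta values must lie in [0, 1]")
  labels <- .align_labels(labels, colnames(mat))
  w <- .welch_rows(mat, labels)
  out <- data.frame(feature_id = rownames(mat), diff_mean = unname(w$diff),
                    t_stat = unname(w$t), p_value = unname(w$p),
                    fdr = unname(bh_adjust(w$p)),
                    zero_variance = unname(w$zero_var),
                    selected = unname(w$p <= p_cut &
                                        abs(w$diff) >= diffmean_cut),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("diff_table", "data.frame")
  out
}

#' Target genes of differential miRNAs by regulator degree
#'
#' Counts, for every target gene in the miRNA-target edge list, how many
#' *differential* miRNAs regulate it, and keeps targets whose count is
#' strictly greater than `degree_cut` (a gene regulated by more differential
#' miRNAs than the cut; the strict inequality mirrors the usual
#' "degree greater than k" screen).
#'
#' @param demirnas character set of differential miRNA identifiers.
#' @param target_edges `typed_edges` containing `mirna_target` rows
#'   (gene_a = miRNA, gene_b = target gene).
#' @param degree_cut integer threshold (default 2).
#' @return character vector of target gene identifiers (sorted).
#' @export
mirna_target_genes <- function(demirnas, target_edges, degree_cut = 2) {
  if (length(demirnas) == 0L) return(character())
  te <- target_edges[target_edges$interaction_type == "mirna_target", ,
                     drop = FALSE]
  te <- te[te$gene_a %in% demirnas, , drop = FALSE]
  if (nrow(te) == 0L) return(character())
  deg <- table(te$gene_b)
  sort(names(deg)[deg > degree_cut])
}

#' Union of the three differential gene sets
#'
#' Combines differentially expressed genes, differentially methylated genes
#' and differential-miRNA target genes into the diff-gene set, recording per
#' gene which sources it came from and the sizes of all intersections.
#'
#' @param degs,dmet_genes,demirna_target_genes character gene-ID sets.
#' @return a list of class `diff_gene_set` with elements `diff_genes`
#'   (sorted union), `provenance` (data frame gene / deg / dmet / mirna
#'   logical columns) and `intersections` (named counts of the 7 regions).
#' @export
union_diff_genes <- function(degs, dmet_genes, demirna_target_genes) {
  degs <- unique(as.character(degs))
  dmet_genes <- unique(as.character(dmet_genes))
  demirna_target_genes <- unique(as.character(demirna_target_genes))
  all_genes <- sort(unique(c(degs, dmet_genes, demirna_target_genes)))
  prov <- data.frame(gene = all_genes,
                     deg = all_genes %in% degs,
                     dmet = all_genes %in% dmet_genes,
                     mirna = all_genes %in% demirna_target_genes,
                     stringsAsFactors = FALSE)
  inter <- c(
    deg_only = sum(prov$deg & !prov$dmet & !prov$mirna),
    dmet_only = sum(!prov$deg & prov$dmet & !prov$mirna),
    mirna_only = sum(!prov$deg & !prov$dmet & prov$mirna),
    deg_dmet = sum(prov$deg & prov$dmet & !prov$mirna),
    deg_mirna = sum(prov$deg & !prov$dmet & prov$mirna),
    dmet_mirna = sum(!prov$deg & prov$dmet & prov$mirna),
    all_three = sum(prov$deg & prov$dmet & prov$mirna))
  structure(list(diff_genes = all_genes, provenance = prov,
                 intersections = inter,
                 degs = sort(degs), dmet_genes = sort(dmet_genes),
                 demirna_target_genes = sort(demirna_target_genes)),
            class = "diff_gene_set")
}

#' @export
print.diff_gene_set <- function(x, ...) {
  cat(sprintf(
    "diff-gene set: %d genes (%d DEG, %d methylation, %d miRNA-target)\n",
    length(x$diff_genes), length(x$degs), length(x$dmet_genes),
    length(x$demirna_target_genes)))
  invisible(x)
}

#' Write a differential analysis table as TSV
#' @param tab a `diff_table`.
#' @param path output path.
#' @export
write_diff_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
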