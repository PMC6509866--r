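#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm qnorm pt pf approx cor lm coef residuals sd
#'   quantile rnorm runif rbinom predict setNames complete.cases aggregate
#' @importFrom utils read.delim write.table head
NULL

# Recognised interaction types. The first three are undirected gene-gene
# interactions; mirna_target is a directed regulator -> target relation.
UNDIRECTED_TYPES <- c("colocation", "physical", "shared_domain")
EDGE_TYPES <- c(UNDIRECTED_TYPES, "mirna_target")

#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix with unique gene identifiers
#' as row names and unique sample identifiers as column names. Values are
#' expected on the log2 scale for expression data, or in \[0, 1\] for
#' methylation beta values. Identifiers are opaque, case-sensitive strings.
#'
#' @param values numeric matrix, genes in rows and samples in columns.
#' @param gene_ids,sample_ids optional character vectors overriding the
#'   dimnames of `values`.
#' @return the validated matrix with dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("dimnames lengths do not match matrix dimensions")
  .check_unique(gene_ids, "gene")
  .check_unique(sample_ids, "sample")
  if (!all(is.finite(values)))
    stop("expression values must all be finite (no NA/NaN/Inf)")
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

.check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicate %s identifier(s): %s", what,
                 paste(head(dup, 5L), collapse = ", ")))
  invisible(TRUE)
}

#' Construct binary sample labels
#'
#' Labels are a factor with levels `c("NT", "TP")`: `"TP"` marks the positive
#' (tumour) class and `"NT"` the negative (normal) class, named by sample
#' identifier.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param label vector coercible to the two classes; anything equal to
#'   `"TP"`/`"tumor"`/`1`/`TRUE` is positive.
#' @export
sample_labels <- function(sample_ids, label) {
  if (length(sample_ids) != length(label))
    stop("sample_ids and label lengths differ")
  .check_unique(sample_ids, "sample")
  pos <- label %in% c("TP", "tumor", "tumour", "1", 1, TRUE)
  neg <- label %in% c("NT", "normal", "0", 0, FALSE)
  if (!all(pos | neg))
    stop("unrecognised label value(s): ",
         paste(unique(label[!(pos | neg)]), collapse = ", "))
  out <- factor(ifelse(pos, "TP", "NT"), levels = c("NT", "TP"))
  names(out) <- sample_ids
  out
}

.align_labels <- function(labels, sample_ids) {
  missing <- setdiff(sample_ids, names(labels))
  if (length(missing))
    stop("sample(s) without a label: ", paste(head(missing, 5L), collapse = ", "))
  unknown <- setdiff(names(labels), sample_ids)
  if (length(unknown))
    stop("label file references unknown sample(s): ",
         paste(head(unknown, 5L), collapse = ", "))
  labels[sample_ids]
}

#' Read an expression (or methylation / miRNA) matrix from TSV
#'
#' The file must be tab-separated with a header row of sample identifiers and
#' gene identifiers in the first column; the body is numeric. When
#' `labels_path` is given, a two-column TSV (sample_id, class) is read and
#' aligned to the matrix column order; every matrix sample must be labelled
#' and every label must reference a matrix sample.
#'
#' @param path path to the matrix TSV.
#' @param labels_path optional path to a two-column label TSV.
#' @return the matrix, with the aligned labels attached as
#'   `attr(, "labels")` when requested.
#' @export
read_expression <- function(path, labels_path = NULL) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(raw) < 2L) stop("matrix TSV needs a gene-id column plus >= 1 sample")
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !(body %in% c("NA", "NaN")), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at gene '%s', sample '%s': '%s'",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]],
                 body[bad[1L, 1L], bad[1L, 2L]]))
  mat <- expression_matrix(num, gene_ids, sample_ids)
  if (!is.null(labels_path)) {
    attr(mat, "labels") <- .align_labels(read_labels(labels_path), sample_ids)
  }
  mat
}

#' Read a two-column sample label TSV
#' @param path path to a TSV with columns sample_id and class.
#' @export
read_labels <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(tab) < 2L) stop("label TSV needs columns sample_id and class")
  sample_labels(tab[[1L]], tab[[2L]])
}

# full-precision numeric formatting so write/read round-trips are exact
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1L))
  out
}

#' Write an expression matrix as TSV
#'
#' Values are written with 17 significant digits so that
#' `read_expression(write_expression(m))` reproduces `m` exactly.
#'
#' @param mat matrix from [expression_matrix()].
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  header <- paste(c("gene_id", colnames(mat)), collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], .fmt_num(mat[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write sample labels as TSV
#' @param labels factor from [sample_labels()].
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  writeLines(c("sample_id\tclass",
               paste(names(labels), as.character(labels), sep = "\t")), path)
  invisible(path)
}

#' Construct a typed edge list
#'
#' Edges of the undirected types (`colocation`, `physical`, `shared_domain`)
#' are canonicalised with the lexicographically smaller gene first, so
#' `(A,B,t)` and `(B,A,t)` are the same edge; `mirna_target` edges stay
#' directed (gene_a = miRNA regulator, gene_b = target gene). Self-edges are
#' dropped with a warning; the drop count is returned in
#' `attr(, "n_self_dropped")`. Duplicate edges collapse to one.
#'
#' @param gene_a,gene_b character vectors of endpoint identifiers.
#' @param interaction_type character vector of edge types.
#' @return a `data.frame` of class `typed_edges` with columns gene_a, gene_b,
#'   interaction_type.
#' @export
typed_edges <- function(gene_a, gene_b, interaction_type) {
  stopifnot(length(gene_a) == length(gene_b),
            length(gene_a) == length(interaction_type))
  bad <- setdiff(unique(interaction_type), EDGE_TYPES)
  if (length(bad))
    stop("unknown interaction type(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(EDGE_TYPES, collapse = ", "), ")")
  gene_a <- as.character(gene_a); gene_b <- as.character(gene_b)
  self <- gene_a == gene_b
  n_self <- sum(self)
  if (n_self) {
    warning(sprintf("dropped %d self-edge(s)", n_self))
    gene_a <- gene_a[!self]; gene_b <- gene_b[!self]
    interaction_type <- interaction_type[!self]
  }
  undirected <- interaction_type %in% UNDIRECTED_TYPES
  swap <- undirected & gene_a > gene_b
  tmp <- gene_a[swap]; gene_a[swap] <- gene_b[swap]; gene_b[swap] <- tmp
  df <- data.frame(gene_a = gene_a, gene_b = gene_b,
                   interaction_type = interaction_type,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("typed_edges", "data.frame")
  attr(df, "n_self_dropped") <- n_self
  df
}

#' Read a typed edge list from TSV
#'
#' Expects columns gene_a, gene_b, interaction_type. See [typed_edges()] for
#' canonicalisation and self-edge handling.
#'
#' @param path path to the edge TSV.
#' @export
read_edge_list <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  need <- c("gene_a", "gene_b", "interaction_type")
  if (!all(need %in% colnames(tab)))
    stop("edge TSV must have columns: ", paste(need, collapse = ", "))
  typed_edges(tab$gene_a, tab$gene_b, tab$interaction_type)
}

#' Write a typed edge list as TSV
#' @param edges a `typed_edges` data frame.
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  writeLines(c("gene_a\tgene_b\tinteraction_type",
               paste(edges$gene_a, edges$gene_b, edges$interaction_type,
                     sep = "\t")), path)
  invisible(path)
}

# column layout of a causal network table
CAUSAL_COLS <- c("source", "target", "interaction_type", "pearson_r",
                 "pearson_p", "cointegration_p", "granger_p_forward",
                 "granger_p_reverse", "lag_used")

#' Construct a directed causal network table
#'
#' One row per directed edge and interaction type, carrying the diagnostics
#' of the test cascade that produced it. `cointegration_p` is `NA` for pairs
#' that were stationary in levels and never reached the cointegration gate.
#'
#' @param df data frame with columns `source`, `target`, `interaction_type`,
#'   `pearson_r`, `pearson_p`, `cointegration_p`, `granger_p_forward`,
#'   `granger_p_reverse`, `lag_used`.
#' @export
causal_network <- function(df = NULL) {
  if (is.null(df))
    df <- data.frame(source = character(), target = character(),
                     interaction_type = character(), pearson_r = numeric(),
                     pearson_p = numeric(), cointegration_p = numeric(),
                     granger_p_forward = numeric(),
                     granger_p_reverse = numeric(), lag_used = integer(),
                     stringsAsFactors = FALSE)
  if (!all(CAUSAL_COLS %in% colnames(df)))
    stop("causal network needs columns: ", paste(CAUSAL_COLS, collapse = ", "))
  df <- df[, CAUSAL_COLS, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("causal_network", "data.frame")
  df
}

#' Write a causal network as TSV
#'
#' Numeric diagnostics are written at full precision so
#' [read_causal_network()] reproduces the network exactly.
#'
#' @param net a `causal_network` data frame.
#' @param path output path.
#' @export
write_causal_network <- function(net, path) {
  header <- paste(CAUSAL_COLS, collapse = "\t")
  if (nrow(net) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  rows <- vapply(seq_len(nrow(net)), function(i) {
    paste(c(net$source[i], net$target[i], net$interaction_type[i],
            .fmt_num(c(net$pearson_r[i], net$pearson_p[i],
                       net$cointegration_p[i], net$granger_p_forward[i],
                       net$granger_p_reverse[i])),
            sprintf("%d", net$lag_used[i])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a causal network TSV written by [write_causal_network()]
#' @param path path to the TSV.
#' @export
read_causal_network <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (!all(CAUSAL_COLS %in% colnames(tab)))
    stop("not a causal network TSV: ", path)
  if (nrow(tab) == 0L) return(causal_network())
  num <- function(col) as.numeric(ifelse(tab[[col]] == "NA", NA, tab[[col]]))
  causal_network(data.frame(
    source = tab$source, target = tab$target,
    interaction_type = tab$interaction_type,
    pearson_r = num("pearson_r"), pearson_p = num("pearson_p"),
    cointegration_p = num("cointegration_p"),
    granger_p_forward = num("granger_p_forward"),
    granger_p_reverse = num("granger_p_reverse"),
    lag_used = as.integer(tab$lag_used), stringsAsFactors = FALSE))
}

#' Construct a validated time-series expression matrix
#'
#' Rows are genes, columns are ordered time points (hours). At least 8 time
#' points are required for any causality testing downstream; time points must
#' be strictly increasing.
#'
#' @param values numeric matrix, genes x time points.
#' @param gene_ids character row identifiers.
#' @param time_points strictly increasing numeric vector (hours).
#' @export
timeseries_matrix <- function(values, gene_ids = rownames(values),
                              time_points = NULL) {
  if (is.null(time_points)) {
    time_points <- suppressWarnings(as.numeric(colnames(values)))
    if (anyNA(time_points)) time_points <- seq_len(ncol(values)) - 1
  }
  if (length(time_points) != ncol(values))
    stop("time_points length must equal the number of columns")
  if (any(diff(time_points) <= 0))
    stop("time points must be strictly increasing")
  if (ncol(values) < 8L)
    stop("at least 8 time points are required for causality testing")
  mat <- expression_matrix(values, gene_ids,
                           sample_ids = as.character(time_points))
  attr(mat, "time_points") <- time_points
  mat
}

#' Read a time-series matrix from TSV
#'
#' Same layout as [read_expression()], with the header row holding numeric
#' time points (hours).
#'
#' @param path path to the TSV.
#' @export
read_timeseries <- function(path) {
  mat <- read_expression(path)
  timeseries_matrix(mat, rownames(mat))
}
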