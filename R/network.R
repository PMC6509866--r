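#' Build the multi-interaction diff-gene network
#'
#' Induced subgraph of the typed interaction edge list on the diff-gene set.
#' Parallel edges of different interaction types between the same pair are
#' retained, and node degree counts that multiplicity (a pair linked by two
#' types contributes two to each endpoint's degree): the three interaction
#' sources are treated as accumulating evidence. Edges touching genes outside
#' the diff-gene set are dropped and counted.
#'
#' @param diff_genes character gene-ID set (network nodes; genes without any
#'   retained edge stay as degree-0 nodes).
#' @param edges `typed_edges`; only the undirected gene-gene types
#'   (`colocation`, `physical`, `shared_domain`) are used.
#' @return an object of class `multi_network`: list with `nodes`, `edges`
#'   (typed_edges restricted to node pairs), `degree` (named integer vector,
#'   multiplicity counted) and `n_dropped`.
#' @export
build_network <- function(diff_genes, edges) {
  diff_genes <- sort(unique(as.character(diff_genes)))
  ed <- edges[edges$interaction_type %in% UNDIRECTED_TYPES, , drop = FALSE]
  keep <- ed$gene_a %in% diff_genes & ed$gene_b %in% diff_genes
  n_dropped <- sum(!keep)
  ed <- ed[keep, , drop = FALSE]
  rownames(ed) <- NULL
  degree <- setNames(integer(length(diff_genes)), diff_genes)
  if (nrow(ed)) {
    cnt <- table(c(ed$gene_a, ed$gene_b))
    degree[names(cnt)] <- as.integer(cnt)
  }
  structure(list(nodes = diff_genes, edges = ed, degree = degree,
                 n_dropped = n_dropped),
            class = "multi_network")
}

#' @export
print.multi_network <- function(x, ...) {
  cat(sprintf("multi-interaction network: %d nodes, %d typed edges (%d dropped)\n",
              length(x$nodes), nrow(x$edges), x$n_dropped))
  if (nrow(x$edges))
    print(table(x$edges$interaction_type))
  invisible(x)
}

#' Select feature genes by network degree
#'
#' Keeps nodes whose degree (with type multiplicity) is strictly greater
#' than `degree_cut`, or alternatively the `top_k` nodes by degree with ties
#' at the boundary included. Exactly one of the two must be given; the
#' absolute cut is data-density dependent, so the top-k form is offered for
#' reproducibility across datasets.
#'
#' @param net a `multi_network`.
#' @param degree_cut strict lower degree bound.
#' @param top_k number of top-degree genes to keep (ties included).
#' @return character vector of feature gene identifiers (sorted).
#' @export
select_by_degree <- function(net, degree_cut = NULL, top_k = NULL) {
  if (is.null(degree_cut) == is.null(top_k))
    stop("give exactly one of degree_cut or top_k")
  deg <- net$degree
  if (!is.null(degree_cut)) {
    return(sort(names(deg)[deg > degree_cut]))
  }
  if (top_k <= 0) stop("top_k must be positive")
  if (top_k >= length(deg)) return(sort(names(deg)))
  thr <- sort(deg, decreasing = TRUE)[top_k]
  sort(names(deg)[deg >= thr])
}

#' Induced subnetwork on a gene subset
#'
#' Restricts a `multi_network` to the given genes and recomputes degrees.
#' Every requested gene must already be a node.
#'
#' @param net a `multi_network`.
#' @param genes character subset of `net$nodes`.
#' @export
induced_subnetwork <- function(net, genes) {
  genes <- unique(as.character(genes))
  unknown <- setdiff(genes, net$nodes)
  if (length(unknown))
    stop("gene(s) not in network: ", paste(head(unknown, 5L), collapse = ", "))
  build_network(genes, net$edges)
}

#' Unique unordered gene pairs of a network
#'
#' The pairs that feed the causality cascade: one entry per unordered pair
#' regardless of how many interaction types link it, with the types collapsed
#' into a comma-separated annotation.
#'
#' @param net a `multi_network`.
#' @return data frame with columns gene_a, gene_b, types.
#' @export
network_pairs <- function(net) {
  if (nrow(net$edges) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      types = character(), stringsAsFactors = FALSE))
  key <- paste(net$edges$gene_a, net$edges$gene_b, sep = "\r")
  types <- vapply(split(net$edges$interaction_type, key),
                  function(tt) paste(sort(unique(tt)), collapse = ","),
                  character(1L))
  parts <- strsplit(names(types), "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[`, "", 1L),
                    gene_b = vapply(parts, `[`, "", 2L),
                    types = unname(types), stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}
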