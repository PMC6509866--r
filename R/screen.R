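# Directed graph view of a causal network: unique source->target arcs.
.causal_arcs <- function(net) {
  if (nrow(net) == 0L)
    return(data.frame(source = character(), target = character(),
                      stringsAsFactors = FALSE))
  unique(data.frame(source = net$source, target = net$target,
                    stringsAsFactors = FALSE))
}

#' Feedback components of a directed causal network
#'
#' A feedback subnetwork is a set of genes that are mutually reachable along
#' directed edges: a strongly connected component of size >= 2, or a single
#' gene with a self-loop. Computed with igraph's strong components.
#'
#' @param net a [causal_network()] data frame (or anything with `source` and
#'   `target` columns).
#' @param nodes optional extra node identifiers to include as isolated
#'   vertices.
#' @return list of character vectors, one per feedback component (each
#'   sorted; the list ordered by first member).
#' @export
find_feedback_components <- function(net, nodes = NULL) {
  arcs <- .causal_arcs(net)
  verts <- sort(unique(c(arcs$source, arcs$target, nodes)))
  if (length(verts) == 0L) return(list())
  g <- igraph::graph_from_data_frame(arcs, directed = TRUE,
                                     vertices = verts)
  comp <- igraph::components(g, mode = "strong")
  members <- split(names(comp$membership), comp$membership)
  self_loop <- unique(arcs$source[arcs$source == arcs$target])
  keep <- vapply(members, function(m) {
    length(m) >= 2L || m %in% self_loop
  }, logical(1L))
  out <- lapply(unname(members[keep]), sort)
  out[order(vapply(out, `[`, "", 1L))]
}

#' Screen globally independent genes
#'
#' Applies the topology rule to a directed causal network: a gene is
#' globally independent when its indegree is 0 (a source of the directed
#' network, or an isolated gene with no causal edges at all) or when it lies
#' in a feedback subnetwork (a nontrivial strongly connected component or a
#' self-loop). Dependent genes -- those only receiving regulation -- are
#' excluded.
#'
#' @param net a [causal_network()].
#' @param all_genes optional character vector of the full feature-gene pool;
#'   genes absent from the network are treated as isolated nodes (set
#'   `include_isolated = FALSE` to drop them instead).
#' @param include_isolated keep degree-0 genes as independent (default
#'   `TRUE`).
#' @return list of class `screen_result`: `independent_genes` (sorted),
#'   `category` (named vector with values `source`, `isolated`, `feedback`,
#'   `dependent`), `feedback_components` and `scc_partition`.
#' @export
screen_independent <- function(net, all_genes = NULL,
                               include_isolated = TRUE) {
  arcs <- .causal_arcs(net)
  verts <- sort(unique(c(arcs$source, arcs$target, all_genes)))
  indeg <- setNames(integer(length(verts)), verts)
  if (nrow(arcs)) {
    cnt <- table(arcs$target)
    indeg[names(cnt)] <- as.integer(cnt)
  }
  outdeg <- setNames(integer(length(verts)), verts)
  if (nrow(arcs)) {
    cnt <- table(arcs$source)
    outdeg[names(cnt)] <- as.integer(cnt)
  }
  fb <- find_feedback_components(net, nodes = all_genes)
  fb_genes <- unlist(fb)
  category <- setNames(rep("dependent", length(verts)), verts)
  category[indeg == 0L & outdeg > 0L] <- "source"
  category[indeg == 0L & outdeg == 0L] <- "isolated"
  category[verts %in% fb_genes] <- "feedback"   # feedback takes precedence
  independent <- verts[category %in%
                         c("source", "feedback",
                           if (include_isolated) "isolated")]
  g <- igraph::graph_from_data_frame(
    arcs, directed = TRUE, vertices = verts)
  scc <- igraph::components(g, mode = "strong")
  structure(list(independent_genes = sort(independent), category = category,
                 feedback_components = fb,
                 scc_partition = lapply(
                   unname(split(names(scc$membership), scc$membership)),
                   sort)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("globally independent genes: %d of %d nodes\n",
              length(x$independent_genes), length(x$category)))
  print(table(x$category))
  invisible(x)
}
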