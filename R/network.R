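# Interaction-network construction and unweighted centrality: direct
# (induced) subnetworks for affected gene sets, bridge-admitting subnetworks
# for hub discovery, degree/betweenness/closeness ranking, network overlap
# and the hub-adjacency contrast test.

#' Read a protein-interaction edge list
#'
#' Two tab-separated symbol columns; `#` starts a comment. Self-loops and
#' duplicate/reversed edges are removed with a message.
#'
#' @param path Edge-list file.
#' @return Data frame with columns `from`, `to`.
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) .stopf("edge list needs two symbol columns")
  edges <- data.frame(from = as.character(df[[1]]), to = as.character(df[[2]]),
                      stringsAsFactors = FALSE)
  n0 <- nrow(edges)
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  edges <- edges[!duplicated(key), , drop = FALSE]
  if (nrow(edges) < n0)
    message(sprintf("dropped %d self-loop/duplicate edges on load", n0 - nrow(edges)))
  rownames(edges) <- NULL
  edges
}

#' Write an edge list
#' @param edges Data frame with columns `from`, `to`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  write.table(edges[, c("from", "to")], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.edges_to_graph <- function(edges) {
  igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE)
}

#' Build an interaction subnetwork for a gene set
#'
#' `direct` mode induces the subgraph on the query genes. `plus_bridges`
#' additionally admits non-query nodes adjacent to at least two query genes
#' — the route by which unmutated hub proteins that interact extensively
#' with the affected genes enter the network; bridge nodes carry a logical
#' `bridge` vertex attribute.
#'
#' @param genes A `gene_set` or character vector of query symbols.
#' @param edges Edge-list data frame (`from`, `to`) or file path.
#' @param mode `"direct"` or `"plus_bridges"`.
#' @return An undirected simple igraph with vertex attributes `query` and
#'   `bridge`.
#' @export
build_subnetwork <- function(genes, edges, mode = c("direct", "plus_bridges")) {
  mode <- match.arg(mode)
  if (inherits(genes, "gene_set")) genes <- genes$genes
  if (!length(genes)) .stopf("query gene set is empty")
  if (is.character(edges) && length(edges) == 1) edges <- read_edge_list(edges)
  g <- .edges_to_graph(edges)
  vnames <- igraph::V(g)$name
  present <- intersect(genes, vnames)
  keep <- present
  bridges <- character()
  if (mode == "plus_bridges") {
    el <- igraph::as_edgelist(g)
    qa <- el[, 1] %in% genes
    qb <- el[, 2] %in% genes
    cnt <- table(c(el[, 1][qb & !qa], el[, 2][qa & !qb]))
    bridges <- names(cnt)[cnt >= 2]
    keep <- union(present, bridges)
  }
  if (!length(keep)) {
    .warnf("query genes are disjoint from the edge list: empty subnetwork")
    sub <- igraph::make_empty_graph(0, directed = FALSE)
    return(sub)
  }
  sub <- igraph::induced_subgraph(g, keep)
  igraph::V(sub)$query <- igraph::V(sub)$name %in% genes
  igraph::V(sub)$bridge <- igraph::V(sub)$name %in% bridges
  sub
}

#' Unweighted centrality report
#'
#' Degree (incident edge count), betweenness (Brandes' algorithm on
#' unweighted shortest paths, unnormalized, path endpoints excluded) and
#' the Wasserman-Faust composite closeness
#' `((r-1)/(n-1)) * ((r-1)/sum d(v,u))` over the `r` nodes reachable from
#' `v`, which handles disconnected graphs and gives isolated nodes
#' closeness 0. Ranks (1 = most central) accompany each measure.
#'
#' @param graph An undirected simple igraph.
#' @param measures Subset of `c("degree", "betweenness", "closeness")`.
#' @return Data frame with one row per node: the requested measures plus
#'   `<measure>_rank` columns. Empty graph gives an empty report.
#' @export
centrality <- function(graph, measures = c("degree", "betweenness", "closeness")) {
  measures <- match.arg(measures, several.ok = TRUE)
  n <- igraph::vcount(graph)
  if (n == 0)
    return(data.frame(node = character(), stringsAsFactors = FALSE))
  out <- data.frame(node = igraph::V(graph)$name %||% as.character(seq_len(n)),
                    stringsAsFactors = FALSE)
  if ("degree" %in% measures)
    out$degree <- as.integer(igraph::degree(graph))
  if ("betweenness" %in% measures)
    out$betweenness <- igraph::betweenness(graph, directed = FALSE,
                                           normalized = FALSE)
  if ("closeness" %in% measures) {
    dm <- igraph::distances(graph)
    out$closeness <- vapply(seq_len(n), function(i) {
      d <- dm[i, -i]
      reach <- is.finite(d)
      r1 <- sum(reach)            # r - 1 reachable others
      if (r1 == 0 || n == 1) return(0)
      (r1 / (n - 1)) * (r1 / sum(d[reach]))
    }, numeric(1))
  }
  for (m in intersect(c("degree", "betweenness", "closeness"), names(out)))
    out[[paste0(m, "_rank")]] <- as.integer(rank(-out[[m]], ties.method = "min"))
  out
}

#' Percentage of query genes in the largest connected component
#'
#' `100 * |largest component ∩ query| / |query|`, components by
#' breadth-first search. Every query gene absent from the graph counts as
#' its own singleton component, so an edgeless input yields
#' `100 / |query|`. Ties between equally large components resolve to the
#' one whose lexicographically smallest member sorts first (logged).
#'
#' @param graph igraph built from the query genes (see [build_subnetwork()]).
#' @param query_genes Character vector of query symbols (nonempty).
#' @return Percentage in (0, 100\].
#' @export
largest_component_fraction <- function(graph, query_genes) {
  if (!length(query_genes)) .stopf("empty query gene set")
  query_genes <- unique(query_genes)
  nq <- length(query_genes)
  best <- 1L  # any query gene outside the graph is a singleton component
  best_label <- NULL
  if (igraph::vcount(graph) > 0) {
    comp <- igraph::components(graph)
    vnames <- igraph::V(graph)$name
    for (ci in seq_len(comp$no)) {
      members <- vnames[comp$membership == ci]
      cnt <- length(intersect(members, query_genes))
      lab <- min(members)
      if (cnt > best || (cnt == best && (is.null(best_label) || lab < best_label))) {
        best <- cnt
        best_label <- lab
      }
    }
    if (all(query_genes %in% vnames) && comp$no > 0) {
      # no implicit singletons; best over graph components only
    }
  }
  if (!is.null(best_label))
    message(sprintf("largest component (ties -> lexicographic): anchored at %s, %d query genes",
                    best_label, best))
  100 * best / nq
}

#' Overlap report for two interaction networks
#'
#' Shared node and edge sets with Jaccard indices, and the mean degree rank
#' of the shared nodes within each network (low mean rank in both networks
#' indicates sharing concentrated around central nodes).
#'
#' @param graphA,graphB igraph objects.
#' @return List with `shared_nodes`, `shared_edges`, `node_jaccard`,
#'   `edge_jaccard`, `mean_shared_rank_A`, `mean_shared_rank_B`.
#' @export
network_overlap <- function(graphA, graphB) {
  nodes <- function(g) if (igraph::vcount(g)) igraph::V(g)$name else character()
  edge_keys <- function(g) {
    if (igraph::ecount(g) == 0) return(character())
    el <- igraph::as_edgelist(g)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "--")
  }
  nA <- nodes(graphA); nB <- nodes(graphB)
  eA <- edge_keys(graphA); eB <- edge_keys(graphB)
  shared_nodes <- intersect(nA, nB)
  shared_edges <- intersect(eA, eB)
  jac <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0) 0 else length(intersect(a, b)) / u
  }
  mean_rank <- function(g, shared) {
    if (!length(shared) || igraph::vcount(g) == 0) return(NA_real_)
    cr <- centrality(g, "degree")
    mean(cr$degree_rank[cr$node %in% shared])
  }
  list(shared_nodes = shared_nodes, shared_edges = shared_edges,
       node_jaccard = jac(nA, nB), edge_jaccard = jac(eA, eB),
       mean_shared_rank_A = mean_rank(graphA, shared_nodes),
       mean_shared_rank_B = mean_rank(graphB, shared_nodes))
}

#' Hub adjacency contrast between two gene sets
#'
#' Tests whether a hub interacts preferentially with one gene set (e.g.
#' genes carrying nonsynonymous SNVs) over another (e.g. genes with only
#' synonymous SNVs): a two-sided Fisher exact test on the 2x2 table
#' (adjacent to hub, not adjacent) x (set A, set B).
#'
#' @param hub Hub gene symbol; must occur in the edge list.
#' @param setA,setB Disjoint gene sets (the hub itself is removed first).
#' @param edges Edge-list data frame or file path.
#' @return A `fisher2x2` (see [fisher_exact_2x2()]).
#' @export
hub_interaction_contrast <- function(hub, setA, setB, edges) {
  if (is.character(edges) && length(edges) == 1) edges <- read_edge_list(edges)
  g <- .edges_to_graph(edges)
  if (!hub %in% igraph::V(g)$name) .stopf("hub gene '%s' absent from edge list", hub)
  setA <- setdiff(unique(setA), hub)
  setB <- setdiff(unique(setB), hub)
  if (length(intersect(setA, setB)))
    .stopf("setA and setB must be disjoint after removing the hub")
  nb <- igraph::V(g)$name[igraph::neighbors(g, hub)]
  tab <- rbind(setA = c(sum(setA %in% nb), sum(!setA %in% nb)),
               setB = c(sum(setB %in% nb), sum(!setB %in% nb)))
  colnames(tab) <- c("adjacent", "not_adjacent")
  fisher_exact_2x2(tab)
}
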