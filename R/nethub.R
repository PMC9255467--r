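# Interaction-network ingestion, centrality computation, low-degree pruning,
# and above-all-means hub selection. Graph algorithms delegate to igraph;
# the closeness convention is the reciprocal of the summed shortest-path
# distances to reachable nodes (the convention under which hub closeness
# values of a few-hundred-node network land near 1/200).

#' Load an undirected interaction network
#'
#' Accepts an edge-list data frame (columns `from`, `to`) or a two-column
#' TSV path. Duplicate edges are merged and self-loops dropped (with a
#' message reporting counts). An optional node-attribute table can flag
#' nodes added by an external prediction service.
#'
#' @param edges edge-list data frame or TSV path.
#' @param node_attrs optional data frame with columns `node` and `predicted`
#'   (logical).
#' @return an [igraph::graph] with vertex attribute `predicted`.
#' @export
load_network <- function(edges, node_attrs = NULL) {
  if (is.character(edges)) edges <- read_edge_list(edges)
  if (nrow(edges) == 0) {
    warning("empty edge list: returning an empty network")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(g)
  }
  if (any(is.na(edges$from) | is.na(edges$to) |
          edges$from == "" | edges$to == ""))
    stop("malformed edge at line ",
         which(is.na(edges$from) | is.na(edges$to) |
                 edges$from == "" | edges$to == "")[1])
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE)
  n_loop <- sum(igraph::which_loop(g))
  n_multi <- sum(igraph::which_multiple(g))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (n_loop + n_multi > 0)
    message("dropped ", n_loop, " self-loop(s) and ", n_multi,
            " duplicate edge(s)")
  pred <- rep(FALSE, igraph::vcount(g))
  if (!is.null(node_attrs)) {
    i <- match(igraph::V(g)$name, node_attrs$node)
    pred <- ifelse(is.na(i), FALSE, as.logical(node_attrs$predicted[i]))
  }
  igraph::set_vertex_attr(g, "predicted", value = pred)
}

#' Prune low-degree nodes
#'
#' Removes nodes with degree < k. By default the rule is iterated to a fixed
#' point (removals can expose new low-degree nodes), which equals the graph's
#' k-core; `iterative = FALSE` applies a single pass.
#'
#' @param g an igraph graph.
#' @param k minimum degree retained (default 2).
#' @param iterative iterate to a fixed point (default TRUE).
#' @return the pruned graph.
#' @export
prune_min_degree <- function(g, k = 2, iterative = TRUE) {
  if (k <= 0) return(g)
  repeat {
    low <- which(igraph::degree(g) < k)
    if (length(low) == 0) break
    g <- igraph::delete_vertices(g, low)
    if (!iterative) break
  }
  g
}

#' Node centralities
#'
#' Degree (incident edge count), closeness (reciprocal of the sum of
#' shortest-path distances to reachable nodes, unit edge weights, computed
#' within each connected component), and unnormalized Brandes betweenness
#' (undirected, endpoints excluded). Isolated nodes get closeness 0 with a
#' warning.
#'
#' @param g an igraph graph.
#' @return data frame with columns `node`, `degree`, `closeness`,
#'   `betweenness`, `predicted`.
#' @export
network_centralities <- function(g) {
  if (igraph::vcount(g) == 0) stop("network is empty")
  d <- igraph::distances(g)
  sums <- apply(d, 1, function(r) sum(r[is.finite(r)]))
  clo <- ifelse(sums > 0, 1 / sums, 0)
  if (any(sums == 0))
    warning("isolated node(s): closeness reported as 0")
  pred <- igraph::vertex_attr(g, "predicted")
  if (is.null(pred)) pred <- rep(FALSE, igraph::vcount(g))
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  data.frame(
    node = nm,
    degree = as.integer(igraph::degree(g)),
    closeness = unname(clo),
    betweenness = unname(igraph::betweenness(g, directed = FALSE,
                                             normalized = FALSE)),
    predicted = pred,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Select hub nodes
#'
#' A node is a hub when its betweenness, closeness, and degree all strictly
#' exceed the respective means over all (post-pruning) nodes. The three
#' means are attached as attribute `"means"`.
#'
#' @param records output of [network_centralities()].
#' @return the records with an `is_hub` column.
#' @export
select_hubs <- function(records) {
  means <- c(betweenness = mean(records$betweenness),
             closeness = mean(records$closeness),
             degree = mean(records$degree))
  records$is_hub <- records$betweenness > means["betweenness"] &
    records$closeness > means["closeness"] &
    records$degree > means["degree"]
  attr(records, "means") <- means
  records
}

#' Full network stage: load, prune, centralities, hubs
#'
#' @param edges edge list (data frame or path), see [load_network()].
#' @param min_degree pruning threshold, see [prune_min_degree()].
#' @param node_attrs optional predicted-node flags, see [load_network()].
#' @return centrality records with `is_hub`; attribute `"means"` carries the
#'   three selection means.
#' @export
run_nethub <- function(edges, min_degree = 2, node_attrs = NULL) {
  g <- load_network(edges, node_attrs = node_attrs)
  g <- prune_min_degree(g, k = min_degree)
  if (igraph::vcount(g) == 0)
    return(structure(data.frame(node = character(0), degree = integer(0),
                                closeness = numeric(0),
                                betweenness = numeric(0),
                                predicted = logical(0),
                                is_hub = logical(0)),
                     means = c(betweenness = NaN, closeness = NaN,
                               degree = NaN)))
  select_hubs(network_centralities(g))
}
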