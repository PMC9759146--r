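#' Weighted adjacency matrix of a thresholded network
#'
#' @param net A `meg_network`.
#' @param edge_policy Which retained edges enter graph-theory analysis:
#'   `"positive"` (default; only positive connections, weight |R|),
#'   `"absolute"` (all connections, weight |R|) or `"signed"` (all
#'   connections, weight R -- only meaningful for strength/degree).
#' @return A symmetric N x N matrix with zero diagonal.
#' @export
adjacency_matrix <- function(net, edge_policy = c("positive", "absolute", "signed")) {
  edge_policy <- match.arg(edge_policy)
  stopifnot(inherits(net, "meg_network"))
  W <- matrix(0, net$n_nodes, net$n_nodes,
    dimnames = list(net$node_labels, net$node_labels)
  )
  e <- net$edges
  if (edge_policy == "positive") e <- e[e$sign > 0, ]
  w <- if (edge_policy == "signed") e$r else e$weight
  W[cbind(e$from, e$to)] <- w
  W[cbind(e$to, e$from)] <- w
  W
}

#' Node and network strength
#'
#' The strength of node i is the sum of the weights of its incident edges,
#' normalized by the node count N (the published definition carries a 1/N
#' factor); network strength SA is the mean node strength. Set
#' `normalization = "classic"` for the plain unnormalized sum used by most
#' other toolboxes.
#'
#' @param net A `meg_network`.
#' @param edge_policy See [adjacency_matrix()].
#' @param normalization `"n"` (divide by N, default) or `"classic"`.
#' @return `node_strength()`: numeric vector S_i; `network_strength()`: SA.
#' @export
node_strength <- function(net, edge_policy = "positive", normalization = c("n", "classic")) {
  normalization <- match.arg(normalization)
  W <- adjacency_matrix(net, edge_policy)
  s <- rowSums(W)
  if (normalization == "n") s <- s / net$n_nodes
  s
}

#' @rdname node_strength
#' @export
network_strength <- function(net, edge_policy = "positive", normalization = c("n", "classic")) {
  if (net$n_nodes == 0) {
    return(0)
  }
  mean(node_strength(net, edge_policy, normalization))
}

#' Node and network degree
#'
#' The degree of node i is the number of nodes directly connected to it;
#' network degree DA is the mean over nodes.
#'
#' @inheritParams node_strength
#' @return `node_degree()`: integer vector d_i; `network_degree()`: DA.
#' @export
node_degree <- function(net, edge_policy = "positive") {
  W <- adjacency_matrix(net, edge_policy)
  rowSums(W != 0)
}

#' @rdname node_degree
#' @export
network_degree <- function(net, edge_policy = "positive") {
  if (net$n_nodes == 0) {
    return(0)
  }
  mean(node_degree(net, edge_policy))
}

#' Shortest-path length matrix with inverse-weight edge lengths
#'
#' Each edge's length is 1/w_ij; L_ij is the shortest-path distance
#' (Dijkstra). By the published convention L_ij = 0 when j cannot be reached
#' from i or when i = j -- note this makes sparser graphs look "shorter".
#'
#' @inheritParams node_strength
#' @return A symmetric N x N matrix.
#' @export
path_length_matrix <- function(net, edge_policy = c("positive", "absolute")) {
  edge_policy <- match.arg(edge_policy)
  W <- adjacency_matrix(net, edge_policy)
  n <- nrow(W)
  if (n == 0 || all(W == 0)) {
    return(matrix(0, n, n, dimnames = dimnames(W)))
  }
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
  L <- igraph::distances(g, weights = 1 / igraph::E(g)$weight, algorithm = "dijkstra")
  L[!is.finite(L)] <- 0
  diag(L) <- 0
  dimnames(L) <- dimnames(W)
  L
}

#' Average path length LA
#'
#' Mean of L_ij over all ordered pairs i != j, with unreachable pairs
#' contributing 0 per the published convention.
#'
#' @inheritParams path_length_matrix
#' @return LA (0 for an empty or single-node network).
#' @export
average_path_length <- function(net, edge_policy = "positive") {
  n <- net$n_nodes
  if (n < 2) {
    return(0)
  }
  L <- path_length_matrix(net, edge_policy)
  sum(L) / (n * (n - 1))
}

#' Geometric-mean weighted clustering coefficient
#'
#' C_i = (1 / (d_i (d_i - 1))) * sum over ordered neighbour pairs (j, k) of
#' (w_ij w_jk w_ki)^(1/3), with weights first normalized by the network's
#' maximum weight so that C_i lies in `[0, 1]` (the standard geometric-mean
#' convention; the published formula leaves the normalization implicit).
#' Nodes with degree < 2 have C_i = 0.
#'
#' @inheritParams node_strength
#' @return `clustering_coefficient()`: numeric vector C_i;
#'   `network_clustering()`: CA, the mean over all nodes.
#' @export
clustering_coefficient <- function(net, edge_policy = c("positive", "absolute")) {
  edge_policy <- match.arg(edge_policy)
  W <- adjacency_matrix(net, edge_policy)
  n <- nrow(W)
  if (n == 0 || all(W == 0)) {
    return(rep(0, n))
  }
  Wn <- W / max(W)
  W3 <- Wn^(1 / 3)
  num <- diag(W3 %*% W3 %*% W3) # sum over ordered (j, k) of cube-root products
  d <- rowSums(W != 0)
  ci <- ifelse(d >= 2, num / (d * (d - 1)), 0)
  names(ci) <- rownames(W)
  ci
}

#' @rdname clustering_coefficient
#' @export
network_clustering <- function(net, edge_policy = "positive") {
  if (net$n_nodes == 0) {
    return(0)
  }
  mean(clustering_coefficient(net, edge_policy))
}

#' Regional connectivity summary
#'
#' Mean weight of retained positive edges incident to nodes of the given
#' role(s) (e.g. `"frontal"` or `"pcc"`); the regional functional-
#' connectivity statistic entering the band-wise group comparison. Returns 0
#' when the region has no retained positive edge.
#'
#' @param net A `meg_network`.
#' @param roles Character vector of node roles defining the region.
#' @return Mean positive-edge weight over edges with at least one endpoint
#'   in the region.
#' @export
regional_connectivity <- function(net, roles) {
  in_region <- which(net$node_roles %in% roles)
  e <- net$edges
  e <- e[e$sign > 0 & (e$from %in% in_region | e$to %in% in_region), ]
  if (nrow(e) == 0) {
    return(0)
  }
  mean(e$weight)
}

#' All network metrics for one subject-band network
#'
#' @param net A `meg_network`.
#' @param edge_policy See [adjacency_matrix()].
#' @param subject_id Optional identifier carried into the output.
#' @param fc_roles Named list of role sets for regional connectivity columns
#'   (default frontal and pcc).
#' @return A one-row tibble: `subject_id`, `band`, `n_nodes`, `k_edges`,
#'   `SA`, `DA`, `LA`, `CA`, plus one `fc_<name>` column per role set.
#' @export
graph_metrics <- function(net, edge_policy = "positive", subject_id = NA_integer_,
                          fc_roles = list(frontal = "frontal", pcc = "pcc")) {
  out <- tibble::tibble(
    subject_id = subject_id,
    band = net$band,
    n_nodes = net$n_nodes,
    k_edges = net$k_edges,
    SA = network_strength(net, edge_policy),
    DA = network_degree(net, edge_policy),
    LA = average_path_length(net, edge_policy),
    CA = network_clustering(net, edge_policy)
  )
  for (nm in names(fc_roles)) {
    out[[paste0("fc_", nm)]] <- regional_connectivity(net, fc_roles[[nm]])
  }
  out
}
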