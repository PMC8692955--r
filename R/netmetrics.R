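#' Weighted global efficiency
#'
#' Global efficiency of a weighted graph is the mean inverse shortest-path
#' length over ordered node pairs,
#' \deqn{E = \frac{1}{n(n-1)} \sum_{i \ne j} \frac{1}{d_{ij}},}
#' with disconnected pairs contributing 0.  Tie weights (co-location counts)
#' are converted to edge lengths by \eqn{\ell_{ij} = w_{max}/w_{ij}}: the
#' strongest observed tie has unit length, so \eqn{E \in [0,1]}, equals 1 on
#' a complete equal-weight graph, and is invariant to rescaling all weights
#' (the measure is scale-free in total observation time).
#'
#' @param g An igraph with edge attribute `weight` (positive), or a square
#'   weight matrix / edge-list data.frame (`u`, `v`, `weight`).
#' @param w_max Normalising weight; defaults to the maximum edge weight of
#'   `g`.  Supplying it allows subgraph efficiencies to be normalised by the
#'   parent network's strongest tie.
#' @return Efficiency in `[0, 1]`; 0 for graphs with fewer than two nodes or
#'   no edges.
#' @examples
#' g <- igraph::make_graph(~ A - B, B - C)
#' igraph::E(g)$weight <- c(1, 1)
#' global_efficiency(g)  # 5/6
#' @export
global_efficiency <- function(g, w_max = NULL) {
  g <- as_interaction_graph(g)
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  w <- igraph::E(g)$weight
  if (length(w) == 0) return(0)
  if (is.null(w_max)) w_max <- max(w)
  D <- igraph::distances(g, weights = w_max / w)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced on each
#' node's neighbours, all normalised by the full network's maximum tie
#' weight.  It measures how well each local neighbourhood can exchange
#' information when the node itself is removed (a weighted clustering
#' notion).  Isolated and degree-1 nodes contribute 0.
#'
#' @inheritParams global_efficiency
#' @return Efficiency in `[0, 1]`.
#' @examples
#' tri <- igraph::make_full_graph(3)
#' igraph::E(tri)$weight <- c(4, 4, 4)
#' local_efficiency(tri)  # 1
#' @export
local_efficiency <- function(g) {
  g <- as_interaction_graph(g)
  n <- igraph::vcount(g)
  if (n < 1) return(0)
  w <- igraph::E(g)$weight
  if (length(w) == 0) return(0)
  w_max <- max(w)
  effs <- vapply(seq_len(n), function(i) {
    nb <- igraph::neighbors(g, i)
    if (length(nb) < 2) return(0)
    global_efficiency(igraph::induced_subgraph(g, nb), w_max = w_max)
  }, numeric(1))
  mean(effs)
}

#' Subgroup structure of an interaction network
#'
#' Components by connectivity, communities (subgroups, the model's analogue
#' of co-residing bands) by weighted Louvain modularity maximisation, and
#' the number of communities whose nodes lie in the largest component (the
#' "connected" subgroups forming the higher organisational level).  Louvain
#' is randomised, so the community count reported is the modal count over
#' `restarts` seeded runs; sizes come from the first run achieving the modal
#' count.
#'
#' @inheritParams global_efficiency
#' @param restarts Number of seeded Louvain restarts (default 10).
#' @param seed Base seed for the restarts (default 1).
#' @return List of class `cpf_subgroups`: `n_components`, `n_communities`,
#'   `n_connected_communities`, `community_sizes`, `membership`.
#' @export
subgroup_summary <- function(g, restarts = 10, seed = 1) {
  g <- as_interaction_graph(g)
  comp <- igraph::components(g)
  n_components <- comp$no
  if (igraph::ecount(g) == 0) {
    memb <- seq_len(igraph::vcount(g))
    counts <- length(memb)
    sizes <- rep(1L, length(memb))
  } else {
    runs <- lapply(seq_len(restarts), function(i) {
      set.seed(seed + i - 1L)
      igraph::membership(igraph::cluster_louvain(
        g, weights = igraph::E(g)$weight))
    })
    ns <- vapply(runs, function(m) length(unique(m)), integer(1))
    tab <- table(ns)
    modal <- as.integer(names(tab)[which.max(tab)])
    memb <- runs[[which(ns == modal)[1]]]
    counts <- modal
    sizes <- as.integer(table(memb))
  }
  largest <- which(comp$membership == which.max(comp$csize))
  n_conn <- length(unique(memb[largest]))
  structure(list(
    n_components = n_components,
    n_communities = counts,
    n_connected_communities = n_conn,
    community_sizes = sizes,
    membership = memb), class = "cpf_subgroups")
}

#' @export
print.cpf_subgroups <- function(x, ...) {
  cat(sprintf(
    "Subgroups: %d components, %d communities (%d in largest component)\n",
    x$n_components, x$n_communities, x$n_connected_communities))
  invisible(x)
}

#' Coerce to a weighted undirected igraph
#'
#' Accepts an igraph (edges must carry a `weight` attribute unless the graph
#' is edgeless), a square symmetric weight matrix, or an edge-list
#' data.frame with columns `u`, `v`, `weight`.
#'
#' @param x Network in any of the accepted forms.
#' @return An undirected igraph with positive edge weights.
#' @export
as_interaction_graph <- function(x) {
  if (igraph::is_igraph(x)) {
    if (igraph::ecount(x) > 0 && is.null(igraph::E(x)$weight))
      igraph::E(x)$weight <- 1
    return(x)
  }
  if (is.matrix(x))
    return(.weights_to_graph(x))
  if (is.data.frame(x)) {
    stopifnot(all(c("u", "v", "weight") %in% names(x)))
    g <- igraph::graph_from_data_frame(
      x[, c("u", "v", "weight")], directed = FALSE)
    return(g)
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as an interaction network")
}

#' Select the most globally efficient network
#'
#' @param networks List of networks (any form [as_interaction_graph()]
#'   accepts).
#' @return The network with maximal [global_efficiency()]; ties break toward
#'   the lowest index.  The chosen index is attached as attribute `"index"`.
#' @export
select_most_efficient <- function(networks) {
  if (length(networks) == 0) stop("no networks supplied")
  effs <- vapply(networks, global_efficiency, numeric(1))
  i <- which.max(effs)
  out <- networks[[i]]
  attr(out, "index") <- i
  attr(out, "global_efficiency") <- effs[i]
  out
}
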