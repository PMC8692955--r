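#' Build a tiny deterministic environment from explicit patches
#'
#' Hand-specified micro-environments (no randomness) for traceable agent
#' scenarios and tests.
#'
#' @param x,y Patch coordinates in `[0, 1]`.
#' @param k0 Initial integer resource contents (>= 1).
#' @param beta Nominal exponent recorded on the object (default NA; the
#'   contents are explicit, not sampled).
#' @return A `cpf_environment`.
#' @examples
#' env <- toy_environment(x = c(0, 0.1), y = c(0, 0), k0 = c(2, 1))
#' @export
toy_environment <- function(x, y, k0, beta = NA_real_) {
  stopifnot(length(x) == length(y), length(x) == length(k0),
            length(x) >= 1, length(x) <= 100)
  if (any(x < 0 | x > 1 | y < 0 | y > 1))
    stop("patch positions must lie in the unit square")
  if (any(k0 < 1)) stop("k0 must be >= 1")
  structure(list(
    patches = data.frame(id = seq_along(x), x = x, y = y,
                         k0 = as.integer(k0), k = as.integer(k0)),
    beta = beta, k_max = max(as.integer(k0)), seed = NULL),
    class = "cpf_environment")
}

#' The three-neighbour contagion worked example
#'
#' A focal agent with tie weights (2, 5, 10) to three neighbours, with the
#' three canonical informed scenarios and their adoption probabilities:
#' simple contagion with only the weight-10 neighbour informed (10/17 ~
#' 0.59), simple with only the weight-2 neighbour informed (2/17 ~ 0.12),
#' and complex with only the weight-10 neighbour informed ((10/17)^2 ~
#' 0.34).
#'
#' @return List with `weights` and `scenarios` (data.frame: `mode`,
#'   `informed` list-column, `expected` to two decimals).
#' @export
contagion_worked_example <- function() {
  w <- c(2, 5, 10)
  scen <- data.frame(mode = c("simple", "simple", "complex"),
                     expected = c(0.59, 0.12, 0.34))
  scen$informed <- list(c(0, 0, 1), c(1, 0, 0), c(0, 0, 1))
  list(weights = w, scenarios = scen)
}

#' Toy weighted graphs with closed-form metric values
#'
#' A small collection used across the metric and contagion tests:
#' * `triangle`: 3-clique, equal weights — global and local efficiency 1.
#' * `star`: star on 5 nodes — local efficiency 0.
#' * `path3`: path A-B-C, weights 1, 1 — global efficiency 5/6.
#' * `clique4`: 4-clique, all weights 2 — both efficiencies 1.
#' * `bridged_cliques`: two 5-cliques joined by one weight-1 bridge — one
#'   component, two Louvain communities.
#' * `isolated5`: 5 nodes, no edges — 5 components, efficiency 0.
#'
#' @return Named list of igraphs.
#' @export
toy_graphs <- function() {
  wgraph <- function(el, w, n = max(el)) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(el))
    igraph::E(g)$weight <- w
    g
  }
  triangle <- wgraph(rbind(c(1, 2), c(2, 3), c(1, 3)), c(3, 3, 3))
  star <- wgraph(cbind(1, 2:5), c(1, 2, 3, 4))
  path3 <- wgraph(rbind(c(1, 2), c(2, 3)), c(1, 1))
  cl4 <- t(utils::combn(4, 2))
  clique4 <- wgraph(cl4, rep(2, nrow(cl4)))
  c5a <- t(utils::combn(1:5, 2))
  c5b <- t(utils::combn(6:10, 2))
  bridged <- wgraph(rbind(c5a, c5b, c(5, 6)),
                    c(rep(5, nrow(c5a)), rep(5, nrow(c5b)), 1), n = 10)
  isolated5 <- igraph::make_empty_graph(5, directed = FALSE)
  list(triangle = triangle, star = star, path3 = path3, clique4 = clique4,
       bridged_cliques = bridged, isolated5 = isolated5)
}
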