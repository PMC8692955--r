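#' Read and write weighted edge lists and GraphML
#'
#' Edge-list CSVs have columns `u`, `v`, `weight`.  Vertex count is
#' preserved through an `n` comment on the first line so isolated nodes
#' survive the round trip.
#'
#' @param g Network in any form [as_interaction_graph()] accepts.
#' @param path File path.
#' @return Readers return an igraph; writers return `path` invisibly.
#' @export
write_edgelist <- function(g, path) {
  g <- as_interaction_graph(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  d <- data.frame(u = el[, 1], v = el[, 2],
                  weight = if (igraph::ecount(g))
                    igraph::E(g)$weight else numeric())
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d", igraph::vcount(g)), con)
  utils::write.csv(d, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  first <- readLines(path, n = 1)
  n <- if (grepl("^# n=", first))
    as.integer(sub("^# n=", "", first)) else NA_integer_
  d <- utils::read.csv(path, comment.char = "#")
  g <- igraph::make_empty_graph(if (is.na(n)) max(d$u, d$v, 0) else n,
                                directed = FALSE)
  if (nrow(d)) {
    g <- igraph::add_edges(g, rbind(d$u, d$v))
    igraph::E(g)$weight <- d$weight
  }
  g
}

#' @rdname write_edgelist
#' @export
write_graphml <- function(g, path) {
  g <- as_interaction_graph(g)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Write a move log or metric table as CSV
#' @param x Data.frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
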