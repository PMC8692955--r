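# Independent oracles, deliberately different algorithms from the package:
# efficiency via Floyd-Warshall on dense length matrices (the package uses
# igraph Dijkstra), tie weights via replay of the move log.

# all-pairs shortest paths by Floyd-Warshall; L: length matrix, Inf = no edge
fw_distances <- function(L) {
  n <- nrow(L)
  D <- L
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# brute-force weighted global efficiency from a weight matrix
oracle_global_eff <- function(W, w_max = NULL) {
  n <- nrow(W)
  if (n < 2) return(0)
  if (all(W == 0)) return(0)
  if (is.null(w_max)) w_max <- max(W)
  L <- ifelse(W > 0, w_max / W, Inf)
  D <- fw_distances(L)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  sum(inv) / (n * (n - 1))
}

# brute-force weighted local efficiency (neighbour-induced subgraphs,
# lengths normalised by the full network's maximum weight)
oracle_local_eff <- function(W) {
  n <- nrow(W)
  if (n < 1 || all(W == 0)) return(0)
  w_max <- max(W)
  effs <- vapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_eff(W[nb, nb, drop = FALSE], w_max = w_max)
  }, numeric(1))
  mean(effs)
}

# random weighted graph as weight matrix (integer weights 1..10)
random_weight_matrix <- function(n, p = 0.3) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      if (stats::runif(1) < p)
        W[i, j] <- W[j, i] <- sample.int(10, 1)
  W
}

# replay unit locations per step from init patches and the move log;
# returns an n_steps x n_units matrix of patch ids (state after the move
# phase of each step, i.e. when depletion/co-location apply)
replay_locations <- function(init_patches, moves, n_units, n_steps) {
  loc <- matrix(NA_integer_, n_steps, n_units)
  cur <- init_patches
  for (t in seq_len(n_steps)) {
    mt <- moves[moves$step == t, ]
    if (nrow(mt)) cur[mt$unit] <- mt$to
    loc[t, ] <- cur
  }
  loc
}

# tie-weight matrix recomputed from a location replay
oracle_weights <- function(loc_matrix) {
  n <- ncol(loc_matrix)
  W <- matrix(0, n, n)
  for (t in seq_len(nrow(loc_matrix))) {
    l <- loc_matrix[t, ]
    for (u in seq_len(n - 1))
      for (v in (u + 1):n)
        if (l[u] == l[v]) {
          W[u, v] <- W[u, v] + 1
          W[v, u] <- W[v, u] + 1
        }
  }
  W
}

# small random environment + simulation helper for property tests
random_sim <- function(seed, radius, n_patches = 1000, n_units = 12,
                       n_steps = 40, beta = 2.5, k_max = 100, ...) {
  env <- build_environment(beta, n_patches = n_patches, k_max = k_max,
                           seed = seed)
  run_simulation(env, n_units = n_units, radius = radius, n_steps = n_steps,
                 seed = seed + 1, ...)
}
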