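#' A central-place foraging unit
#'
#' A foraging unit (a nuclear family in the hunter-gatherer reading) has a
#' home patch (its central place), a current location and a foraging radius
#' `r` in unit-square distance units.  `radius = 0` is point-to-point mode:
#' the unit has no meaningful home range and every move is residential.
#'
#' @param home Patch id of the home (central place).
#' @param location Patch id of the current location (defaults to home).
#' @param radius Foraging radius, >= 0.
#' @return An object of class `cpf_unit`.
#' @export
cpf_unit <- function(home, location = home, radius) {
  stopifnot(radius >= 0)
  structure(list(home = as.integer(home), location = as.integer(location),
                 radius = radius), class = "cpf_unit")
}

# distances from a patch to all patches
.dist_from <- function(env, patch_id) {
  p <- env$patches
  sqrt((p$x - p$x[patch_id])^2 + (p$y - p$y[patch_id])^2)
}

#' Best foraging target within the radius
#'
#' Returns the patch \eqn{p_j} with food left (`k > 0`) within radius `r` of
#' the unit's home that minimises the cost/gain ratio \eqn{d_{hj}/k_j}, where
#' `d_hj` is the distance from the home patch.  Ties break toward the lowest
#' patch id.
#'
#' @param unit A [cpf_unit()].
#' @param env A `cpf_environment`.
#' @return Patch id, or `NA_integer_` when no in-radius patch has food.
#' @export
best_within_radius <- function(unit, env) {
  d <- .dist_from(env, unit$home)
  k <- env$patches$k
  ok <- k > 0 & d <= unit$radius
  if (!any(ok)) return(NA_integer_)
  ratio <- ifelse(ok, d / k, Inf)
  which.min(ratio)
}

# best ratio outside the radius and best eligible new home, both from home
.outside_best <- function(unit, env) {
  d <- .dist_from(env, unit$home)
  k <- env$patches$k
  out <- k > 0 & d > unit$radius
  elig <- k > 0 & d >= 2 * unit$radius
  list(
    out_id   = if (any(out)) which.min(ifelse(out, d / k, Inf)) else NA_integer_,
    out_rat  = if (any(out)) min((d / k)[out]) else Inf,
    home_id  = if (any(elig)) which.min(ifelse(elig, d / k, Inf)) else NA_integer_,
    home_rat = if (any(elig)) min((d / k)[elig]) else Inf)
}

#' Should a unit make a residential move?
#'
#' Evaluated when the unit's current patch is exhausted.  The unit relocates
#' when resource quality within its radius has diminished relative to the
#' rest of the environment: the best outside cost/gain ratio is strictly
#' smaller than the best inside ratio (or no in-radius patch has food left).
#' Relocation additionally requires an eligible new home: a patch with food
#' at distance >= 2r from the current home (so successive home ranges do not
#' overlap).  With `radius = 1` on the unit square no patch pair is 2 apart,
#' so such units never relocate and stay tethered to their original home.
#'
#' @inheritParams best_within_radius
#' @return Logical.
#' @export
should_relocate <- function(unit, env) {
  inside <- best_within_radius(unit, env)
  ob <- .outside_best(unit, env)
  if (is.na(inside)) return(!is.na(ob$home_id))
  if (is.na(ob$out_id)) return(FALSE)
  d <- .dist_from(env, unit$home)
  in_rat <- d[inside] / env$patches$k[inside]
  ob$out_rat < in_rat && !is.na(ob$home_id)
}

#' Choose a new home for a residential move
#'
#' The new home \eqn{p_{h'}} minimises \eqn{d_{hh'}/k_{h'}} over patches with
#' food at distance >= 2r from the current home; with `radius = 0` the
#' constraint is vacuous and the rule degenerates to the global
#' point-to-point move rule.  Ties break toward the lowest patch id.
#'
#' @inheritParams best_within_radius
#' @return Patch id of the new home.
#' @export
choose_new_home <- function(unit, env) {
  ob <- .outside_best(unit, env)
  if (is.na(ob$home_id))
    stop("no eligible new home (guarded by should_relocate)")
  ob$home_id
}

#' Advance a foraging simulation state by one time-step
#'
#' Reference (plain R) implementation of the step rule, used for
#' hand-traceable fixtures and as the cross-check for the compiled engine.
#' Units whose current patch is exhausted either forage (move to
#' [best_within_radius()], logging the displacement from the previous
#' location) or relocate (home and location jump to [choose_new_home()],
#' logging the home-to-new-home distance).  Units on patches with food stay.
#' Then every unit removes one resource unit from its patch, and every
#' co-located unordered pair gains one tie-weight unit.
#'
#' @param state List with elements `env` (a `cpf_environment`), `home`,
#'   `location` (integer vectors over units), `radius`, `weights`
#'   (n x n matrix), `moves` (data.frame), `step` (completed step count),
#'   `coloc` (integer vector).
#' @return The updated state.
#' @export
step_state <- function(state) {
  env <- state$env
  n <- length(state$home)
  t <- state$step + 1L
  for (u in seq_len(n)) {
    if (env$patches$k[state$location[u]] > 0) next
    unit <- cpf_unit(state$home[u], state$location[u], state$radius)
    inside <- best_within_radius(unit, env)
    if (should_relocate(unit, env)) {
      nh <- choose_new_home(unit, env)
      dist <- .dist_from(env, unit$home)[nh]
      state$moves <- rbind(state$moves, data.frame(
        unit = u, step = t, kind = "residential", to = nh, distance = dist))
      state$home[u] <- nh
      state$location[u] <- nh
    } else if (!is.na(inside)) {
      dist <- .dist_from(env, state$location[u])[inside]
      state$moves <- rbind(state$moves, data.frame(
        unit = u, step = t, kind = "foraging", to = inside,
        distance = dist))
      state$location[u] <- inside
    }
  }
  occ <- tabulate(state$location, nbins = nrow(env$patches))
  env$patches$k <- pmax(0L, env$patches$k - occ)
  state$env <- env
  cc <- 0L
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      if (v > u && state$location[u] == state$location[v]) {
        state$weights[u, v] <- state$weights[u, v] + 1
        state$weights[v, u] <- state$weights[v, u] + 1
        cc <- cc + 1L
      }
    }
  }
  state$coloc <- c(state$coloc, cc)
  state$step <- t
  state
}

#' Run a central-place foraging simulation
#'
#' Places `n_units` foraging units on uniformly random patches (home =
#' starting patch), then iterates the move/deplete/co-locate step rule for
#' `n_steps` time-steps.  Tie weights count the time-steps each unordered
#' pair of units spent co-located on a patch; the cumulative weighted graph
#' is the interaction network.
#'
#' @param env A `cpf_environment` (the environment is copied; the caller's
#'   object is not depleted).
#' @param n_units Number of foraging units (>= 2 for any network to form).
#' @param radius Foraging radius `r` (0 = point-to-point mode).
#' @param n_steps Number of time-steps (default 100).
#' @param snapshot_interval If non-NULL, record the cumulative network every
#'   this many steps (must divide `n_steps`).
#' @param seed Optional seed for the initial placement.
#' @param init_patches Optional integer vector of starting patch ids
#'   (overrides random placement; used by deterministic fixtures).
#' @param engine `"cpp"` (compiled, default) or `"reference"` (plain R,
#'   identical results, small problems only).
#' @return An object of class `cpf_sim`: list with `network` (igraph,
#'   weighted, undirected, one vertex per unit), `weights` (matrix),
#'   `moves` (data.frame: unit, step, kind, distance), `mobility`
#'   (see [mobility_summary()]), `coloc` (per-step co-location pair counts),
#'   `snapshots` (list of igraphs), `snapshot_steps`, `k_final`, `home`,
#'   `location`, and the call parameters.
#' @examples
#' env <- build_environment(2.5, n_patches = 500, seed = 1)
#' sim <- run_simulation(env, n_units = 10, radius = 0.1, n_steps = 20, seed = 2)
#' sim
#' @export
run_simulation <- function(env, n_units, radius, n_steps = 100,
                           snapshot_interval = NULL, seed = NULL,
                           init_patches = NULL,
                           engine = c("cpp", "reference")) {
  stopifnot(inherits(env, "cpf_environment"), n_units >= 1, radius >= 0,
            n_steps >= 0)
  engine <- match.arg(engine)
  if (!is.null(snapshot_interval)) {
    stopifnot(snapshot_interval >= 1, n_steps %% snapshot_interval == 0)
  }
  if (is.null(init_patches)) {
    if (!is.null(seed)) set.seed(seed)
    init_patches <- sample.int(nrow(env$patches), n_units, replace = TRUE)
  } else {
    stopifnot(length(init_patches) == n_units,
              all(init_patches >= 1), all(init_patches <= nrow(env$patches)))
    init_patches <- as.integer(init_patches)
  }
  si <- if (is.null(snapshot_interval)) 0L else as.integer(snapshot_interval)

  if (engine == "cpp") {
    res <- cpf_core(env$patches$x, env$patches$y, as.integer(env$patches$k),
                    radius, init_patches - 1L, as.integer(n_steps), si)
    weights <- res$weights
    moves <- as.data.frame(res$moves)
    moves$kind <- ifelse(moves$kind == 1L, "residential", "foraging")
    k_final <- res$k_final
    home <- res$home + 1L
    location <- res$location + 1L
    coloc <- as.integer(res$coloc)
    snaps <- res$snapshots
    snap_steps <- as.integer(res$snap_steps)
  } else {
    state <- list(env = env, home = init_patches, location = init_patches,
                  radius = radius,
                  weights = matrix(0, n_units, n_units),
                  moves = data.frame(unit = integer(), step = integer(),
                                     kind = character(), to = integer(),
                                     distance = numeric()),
                  step = 0L, coloc = integer())
    snaps <- list(); snap_steps <- integer()
    for (t in seq_len(n_steps)) {
      state <- step_state(state)
      if (si > 0L && t %% si == 0L) {
        snaps[[length(snaps) + 1L]] <- state$weights
        snap_steps <- c(snap_steps, t)
      }
    }
    weights <- state$weights
    moves <- state$moves
    k_final <- state$env$patches$k
    home <- state$home
    location <- state$location
    coloc <- state$coloc
  }

  if (length(moves$unit) == 0)
    moves <- data.frame(unit = integer(), step = integer(),
                        kind = character(), to = integer(),
                        distance = numeric())
  net <- .weights_to_graph(weights)
  snapshots <- lapply(snaps, .weights_to_graph)
  structure(list(
    network = net, weights = weights, moves = moves,
    mobility = mobility_summary(moves, n_units, n_steps),
    coloc = coloc, snapshots = snapshots, snapshot_steps = snap_steps,
    k_final = as.integer(k_final), home = home, location = location,
    init_patches = init_patches,
    n_units = as.integer(n_units), radius = radius,
    n_steps = as.integer(n_steps), beta = env$beta, seed = seed),
    class = "cpf_sim")
}

.weights_to_graph <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- as.character(seq_len(nrow(W)))
  g
}

#' Extract the interaction network of a simulation
#' @param sim A `cpf_sim`.
#' @return The final cumulative weighted igraph.
#' @export
interaction_network <- function(sim) {
  stopifnot(inherits(sim, "cpf_sim"))
  sim$network
}

#' Mobility summary of a move log
#'
#' Per-condition aggregates used throughout: `n_r`, `n_f` are the mean
#' per-unit counts of residential and foraging moves over the run; `d_r`,
#' `d_f` the mean per-move distances.  A category with no moves has count 0
#' and distance `NA` (undefined).
#'
#' @param moves Move-log data.frame with columns `unit`, `step`, `kind`
#'   (`"foraging"`/`"residential"`), `distance`.
#' @param n_units Number of units in the run.
#' @param n_steps Number of steps (carried through for reference).
#' @return A list of class `cpf_mobility` with `n_r`, `d_r`, `n_f`, `d_f`,
#'   `total_r`, `total_f`, `sum_d_r`, `sum_d_f`, `n_units`, `n_steps`.
#' @export
mobility_summary <- function(moves, n_units, n_steps) {
  res <- moves$kind == "residential"
  total_r <- sum(res); total_f <- sum(!res)
  structure(list(
    n_r = total_r / n_units,
    d_r = if (total_r > 0) mean(moves$distance[res]) else NA_real_,
    n_f = total_f / n_units,
    d_f = if (total_f > 0) mean(moves$distance[!res]) else NA_real_,
    total_r = total_r, total_f = total_f,
    sum_d_r = sum(moves$distance[res]), sum_d_f = sum(moves$distance[!res]),
    n_units = n_units, n_steps = n_steps), class = "cpf_mobility")
}

#' @export
print.cpf_mobility <- function(x, ...) {
  cat(sprintf("Mobility: n_r = %.3g (d_r = %.3g), n_f = %.3g (d_f = %.3g)\n",
              x$n_r, x$d_r, x$n_f, x$d_f))
  invisible(x)
}

#' @export
print.cpf_sim <- function(x, ...) {
  cat("Central-place foraging simulation\n")
  cat(sprintf("  units: %d   radius: %g   steps: %d   beta: %g\n",
              x$n_units, x$radius, x$n_steps, x$beta))
  cat(sprintf("  network: %d edges, total tie weight %g\n",
              igraph::ecount(x$network), sum(x$weights) / 2))
  print(x$mobility)
  invisible(x)
}

#' @export
summary.cpf_sim <- function(object, ...) {
  g <- object$network
  out <- list(
    n_units = object$n_units, radius = object$radius,
    n_steps = object$n_steps, beta = object$beta,
    n_edges = igraph::ecount(g), total_weight = sum(object$weights) / 2,
    global_efficiency = global_efficiency(g),
    local_efficiency = local_efficiency(g),
    subgroups = subgroup_summary(g),
    mobility = object$mobility)
  class(out) <- "summary.cpf_sim"
  out
}

#' @export
print.summary.cpf_sim <- function(x, ...) {
  cat("Central-place foraging simulation summary\n")
  cat(sprintf("  units: %d  radius: %g  steps: %d  beta: %g\n",
              x$n_units, x$radius, x$n_steps, x$beta))
  cat(sprintf("  edges: %d  total weight: %g\n", x$n_edges, x$total_weight))
  cat(sprintf("  global efficiency: %.4f  local efficiency: %.4f\n",
              x$global_efficiency, x$local_efficiency))
  cat(sprintf("  components: %d  communities: %d (connected: %d)\n",
              x$subgroups$n_components, x$subgroups$n_communities,
              x$subgroups$n_connected_communities))
  print(x$mobility)
  invisible(x)
}

#' Plot the interaction network of a simulation
#'
#' Spring (Fruchterman-Reingold) layout with edge width proportional to tie
#' weight; a quick look at the fission-fusion subgroup structure.
#'
#' @param x A `cpf_sim`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.cpf_sim <- function(x, ...) {
  g <- x$network
  w <- igraph::E(g)$weight
  igraph::plot.igraph(
    g, layout = igraph::layout_with_fr(g, weights = w),
    edge.width = if (length(w)) 0.5 + 2.5 * w / max(w) else 1,
    vertex.size = 4, vertex.label = NA, ...)
  invisible(x)
}
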