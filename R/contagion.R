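#' Adoption probability under simple or complex contagion
#'
#' A focal agent with tie weights `weights` to its neighbours, of whom those
#' flagged in `informed` carry the behaviour, adopts with probability equal
#' to the informed-weighted fraction of its ties,
#' \deqn{\Pr(A) = \frac{\sum_i w_i d_i}{\sum_i w_i},}
#' under simple contagion, and the square of that fraction under complex
#' contagion (social reinforcement: weak single sources rarely suffice).
#'
#' @param weights Positive tie-weight vector of the focal agent.
#' @param informed 0/1 (or logical) vector, same length: which neighbours
#'   carry the behaviour.
#' @param mode `"simple"` or `"complex"`.
#' @return Probability in `[0, 1]`; 0 for an empty neighbourhood.
#' @examples
#' adoption_probability(c(2, 5, 10), c(0, 0, 1), "simple")   # ~0.59
#' adoption_probability(c(2, 5, 10), c(1, 0, 0), "simple")   # ~0.12
#' adoption_probability(c(2, 5, 10), c(0, 0, 1), "complex")  # ~0.35
#' @export
adoption_probability <- function(weights, informed,
                                 mode = c("simple", "complex")) {
  mode <- match.arg(mode)
  if (length(weights) == 0) return(0)
  stopifnot(length(weights) == length(informed), all(weights > 0))
  frac <- sum(weights * as.numeric(informed)) / sum(weights)
  if (mode == "complex") frac^2 else frac
}

#' Run contagion simulations on a weighted network
#'
#' Each run seeds one uniformly random agent with the behaviour and then
#' updates synchronously: every uninformed agent adopts at `t + 1` with its
#' [adoption_probability()] computed from the state at `t`.  Informed agents
#' never revert, so trajectories are monotone and the spread is absorbed
#' once the seed's connected component is saturated (the run is then
#' completed analytically, which is why long `n_steps` are cheap).
#'
#' @param g Network in any form [as_interaction_graph()] accepts.
#' @param mode `"simple"` or `"complex"`.
#' @param n_steps Time-steps per run (default 5000).
#' @param n_runs Number of runs (default 50).
#' @param seed Optional RNG seed.
#' @return Object of class `cpf_contagion`: `trajectory` (matrix,
#'   `n_runs` x `n_steps + 1`, informed fraction with column 1 = state at
#'   t = 0), `seeds` (seed agent per run), `mode`, `n`.
#' @examples
#' g <- igraph::make_full_graph(5)
#' igraph::E(g)$weight <- 10
#' res <- run_contagion(g, "simple", n_steps = 50, n_runs = 5, seed = 1)
#' time_to_fraction(res, 0.75)
#' @export
run_contagion <- function(g, mode = c("simple", "complex"),
                          n_steps = 5000, n_runs = 50, seed = NULL) {
  mode <- match.arg(mode)
  g <- as_interaction_graph(g)
  n <- igraph::vcount(g)
  if (n < 1) stop("network is empty")
  stopifnot(n_steps >= 1, n_runs >= 1)
  W <- igraph::as_adjacency_matrix(g, attr = if (igraph::ecount(g)) "weight",
                                   sparse = FALSE)
  s <- rowSums(W)
  comp <- igraph::components(g)$membership
  if (!is.null(seed)) set.seed(seed)
  traj <- matrix(NA_real_, n_runs, n_steps + 1)
  seeds <- integer(n_runs)
  for (run in seq_len(n_runs)) {
    seeds[run] <- sample.int(n, 1)
    informed <- logical(n)
    informed[seeds[run]] <- TRUE
    reachable <- sum(comp == comp[seeds[run]])
    traj[run, 1] <- 1 / n
    for (t in seq_len(n_steps)) {
      if (sum(informed) >= reachable) {
        traj[run, (t + 1):(n_steps + 1)] <- sum(informed) / n
        break
      }
      p <- as.vector(W %*% informed)
      p <- ifelse(s > 0, p / s, 0)
      if (mode == "complex") p <- p^2
      p[informed] <- 0
      informed <- informed | (stats::runif(n) < p)
      traj[run, t + 1] <- sum(informed) / n
    }
  }
  structure(list(trajectory = traj, seeds = seeds, mode = mode, n = n),
            class = "cpf_contagion")
}

#' Time for contagion runs to reach a target informed fraction
#'
#' @param result A `cpf_contagion`.
#' @param f Target fraction in (0, 1].
#' @return List of class `cpf_time_to_fraction`: `times` (per-run first
#'   step with informed fraction >= `f`; `NA` when never reached), `mean`
#'   and `sd` over the runs that reached the target, `n_reached`,
#'   `n_censored`, `f`.
#' @export
time_to_fraction <- function(result, f) {
  stopifnot(inherits(result, "cpf_contagion"))
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    stop("f must be in (0, 1]")
  times <- apply(result$trajectory, 1, function(tr) {
    i <- which(tr >= f)[1]
    if (is.na(i)) NA_integer_ else i - 1L  # column 1 is t = 0
  })
  reached <- times[!is.na(times)]
  structure(list(
    times = times,
    mean = if (length(reached)) mean(reached) else NA_real_,
    sd = if (length(reached) > 1) stats::sd(reached) else NA_real_,
    n_reached = length(reached),
    n_censored = sum(is.na(times)),
    f = f), class = "cpf_time_to_fraction")
}

#' @export
print.cpf_time_to_fraction <- function(x, ...) {
  cat(sprintf(
    "Time to reach %.0f%% informed: mean %.1f +/- %.1f sd (%d/%d runs)\n",
    100 * x$f, x$mean, x$sd, x$n_reached, x$n_reached + x$n_censored))
  invisible(x)
}

#' @export
print.cpf_contagion <- function(x, ...) {
  final <- x$trajectory[, ncol(x$trajectory)]
  cat(sprintf("%s contagion: %d runs on %d nodes\n",
              x$mode, nrow(x$trajectory), x$n))
  cat(sprintf("  final informed fraction: mean %.2f (range %.2f-%.2f)\n",
              mean(final), min(final), max(final)))
  invisible(x)
}

#' Plot contagion trajectories
#'
#' Median informed-fraction trajectory with a band between the 25th and 75th
#' percentiles across runs.
#'
#' @param x A `cpf_contagion`.
#' @param max_steps Right edge of the time axis (default: last step at which
#'   the inter-quartile band still moves).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cpf_contagion <- function(x, max_steps = NULL, ...) {
  q <- apply(x$trajectory, 2, stats::quantile, c(0.25, 0.5, 0.75))
  if (is.null(max_steps)) {
    moving <- which(diff(q[3, ]) > 0 | diff(q[1, ]) > 0)
    max_steps <- if (length(moving)) min(ncol(q), max(moving) + 5) else ncol(q)
  }
  tt <- seq_len(max_steps) - 1
  graphics::plot(tt, q[2, seq_len(max_steps)], type = "l", ylim = c(0, 1),
                 xlab = "time-step", ylab = "informed fraction",
                 main = sprintf("%s contagion", x$mode), ...)
  graphics::polygon(c(tt, rev(tt)),
                    c(q[1, seq_len(max_steps)], rev(q[3, seq_len(max_steps)])),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(tt, q[2, seq_len(max_steps)])
  invisible(x)
}
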