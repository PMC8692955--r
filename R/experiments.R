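#' Derive a reproducible 31-bit seed from a base seed and labels
#'
#' Polynomial string hash of the base seed plus arbitrary labels (condition
#' parameters, replicate index, role).  Conditions and replicates are
#' thereby independently reproducible regardless of execution order.
#'
#' @param base_seed Integer base seed.
#' @param ... Labels (numbers or strings) identifying the stream.
#' @return Integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(base_seed, ...) {
  key <- paste(c(base_seed, ...), collapse = "|")
  h <- 17
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h + 1L)
}

#' Run one replicate of a sweep condition
#'
#' Builds a fresh random environment and runs one simulation, both seeded
#' deterministically from `base_seed` and the condition labels, then
#' computes network metrics and the mobility summary.
#'
#' @param beta,radius,n_units Condition parameters.
#' @param rep Replicate index.
#' @param base_seed Base seed of the sweep.
#' @param n_steps,n_patches,k_max Scale parameters.
#' @param metrics Compute efficiency/subgroup metrics (default TRUE).
#' @return List with `row` (one-row data.frame of per-rep aggregates) and
#'   `sim` (the `cpf_sim`).
#' @export
run_condition_rep <- function(beta, radius, n_units, rep, base_seed,
                              n_steps = 100, n_patches = 50000,
                              k_max = 10000, metrics = TRUE) {
  env_seed <- derive_seed(base_seed, beta, radius, n_units, rep, "env")
  sim_seed <- derive_seed(base_seed, beta, radius, n_units, rep, "sim")
  env <- build_environment(beta, n_patches = n_patches, k_max = k_max,
                           seed = env_seed)
  sim <- run_simulation(env, n_units = n_units, radius = radius,
                        n_steps = n_steps, seed = sim_seed)
  g <- sim$network
  mob <- sim$mobility
  row <- data.frame(
    beta = beta, radius = radius, n_units = n_units, rep = rep,
    n_edges = igraph::ecount(g), total_weight = sum(sim$weights) / 2,
    n_r = mob$n_r, d_r = mob$d_r, n_f = mob$n_f, d_f = mob$d_f,
    total_r = mob$total_r, total_f = mob$total_f,
    sum_d_r = mob$sum_d_r, sum_d_f = mob$sum_d_f)
  if (metrics) {
    sg <- subgroup_summary(g, seed = derive_seed(base_seed, beta, radius,
                                                 n_units, rep, "louvain"))
    row$global_eff <- global_efficiency(g)
    row$local_eff <- local_efficiency(g)
    row$n_components <- sg$n_components
    row$n_communities <- sg$n_communities
    row$n_connected_communities <- sg$n_connected_communities
  }
  list(row = row, sim = sim)
}

#' Run a factorial sweep over environments, radii and population sizes
#'
#' For every combination of `betas` x `radii` x `populations`, runs `reps`
#' seeded replicate simulations (fresh random landscape per replicate),
#' computes per-replicate network and mobility aggregates, and summarises
#' each condition by means with 95% normal-approximation confidence
#' intervals.  Per-replicate rows can be cached on disk so an interrupted
#' sweep resumes where it stopped.
#'
#' @param betas Resource exponents (default `c(1.5, 2.5, 3.5, 4.5)`).
#' @param radii Foraging radii (default `c(0, 0.001, 0.01, 0.1, 1)`;
#'   0 = point-to-point).
#' @param populations Population sizes (default `c(50, 100, 200)`).
#' @param reps Replicates per condition (default 50).
#' @param n_steps,n_patches,k_max Scale parameters (defaults 100, 50000,
#'   10000).
#' @param base_seed Base seed (default 1); per-rep seeds derive from it and
#'   the condition labels via [derive_seed()].
#' @param metrics Compute efficiency/subgroup metrics per rep (default TRUE).
#' @param keep_networks Keep each replicate's final network (default FALSE;
#'   needed for [select_most_efficient()] / contagion follow-ups).
#' @param cache_dir Optional directory for per-rep row caching.  A config
#'   echo is written there; resuming against a cache written under a
#'   different configuration is refused.
#' @param progress Print per-condition progress (default FALSE).
#' @return Object of class `cpf_sweep`: `reps` (one row per replicate),
#'   `conditions` (one row per condition with means and 95% CIs), `grid`,
#'   and optionally `networks` (list keyed by condition label).
#' @export
run_sweep <- function(betas = c(1.5, 2.5, 3.5, 4.5),
                      radii = c(0, 0.001, 0.01, 0.1, 1),
                      populations = c(50, 100, 200),
                      reps = 50, n_steps = 100, n_patches = 50000,
                      k_max = 10000, base_seed = 1, metrics = TRUE,
                      keep_networks = FALSE, cache_dir = NULL,
                      progress = FALSE) {
  grid <- expand.grid(beta = betas, radius = radii, n_units = populations,
                      KEEP.OUT.ATTRS = FALSE)
  config <- list(betas = betas, radii = radii, populations = populations,
                 reps = reps, n_steps = n_steps, n_patches = n_patches,
                 k_max = k_max, base_seed = base_seed)
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_path <- file.path(cache_dir, "sweep-config.yaml")
    if (file.exists(cfg_path)) {
      old <- yaml::read_yaml(cfg_path)
      if (!isTRUE(all.equal(old, config, tolerance = 1e-12)))
        stop("cache_dir holds replicates from a different sweep ",
             "configuration; refusing to mix (", cfg_path, ")")
    } else {
      yaml::write_yaml(config, cfg_path)
    }
  }
  rep_rows <- list()
  networks <- list()
  for (i in seq_len(nrow(grid))) {
    b <- grid$beta[i]; r <- grid$radius[i]; nu <- grid$n_units[i]
    label <- sprintf("beta%s_r%s_n%d", b, r, nu)
    if (progress)
      message(sprintf("condition %d/%d: %s", i, nrow(grid), label))
    cond_nets <- vector("list", reps)
    for (j in seq_len(reps)) {
      cache_file <- if (!is.null(cache_dir))
        file.path(cache_dir, sprintf("%s_rep%03d.csv", label, j))
      if (!is.null(cache_dir) && file.exists(cache_file) && !keep_networks) {
        row <- utils::read.csv(cache_file)
      } else {
        out <- run_condition_rep(b, r, nu, j, base_seed,
                                 n_steps = n_steps, n_patches = n_patches,
                                 k_max = k_max, metrics = metrics)
        row <- out$row
        if (keep_networks) cond_nets[[j]] <- out$sim$network
        if (!is.null(cache_dir))
          utils::write.csv(row, cache_file, row.names = FALSE)
      }
      rep_rows[[length(rep_rows) + 1L]] <- row
    }
    if (keep_networks) networks[[label]] <- cond_nets
  }
  rep_df <- do.call(rbind, rep_rows)
  out <- structure(list(reps = rep_df,
                        conditions = summarise_conditions(rep_df),
                        grid = grid, config = config),
                   class = "cpf_sweep")
  if (keep_networks) out$networks <- networks
  out
}

#' Summarise per-replicate sweep rows into condition means
#'
#' Means over replicates with 95% normal-approximation confidence
#' half-widths (`*_ci`).  Pooled mobility distances (`d_r`, `d_f`) weight
#' every move equally across replicates.
#'
#' @param rep_df Per-replicate data.frame as produced by [run_sweep()].
#' @return One row per condition.
#' @export
summarise_conditions <- function(rep_df) {
  key <- interaction(rep_df$beta, rep_df$radius, rep_df$n_units, drop = TRUE)
  rows <- lapply(split(rep_df, key), function(d) {
    num <- setdiff(names(d)[vapply(d, is.numeric, logical(1))],
                   c("beta", "radius", "n_units", "rep"))
    out <- data.frame(beta = d$beta[1], radius = d$radius[1],
                      n_units = d$n_units[1], reps = nrow(d))
    for (v in num) {
      x <- d[[v]][!is.na(d[[v]])]
      out[[paste0(v, "_mean")]] <- if (length(x)) mean(x) else NA_real_
      out[[paste0(v, "_ci")]] <- if (length(x) > 1)
        1.96 * stats::sd(x) / sqrt(length(x)) else NA_real_
    }
    # pooled per-move distances over all replicates
    out$d_r_pooled <- if (sum(d$total_r) > 0)
      sum(d$sum_d_r) / sum(d$total_r) else NA_real_
    out$d_f_pooled <- if (sum(d$total_f) > 0)
      sum(d$sum_d_f) / sum(d$total_f) else NA_real_
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$beta, out$radius, out$n_units), ]
}

#' @export
print.cpf_sweep <- function(x, ...) {
  cat(sprintf("Parameter sweep: %d conditions x %d reps\n",
              nrow(x$grid), x$config$reps))
  cols <- intersect(c("beta", "radius", "n_units", "reps",
                      "global_eff_mean", "local_eff_mean",
                      "n_r_mean", "n_f_mean"), names(x$conditions))
  print(x$conditions[, cols], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write the standard figure set for a sweep
#'
#' Efficiency-versus-beta curves per radius, the mobility scatter (mean
#' move distances and counts), efficiency-versus-population bars with 95%
#' CIs, and (when trajectories are supplied) contagion trajectory bands
#' between the 25th and 75th percentiles.
#'
#' @param sweep A `cpf_sweep` (or its `conditions` data.frame).
#' @param dir Output directory (created if needed).
#' @param contagion Optional named list of `cpf_contagion` objects for the
#'   trajectory panel.
#' @param format `"png"` or `"pdf"`.
#' @return Invisibly, the paths written; with an empty table, warns and
#'   writes nothing.
#' @export
make_figures <- function(sweep, dir, contagion = NULL,
                         format = c("png", "pdf")) {
  format <- match.arg(format)
  cond <- if (inherits(sweep, "cpf_sweep")) sweep$conditions else sweep
  if (is.null(cond) || nrow(cond) == 0) {
    warning("empty condition table; no figures written")
    return(invisible(character()))
  }
  need <- c("beta", "radius", "n_units", "global_eff_mean", "local_eff_mean",
            "n_r_mean", "n_f_mean", "d_r_pooled", "d_f_pooled")
  if (!all(need %in% names(cond)))
    stop("condition table lacks columns: ",
         paste(setdiff(need, names(cond)), collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dev_open <- function(path) {
    if (format == "png") grDevices::png(path, 1200, 600, res = 120)
    else grDevices::pdf(path, 10, 5)
  }
  paths <- character()
  radii <- sort(unique(cond$radius))
  cols <- grDevices::hcl.colors(max(2, length(radii)), "Dark 2")

  p <- file.path(dir, paste0("efficiency_vs_beta.", format))
  dev_open(p)
  graphics::par(mfrow = c(1, 2))
  for (metric in c("global_eff_mean", "local_eff_mean")) {
    graphics::plot(NULL, xlim = range(cond$beta), ylim = c(0, 1),
                   xlab = expression(beta), ylab = metric)
    for (ri in seq_along(radii)) {
      d <- cond[cond$radius == radii[ri], ]
      d <- d[order(d$beta), ]
      graphics::lines(d$beta, d[[metric]], col = cols[ri], type = "b",
                      pch = 16)
    }
    graphics::legend("topright", legend = paste("r =", radii), col = cols,
                     lty = 1, cex = 0.7)
  }
  grDevices::dev.off(); paths <- c(paths, p)

  p <- file.path(dir, paste0("mobility.", format))
  dev_open(p)
  graphics::par(mfrow = c(1, 2))
  graphics::plot(cond$d_f_pooled, cond$d_r_pooled, col = cols[match(
    cond$radius, radii)], pch = 16,
    xlab = "mean foraging-move distance", ylab = "mean residential distance")
  graphics::plot(cond$n_f_mean, cond$n_r_mean, col = cols[match(
    cond$radius, radii)], pch = 16,
    xlab = "foraging moves per unit", ylab = "residential moves per unit")
  graphics::legend("topright", legend = paste("r =", radii), col = cols,
                   pch = 16, cex = 0.7)
  grDevices::dev.off(); paths <- c(paths, p)

  p <- file.path(dir, paste0("efficiency_vs_population.", format))
  dev_open(p)
  graphics::par(mfrow = c(1, 2))
  for (metric in c("local_eff_mean", "global_eff_mean")) {
    ci <- sub("_mean$", "_ci", metric)
    pops <- sort(unique(cond$n_units))
    m <- tapply(cond[[metric]], list(cond$radius, cond$n_units), mean)
    bp <- graphics::barplot(m, beside = TRUE, col = cols[seq_len(nrow(m))],
                            ylim = c(0, 1), xlab = "population size",
                            ylab = metric, names.arg = pops)
    if (ci %in% names(cond)) {
      e <- tapply(cond[[ci]], list(cond$radius, cond$n_units), mean)
      graphics::arrows(bp, m - e, bp, m + e, angle = 90, code = 3,
                       length = 0.02)
    }
  }
  grDevices::dev.off(); paths <- c(paths, p)

  if (!is.null(contagion) && length(contagion)) {
    p <- file.path(dir, paste0("contagion_trajectories.", format))
    dev_open(p)
    graphics::par(mfrow = c(1, length(contagion)))
    for (nm in names(contagion)) plot(contagion[[nm]], main = nm)
    grDevices::dev.off(); paths <- c(paths, p)
  }
  invisible(paths)
}
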