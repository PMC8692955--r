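#' Truncated power-law probability mass function for patch resource content
#'
#' Resource content of a patch is a positive integer \eqn{k} drawn from
#' \eqn{P(k) = C k^{-\beta}} on the support \eqn{k = 1, \dots, k_{max}},
#' with \eqn{C} the normalisation constant.  Small \eqn{\beta} gives rich,
#' heterogeneous landscapes (heavy tail of very rich patches); large
#' \eqn{\beta} gives poor, homogeneous ones where almost every patch holds a
#' single unit of food.
#'
#' @param beta Power-law exponent, must exceed 1 so the (untruncated)
#'   normalisation constant is finite.
#' @param k_max Upper truncation of the support (integer, >= 1).
#' @return Numeric vector of length `k_max`; element `k` is `P(k)`.
#'   Sums to 1.
#' @examples
#' pmf <- powerlaw_pmf(2.5, 100)
#' sum(pmf)
#' @export
powerlaw_pmf <- function(beta, k_max) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 1)
    stop("beta must be a single number > 1 (normalisation diverges otherwise)")
  if (!is.numeric(k_max) || length(k_max) != 1L || k_max < 1)
    stop("k_max must be >= 1")
  k_max <- as.integer(k_max)
  # work in logs: k^-beta underflows for large beta long before k_max
  logw <- -beta * log(seq_len(k_max))
  w <- exp(logw - max(logw))
  w / sum(w)
}

#' Build a patchy resource environment
#'
#' Generates `n_patches` patches placed i.i.d. uniformly on the unit square,
#' each assigned an initial integer resource content `k0` drawn from
#' [powerlaw_pmf()] by exact inverse-CDF sampling.  Patches deplete (see
#' [deplete()]) and never regenerate.
#'
#' @param beta Power-law exponent of the resource distribution (> 1).
#' @param n_patches Number of patches (default 50000).
#' @param k_max Truncation cap for resource sampling (default 10000).
#' @param seed Optional integer seed; when given, the environment is a
#'   deterministic function of the arguments.
#' @return An object of class `cpf_environment`: a list with `patches`
#'   (data.frame with columns `id`, `x`, `y`, `k0`, `k`), `beta`, `k_max`
#'   and `seed`.
#' @examples
#' env <- build_environment(2.5, n_patches = 100, seed = 1)
#' env
#' @export
build_environment <- function(beta, n_patches = 50000, k_max = 10000,
                              seed = NULL) {
  if (!is.numeric(n_patches) || n_patches < 1)
    stop("n_patches must be >= 1")
  n_patches <- as.integer(n_patches)
  pmf <- powerlaw_pmf(beta, k_max)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::runif(n_patches)
  y <- stats::runif(n_patches)
  k0 <- findInterval(stats::runif(n_patches), cumsum(pmf)) + 1L
  structure(list(
    patches = data.frame(id = seq_len(n_patches), x = x, y = y,
                         k0 = k0, k = k0),
    beta = beta, k_max = as.integer(k_max), seed = seed),
    class = "cpf_environment")
}

#' Deplete a patch by a number of resource units
#'
#' Patches never regenerate; content is floored at zero.  One co-located
#' foraging unit removes one unit per time-step, so `amount` equals the
#' number of occupants during a step.
#'
#' @param env A `cpf_environment`.
#' @param patch_id Patch id (row of `env$patches`).
#' @param amount Non-negative integer number of units to remove.
#' @return The environment with the patch's `k` reduced to
#'   `max(0, k - amount)`.
#' @export
deplete <- function(env, patch_id, amount = 1) {
  stopifnot(inherits(env, "cpf_environment"))
  if (!is.numeric(patch_id) || length(patch_id) != 1L ||
      is.na(patch_id) || patch_id < 1 || patch_id > nrow(env$patches))
    stop("unknown patch_id: ", patch_id)
  if (amount < 0) stop("amount must be >= 0")
  i <- as.integer(patch_id)
  env$patches$k[i] <- max(0L, env$patches$k[i] - as.integer(amount))
  env
}

#' Total remaining resource in an environment
#' @param env A `cpf_environment`.
#' @return Sum of remaining `k` over all patches.
#' @export
total_resource <- function(env) {
  stopifnot(inherits(env, "cpf_environment"))
  sum(env$patches$k)
}

#' @export
print.cpf_environment <- function(x, ...) {
  cat("Patchy resource environment\n")
  cat(sprintf("  patches: %d   beta: %g   k_max: %d\n",
              nrow(x$patches), x$beta, x$k_max))
  cat(sprintf("  resource remaining: %d of %d initial units\n",
              sum(x$patches$k), sum(x$patches$k0)))
  invisible(x)
}

#' Write / read an environment as CSV
#'
#' Columns `patch_id, x, y, k0, k`; `beta` and `k_max` travel in a YAML
#' side-car written next to the CSV (same path with extension `.yaml`).
#'
#' @param env A `cpf_environment`.
#' @param path CSV file path.
#' @return `write_environment_csv` returns `path` invisibly;
#'   `read_environment_csv` returns a `cpf_environment`.
#' @export
write_environment_csv <- function(env, path) {
  stopifnot(inherits(env, "cpf_environment"))
  d <- env$patches
  names(d)[1] <- "patch_id"
  utils::write.csv(d, path, row.names = FALSE)
  yaml::write_yaml(list(beta = env$beta, k_max = env$k_max,
                        n_patches = nrow(env$patches)),
                   paste0(tools::file_path_sans_ext(path), ".yaml"))
  invisible(path)
}

#' @rdname write_environment_csv
#' @export
read_environment_csv <- function(path) {
  d <- utils::read.csv(path)
  meta_path <- paste0(tools::file_path_sans_ext(path), ".yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else
    list(beta = NA_real_, k_max = max(d$k0))
  names(d)[names(d) == "patch_id"] <- "id"
  structure(list(patches = d, beta = meta$beta,
                 k_max = as.integer(meta$k_max), seed = NULL),
            class = "cpf_environment")
}
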