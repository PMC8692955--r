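# 4-patch line fixture used by the hand-written trace below
trace_env <- function() {
  toy_environment(x = c(0, 0.1, 0.2, 0.9), y = c(0, 0, 0, 0),
                  k0 = c(2, 1, 3, 5))
}

test_that("best_within_radius minimises d/k over in-radius patches with food", {
  env <- toy_environment(x = c(0.5, 0.6, 0.4), y = c(0.5, 0.5, 0.5),
                         k0 = c(1, 10, 5))
  env <- deplete(env, 1, 1)  # unit sits on an exhausted home
  u <- cpf_unit(home = 1, radius = 0.2)
  # equal distance 0.1: ratios 0.01 vs 0.02 -> the k = 10 patch
  expect_equal(best_within_radius(u, env), 2)
  # all within-radius patches exhausted -> none
  env0 <- deplete(deplete(env, 2, 10), 3, 5)
  expect_identical(best_within_radius(u, env0), NA_integer_)
  # single in-radius patch with food
  env1 <- toy_environment(x = c(0.5, 0.55), y = c(0.5, 0.5), k0 = c(1, 1))
  env1 <- deplete(env1, 1, 1)
  expect_equal(best_within_radius(cpf_unit(1, radius = 0.1), env1), 2)
})

test_that("relocation triggers only when outside beats inside and a home is eligible", {
  # best inside ratio 0.01 < best outside 0.02 -> stay
  env <- toy_environment(x = c(0.5, 0.6, 0.9), y = c(0.5, 0.5, 0.5),
                         k0 = c(1, 10, 20))
  env <- deplete(env, 1, 1)
  u <- cpf_unit(1, radius = 0.2)
  expect_false(should_relocate(u, env))
  # inside exhausted, outside has food, eligible home exists -> relocate
  env2 <- deplete(env, 2, 10)
  expect_true(should_relocate(u, env2))
  expect_equal(choose_new_home(u, env2), 3)
  # r = 1 in the unit square: no patch can be 2r = 2 away -> never relocate
  u1 <- cpf_unit(1, radius = 1)
  expect_false(should_relocate(u1, deplete(env, 2, 10)))
})

test_that("choose_new_home minimises d/k subject to the 2r overlap constraint", {
  env <- toy_environment(x = c(0.1, 0.4, 0.5), y = c(0.5, 0.5, 0.5),
                         k0 = c(1, 3, 8))
  env <- deplete(env, 1, 1)
  # candidates (d = 0.3, k = 3) ratio 0.1 and (d = 0.4, k = 8) ratio 0.05
  expect_equal(choose_new_home(cpf_unit(1, radius = 0.15), env), 3)
  # exactly one patch beyond 2r
  env2 <- toy_environment(x = c(0.1, 0.15, 0.9), y = c(0.5, 0.5, 0.5),
                          k0 = c(1, 5, 2))
  env2 <- deplete(env2, 1, 1)
  expect_equal(choose_new_home(cpf_unit(1, radius = 0.1), env2), 3)
  # r = 0: constraint vacuous, global argmin of d/k
  expect_equal(choose_new_home(cpf_unit(1, radius = 0), env), 3)
})

test_that("five-step run reproduces the hand-written trace exactly", {
  # trace (worked by hand on the 4-patch line, r = 0.15, units start
  # on patches 1 and 2):
  #   step 1: both sit (k > 0); deplete p1 2->1, p2 1->0
  #   step 2: unit 2 forages p2 -> p3 (ratios: p1 0.1/1, p3 0.1/3;
  #           outside p4 0.8/5 = 0.16 does not beat 0.0333); p1 -> 0, p3 -> 2
  #   step 3: unit 1 has no in-radius food; eligible home p4 (d = 0.9 >= 0.3)
  #           -> residential, distance 0.9; p3 2 -> 1, p4 5 -> 4
  #   step 4: both sit; p3 1 -> 0, p4 4 -> 3
  #   step 5: unit 2 relocates home p2 -> p4, distance 0.8; both on p4:
  #           tie weight + 1, p4 3 -> 1
  sim <- run_simulation(trace_env(), n_units = 2, radius = 0.15,
                        n_steps = 5, init_patches = c(1, 2))
  mv <- sim$moves
  expect_equal(nrow(mv), 3)
  expect_equal(mv$unit, c(2, 1, 2))
  expect_equal(mv$step, c(2, 3, 5))
  expect_equal(mv$kind, c("foraging", "residential", "residential"))
  expect_equal(mv$to, c(3, 4, 4))
  expect_equal(mv$distance, c(0.1, 0.9, 0.8), tolerance = 1e-12)
  expect_equal(sim$weights[1, 2], 1)
  expect_equal(sim$k_final, c(0L, 0L, 0L, 1L))
  expect_equal(sim$coloc, c(0L, 0L, 0L, 0L, 1L))
  expect_equal(sim$home, c(4, 4))
  m <- sim$mobility
  expect_equal(m$n_r, 1)       # 2 residential moves / 2 units
  expect_equal(m$d_r, 0.85)
  expect_equal(m$n_f, 0.5)
  expect_equal(m$d_f, 0.1)
})

test_that("compiled and reference engines agree exactly", {
  for (seed in 1:4) {
    for (r in c(0, 0.05, 0.3)) {
      env <- build_environment(2.5, n_patches = 150, k_max = 30, seed = seed)
      set.seed(seed + 100)
      init <- sample.int(150, 6, replace = TRUE)
      a <- run_simulation(env, 6, radius = r, n_steps = 25,
                          init_patches = init, engine = "cpp")
      b <- run_simulation(env, 6, radius = r, n_steps = 25,
                          init_patches = init, engine = "reference")
      expect_equal(a$weights, b$weights)
      expect_equal(a$moves$unit, b$moves$unit)
      expect_equal(a$moves$step, b$moves$step)
      expect_equal(a$moves$kind, b$moves$kind)
      expect_equal(a$moves$to, b$moves$to)
      expect_equal(a$moves$distance, b$moves$distance, tolerance = 1e-14)
      expect_equal(a$k_final, b$k_final)
      expect_equal(a$home, b$home)
      expect_equal(a$coloc, b$coloc)
    }
  }
})

test_that("simulations are deterministic given a seed and empty at 0 steps", {
  env <- build_environment(2.5, n_patches = 300, k_max = 50, seed = 8)
  a <- run_simulation(env, 5, radius = 0.1, n_steps = 20, seed = 3)
  b <- run_simulation(env, 5, radius = 0.1, n_steps = 20, seed = 3)
  expect_identical(a$weights, b$weights)
  expect_identical(a$moves, b$moves)
  z <- run_simulation(env, 5, radius = 0.1, n_steps = 0, seed = 3)
  expect_equal(nrow(z$moves), 0)
  expect_equal(igraph::ecount(z$network), 0)
})

test_that("two units funnelled to one rich patch form exactly one edge", {
  env <- toy_environment(x = c(0.5, 0.45, 0.55), y = c(0.5, 0.5, 0.5),
                         k0 = c(10, 1, 1))
  sim <- run_simulation(env, 2, radius = 0, n_steps = 4,
                        init_patches = c(2, 3))
  expect_equal(igraph::ecount(sim$network), 1)
  # co-located from step 2 on: weight 3 after 4 steps
  expect_equal(sim$weights[1, 2], 3)
})

test_that("tie weights equal replayed co-location counts", {
  for (seed in 1:3) {
    sim <- random_sim(seed, radius = c(0.02, 0.1, 0)[seed])
    loc <- replay_locations(sim$init_patches, sim$moves, sim$n_units,
                            sim$n_steps)
    expect_equal(sim$weights, oracle_weights(loc))
    expect_equal(sum(sim$weights) / 2, sum(sim$coloc))
  }
})

test_that("move-kind geometry invariants hold", {
  # every residential move at least 2r; r = 0 logs no foraging moves;
  # r = 1 logs no residential moves; r > 0 units stay within r of home
  s <- random_sim(1, radius = 0.05, n_steps = 60)
  res <- s$moves[s$moves$kind == "residential", ]
  expect_true(all(res$distance >= 2 * 0.05 - 1e-12))

  s0 <- random_sim(2, radius = 0)
  expect_false(any(s0$moves$kind == "foraging"))

  s1 <- random_sim(3, radius = 1)
  expect_false(any(s1$moves$kind == "residential"))
  env <- build_environment(2.5, n_patches = 1000, k_max = 100, seed = 3)
  loc <- replay_locations(s1$init_patches, s1$moves, s1$n_units, s1$n_steps)
  p <- env$patches
  for (u in seq_len(s1$n_units)) {
    h <- s1$init_patches[u]
    d <- sqrt((p$x[loc[, u]] - p$x[h])^2 + (p$y[loc[, u]] - p$y[h])^2)
    expect_true(all(d <= 1 + 1e-12))
  }
})

test_that("mobility_summary arithmetic matches direct computation", {
  empty <- data.frame(unit = integer(), step = integer(), kind = character(),
                      to = integer(), distance = numeric())
  m0 <- mobility_summary(empty, n_units = 4, n_steps = 10)
  expect_equal(m0$n_r, 0); expect_equal(m0$n_f, 0)
  expect_true(is.na(m0$d_r)); expect_true(is.na(m0$d_f))

  one <- data.frame(unit = 1, step = 3, kind = "residential", to = 2,
                    distance = 0.5)
  m1 <- mobility_summary(one, n_units = 2, n_steps = 10)
  expect_equal(m1$n_r, 0.5); expect_equal(m1$d_r, 0.5)

  set.seed(42)
  d <- stats::runif(10)
  kinds <- rep(c("residential", "foraging"), 5)
  log10 <- data.frame(unit = rep(1:2, 5), step = 1:10, kind = kinds,
                      to = 1L, distance = d)
  m <- mobility_summary(log10, n_units = 2, n_steps = 10)
  expect_equal(m$n_r, 2.5)
  expect_equal(m$d_r, mean(d[kinds == "residential"]))
  expect_equal(m$d_f, mean(d[kinds == "foraging"]))
})

test_that("snapshots are cumulative subnetworks of later snapshots", {
  sim <- random_sim(7, radius = 0.1, n_steps = 40, snapshot_interval = 10)
  expect_length(sim$snapshots, 4)
  get_w <- function(g) unname(igraph::as_adjacency_matrix(
    g, attr = if (igraph::ecount(g)) "weight", sparse = FALSE))
  prev <- get_w(sim$snapshots[[1]])
  for (i in 2:4) {
    cur <- get_w(sim$snapshots[[i]])
    expect_true(all(cur >= prev))
    prev <- cur
  }
  expect_equal(prev, unname(get_w(sim$network)))
})
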