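env_fixture <- function(hypothesis = "gradient", seed = 1L, size = 32L,
                        noise = 0.2) {
  sc <- corridor_fixture()
  create_tissue_env(sc$series, "Cpaaa", "ABarpaapp",
                    hypothesis = hypothesis, seed = seed,
                    image_size = size, noise_halfwidth = noise)
}

test_that("environment creation derives speed and budget from the data", {
  env <- env_fixture()
  s <- corridor_fixture()$series
  win <- migration_window(s, "Cpaaa", "ABarpaapp")
  steps <- unname(win["end"] - win["start"])
  expect_equal(env$budget_steps, floor(0.9 * steps))
  tab0 <- frame_table(s, win["start"])
  d0 <- sqrt(sum((unlist(tab0[tab0$name == "Cpaaa", c("x", "y", "z")]) -
                  unlist(tab0[tab0$name == "ABarpaapp",
                              c("x", "y", "z")]))^2))
  expect_equal(env$speed$v_avg, d0 / steps)      # initial distance / time
  expect_error(create_tissue_env(s, "nope", "ABarpaapp"), "not in series")
})

test_that("reset restores the initial state and observation exactly", {
  env <- env_fixture()
  o1 <- env_reset(env)
  expect_equal(dim(o1), c(2L, 32L, 32L))
  # 64 px default elsewhere
  env64 <- env_fixture(size = 64L)
  expect_equal(dim(env_reset(env64)), c(2L, 64L, 64L))
  st0 <- env_get_state(env)
  for (a in c(0L, 3L, 5L)) env_step(env, a)
  o2 <- env_reset(env)
  expect_identical(o2, o1)
  st1 <- env_get_state(env)
  expect_identical(st1[c("frame_index", "steps_elapsed", "stable_counter")],
                   st0[c("frame_index", "steps_elapsed", "stable_counter")])
  expect_identical(env_reset(env), env_reset(env))
})

test_that("step size sampling stays in the 20% band with the right mean", {
  env <- env_fixture()
  draws <- local({
    set.seed(42)
    replicate(1e4, sample_step_size(env$speed))
  })
  v <- env$speed$v_avg
  expect_true(all(draws >= 0.8 * v & draws <= 1.2 * v))
  expect_lt(abs(mean(draws) - v) / v, 0.01)
  expect_identical(sample_step_size(list(v_avg = 2, noise_halfwidth = 0)), 2)
})

test_that("the action basis has 8 unit directions in the xy plane", {
  dirs <- action_directions()
  expect_equal(dim(dirs), c(8L, 3L))
  expect_equal(sqrt(rowSums(dirs^2)), rep(1, 8L))
  expect_equal(dirs[, 3L], rep(0, 8L))
  expect_equal(dirs[1L, ], c(1, 0, 0))
})

test_that("stepping moves the agent geometrically and replays the others", {
  env <- env_fixture(noise = 0)                  # deterministic step size
  env_reset(env)
  st0 <- env_get_state(env)
  d0 <- sqrt(sum((st0$agent_pos - cellmigrl:::env_target_pos(env))^2))
  res <- env_step(env, 0L)                       # +x points at the target
  expect_s3_class(res$reward, "reward_breakdown")
  expect_equal(res$info$distance,
               sqrt(sum((env_get_state(env)$agent_pos -
                         cellmigrl:::env_target_pos(env))^2)))
  # moving straight at an in-plane target shortens d by ~the step size
  expect_lt(abs((d0 - res$info$distance) - env$speed$v_avg), 0.2)
  # environment cells equal the replayed series frame exactly
  tab <- env_get_state(env)$cell_table
  ref <- frame_table(env$series, env$frame_index)
  others <- tab$name != "Cpaaa"
  expect_identical(tab[others, ], ref[ref$name != "Cpaaa", ])
  expect_error(env_step(env, 8L), "0..7")
  expect_error(env_step(env, -1L), "0..7")
})

test_that("episodes are bit-reproducible given seed and actions", {
  run <- function() {
    env <- env_fixture(seed = 11L)
    env_reset(env)
    lapply(c(0L, 1L, 7L, 0L, 2L), function(a) env_step(env, a))
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1, r2)
})

test_that("stability pays 100 and finishes; budget exhaustion pays nothing", {
  env <- env_fixture(noise = 0)
  env_reset(env)
  # oracle: walk straight at the target on the corridor scenario
  paid <- FALSE
  k <- 0L
  repeat {
    st <- env_get_state(env)
    v <- cellmigrl:::env_target_pos(env) - st$agent_pos
    dirs <- action_directions()
    a <- which.max(dirs[, 1] * v[1] + dirs[, 2] * v[2]) - 1L
    res <- env_step(env, a)
    k <- k + 1L
    if (res$reward$r_destination != 0) {
      paid <- TRUE
      expect_equal(res$reward$r_destination, 100)
      expect_equal(res$info$stable_counter, 5L)
      expect_true(res$done)
      break
    }
    if (res$done) break
  }
  expect_true(paid)
  expect_lte(k, env$budget_steps)
  expect_error(env_step(env, 0L), "done")

  # never-approaching policy: done with no destination reward
  env2 <- env_fixture(noise = 0)
  env_reset(env2)
  total_dest <- 0
  done <- FALSE
  while (!done) {
    res <- env_step(env2, 4L)                    # straight away (-x)
    total_dest <- total_dest + res$reward$r_destination
    done <- res$done
  }
  expect_equal(total_dest, 0)
  expect_gt(env2$steps_elapsed, env2$budget_steps)
})

test_that("snapshots are isolated from the live environment", {
  env <- env_fixture()
  env_reset(env)
  st <- env_get_state(env)
  st$agent_pos <- st$agent_pos + 100
  st$cell_table$x <- 0
  expect_false(identical(env_get_state(env)$agent_pos, st$agent_pos))
  res <- env_step(env, 0L)
  expect_true(res$info$distance < 100)           # env unaffected
})

test_that("subgoal bookkeeping pays 10 once for the active pair", {
  env <- env_fixture(hypothesis = "subgoal", noise = 0)
  env_reset(env)
  expect_error(env_set_subgoal(env_fixture("gradient"), c("a", "b")),
               "hypothesis")
  tab <- env_get_state(env)$cell_table
  direct <- neighbors_of(tab, "Cpaaa")
  sec <- secondary_neighbors(tab, "Cpaaa")
  expect_error(env_set_subgoal(env, direct[1:2]), "secondary")
  # pick the two secondary neighbors nearest the migrating cell
  pos <- tab[match(sec, tab$name), c("x", "y", "z")]
  mig <- unlist(tab[tab$name == "Cpaaa", c("x", "y", "z")])
  ord <- order(sqrt(rowSums(sweep(as.matrix(pos), 2, mig)^2)))
  pair <- sec[ord[1:2]]
  env_set_subgoal(env, pair)
  expect_identical(env_get_state(env)$active_subgoal, pair)
  # drive toward the subgoal pair midpoint until it pays
  paid_at <- NA
  for (k in 1:40) {
    tab <- env_get_state(env)$cell_table
    mid <- colMeans(tab[match(pair, tab$name), c("x", "y", "z")])
    v <- mid - env_get_state(env)$agent_pos
    dirs <- action_directions()
    a <- which.max(dirs[, 1] * v[1] + dirs[, 2] * v[2]) - 1L
    res <- env_step(env, a)
    if (res$reward$r_subgoal != 0) {
      expect_equal(res$reward$r_subgoal, 10)
      paid_at <- k
      break
    }
    if (res$done) break
  }
  expect_false(is.na(paid_at))
  # the same pair never pays twice
  res2 <- env_step(env, 0L)
  expect_equal(res2$reward$r_subgoal, 0)
  # gradient component is inert under the subgoal hypothesis
  expect_equal(res2$reward$r_gradient, 0)
})
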