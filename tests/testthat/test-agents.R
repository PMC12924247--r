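test_that("policy networks map observations to 8 action values", {
  for (S in c(32L, 64L)) {
    net <- build_policy_network(c(2L, S, S), 8L, seed = 3L)
    obs <- array(runif(2 * S * S), c(2L, S, S))
    q <- policy_values(net, obs)
    expect_equal(dim(q), c(1L, 8L))
    expect_true(all(is.finite(q)))
  }
  # seeded double-build gives identical outputs
  obs <- array(runif(2 * 32 * 32), c(2L, 32L, 32L))
  n1 <- build_policy_network(c(2L, 32L, 32L), seed = 5L)
  n2 <- build_policy_network(c(2L, 32L, 32L), seed = 5L)
  expect_identical(policy_values(n1, obs), policy_values(n2, obs))
  expect_gt(cellmigrl:::policy_count_params(n1), 1e4)
  expect_error(build_policy_network(c(3L, 32L, 32L)), "channels")
})

test_that("network gradients agree with finite differences", {
  net <- build_mlp_network(6L, 3L, hidden = c(8L, 8L), seed = 2L)
  X <- matrix(runif(12), 2L, 6L)
  tgt <- matrix(runif(6), 2L, 3L)
  loss <- function(n) sum((cellmigrl:::net_forward(n, X)$out - tgt)^2) / 2
  fw <- cellmigrl:::net_forward(net, X, keep_cache = TRUE)
  grads <- cellmigrl:::net_backward(net, fw$cache, fw$out - tgt)
  eps <- 1e-6
  for (li in c(1L, 3L)) {
    for (pick in list(c(1L, 1L), c(2L, 3L))) {
      n2 <- net
      n2$layers[[li]]$W[pick[1], pick[2]] <-
        n2$layers[[li]]$W[pick[1], pick[2]] + eps
      num <- (loss(n2) - loss(net)) / eps
      expect_equal(grads[[li]]$dW[pick[1], pick[2]], num, tolerance = 1e-3)
    }
  }
})

test_that("greedy schedule interpolates 0.3 to 0.95 linearly", {
  expect_equal(greedy_schedule(0, 100), 0.3)
  expect_equal(greedy_schedule(100, 100), 0.95)
  expect_equal(greedy_schedule(50, 100), 0.625)
  expect_error(greedy_schedule(5, 4))
})

test_that("replay buffer keeps FIFO order and samples requested batches", {
  buf <- cellmigrl:::replay_new(5L, 3L)
  for (i in 1:7)
    cellmigrl:::replay_add(buf, rep(i, 3), i %% 2L, i, rep(i + 1, 3),
                           FALSE)
  expect_equal(buf$size, 5L)
  stored <- sort(vapply(buf$obs, `[[`, numeric(1), 1L))
  expect_equal(stored, 3:7)                       # oldest two evicted
  b <- cellmigrl:::replay_sample(buf, 64L)        # default batch size
  expect_equal(nrow(b$obs), 64L)
  expect_equal(length(b$act), 64L)
})

test_that("a gradient step changes only the online network", {
  net <- build_mlp_network(4L, 2L, hidden = c(16L), seed = 1L)
  cfg <- dqn_config(epochs = 1L, target_update_every = 3L, batch_size = 4L,
                    learning_rate = 1e-3, seed = 1L)
  learner <- cellmigrl:::qlearner_new(net, cfg)
  batch <- list(obs = matrix(runif(16), 4L), act = c(0L, 1L, 0L, 1L),
                rew = runif(4), nxt = matrix(runif(16), 4L),
                done = rep(FALSE, 4L), disc = rep(NA_real_, 4L))
  l1 <- cellmigrl:::qlearner_update(learner, batch)
  expect_false(identical(l1$net$layers[[1L]]$W, net$layers[[1L]]$W))
  expect_identical(l1$target, net)                # unchanged off-sync
  l2 <- cellmigrl:::qlearner_update(l1, batch)
  l3 <- cellmigrl:::qlearner_update(l2, batch)    # iter 3 = sync point
  expect_identical(l3$target, l3$net)
})

test_that("DQN on the chain MDP recovers the value-iteration policy", {
  env <- chain_env()
  cfg <- dqn_config(epochs = 60L, learning_rate = 3e-3, batch_size = 32L,
                    target_update_every = 50L, gamma = 0.9, warmup = 32L,
                    replay_capacity = 2000L, greedy_start = 0.2,
                    greedy_end = 0.9, seed = 4L)
  fit <- train_dqn(env, cfg)
  expect_length(fit$learning_curve, 60L)
  greedy <- vapply(1:5, function(s) {
    obs <- as.numeric(1:5 == s)
    which.max(policy_values(fit$policy, obs)) - 1L
  }, integer(1))
  expect_equal(greedy, chain_value_iteration())   # oracle equivalence
})

test_that("meta subgoal selection is greedy over candidate values", {
  meta <- build_mlp_network(10L, 1L, hidden = c(16L, 16L), seed = 1L)
  cands <- lapply(1:4, function(i)
    list(pair = c(paste0("a", i), paste0("b", i)), features = runif(10)))
  vals <- vapply(cands, function(cc)
    policy_values(meta, cc$features)[1L], numeric(1))
  pick <- meta_select_subgoal(cands, meta, greedy_factor = 1)
  expect_equal(pick$index, which.max(vals))
  # single candidate chosen regardless of the greedy factor
  one <- meta_select_subgoal(cands[2L], meta, greedy_factor = 0)
  expect_equal(one$pair, cands[[2L]]$pair)
  # empty candidate set falls back to the target with a message
  expect_message(out <- meta_select_subgoal(list(), meta), "target")
  expect_null(out)
})

test_that("hypothesis gating routes the agents", {
  sc <- corridor_fixture()
  env_g <- create_tissue_env(sc$series, "Cpaaa", "ABarpaapp",
                             hypothesis = "gradient", image_size = 32L)
  env_s <- create_tissue_env(sc$series, "Cpaaa", "ABarpaapp",
                             hypothesis = "subgoal", image_size = 32L)
  expect_error(train_dqn(env_s, dqn_config(epochs = 1L)), "gradient")
  expect_error(train_hdqn(env_g, hdqn_config()), "subgoal")
})

test_that("ensemble evaluation returns aligned traces with a sd band", {
  sc <- corridor_fixture()
  env <- create_tissue_env(sc$series, "Cpaaa", "ABarpaapp",
                           hypothesis = "gradient", image_size = 32L,
                           noise_halfwidth = 0)
  net <- build_policy_network(c(2L, 32L, 32L), seed = 1L)
  res <- evaluate_policy(env, net, n_runs = 5L)
  expect_s3_class(res, "ensemble_result")
  expect_length(res$runs, 5L)
  expect_equal(length(res$mean_distance_curve), length(res$sd_band))
  # deterministic env + greedy policy + same seed: zero sd band
  res2 <- evaluate_policy(env, net, n_runs = 3L, seeds = rep(42L, 3L))
  expect_true(all(res2$sd_band == 0, na.rm = TRUE))
  expect_equal(length(res2$mean_distance_curve),
               length(res2$runs[[1L]]$distance))
})
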