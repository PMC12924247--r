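# Single-threaded BLAS keeps seeded training runs reproducible across hosts.
Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")

# Desk-scale training configurations used by the learning checks: 32x32
# observations on the 20-cell corridor scenario, within the 200-epoch cap.
scaled_dqn_config <- function(seed) {
  dqn_config(epochs = 150L, learning_rate = 1e-3, batch_size = 64L,
             target_update_every = 200L, gamma = 0.95, nstep = 3L,
             reward_clip = 10, explore_sticky = 0.5, action_repeat = 5L,
             huber_delta = 5, warmup = 100L, replay_capacity = 5000L,
             eval_every = 25L, eval_episodes = 5L, seed = seed)
}

scaled_hdqn_config <- function(seed) {
  hdqn_config(
    controller = dqn_config(epochs = 150L, learning_rate = 1e-3,
                            batch_size = 32L, target_update_every = 200L,
                            gamma = 0.95, nstep = 3L, reward_clip = 10,
                            action_repeat = 5L, huber_delta = 5,
                            greedy_start = 0.8, greedy_end = 0.95,
                            warmup = 100L, replay_capacity = 5000L,
                            eval_every = 25L, eval_episodes = 5L,
                            seed = seed),
    horizon = 8L, seed = seed)
}

# one trained gradient-hypothesis policy, shared between the learning and
# the neighbor-ablation checks
trained_dqn_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- corridor_fixture()
      env <- create_tissue_env(sc$series, "Cpaaa", "ABarpaapp",
                               hypothesis = "gradient", image_size = 32L,
                               seed = 1L)
      cache <<- train_dqn(env, scaled_dqn_config(1L))
    }
    cache
  }
})
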