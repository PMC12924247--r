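## Minimal neural-network machinery (no deep-learning framework in the R
## stack): dense and 2-D convolutional layers with ReLU, im2col-based conv
## via matrix products, Adam, and a DQN loop with replay and a target
## network. Sized for the small observation stacks this package produces.

# im2col gather indices for one conv layer on a square C x H x H input with
# channel-major (C, H, W) row-major flattening. Rows: (channel, kr, kc)
# receptive-field entries; columns: output positions (row-major).
make_im2col_idx <- function(C, H, k, s) {
  o <- (H - k) %/% s + 1L
  idx <- matrix(0L, C * k * k, o * o)
  for (orow in seq_len(o)) {
    for (ocol in seq_len(o)) {
      p <- (orow - 1L) * o + ocol
      r0 <- (orow - 1L) * s
      c0 <- (ocol - 1L) * s
      q <- 1L
      for (ch in seq_len(C))
        for (kr in seq_len(k))
          for (kc in seq_len(k)) {
            idx[q, p] <- (ch - 1L) * H * H + (r0 + kr - 1L) * H +
              (c0 + kc)
            q <- q + 1L
          }
    }
  }
  list(idx = idx, o = o)
}

dense_layer <- function(n_in, n_out, activation = "relu") {
  sd <- sqrt(2 / n_in)
  list(type = "dense", activation = activation,
       W = matrix(stats::rnorm(n_in * n_out, 0, sd), n_in, n_out),
       b = numeric(n_out))
}

conv_layer <- function(C_in, H_in, channels, kernel, stride) {
  im <- make_im2col_idx(C_in, H_in, kernel, stride)
  K <- C_in * kernel * kernel
  sd <- sqrt(2 / K)
  # precomputed scatter-add mapping for the backward pass: receptive-field
  # entries sorted by their input index, with run-length pointers
  g <- as.vector(im$idx)
  ord <- order(g)
  gs <- g[ord]
  runs <- rle(gs)
  list(type = "conv", idx = im$idx, P = im$o * im$o, o = im$o,
       C_in = C_in, H_in = H_in, C_out = channels,
       n_in = C_in * H_in * H_in,
       sc_ord = ord, sc_targets = runs$values,
       sc_ptr = c(0L, cumsum(runs$lengths)),
       W = matrix(stats::rnorm(channels * K, 0, sd), channels, K),
       b = numeric(channels))
}

net_forward <- function(net, X, keep_cache = FALSE) {
  cache <- if (keep_cache) vector("list", length(net$layers)) else NULL
  cur <- X
  B <- nrow(X)
  for (li in seq_along(net$layers)) {
    l <- net$layers[[li]]
    if (l$type == "conv") {
      K <- nrow(l$idx); P <- ncol(l$idx)
      idxv <- as.vector(l$idx)
      cols <- matrix(0, K, B * P)
      for (b in seq_len(B))
        cols[, (b - 1L) * P + seq_len(P)] <-
          matrix(cur[b, ][idxv], K, P)
      Z <- l$W %*% cols + l$b
      A <- Z * (Z > 0)
      nxt <- matrix(0, B, l$C_out * P)
      for (b in seq_len(B))
        nxt[b, ] <- as.vector(t(A[, (b - 1L) * P + seq_len(P),
                                  drop = FALSE]))
      if (keep_cache) cache[[li]] <- list(cols = cols, Z = Z, n_in = ncol(cur))
      cur <- nxt
    } else {
      Z <- cur %*% l$W + matrix(l$b, B, length(l$b), byrow = TRUE)
      A <- if (l$activation == "relu") Z * (Z > 0) else Z
      if (keep_cache) cache[[li]] <- list(X = cur, Z = Z)
      cur <- A
    }
  }
  list(out = cur, cache = cache)
}

net_backward <- function(net, cache, dOut) {
  grads <- vector("list", length(net$layers))
  d <- dOut
  B <- nrow(dOut)
  for (li in rev(seq_along(net$layers))) {
    l <- net$layers[[li]]
    cc <- cache[[li]]
    if (l$type == "dense") {
      dZ <- if (l$activation == "relu") d * (cc$Z > 0) else d
      grads[[li]] <- list(dW = crossprod(cc$X, dZ), db = colSums(dZ))
      d <- tcrossprod(dZ, l$W)
    } else {
      P <- ncol(l$idx)
      dA <- matrix(0, l$C_out, B * P)
      for (b in seq_len(B))
        dA[, (b - 1L) * P + seq_len(P)] <-
          t(matrix(d[b, ], P, l$C_out))
      dZ <- dA * (cc$Z > 0)
      grads[[li]] <- list(dW = tcrossprod(dZ, cc$cols), db = rowSums(dZ))
      if (li == 1L) next  # input gradient never needed
      dcols <- crossprod(l$W, dZ)
      np <- length(l$sc_ptr)
      dprev <- matrix(0, B, cc$n_in)
      for (b in seq_len(B)) {
        v <- as.vector(dcols[, (b - 1L) * P + seq_len(P),
                             drop = FALSE])[l$sc_ord]
        cum <- c(0, cumsum(v))
        dprev[b, l$sc_targets] <- cum[l$sc_ptr[-1L] + 1L] -
          cum[l$sc_ptr[-np] + 1L]
      }
      d <- dprev
    }
  }
  grads
}

adam_new <- function(net) {
  lapply(net$layers, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
}

adam_apply <- function(net, grads, opt, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (li in seq_along(net$layers)) {
    g <- grads[[li]]
    o <- opt[[li]]
    o$mW <- beta1 * o$mW + (1 - beta1) * g$dW
    o$vW <- beta2 * o$vW + (1 - beta2) * g$dW^2
    o$mb <- beta1 * o$mb + (1 - beta1) * g$db
    o$vb <- beta2 * o$vb + (1 - beta2) * g$db^2
    corr1 <- 1 - beta1^t
    corr2 <- 1 - beta2^t
    net$layers[[li]]$W <- net$layers[[li]]$W -
      lr * (o$mW / corr1) / (sqrt(o$vW / corr2) + eps)
    net$layers[[li]]$b <- net$layers[[li]]$b -
      lr * (o$mb / corr1) / (sqrt(o$vb / corr2) + eps)
    opt[[li]] <- o
  }
  list(net = net, opt = opt)
}

#' Build the convolutional policy network
#'
#' The migrating cell's policy: two convolutional layers extracting
#' features from the 2-channel grayscale+depth observation, followed by a
#' fully connected layer and a linear head with one value per action.
#' Initialization is deterministic given the seed.
#'
#' @param input_shape \code{c(2, H, W)} observation shape.
#' @param n_actions number of discrete actions (default 8).
#' @param conv list of two \code{c(channels, kernel, stride)} triples;
#'   defaults \code{c(16, 8, 4)} and \code{c(32, 4, 2)}.
#' @param fc width of the fully connected layer (default 256).
#' @param seed integer.
#' @return object of class \code{policy_network}.
#' @export
build_policy_network <- function(input_shape = c(2L, 64L, 64L),
                                 n_actions = 8L,
                                 conv = list(c(16L, 8L, 4L), c(32L, 4L, 2L)),
                                 fc = 256L, seed = 1L) {
  if (length(input_shape) != 3L)
    stop("input_shape must be (channels, H, W)")
  if (input_shape[1L] != 2L)
    stop("expected 2 input channels (grayscale, depth); got ",
         input_shape[1L])
  if (input_shape[2L] != input_shape[3L] || input_shape[2L] < 8L)
    stop("observations must be square, at least 8 x 8")
  with_seed(seed, {
    layers <- list()
    C <- input_shape[1L]
    H <- input_shape[2L]
    for (cv in conv) {
      l <- conv_layer(C, H, cv[1L], cv[2L], cv[3L])
      layers[[length(layers) + 1L]] <- l
      C <- cv[1L]
      H <- l$o
    }
    n_flat <- C * H * H
    layers[[length(layers) + 1L]] <- dense_layer(n_flat, fc, "relu")
    layers[[length(layers) + 1L]] <- dense_layer(fc, n_actions, "linear")
    structure(list(layers = layers, input_shape = input_shape,
                   n_actions = n_actions, seed = seed, kind = "cnn"),
              class = "policy_network")
  })
}

#' Build a fully connected policy / value network
#'
#' Used for the hierarchical meta-controller (default hidden sizes 512,
#' 1024, 1024 with a single value output) and for vector-state sanity
#' environments.
#'
#' @param n_in input feature dimension.
#' @param n_out outputs (action values, or 1 for the meta value).
#' @param hidden integer vector of hidden widths.
#' @param seed integer.
#' @return object of class \code{policy_network}.
#' @export
build_mlp_network <- function(n_in, n_out, hidden = c(512L, 1024L, 1024L),
                              seed = 1L) {
  with_seed(seed, {
    sizes <- c(n_in, hidden)
    layers <- list()
    for (i in seq_along(hidden))
      layers[[i]] <- dense_layer(sizes[i], sizes[i + 1L], "relu")
    layers[[length(layers) + 1L]] <-
      dense_layer(sizes[length(sizes)], n_out, "linear")
    structure(list(layers = layers, input_shape = n_in, n_actions = n_out,
                   seed = seed, kind = "mlp"),
              class = "policy_network")
  })
}

#' Action values of a policy for a batch of observations
#'
#' @param policy \code{policy_network}.
#' @param X matrix with one flattened observation per row (channel-major
#'   row-major layout; see \code{build_policy_network}), or a single
#'   observation array/vector.
#' @return matrix of action values, one row per observation.
#' @export
policy_values <- function(policy, X) {
  if (is.array(X) && length(dim(X)) == 3L) X <- flatten_obs(X)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  net_forward(policy, X)$out
}

policy_count_params <- function(policy) {
  sum(vapply(policy$layers, function(l) length(l$W) + length(l$b),
             numeric(1)))
}

#' Exploitation-probability schedule
#'
#' Linear interpolation of the greedy factor (the probability of taking
#' the argmax action) from \code{start} at epoch 0 to \code{end} at the
#' final epoch; exploration decays accordingly.
#'
#' @param epoch current epoch (0-based).
#' @param total_epochs final epoch index (> 0).
#' @param start,end greedy probabilities (defaults 0.3 and 0.95).
#' @return greedy probability.
#' @export
greedy_schedule <- function(epoch, total_epochs, start = 0.3, end = 0.95) {
  stopifnot(epoch >= 0, epoch <= total_epochs)
  if (total_epochs == 0) return(end)
  start + (end - start) * epoch / total_epochs
}

## ---- replay buffer ------------------------------------------------------

# Observations are kept as list elements (not matrix rows) so FIFO writes
# never trigger a copy of the whole store.
replay_new <- function(capacity, obs_dim) {
  buf <- new.env(parent = emptyenv())
  buf$capacity <- as.integer(capacity)
  buf$obs <- vector("list", capacity)
  buf$nxt <- vector("list", capacity)
  buf$act <- integer(capacity)
  buf$rew <- numeric(capacity)
  buf$disc <- numeric(capacity)
  buf$done <- logical(capacity)
  buf$size <- 0L
  buf$pos <- 0L
  buf
}

replay_add <- function(buf, s, a, r, s2, d, disc = NA_real_) {
  buf$pos <- buf$pos %% buf$capacity + 1L
  buf$obs[[buf$pos]] <- s
  buf$act[buf$pos] <- a
  buf$rew[buf$pos] <- r
  buf$nxt[[buf$pos]] <- s2
  buf$done[buf$pos] <- d
  buf$disc[buf$pos] <- disc
  buf$size <- min(buf$size + 1L, buf$capacity)
  invisible(buf)
}

replay_sample <- function(buf, n) {
  idx <- sample.int(buf$size, n, replace = buf$size < n)
  list(obs = do.call(rbind, buf$obs[idx]), act = buf$act[idx],
       rew = buf$rew[idx], nxt = do.call(rbind, buf$nxt[idx]),
       done = buf$done[idx], disc = buf$disc[idx])
}

## ---- generic RL environment interface ----------------------------------

#' Wrap reset/step functions as a lightweight RL environment
#'
#' Lets the DQN machinery run on vector-state environments (e.g. small
#' diagnostic MDPs) through the same interface as the tissue environment.
#'
#' @param reset function(seed) -> observation vector.
#' @param step function(action) -> list(obs, reward, done).
#' @param n_actions number of discrete actions.
#' @return object of class \code{rl_env}.
#' @export
rl_env <- function(reset, step, n_actions) {
  structure(list(reset = reset, step = step, n_actions = n_actions),
            class = "rl_env")
}

rl_reset <- function(env, seed = NULL) {
  if (inherits(env, "tissue_env")) flatten_obs(env_reset(env, seed))
  else env$reset(seed)
}

rl_step <- function(env, action) {
  if (inherits(env, "tissue_env")) {
    res <- env_step(env, action)
    list(obs = flatten_obs(res$observation), reward = res$reward$total,
         done = res$done, info = res$info)
  } else env$step(action)
}

rl_n_actions <- function(env)
  if (inherits(env, "tissue_env")) env$n_actions else env$n_actions

## ---- DQN ----------------------------------------------------------------

#' DQN training configuration
#'
#' Defaults follow the reference training setup: Adam with beta1 = 0.9 and
#' beta2 = 0.999, learning rate 1e-4, batch size 64, target network synced
#' every 1000 gradient steps, greedy factor growing linearly from 0.3 to
#' 0.95 over the epochs. Epoch count, discount and replay capacity are
#' deployment-scale choices and should be scaled down for desktop runs.
#'
#' @param epochs training epochs (one episode rollout each).
#' @param learning_rate Adam step size.
#' @param batch_size replay minibatch size.
#' @param target_update_every gradient steps between target-network syncs.
#' @param greedy_start,greedy_end greedy-factor schedule endpoints.
#' @param replay_capacity transitions kept (FIFO).
#' @param gamma discount factor.
#' @param warmup minimum buffer size before updates start.
#' @param updates_per_step gradient updates per environment step.
#' @param conv,fc network shape (see \code{\link{build_policy_network}}).
#' @param huber_delta TD-error clipping scale of the Huber loss.
#' @param nstep multi-step return length for the TD target (1 = one-step
#'   Q-learning); short n-step returns speed up propagation of the dense
#'   gradient reward in scaled-down runs.
#' @param reward_clip optional symmetric bound: per-step rewards are
#'   clipped to [-reward_clip, reward_clip] inside the learner (the
#'   environment still reports unclipped rewards), keeping the sparse
#'   overlap penalty from dominating the value scale -- the usual DQN
#'   reward-clipping device.
#' @param explore_sticky probability of repeating the previous action when
#'   exploring (persistent exploration; 0 = plain uniform).
#' @param action_repeat frames each chosen action is applied for (DQN
#'   frame-skip); 1 = decide every frame.
#' @param double_dqn use the online network to select the bootstrap action
#'   (Double DQN) instead of a plain max.
#' @param eval_every if > 0, run a few greedy evaluation episodes every
#'   this many epochs and return the best-scoring checkpoint rather than
#'   the last one.
#' @param eval_episodes greedy episodes per checkpoint evaluation.
#' @param seed integer; training is deterministic given the seed.
#' @return list of class \code{dqn_config}.
#' @export
dqn_config <- function(epochs = 900L, learning_rate = 1e-4,
                       batch_size = 64L, target_update_every = 1000L,
                       greedy_start = 0.3, greedy_end = 0.95,
                       replay_capacity = 1e5, gamma = 0.95,
                       warmup = 200L, updates_per_step = 1L,
                       conv = list(c(16L, 8L, 4L), c(32L, 4L, 2L)),
                       fc = 256L, huber_delta = 1, nstep = 1L,
                       reward_clip = NULL, explore_sticky = 0,
                       action_repeat = 1L, double_dqn = TRUE,
                       eval_every = 0L, eval_episodes = 5L, seed = 1L) {
  stopifnot(greedy_start >= 0, greedy_start <= greedy_end, greedy_end <= 1,
            epochs >= 1, batch_size >= 1)
  structure(as.list(environment()), class = "dqn_config")
}

# apply one action for k frames (or until the episode ends), accumulating
# the (optionally per-frame clipped) reward
rl_step_repeat <- function(env, a, k, clip = NULL) {
  total <- 0
  raw <- 0
  terminal <- FALSE
  for (i in seq_len(k)) {
    res <- rl_step(env, a)
    r <- res$reward
    raw <- raw + r
    if (!is.null(clip)) r <- pmin(pmax(r, -clip), clip)
    total <- total + r
    terminal <- terminal || isTRUE(res$info$destination_paid)
    if (res$done) break
  }
  list(obs = res$obs, reward = total, raw_reward = raw, done = res$done,
       terminal = terminal, info = res$info)
}

qlearner_new <- function(net, config) {
  list(net = net, target = net, opt = adam_new(net), iter = 0L,
       config = config)
}

# One Q-learning gradient step on a replay batch. Only the online network
# changes; the target network is replaced at sync points only.
qlearner_update <- function(learner, batch) {
  cfg <- learner$config
  B <- nrow(batch$obs)
  qn <- net_forward(learner$target, batch$nxt)$out
  boot <- if (isTRUE(cfg$double_dqn)) {
    sel_a <- max.col(net_forward(learner$net, batch$nxt)$out,
                     ties.method = "first")
    qn[cbind(seq_len(B), sel_a)]
  } else apply(qn, 1L, max)
  disc <- ifelse(is.na(batch$disc), cfg$gamma, batch$disc)
  target <- batch$rew + disc * (!batch$done) * boot
  fwd <- net_forward(learner$net, batch$obs, keep_cache = TRUE)
  sel <- cbind(seq_len(B), batch$act + 1L)
  delta <- fwd$out[sel] - target
  # Huber gradient: clip TD errors so sparse large penalties cannot blow up
  dsel <- pmin(pmax(delta, -cfg$huber_delta), cfg$huber_delta) / B
  dOut <- matrix(0, B, ncol(fwd$out))
  dOut[sel] <- dsel
  grads <- net_backward(learner$net, fwd$cache, dOut)
  learner$iter <- learner$iter + 1L
  upd <- adam_apply(learner$net, grads, learner$opt, cfg$learning_rate,
                    learner$iter)
  learner$net <- upd$net
  learner$opt <- upd$opt
  if (learner$iter %% cfg$target_update_every == 0L)
    learner$target <- learner$net
  learner
}

#' Train a DQN agent (gradient hypothesis)
#'
#' Standard deep Q-learning: epsilon-greedy episode rollouts, uniform
#' replay sampling, TD targets from a periodically synced target network,
#' Adam updates with a Huber-clipped TD error. One epoch is one episode
#' rollout plus its gradient updates.
#'
#' @param env a \code{tissue_env} with the gradient hypothesis, or an
#'   \code{\link{rl_env}}.
#' @param config \code{\link{dqn_config}}.
#' @param net optional pre-built network (default built from the first
#'   observation's length).
#' @param progress print a line every few epochs.
#' @return list with \code{policy} (trained network), \code{learning_curve}
#'   (per-epoch return), \code{success} (per-epoch destination flag where
#'   applicable), and \code{config}.
#' @export
train_dqn <- function(env, config = dqn_config(), net = NULL,
                      progress = FALSE) {
  if (inherits(env, "tissue_env") && env$hypothesis != "gradient")
    stop("train_dqn requires the gradient hypothesis; use train_hdqn")
  n_actions <- rl_n_actions(env)
  with_seed(derive_seed(config$seed, "train_dqn"), {
    s0 <- rl_reset(env, derive_seed(config$seed, "probe"))
    obs_dim <- length(s0)
    if (is.null(net)) {
      net <- if (inherits(env, "tissue_env")) {
        S <- env$camera$image_size
        build_policy_network(c(2L, S, S), n_actions, conv = config$conv,
                             fc = config$fc, seed = config$seed)
      } else {
        build_mlp_network(obs_dim, n_actions, hidden = c(64L, 64L),
                          seed = config$seed)
      }
    }
    learner <- qlearner_new(net, config)
    buf <- replay_new(config$replay_capacity, obs_dim)
    curve <- numeric(config$epochs)
    success <- logical(config$epochs)
    best <- NULL
    for (ep in seq_len(config$epochs)) {
      gp <- greedy_schedule(ep - 1, max(config$epochs - 1, 1),
                            config$greedy_start, config$greedy_end)
      s <- rl_reset(env, derive_seed(config$seed, paste0("ep", ep)))
      done <- FALSE
      ret <- 0
      # pending window for n-step returns
      pend_s <- list(); pend_a <- integer(); pend_r <- numeric()
      nstep <- config$nstep
      prev_a <- NA_integer_
      while (!done) {
        a <- if (stats::runif(1) < gp)
          which.max(net_forward(learner$net, matrix(s, 1L))$out) - 1L
        else if (!is.na(prev_a) && stats::runif(1) < config$explore_sticky)
          prev_a
        else sample.int(n_actions, 1L) - 1L
        prev_a <- a
        res <- rl_step_repeat(env, a, config$action_repeat,
                              config$reward_clip)
        # time-limit truncations bootstrap through; only reaching the
        # destination is a true terminal state for the TD target
        terminal <- res$terminal
        pend_s[[length(pend_s) + 1L]] <- s
        pend_a <- c(pend_a, a)
        pend_r <- c(pend_r, res$reward)
        if (length(pend_r) >= nstep) {
          R <- sum(config$gamma^(seq_along(pend_r) - 1L) * pend_r)
          replay_add(buf, pend_s[[1L]], pend_a[1L], R, res$obs, terminal,
                     disc = config$gamma^length(pend_r))
          pend_s <- pend_s[-1L]; pend_a <- pend_a[-1L]; pend_r <- pend_r[-1L]
        }
        ret <- ret + res$raw_reward
        s <- res$obs
        done <- res$done
        if (terminal) success[ep] <- TRUE
        if (done && length(pend_r)) {
          for (j in seq_along(pend_r)) {
            rj <- pend_r[j:length(pend_r)]
            R <- sum(config$gamma^(seq_along(rj) - 1L) * rj)
            replay_add(buf, pend_s[[j]], pend_a[j], R, res$obs, terminal,
                       disc = config$gamma^length(rj))
          }
        }
        if (buf$size >= max(config$warmup, config$batch_size))
          for (u in seq_len(config$updates_per_step))
            learner <- qlearner_update(learner,
                                       replay_sample(buf, config$batch_size))
      }
      curve[ep] <- ret
      if (config$eval_every > 0L &&
          (ep %% config$eval_every == 0L || ep == config$epochs)) {
        sc_succ <- 0
        sc_ret <- 0
        for (ev in seq_len(config$eval_episodes)) {
          es <- rl_reset(env, derive_seed(config$seed,
                                          paste0("ckpt", ep, "_", ev)))
          edone <- FALSE
          eterm <- FALSE
          while (!edone) {
            ea <- which.max(net_forward(learner$net,
                                        matrix(es, 1L))$out) - 1L
            eres <- rl_step_repeat(env, ea, config$action_repeat,
                                   config$reward_clip)
            es <- eres$obs
            edone <- eres$done
            eterm <- eterm || eres$terminal
            sc_ret <- sc_ret + eres$raw_reward
          }
          sc_succ <- sc_succ + eterm
        }
        score <- sc_succ * 1e9 + sc_ret
        if (is.null(best) || score > best$score)
          best <- list(score = score, net = learner$net, epoch = ep,
                       success = sc_succ / config$eval_episodes)
      }
      if (progress && ep %% 10L == 0L)
        message("epoch ", ep, "/", config$epochs, " return ",
                signif(ret, 4), " greedy ", signif(gp, 3))
    }
    policy <- if (!is.null(best)) best$net else learner$net
    attr(policy, "action_repeat") <- config$action_repeat
    list(policy = policy, learning_curve = curve, success = success,
         best_checkpoint = if (!is.null(best))
           list(epoch = best$epoch, success = best$success),
         config = config)
  })
}

## ---- hierarchical DQN ---------------------------------------------------

#' H-DQN training configuration
#'
#' The meta-controller is a fully connected network (hidden sizes 512,
#' 1024, 1024) selecting subgoal pairs from secondary neighbors; the
#' controller shares the convolutional policy shape but uses batch size 32
#' and a greedy factor growing from 0.8 to 0.95. Subgoal and destination
#' rewards are 10 and 100 (in \code{\link{reward_config}}).
#'
#' @param controller \code{\link{dqn_config}} for the low-level module.
#' @param meta_hidden hidden sizes of the meta network.
#' @param meta_lr meta Adam step size.
#' @param meta_gamma per-step discount applied to meta returns.
#' @param meta_batch meta replay minibatch size.
#' @param horizon controller steps before the meta re-selects a subgoal
#'   (re-selection also happens on achievement).
#' @param seed integer.
#' @return list of class \code{hdqn_config}.
#' @export
hdqn_config <- function(controller = dqn_config(batch_size = 32L,
                                                greedy_start = 0.8,
                                                greedy_end = 0.95),
                        meta_hidden = c(512L, 1024L, 1024L),
                        meta_lr = 1e-4, meta_gamma = 0.95,
                        meta_batch = 16L, horizon = 25L, seed = 1L) {
  structure(as.list(environment()), class = "hdqn_config")
}

# z-scored meta features: agent position, the candidate pair's positions,
# and the current distance to target.
meta_features <- function(env, pair) {
  tab <- env$cell_table
  sc <- env$feat_scale
  p <- env$agent_pos
  pa <- unlist(tab[tab$name == pair[1L], c("x", "y", "z")])
  pb <- unlist(tab[tab$name == pair[2L], c("x", "y", "z")])
  d <- vec_norm(p - env_target_pos(env))
  c((p - sc$mu) / sc$sd, (pa - sc$mu) / sc$sd, (pb - sc$mu) / sc$sd,
    d / sc$d0)
}

meta_candidates <- function(env) {
  sec <- secondary_neighbors(env$cell_table, env$migrating,
                             env$neighbor_model, env$ratio_cutoff)
  if (length(sec) < 2L) return(list())
  pairs <- utils::combn(sort(sec), 2L)
  lapply(seq_len(ncol(pairs)), function(i)
    list(pair = pairs[, i], features = meta_features(env, pairs[, i])))
}

#' Epsilon-greedy subgoal selection by the meta-controller
#'
#' @param candidates list of candidates, each with \code{pair} (two cell
#'   names) and \code{features} (meta feature vector including the current
#'   migrating-cell position).
#' @param meta_policy meta \code{policy_network} (scalar value head).
#' @param greedy_factor probability of picking the argmax candidate.
#' @return the chosen candidate (list with pair, features, index), or NULL
#'   with a message when there are no candidates (the final target then
#'   becomes the goal).
#' @export
meta_select_subgoal <- function(candidates, meta_policy, greedy_factor = 1) {
  if (!length(candidates)) {
    message("no secondary-neighbor subgoal candidates; ",
            "falling back to the final target as the goal")
    return(NULL)
  }
  X <- do.call(rbind, lapply(candidates, `[[`, "features"))
  vals <- net_forward(meta_policy, X)$out[, 1L]
  i <- if (length(candidates) == 1L || stats::runif(1) < greedy_factor)
    which.max(vals)
  else sample.int(length(candidates), 1L)
  c(candidates[[i]], list(index = i))
}

#' Train a two-level hierarchical DQN agent (subgoal hypothesis)
#'
#' The meta-controller picks subgoal pairs from the migrating cell's
#' secondary neighbors and is trained on the extrinsic (environment)
#' return accumulated while each subgoal is pursued; the controller learns
#' primitive movements from the environment reward, which under the
#' subgoal hypothesis pays +10 per achieved subgoal and +100 at the
#' destination. A new subgoal is selected on achievement or after
#' \code{horizon} controller steps.
#'
#' @param env \code{tissue_env} with the subgoal hypothesis.
#' @param config \code{\link{hdqn_config}}.
#' @param progress print progress lines.
#' @return list with \code{meta_policy}, \code{controller_policy},
#'   \code{learning_curve}, \code{success}, \code{config}.
#' @export
train_hdqn <- function(env, config = hdqn_config(), progress = FALSE) {
  if (!inherits(env, "tissue_env") || env$hypothesis != "subgoal")
    stop("train_hdqn requires a tissue environment with the subgoal ",
         "hypothesis")
  ccfg <- config$controller
  with_seed(derive_seed(config$seed, "train_hdqn"), {
    # feature scaling from the window's coordinate spread
    win_cells <- env$series$cells[
      env$series$cells$frame >= env$window["start"] &
        env$series$cells$frame <= env$window["end"], ]
    env$feat_scale <- list(
      mu = c(mean(win_cells$x), mean(win_cells$y), mean(win_cells$z)),
      sd = pmax(c(stats::sd(win_cells$x), stats::sd(win_cells$y),
                  stats::sd(win_cells$z)), 1e-6),
      d0 = env$d0)
    S <- env$camera$image_size
    ctrl_net <- build_policy_network(c(2L, S, S), env$n_actions,
                                     conv = ccfg$conv, fc = ccfg$fc,
                                     seed = ccfg$seed)
    ctrl <- qlearner_new(ctrl_net, ccfg)
    meta_net <- build_mlp_network(10L, 1L, hidden = config$meta_hidden,
                                  seed = derive_seed(config$seed, "meta"))
    meta_opt <- adam_new(meta_net)
    meta_iter <- 0L
    meta_mem <- list()
    buf <- replay_new(ccfg$replay_capacity, 2L * S * S)
    curve <- numeric(ccfg$epochs)
    success <- logical(ccfg$epochs)
    best <- NULL

    for (ep in seq_len(ccfg$epochs)) {
      gp <- greedy_schedule(ep - 1, max(ccfg$epochs - 1, 1),
                            ccfg$greedy_start, ccfg$greedy_end)
      s <- rl_reset(env, derive_seed(config$seed, paste0("ep", ep)))
      done <- FALSE
      ret <- 0
      while (!done) {
        cands <- meta_candidates(env)
        chosen <- suppressMessages(
          meta_select_subgoal(cands, meta_net, gp))
        if (is.null(chosen)) env_set_subgoal(env, NULL)
        else env_set_subgoal(env, chosen$pair)
        ext <- 0
        k <- 0L
        # n-step pending window within the subgoal segment
        pend_s <- list(); pend_a <- integer(); pend_r <- numeric()
        seg_done <- FALSE
        while (!seg_done) {
          a <- if (stats::runif(1) < gp)
            which.max(net_forward(ctrl$net, matrix(s, 1L))$out) - 1L
          else sample.int(env$n_actions, 1L) - 1L
          res <- rl_step_repeat(env, a, ccfg$action_repeat,
                                ccfg$reward_clip)
          pend_s[[length(pend_s) + 1L]] <- s
          pend_a <- c(pend_a, a)
          pend_r <- c(pend_r, res$reward)
          if (length(pend_r) >= ccfg$nstep) {
            R <- sum(ccfg$gamma^(seq_along(pend_r) - 1L) * pend_r)
            replay_add(buf, pend_s[[1L]], pend_a[1L], R, res$obs,
                       res$terminal, disc = ccfg$gamma^length(pend_r))
            pend_s <- pend_s[-1L]; pend_a <- pend_a[-1L]
            pend_r <- pend_r[-1L]
          }
          ext <- ext + config$meta_gamma^k * res$reward
          ret <- ret + res$raw_reward
          s <- res$obs
          done <- res$done
          k <- k + 1L
          if (res$terminal) success[ep] <- TRUE
          if (buf$size >= max(ccfg$warmup, ccfg$batch_size))
            ctrl <- qlearner_update(ctrl, replay_sample(buf, ccfg$batch_size))
          achieved <- !is.null(env$active_subgoal) && env$subgoal_paid
          seg_done <- done || achieved || k >= config$horizon
          if (seg_done && length(pend_r)) {
            for (j in seq_along(pend_r)) {
              rj <- pend_r[j:length(pend_r)]
              R <- sum(ccfg$gamma^(seq_along(rj) - 1L) * rj)
              replay_add(buf, pend_s[[j]], pend_a[j], R, res$obs,
                         res$terminal, disc = ccfg$gamma^length(rj))
            }
          }
        }
        if (!is.null(chosen)) {
          nxt_feats <- if (done) NULL
          else do.call(rbind, lapply(meta_candidates(env), `[[`, "features"))
          meta_mem[[length(meta_mem) + 1L]] <-
            list(feat = chosen$features, r = ext, k = k, nxt = nxt_feats,
                 done = done)
          if (length(meta_mem) > 2000L)
            meta_mem <- meta_mem[-1L]
          # meta Q update on a small replay batch
          if (length(meta_mem) >= config$meta_batch) {
            idx <- sample.int(length(meta_mem), config$meta_batch)
            X <- do.call(rbind, lapply(meta_mem[idx], `[[`, "feat"))
            tgt <- vapply(meta_mem[idx], function(tr) {
              if (tr$done || is.null(tr$nxt) || !nrow(tr$nxt)) tr$r
              else tr$r + config$meta_gamma^tr$k *
                max(net_forward(meta_net, tr$nxt)$out)
            }, numeric(1))
            fwd <- net_forward(meta_net, X, keep_cache = TRUE)
            delta <- fwd$out[, 1L] - tgt
            dOut <- matrix(pmin(pmax(delta, -1), 1) / length(delta),
                           ncol = 1L)
            grads <- net_backward(meta_net, fwd$cache, dOut)
            meta_iter <- meta_iter + 1L
            upd <- adam_apply(meta_net, grads, meta_opt, config$meta_lr,
                              meta_iter)
            meta_net <- upd$net
            meta_opt <- upd$opt
          }
        }
      }
      curve[ep] <- ret
      if (ccfg$eval_every > 0L &&
          (ep %% ccfg$eval_every == 0L || ep == ccfg$epochs)) {
        cand <- list(meta_policy = meta_net, controller_policy = ctrl$net)
        attr(cand$controller_policy, "action_repeat") <- ccfg$action_repeat
        ev <- evaluate_policy(env, cand, n_runs = ccfg$eval_episodes,
                              seeds = derive_seed(config$seed, "hdeval") +
                                seq_len(ccfg$eval_episodes),
                              horizon = config$horizon)
        score <- ev$success_rate * 1e9 +
          sum(vapply(ev$runs, function(r) sum(r$rewards), numeric(1)))
        if (is.null(best) || score > best$score)
          best <- list(score = score, pair = cand, epoch = ep,
                       success = ev$success_rate)
      }
      if (progress && ep %% 10L == 0L)
        message("epoch ", ep, "/", ccfg$epochs, " return ", signif(ret, 4))
    }
    out_pair <- if (!is.null(best)) best$pair
    else list(meta_policy = meta_net, controller_policy = ctrl$net)
    attr(out_pair$controller_policy, "action_repeat") <- ccfg$action_repeat
    c(out_pair,
      list(learning_curve = curve, success = success,
           best_checkpoint = if (!is.null(best))
             list(epoch = best$epoch, success = best$success),
           config = config))
  })
}

## ---- evaluation ---------------------------------------------------------

#' Evaluate a trained policy over an ensemble of greedy episodes
#'
#' Runs \code{n_runs} greedy episodes with distinct environment seeds and
#' collects per-step distance-to-target curves, the agent's 2-D top-view
#' path, success (destination reward paid) and arrival step, plus the
#' ensemble mean curve and its +/- 1 standard-deviation band.
#'
#' @param env tissue_env.
#' @param policy a \code{policy_network} (DQN) or a list with
#'   \code{meta_policy} and \code{controller_policy} (H-DQN).
#' @param n_runs number of episodes (default 5).
#' @param seeds optional explicit seeds, length \code{n_runs}.
#' @param horizon meta re-selection horizon for hierarchical policies.
#' @param action_repeat frames per policy decision; defaults to the value
#'   the policy was trained with (its \code{action_repeat} attribute).
#' @return list of class \code{ensemble_result}: \code{runs} (per-episode
#'   traces), \code{mean_distance_curve}, \code{sd_band},
#'   \code{success_rate}, \code{arrival_steps}.
#' @export
evaluate_policy <- function(env, policy, n_runs = 5L, seeds = NULL,
                            horizon = 25L, action_repeat = NULL) {
  stopifnot(inherits(env, "tissue_env"))
  hierarchical <- !inherits(policy, "policy_network")
  if (is.null(action_repeat))
    action_repeat <- attr(if (hierarchical) policy$controller_policy
                          else policy, "action_repeat") %||% 1L
  if (is.null(seeds)) seeds <- derive_seed(env$seed, "eval") + seq_len(n_runs)
  stopifnot(length(seeds) == n_runs)
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    s <- rl_reset(env, seeds[i])
    if (hierarchical && is.null(env$feat_scale)) {
      win_cells <- env$series$cells[
        env$series$cells$frame >= env$window["start"] &
          env$series$cells$frame <= env$window["end"], ]
      env$feat_scale <- list(
        mu = c(mean(win_cells$x), mean(win_cells$y), mean(win_cells$z)),
        sd = pmax(c(stats::sd(win_cells$x), stats::sd(win_cells$y),
                    stats::sd(win_cells$z)), 1e-6),
        d0 = env$d0)
    }
    done <- FALSE
    dist <- numeric()
    path <- NULL
    actions <- integer()
    rewards <- numeric()
    k_since <- 0L
    if (hierarchical) {
      chosen <- suppressMessages(
        meta_select_subgoal(meta_candidates(env), policy$meta_policy, 1))
      if (is.null(chosen)) env_set_subgoal(env, NULL)
      else env_set_subgoal(env, chosen$pair)
    }
    while (!done) {
      net <- if (hierarchical) policy$controller_policy else policy
      a <- which.max(net_forward(net, matrix(s, 1L))$out) - 1L
      for (rep_i in seq_len(action_repeat)) {
        res <- rl_step(env, a)
        s <- res$obs
        done <- res$done
        dist <- c(dist, res$info$distance)
        path <- rbind(path, res$info$agent_pos)
        actions <- c(actions, a)
        rewards <- c(rewards, res$reward)
        if (done) break
      }
      k_since <- k_since + 1L
      if (hierarchical && !done &&
          ((!is.null(env$active_subgoal) && env$subgoal_paid) ||
           k_since >= horizon)) {
        chosen <- suppressMessages(
          meta_select_subgoal(meta_candidates(env), policy$meta_policy, 1))
        if (is.null(chosen)) env_set_subgoal(env, NULL)
        else env_set_subgoal(env, chosen$pair)
        k_since <- 0L
      }
    }
    st <- env_get_state(env)
    runs[[i]] <- list(distance = dist, path = path, actions = actions,
                      rewards = rewards, success = st$done &&
                        env$destination_paid,
                      arrival_step = if (env$destination_paid)
                        st$steps_elapsed else NA_integer_,
                      seed = seeds[i])
  }
  len <- max(vapply(runs, function(r) length(r$distance), integer(1)))
  mat <- matrix(NA_real_, n_runs, len)
  for (i in seq_len(n_runs))
    mat[i, seq_along(runs[[i]]$distance)] <- runs[[i]]$distance
  mean_curve <- colMeans(mat, na.rm = TRUE)
  sd_band <- apply(mat, 2L, stats::sd, na.rm = TRUE)
  structure(list(runs = runs, mean_distance_curve = mean_curve,
                 sd_band = sd_band,
                 success_rate = mean(vapply(runs, `[[`, logical(1),
                                            "success")),
                 arrival_steps = vapply(runs, `[[`, integer(1),
                                        "arrival_step")),
            class = "ensemble_result")
}
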