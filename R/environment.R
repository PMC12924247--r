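#' Create a Gym-style tissue environment
#'
#' The environment replays the environment cells of an \code{embryo_series}
#' frame by frame over the migration window of the migrating/target pair,
#' while the migrating cell's position is controlled by an agent through
#' \code{\link{env_step}}. Rewards follow the three-part formulation: the
#' neighbor-distance term every step, the destination term (+100 on
#' becoming a stable neighbor of the target for 5 consecutive steps within
#' 90\% of the window), and -- depending on the hypothesis under test --
#' either the dense gradient term or the +10 subgoal term.
#'
#' The agent's average speed is derived from the data: the initial
#' migrating-to-target distance divided by the window length in steps; each
#' step's size adds truncated-normal noise of +/- 20\%.
#'
#' @param series embryo_series.
#' @param migrating,target cell names; their co-existence window must be
#'   non-empty.
#' @param config \code{\link{reward_config}}.
#' @param hypothesis \code{"gradient"} or \code{"subgoal"}.
#' @param seed integer seed of the environment's private RNG stream.
#' @param neighbor_model \code{"voronoi"} or a fitted
#'   \code{neighbor_classifier}.
#' @param ratio_cutoff Delaunay-edge pruning cutoff of the voronoi model.
#' @param image_size observation resolution (default 64, i.e. 2 x 64 x 64).
#' @param noise_halfwidth speed-noise half-width as a fraction (default
#'   0.2); 0 gives deterministic step sizes.
#' @param action_set \code{"xy8"}: 8 compass directions at 45 degrees in
#'   the xy plane with z held (the top-view observation pairs naturally
#'   with in-plane actions).
#' @return a mutable environment object of class \code{tissue_env}.
#' @export
create_tissue_env <- function(series, migrating, target,
                              config = reward_config(),
                              hypothesis = c("gradient", "subgoal"),
                              seed = 1L,
                              neighbor_model = "voronoi",
                              ratio_cutoff = 2.0,
                              image_size = 64L,
                              noise_halfwidth = 0.2,
                              action_set = "xy8") {
  validate_series(series)
  hypothesis <- match.arg(hypothesis)
  if (!migrating %in% series$cells$name)
    stop("migrating cell '", migrating, "' not in series")
  if (!target %in% series$cells$name)
    stop("target cell '", target, "' not in series")
  win <- migration_window(series, migrating, target)
  window_steps <- unname(win["end"] - win["start"])
  if (window_steps < 1L) stop("migration window has no steps")
  tab0 <- frame_table(series, win["start"])
  p_mig <- unlist(tab0[tab0$name == migrating, c("x", "y", "z")])
  p_tgt <- unlist(tab0[tab0$name == target, c("x", "y", "z")])
  d0 <- vec_norm(p_mig - p_tgt)
  if (d0 <= 0) stop("migrating and target coincide at window start")

  env <- new.env(parent = emptyenv())
  class(env) <- "tissue_env"
  env$series <- series
  env$migrating <- migrating
  env$target <- target
  env$config <- config
  env$hypothesis <- hypothesis
  env$neighbor_model <- neighbor_model
  env$ratio_cutoff <- ratio_cutoff
  env$window <- win
  env$window_steps <- window_steps
  env$budget_steps <- floor(config$time_budget_fraction * window_steps)
  env$speed <- list(v_avg = d0 / window_steps,
                    noise_halfwidth = noise_halfwidth)
  env$d0 <- d0
  env$seed <- as.integer(seed)
  env$n_actions <- 8L
  env$action_set <- action_set
  # fixed camera over the whole window so agent motion is visible
  all_cells <- series$cells[series$cells$frame >= win["start"] &
                              series$cells$frame <= win["end"], ]
  env$camera <- default_camera(all_cells, image_size = image_size)
  env$palette <- role_palette()
  # eggshell clamp: series bounding box inflated by one mean radius
  pad <- mean(all_cells$diameter) / 2
  env$clamp_lo <- c(min(all_cells$x), min(all_cells$y), min(all_cells$z)) - pad
  env$clamp_hi <- c(max(all_cells$x), max(all_cells$y), max(all_cells$z)) + pad
  env_reset(env)
  env
}

#' @export
print.tissue_env <- function(x, ...) {
  cat("tissue_env: '", x$migrating, "' -> '", x$target, "' (",
      x$hypothesis, " hypothesis), window [", x$window["start"], ", ",
      x$window["end"], "], budget ", x$budget_steps, " steps, step ",
      x$steps_elapsed, if (x$done) ", done" else "", "\n", sep = "")
  invisible(x)
}

# role annotations of the current state (subgoal cells marked white)
env_annotations <- function(env) {
  ann <- c("migrating", "target")
  names(ann) <- c(env$migrating, env$target)
  if (!is.null(env$active_subgoal)) {
    sg <- rep("subgoal", 2L)
    names(sg) <- env$active_subgoal
    ann <- c(ann, sg)
  }
  ann
}

env_observe <- function(env) {
  img <- rasterize(env$cell_table, env$camera, env$palette,
                   env_annotations(env))
  build_observation(img$gray, img$depth)
}

# assemble the current frame table with the agent's position override
env_build_table <- function(env) {
  tab <- frame_table(env$series, env$frame_index)
  i <- match(env$migrating, tab$name)
  tab$x[i] <- env$agent_pos[1L]
  tab$y[i] <- env$agent_pos[2L]
  tab$z[i] <- env$agent_pos[3L]
  tab
}

env_target_pos <- function(env) {
  tab <- env$cell_table
  unlist(tab[tab$name == env$target, c("x", "y", "z")])
}

#' Reset a tissue environment to its initial state
#'
#' Restores the frame pointer, counters, subgoal state and the private RNG
#' stream, so two resets give bit-identical episodes for the same action
#' sequence.
#'
#' @param env tissue_env.
#' @param seed optional new seed for the private RNG (used to run
#'   independent evaluation episodes); default keeps the creation seed.
#' @return the initial observation (2 x S x S array), invisibly mutating
#'   \code{env}.
#' @export
env_reset <- function(env, seed = NULL) {
  stopifnot(inherits(env, "tissue_env"))
  if (!is.null(seed)) env$seed <- as.integer(seed)
  env$rng <- rng_stream(env$seed)
  env$frame_index <- unname(env$window["start"])
  tab <- frame_table(env$series, env$frame_index)
  env$agent_pos <- unlist(tab[tab$name == env$migrating, c("x", "y", "z")])
  env$cell_table <- env_build_table(env)
  env$steps_elapsed <- 0L
  env$stable_counter <- 0L
  env$destination_paid <- FALSE
  env$active_subgoal <- NULL
  env$subgoal_paid <- FALSE
  env$subgoal_counter <- 0L
  env$done <- FALSE
  invisible(env_observe(env))
}

#' Eight-direction action basis
#'
#' Unit vectors of the discrete action space: compass directions at 45
#' degree increments in the xy plane (z held fixed), action index 0 along
#' +x, counter-clockwise.
#'
#' @param action_set currently \code{"xy8"}.
#' @return 8 x 3 matrix of unit direction vectors.
#' @export
action_directions <- function(action_set = "xy8") {
  if (!identical(action_set, "xy8")) stop("unknown action set")
  ang <- (0:7) * pi / 4
  cbind(cos(ang), sin(ang), 0)
}

#' Sample one noisy step size
#'
#' \code{v_avg * (1 + delta)} with \code{delta ~ Normal(0, halfwidth / 2)}
#' truncated to \code{[-halfwidth, +halfwidth]}, i.e. +/- 20\% of the
#' average speed at the defaults (the 20\% band sits at about 2 sigma).
#'
#' @param speed list with \code{v_avg} and \code{noise_halfwidth}.
#' @return step size in micrometres.
#' @export
sample_step_size <- function(speed) {
  hw <- speed$noise_halfwidth
  if (hw == 0) return(speed$v_avg)
  repeat {
    delta <- stats::rnorm(1L, 0, hw / 2)
    if (abs(delta) <= hw) return(speed$v_avg * (1 + delta))
  }
}

#' Advance the environment by one agent action
#'
#' Environment cells move to their next replayed frame; the migrating cell
#' moves by a noisy step along the chosen direction (clamped inside the
#' inflated eggshell bounding box); the reward breakdown of the active
#' hypothesis is computed; stability and subgoal counters update. The
#' episode ends when the destination reward is paid, the step budget is
#' exceeded, or the series is exhausted.
#'
#' @param env tissue_env (not done).
#' @param action integer action index in 0..7.
#' @return list of class \code{step_result}: \code{observation},
#'   \code{reward} (\code{reward_breakdown}), \code{done}, \code{info}
#'   (distance to target, neighbor set, subgoal status, step/frame index).
#' @export
env_step <- function(env, action) {
  stopifnot(inherits(env, "tissue_env"))
  if (env$done) stop("episode is done; call env_reset()")
  if (!is.numeric(action) || length(action) != 1L ||
      is.na(action) || action != as.integer(action) ||
      action < 0L || action > 7L)
    stop("action must be an integer in 0..7")
  env$steps_elapsed <- env$steps_elapsed + 1L
  env$frame_index <- env$frame_index + 1L

  draw <- rng_draw(env$rng, function() sample_step_size(env$speed))
  env$rng <- draw$stream
  dir <- action_directions(env$action_set)[action + 1L, ]
  pos <- env$agent_pos + dir * draw$value
  env$agent_pos <- pmin(pmax(pos, env$clamp_lo), env$clamp_hi)
  env$cell_table <- env_build_table(env)

  tab <- env$cell_table
  nb <- neighbors_of(tab, env$migrating, env$neighbor_model,
                     env$ratio_cutoff)
  r_nb <- neighbor_distance_reward(tab, env$migrating, env$neighbor_model,
                                   env$config)
  is_nb_target <- env$target %in% nb
  env$stable_counter <- if (is_nb_target) env$stable_counter + 1L else 0L
  r_dest <- destination_reward(env$stable_counter, env$steps_elapsed,
                               env$budget_steps, env$config,
                               env$destination_paid)
  if (r_dest != 0) env$destination_paid <- TRUE

  d_now <- vec_norm(env$agent_pos - env_target_pos(env))
  r_grad <- 0
  r_sub <- 0
  subgoal_achieved <- NA
  if (env$hypothesis == "gradient") {
    r_grad <- gradient_reward(d_now, env$d0, env$config)
  } else if (!is.null(env$active_subgoal)) {
    both_nb <- all(env$active_subgoal %in% nb)
    env$subgoal_counter <- if (both_nb) env$subgoal_counter + 1L else 0L
    subgoal_achieved <- env$subgoal_counter >= env$config$subgoal_stable_steps
    r_sub <- subgoal_reward(subgoal_achieved, env$config, env$subgoal_paid)
    if (r_sub != 0) env$subgoal_paid <- TRUE
  }

  if (env$destination_paid || env$steps_elapsed > env$budget_steps ||
      env$frame_index >= env$window["end"])
    env$done <- TRUE

  structure(list(
    observation = env_observe(env),
    reward = reward_breakdown(r_neighbor = r_nb, r_destination = r_dest,
                              r_gradient = r_grad, r_subgoal = r_sub),
    done = env$done,
    info = list(distance = d_now, neighbors = nb,
                subgoal_achieved = subgoal_achieved,
                subgoal_paid = env$subgoal_paid,
                stable_counter = env$stable_counter,
                destination_paid = env$destination_paid,
                step = env$steps_elapsed, frame = env$frame_index,
                agent_pos = env$agent_pos)),
    class = "step_result")
}

#' Read-only snapshot of the environment state
#'
#' @param env tissue_env.
#' @return list with the frame index, current cell table (agent position
#'   applied), cell names, counters and budget; mutating the snapshot does
#'   not affect the environment.
#' @export
env_get_state <- function(env) {
  stopifnot(inherits(env, "tissue_env"))
  list(frame_index = env$frame_index,
       cell_table = env$cell_table,
       migrating = env$migrating, target = env$target,
       active_subgoal = env$active_subgoal,
       stable_counter = env$stable_counter,
       steps_elapsed = env$steps_elapsed,
       budget_steps = env$budget_steps,
       agent_pos = env$agent_pos,
       done = env$done)
}

#' Set (or clear) the active subgoal pair
#'
#' Only meaningful under the subgoal hypothesis: the pair must currently be
#' secondary neighbors of the migrating cell. Setting a subgoal resets its
#' pay-once flag; the pair is annotated white in subsequent observations.
#'
#' @param env tissue_env with hypothesis \code{"subgoal"}.
#' @param pair character vector of 2 cell names, or NULL to clear.
#' @return the env, invisibly.
#' @export
env_set_subgoal <- function(env, pair) {
  stopifnot(inherits(env, "tissue_env"))
  if (env$hypothesis != "subgoal")
    stop("subgoals require the subgoal hypothesis")
  if (is.null(pair)) {
    env$active_subgoal <- NULL
    env$subgoal_paid <- FALSE
    env$subgoal_counter <- 0L
    return(invisible(env))
  }
  stopifnot(is.character(pair), length(pair) == 2L)
  sec <- secondary_neighbors(env$cell_table, env$migrating,
                             env$neighbor_model, env$ratio_cutoff)
  bad <- setdiff(pair, sec)
  if (length(bad))
    stop("subgoal cells must be secondary neighbors of the migrating cell; ",
         "not secondary: ", paste(bad, collapse = ", "))
  env$active_subgoal <- pair
  env$subgoal_paid <- FALSE
  env$subgoal_counter <- 0L
  invisible(env)
}
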