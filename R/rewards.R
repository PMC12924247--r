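#' Reward configuration
#'
#' All printed constants of the three-part reward formulation, overridable:
#' the acceptable distance-ratio band (0.3, 0.8) estimated from wild-type
#' embryo statistics, the overlap penalty (-1000) for ratios below the band,
#' the destination reward (+100) for becoming a stable neighbor of the
#' target within the time budget (90\% of the observed migration time, with
#' stability meaning 5 consecutive timesteps), the intermediate subgoal
#' reward (+10) of the collective-behavior hypothesis, and the coefficient
#' of the dense gradient reward of the gradient hypothesis.
#'
#' @param ratio_low,ratio_high acceptable distance-ratio band.
#' @param overlap_penalty reward for ratio below \code{ratio_low}.
#' @param destination_reward reward on reaching the destination.
#' @param subgoal_reward intermediate reward per achieved subgoal.
#' @param stable_steps consecutive neighbor timesteps defining stability.
#' @param subgoal_stable_steps consecutive timesteps for subgoal stability.
#' @param time_budget_fraction fraction of the observed migration window
#'   within which the destination must be reached.
#' @param gradient_coeff coefficient c of the gradient reward
#'   \code{-c * d / d0}.
#' @return list of class \code{reward_config}.
#' @export
reward_config <- function(ratio_low = 0.3, ratio_high = 0.8,
                          overlap_penalty = -1000,
                          destination_reward = 100,
                          subgoal_reward = 10,
                          stable_steps = 5L,
                          subgoal_stable_steps = 1L,
                          time_budget_fraction = 0.9,
                          gradient_coeff = 1) {
  stopifnot(ratio_low > 0, ratio_low < ratio_high,
            stable_steps >= 1L, subgoal_stable_steps >= 1L,
            time_budget_fraction > 0, time_budget_fraction <= 1,
            gradient_coeff >= 0)
  structure(list(ratio_low = ratio_low, ratio_high = ratio_high,
                 overlap_penalty = overlap_penalty,
                 destination_reward = destination_reward,
                 subgoal_reward = subgoal_reward,
                 stable_steps = as.integer(stable_steps),
                 subgoal_stable_steps = as.integer(subgoal_stable_steps),
                 time_budget_fraction = time_budget_fraction,
                 gradient_coeff = gradient_coeff),
            class = "reward_config")
}

#' Per-pair neighbor-distance reward
#'
#' The distance-based reward for one neighbor pair as a function of the
#' centre-distance to radius-sum ratio: the overlap penalty (-1000) below
#' the acceptable band, a linear ramp from -1 (at the low edge, 0.3) to 0
#' (at the high edge, 0.8) inside the band, and 0 above it. The low boundary
#' itself belongs to the linear regime (the penalty applies to ratios
#' strictly below it).
#'
#' @param ratio non-negative distance ratio(s); vectorised.
#' @param config \code{\link{reward_config}}.
#' @return reward value(s) in \{overlap_penalty\} U [-1, 0].
#' @export
pair_reward <- function(ratio, config = reward_config()) {
  if (any(!is.finite(ratio)) || any(ratio < 0))
    stop("ratio must be finite and >= 0")
  ifelse(ratio < config$ratio_low, config$overlap_penalty,
         ifelse(ratio > config$ratio_high, 0,
                -(config$ratio_high - ratio) /
                  (config$ratio_high - config$ratio_low)))
}

#' Total neighbor-distance reward of a cell
#'
#' Sum of \code{\link{pair_reward}} over all direct neighbors of the cell
#' under the chosen neighbor model; 0 for a cell with no neighbors.
#'
#' @param frame_tab one frame of cell records.
#' @param cell cell name.
#' @param model neighbor model (see \code{\link{neighbors_of}}).
#' @param config \code{\link{reward_config}}.
#' @param radii optional per-cell effective radii aligned with
#'   \code{frame_tab}; default \code{\link{cell_radii}}.
#' @return scalar reward (<= 0).
#' @export
neighbor_distance_reward <- function(frame_tab, cell, model = "voronoi",
                                     config = reward_config(),
                                     radii = NULL) {
  nb <- neighbors_of(frame_tab, cell, model)
  if (!length(nb)) return(0)
  if (is.null(radii)) radii <- cell_radii(frame_tab)
  ic <- match(cell, frame_tab$name)
  inb <- match(nb, frame_tab$name)
  pts <- as.matrix(frame_tab[c("x", "y", "z")])
  d <- sqrt(rowSums((pts[inb, , drop = FALSE] -
                     matrix(pts[ic, ], length(inb), 3, byrow = TRUE))^2))
  ratio <- d / (radii[ic] + radii[inb])
  sum(pair_reward(ratio, config))
}

#' Destination-model reward
#'
#' Pays the destination reward (+100) exactly once: at the first step where
#' the migrating cell has been a neighbor of the target for
#' \code{stable_steps} consecutive timesteps (the counter resets whenever
#' the neighbor relationship breaks), provided that step is within the
#' episode time budget. The caller tracks the stability counter and the
#' pay-once flag; the tissue environment does this automatically.
#'
#' @param stable_counter consecutive neighbor timesteps including this one.
#' @param step_index 1-based index of the current step.
#' @param budget_steps time budget in steps.
#' @param config \code{\link{reward_config}}.
#' @param already_paid has the destination reward been paid this episode?
#' @return \code{destination_reward} or 0.
#' @export
destination_reward <- function(stable_counter, step_index, budget_steps,
                               config = reward_config(),
                               already_paid = FALSE) {
  stopifnot(stable_counter >= 0, step_index >= 0, budget_steps >= 0)
  if (!already_paid && stable_counter >= config$stable_steps &&
      step_index <= budget_steps)
    config$destination_reward
  else 0
}

#' Gradient-hypothesis dense reward
#'
#' Under the gradient-driven hypothesis the destination model additionally
#' emits a dense reward proportional to the current migrating-to-target
#' distance, normalised by the initial distance so the coefficient is
#' scale-free: \code{-c * d / d0}. It is 0 at the target and most negative
#' far from it, pushing value toward approach behavior every step.
#'
#' @param distance_now current distance, micrometres.
#' @param distance_initial distance at the start of the window (> 0).
#' @param config \code{\link{reward_config}}.
#' @return scalar reward (<= 0).
#' @export
gradient_reward <- function(distance_now, distance_initial,
                            config = reward_config()) {
  if (any(distance_now < 0)) stop("distance must be >= 0")
  if (!is.finite(distance_initial) || distance_initial <= 0)
    stop("distance_initial must be > 0")
  -config$gradient_coeff * distance_now / distance_initial
}

#' Subgoal (collective-behavior) intermediate reward
#'
#' Pays +10 once per subgoal, at the first step where the migrating cell is
#' simultaneously a neighbor of both cells of the active subgoal pair.
#'
#' @param subgoal_achieved was the active subgoal achieved this step?
#' @param config \code{\link{reward_config}}.
#' @param already_paid has this subgoal already paid?
#' @return \code{subgoal_reward} or 0.
#' @export
subgoal_reward <- function(subgoal_achieved, config = reward_config(),
                           already_paid = FALSE) {
  if (is.null(subgoal_achieved) || is.na(subgoal_achieved))
    stop("no active subgoal")
  if (isTRUE(subgoal_achieved) && !already_paid) config$subgoal_reward else 0
}

#' Assemble a per-step reward breakdown
#'
#' @param r_neighbor neighbor-distance component (<= 0).
#' @param r_destination destination component.
#' @param r_gradient gradient component (gradient hypothesis only).
#' @param r_subgoal subgoal component (subgoal hypothesis only).
#' @return list of class \code{reward_breakdown} with a \code{total} field.
#' @export
reward_breakdown <- function(r_neighbor = 0, r_destination = 0,
                             r_gradient = 0, r_subgoal = 0) {
  structure(list(r_neighbor = r_neighbor, r_destination = r_destination,
                 r_gradient = r_gradient, r_subgoal = r_subgoal,
                 total = r_neighbor + r_destination + r_gradient + r_subgoal),
            class = "reward_breakdown")
}

#' Total reward of a breakdown
#'
#' The reward is the sum of the three model feedbacks; the gradient and
#' subgoal variants are mutually exclusive hypotheses, so a breakdown with
#' both components non-zero is a configuration error.
#'
#' @param components \code{\link{reward_breakdown}}.
#' @return scalar total reward.
#' @export
total_reward <- function(components) {
  stopifnot(inherits(components, "reward_breakdown"))
  if (components$r_gradient != 0 && components$r_subgoal != 0)
    stop("gradient and subgoal rewards cannot both be active")
  components$r_neighbor + components$r_destination +
    components$r_gradient + components$r_subgoal
}
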