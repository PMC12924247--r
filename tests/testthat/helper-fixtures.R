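# Small in-code fixtures shared across the suite.

# a minimal hand-built series: `n` cells drifting along +x over `nf` frames
toy_series <- function(nf = 3L, n = 3L, interval = 60) {
  cells <- do.call(rbind, lapply(seq_len(nf) - 1L, function(f) {
    data.frame(frame = f, name = paste0("C", letters[seq_len(n)]),
               x = seq_len(n) * 10 + f, y = rep(0, n), z = rep(0, n),
               diameter = rep(4, n), stringsAsFactors = FALSE)
  }))
  embryo_series(cells, frame_interval = interval)
}

# one frame table built directly from coordinates
toy_frame <- function(pts, diameter = 2, names = NULL) {
  pts <- as.matrix(pts)
  if (is.null(names)) names <- paste0("c", seq_len(nrow(pts)))
  data.frame(frame = 0L, name = names, x = pts[, 1], y = pts[, 2],
             z = pts[, 3], diameter = diameter, stringsAsFactors = FALSE)
}

# cached small corridor scenario (shared by environment/agent tests)
corridor_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_migration_scenario(scenario_spec(seed = 1L))
    cache
  }
})

# independent Delaunay adjacency oracle through scipy (pre-installed python)
scipy_delaunay_edges <- function(pts) {
  inp <- tempfile(fileext = ".txt")
  out <- tempfile(fileext = ".txt")
  utils::write.table(pts, inp, row.names = FALSE, col.names = FALSE)
  code <- paste(
    "import sys, numpy as np",
    "from scipy.spatial import Delaunay",
    sprintf("p = np.loadtxt('%s')", inp),
    "tri = Delaunay(p)",
    "edges = set()",
    "for simplex in tri.simplices:",
    "    for i in range(len(simplex)):",
    "        for j in range(i + 1, len(simplex)):",
    "            edges.add((min(simplex[i], simplex[j]) + 1,",
    "                       max(simplex[i], simplex[j]) + 1))",
    sprintf("np.savetxt('%s', np.array(sorted(edges)), fmt='%%d')", out),
    sep = "\n")
  status <- system2("python", c("-c", shQuote(code)))
  if (status != 0) stop("python/scipy oracle failed")
  as.matrix(utils::read.table(out))
}

# deterministic 5-state chain MDP over one-hot states: LEFT/RIGHT actions,
# stepping right from state 5 pays +1 and terminates; discounted value
# iteration is the oracle for the greedy policy.
chain_env <- function(n = 5L) {
  state <- 1L
  steps <- 0L
  onehot <- function(i) as.numeric(seq_len(n) == i)
  rl_env(
    reset = function(seed = NULL) {
      state <<- 1L
      steps <<- 0L
      onehot(state)
    },
    step = function(a) {
      steps <<- steps + 1L
      reward <- -0.01
      done <- FALSE
      if (a == 1L) {                      # right
        if (state == n) {
          reward <- 1
          done <- TRUE
        } else state <<- state + 1L
      } else if (state > 1L) state <<- state - 1L
      if (steps >= 30L) done <- TRUE
      list(obs = onehot(state), reward = reward, done = done,
           info = list(destination_paid = state == n && reward == 1))
    },
    n_actions = 2L)
}

chain_value_iteration <- function(n = 5L, gamma = 0.9) {
  V <- numeric(n)
  for (it in 1:500) {
    Q <- matrix(0, n, 2L)
    for (s in seq_len(n)) {
      sl <- max(s - 1L, 1L)
      Q[s, 1L] <- -0.01 + gamma * V[sl]
      Q[s, 2L] <- if (s == n) 1 else -0.01 + gamma * V[s + 1L]
    }
    V <- apply(Q, 1L, max)
  }
  max.col(Q) - 1L
}


# cached embryo frames + Voronoi ground truth for classifier checks
neighbor_ground_truth_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      frames <- lapply(1:12, function(s)
        frame_table(generate_embryo(scenario_spec(seed = s)), 0L))
      cache <<- list(frames = frames,
                     graphs = lapply(frames, voronoi_neighbors))
    }
    cache
  }
})

# pooled balanced accuracy of a classifier against held-out Voronoi truth
classifier_balanced_accuracy <- function(clf, ng, test) {
  pred <- logical(0)
  truth <- logical(0)
  for (i in test) {
    tab <- ng$frames[[i]]
    pairs <- t(utils::combn(nrow(tab), 2L))
    pred <- c(pred, predict(clf, cellmigrl:::pair_feature_matrix(tab, pairs)))
    key <- paste(pmin(tab$name[pairs[, 1]], tab$name[pairs[, 2]]),
                 pmax(tab$name[pairs[, 1]], tab$name[pairs[, 2]]))
    ekey <- paste(pmin(ng$graphs[[i]]$edges[, 1], ng$graphs[[i]]$edges[, 2]),
                  pmax(ng$graphs[[i]]$edges[, 1], ng$graphs[[i]]$edges[, 2]))
    truth <- c(truth, key %in% ekey)
  }
  (mean(pred[truth]) + mean(!pred[!truth])) / 2
}
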