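#' Lineage generation (division depth) of a cell name
#'
#' Counted as the number of division-suffix characters (a, p, d, v, l, r)
#' following the founder prefix, e.g. \code{"Cpaaa"} is generation 4 within
#' the C lineage.
#'
#' @param name lineage name.
#' @return integer generation.
#' @export
lineage_generation <- function(name) {
  rest <- sub("^[A-Z0-9]+", "", name)
  nchar(rest)
}

#' Estimate a cell's effective (tissue) radius
#'
#' Nuclei underestimate cell extent, so cell radii are estimated from how
#' much embryo volume each cell occupies: \code{radius =
#' (3 * volume * w(g) / (4 * pi * N))^(1/3)} where N is the number of cells
#' in the frame and \code{w(g)} an optional per-generation weight
#' (default 1, a configuration hook for lineage-specific size laws).
#'
#' @param cell cell name (used for the generation weight).
#' @param frame_tab one frame of cell records.
#' @param embryo_volume embryo volume in cubic micrometres; default estimated
#'   from the frame via \code{\link{embryo_volume_estimate}}.
#' @param weight_fn function(generation) -> positive weight.
#' @return list with \code{radius}, \code{generation}, \code{embryo_volume},
#'   \code{n_cells}.
#' @export
estimate_radius <- function(cell, frame_tab, embryo_volume = NULL,
                            weight_fn = function(g) 1) {
  if (is.null(embryo_volume)) embryo_volume <- embryo_volume_estimate(frame_tab)
  if (!is.finite(embryo_volume) || embryo_volume <= 0)
    stop("embryo_volume must be > 0")
  n <- nrow(frame_tab)
  if (n < 1L) stop("empty frame")
  g <- lineage_generation(cell)
  w <- weight_fn(g)
  list(radius = (3 * embryo_volume * w / (4 * pi * n))^(1 / 3),
       generation = g, embryo_volume = embryo_volume, n_cells = n)
}

#' Estimate embryo volume from one frame
#'
#' Volume of the axis-aligned bounding ellipsoid of the nuclear centres,
#' inflated by the mean nucleus radius to account for cells whose centres
#' sit inside the eggshell by about one radius.
#'
#' @param frame_tab one frame of cell records.
#' @return volume in cubic micrometres.
#' @export
embryo_volume_estimate <- function(frame_tab) {
  pad <- mean(frame_tab$diameter) / 2
  semi <- c(diff(range(frame_tab$x)), diff(range(frame_tab$y)),
            diff(range(frame_tab$z))) / 2 + pad
  4 / 3 * pi * prod(semi)
}

# Contact calibration: the volume-equipartition radius underestimates a
# cell's spatial reach in a confluent tissue (the mean Delaunay edge length
# is about twice the equipartition radius), so ratios fed to the reward
# band and the classifier use contact radii = factor * equipartition
# radius. 1.55 centres adjacent-pair ratios of close-packed frames in the
# acceptable (0.3, 0.8) band.
CONTACT_FACTOR <- 1.55

# Effective contact radii for every cell of a frame (vectorised
# estimate_radius with w == 1, times the contact calibration).
cell_radii <- function(frame_tab, embryo_volume = NULL,
                       contact_factor = CONTACT_FACTOR) {
  if (is.null(embryo_volume)) embryo_volume <- embryo_volume_estimate(frame_tab)
  rep(contact_factor *
        (3 * embryo_volume / (4 * pi * nrow(frame_tab)))^(1 / 3),
      nrow(frame_tab))
}

new_neighbor_graph <- function(frame, edges, provenance) {
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2)
  structure(list(frame = frame, edges = edges, provenance = provenance),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("neighbor_graph (", x$provenance, "): ", nrow(x$edges),
      " edges at frame ", x$frame, "\n", sep = "")
  invisible(x)
}

#' Voronoi/Delaunay neighbor graph of one frame
#'
#' Ground-truth neighborship: two cells are neighbors when their Voronoi
#' regions share a face, i.e. their nuclei are adjacent in the 3-D Delaunay
#' tessellation. Raw Delaunay over-connects across the convex hull, so edges
#' whose centre-distance to radius-sum ratio exceeds \code{ratio_cutoff} are
#' pruned (the cutoff sits far above the packed-tissue range of roughly
#' 0.3--0.8). Coplanar or collinear frames fall back to lower-dimensional
#' tessellations with a warning; two cells form a single edge.
#'
#' @param frame_tab one frame of cell records (>= 2 cells).
#' @param ratio_cutoff prune Delaunay edges with distance/radius-sum above
#'   this (default 2.0).
#' @param radii per-cell effective radii; default \code{\link{cell_radii}}.
#' @return \code{neighbor_graph} with provenance \code{"voronoi"}.
#' @export
voronoi_neighbors <- function(frame_tab, ratio_cutoff = 2.0, radii = NULL) {
  n <- nrow(frame_tab)
  if (n < 2L) stop("need at least 2 cells")
  if (is.null(radii)) radii <- cell_radii(frame_tab)
  pts <- as.matrix(frame_tab[c("x", "y", "z")])
  frame <- frame_tab$frame[1L] %||% NA_integer_
  if (n == 2L) {
    warning("2 cells: degenerate tessellation, single edge")
    idx <- matrix(c(1L, 2L), ncol = 2)
  } else if (n == 3L) {
    warning("3 cells: degenerate tessellation, using 2-D rule")
    idx <- planar_delaunay(pts)
  } else {
    idx <- .delaunay_edges_3d(pts)
    if (isTRUE(attr(idx, "degenerate"))) {
      warning("coplanar frame: falling back to 2-D tessellation")
      idx <- planar_delaunay(pts)
    }
  }
  if (nrow(idx)) {
    d <- sqrt(rowSums((pts[idx[, 1L], , drop = FALSE] -
                       pts[idx[, 2L], , drop = FALSE])^2))
    keep <- d / (radii[idx[, 1L]] + radii[idx[, 2L]]) <= ratio_cutoff
    idx <- idx[keep, , drop = FALSE]
  }
  edges <- cbind(frame_tab$name[idx[, 1L]], frame_tab$name[idx[, 2L]])
  new_neighbor_graph(frame, edges, "voronoi")
}

# 2-D (or 1-D) fallback for degenerate geometry: project onto the principal
# plane and take empty-circumcircle adjacency; collinear points chain up.
planar_delaunay <- function(pts) {
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr)
  proj <- ctr %*% sv$v[, 1:2, drop = FALSE]
  if (nrow(pts) >= 3L) {
    idx <- .delaunay_edges_2d(proj)
    if (!isTRUE(attr(idx, "degenerate"))) return(idx)
  }
  # collinear: connect consecutive points along the principal axis
  ord <- order(ctr %*% sv$v[, 1L])
  cbind(ord[-length(ord)], ord[-1L])
}

#' Handcrafted features of a cell pair
#'
#' The feature set of the neighbor-relationship classifier: centre distance,
#' the two nucleus sizes, the estimated radius sum, the distance/radius-sum
#' ratio, the total number of cells in the embryo, the number of other
#' cells inside the pair's diametral sphere (the Gabriel-graph blocking
#' count), the relative-neighborhood lune blocking count -- both strong
#' geometric predictors of tessellation adjacency -- and the
#' pair distance relative to the endpoints' nearest-neighbor distances
#' (local-spacing normalization).
#'
#' @param frame_tab one frame of cell records.
#' @param a,b distinct cell names present in the frame.
#' @param n_cells_total total number of cells in the embryo (defaults to the
#'   frame's cell count).
#' @return named numeric vector (distance, size_a, size_b, radius_sum,
#'   ratio, n_cells_total).
#' @export
pair_features <- function(frame_tab, a, b, n_cells_total = nrow(frame_tab)) {
  ia <- match(a, frame_tab$name)
  ib <- match(b, frame_tab$name)
  if (is.na(ia)) stop("cell '", a, "' not in frame")
  if (is.na(ib)) stop("cell '", b, "' not in frame")
  if (ia == ib) stop("a and b must differ")
  radii <- cell_radii(frame_tab)
  d <- vec_norm(unlist(frame_tab[ia, c("x", "y", "z")]) -
                unlist(frame_tab[ib, c("x", "y", "z")]))
  rs <- radii[ia] + radii[ib]
  pts <- as.matrix(frame_tab[c("x", "y", "z")])
  mid <- (pts[ia, ] + pts[ib, ]) / 2
  d_mid <- sqrt(rowSums(sweep(pts, 2L, mid)^2))
  blockers <- sum(d_mid[-c(ia, ib)] < d / 2)
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  rel <- if (nrow(pts) > 2L)
    d / mean(c(min(dm[ia, ]), min(dm[ib, ]))) else 1
  lune <- sum(pmax(dm[ia, ], dm[ib, ])[-c(ia, ib)] < d)
  c(distance = d, size_a = frame_tab$diameter[ia],
    size_b = frame_tab$diameter[ib], radius_sum = rs,
    ratio = if (rs > 0) d / rs else 0,
    n_cells_total = n_cells_total,
    midpoint_blockers = blockers,
    lune_blockers = lune,
    relative_distance = rel)
}

pair_feature_matrix <- function(frame_tab, pairs_idx,
                                n_cells_total = nrow(frame_tab)) {
  pts <- as.matrix(frame_tab[c("x", "y", "z")])
  radii <- cell_radii(frame_tab)
  d <- sqrt(rowSums((pts[pairs_idx[, 1L], , drop = FALSE] -
                     pts[pairs_idx[, 2L], , drop = FALSE])^2))
  rs <- radii[pairs_idx[, 1L]] + radii[pairs_idx[, 2L]]
  blockers <- vapply(seq_len(nrow(pairs_idx)), function(r) {
    ia <- pairs_idx[r, 1L]
    ib <- pairs_idx[r, 2L]
    mid <- (pts[ia, ] + pts[ib, ]) / 2
    d_mid <- sqrt(rowSums(sweep(pts, 2L, mid)^2))
    sum(d_mid[-c(ia, ib)] < d[r] / 2)
  }, numeric(1))
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  nn <- apply(dm, 1L, min)
  rel <- d / ((nn[pairs_idx[, 1L]] + nn[pairs_idx[, 2L]]) / 2)
  lune <- vapply(seq_len(nrow(pairs_idx)), function(r) {
    ia <- pairs_idx[r, 1L]
    ib <- pairs_idx[r, 2L]
    sum(pmax(dm[ia, ], dm[ib, ])[-c(ia, ib)] < d[r])
  }, numeric(1))
  cbind(distance = d,
        size_a = frame_tab$diameter[pairs_idx[, 1L]],
        size_b = frame_tab$diameter[pairs_idx[, 2L]],
        radius_sum = rs,
        ratio = ifelse(rs > 0, d / rs, 0),
        n_cells_total = n_cells_total,
        midpoint_blockers = blockers,
        lune_blockers = lune,
        relative_distance = rel)
}

## ---- random forest (hand-rolled: no forest package in the stack) --------

rf_gini <- function(n1, n0) {
  n <- n1 + n0
  ifelse(n == 0, 0, 1 - (n1 / n)^2 - (n0 / n)^2)
}

rf_build_tree <- function(X, y, mtry, max_depth, min_node) {
  build <- function(rows, depth) {
    n1 <- sum(y[rows])
    n0 <- length(rows) - n1
    prob <- n1 / (n1 + n0)
    if (depth >= max_depth || length(rows) < min_node || n1 == 0 || n0 == 0)
      return(list(leaf = TRUE, prob = prob))
    feats <- sample.int(ncol(X), min(mtry, ncol(X)))
    best <- NULL
    parent <- rf_gini(n1, n0) * length(rows)
    for (j in feats) {
      v <- X[rows, j]
      cuts <- unique(stats::quantile(v, probs = seq(0.1, 0.9, by = 0.1),
                                     names = FALSE, type = 7))
      for (cut in cuts) {
        left <- v <= cut
        nl <- sum(left)
        if (nl == 0 || nl == length(rows)) next
        n1l <- sum(y[rows][left])
        n1r <- n1 - n1l
        score <- rf_gini(n1l, nl - n1l) * nl +
          rf_gini(n1r, length(rows) - nl - n1r) * (length(rows) - nl)
        if (is.null(best) || score < best$score)
          best <- list(score = score, j = j, cut = cut)
      }
    }
    if (is.null(best) || best$score >= parent - 1e-12)
      return(list(leaf = TRUE, prob = prob))
    left_rows <- rows[X[rows, best$j] <= best$cut]
    right_rows <- rows[X[rows, best$j] > best$cut]
    list(leaf = FALSE, j = best$j, cut = best$cut,
         left = build(left_rows, depth + 1L),
         right = build(right_rows, depth + 1L))
  }
  build(seq_len(nrow(X)), 0L)
}

rf_predict_tree <- function(tree, x) {
  while (!tree$leaf) {
    tree <- if (x[tree$j] <= tree$cut) tree$left else tree$right
  }
  tree$prob
}

#' Train the neighbor-relationship classifier
#'
#' A random forest over \code{\link{pair_features}}, trained with Voronoi
#' ground truth: positive pairs are Voronoi edges, negative pairs are
#' non-edges sampled at a 1:1 class balance. The fitted object predicts
#' whether an arbitrary cell pair are neighbors without running a
#' tessellation.
#'
#' @param frames list of frame tables.
#' @param graphs matching list of \code{neighbor_graph}s (typically from
#'   \code{\link{voronoi_neighbors}}).
#' @param config list: \code{ntree} (50), \code{mtry} (2), \code{max_depth}
#'   (8), \code{min_node} (4).
#' @param seed integer; training is deterministic given the seed.
#' @return object of class \code{neighbor_classifier}.
#' @export
train_classifier <- function(frames, graphs, config = list(), seed = 1L) {
  stopifnot(length(frames) == length(graphs), length(frames) >= 1L)
  cfg <- utils::modifyList(
    list(ntree = 200L, mtry = 3L, max_depth = 12L, min_node = 2L), config)
  Xs <- list()
  ys <- list()
  for (i in seq_along(frames)) {
    tab <- frames[[i]]
    g <- graphs[[i]]
    all_pairs <- t(utils::combn(nrow(tab), 2L))
    ekey <- paste(pmin(g$edges[, 1L], g$edges[, 2L]),
                  pmax(g$edges[, 1L], g$edges[, 2L]))
    pnames <- cbind(tab$name[all_pairs[, 1L]], tab$name[all_pairs[, 2L]])
    pkey <- paste(pmin(pnames[, 1L], pnames[, 2L]),
                  pmax(pnames[, 1L], pnames[, 2L]))
    pos <- pkey %in% ekey
    pos_idx <- which(pos)
    neg_idx <- which(!pos)
    n_neg <- min(length(neg_idx), length(pos_idx))
    neg_idx <- with_seed(derive_seed(seed, paste0("negpairs", i)),
                         sample(neg_idx, n_neg))
    use <- c(pos_idx, neg_idx)
    Xs[[i]] <- pair_feature_matrix(tab, all_pairs[use, , drop = FALSE])
    ys[[i]] <- as.integer(pos[use])
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys)
  if (length(unique(y)) < 2L)
    stop("training set has a single class; need both edges and non-edges")
  trees <- with_seed(derive_seed(seed, "forest"), {
    lapply(seq_len(cfg$ntree), function(t) {
      boot <- sample.int(nrow(X), nrow(X), replace = TRUE)
      rf_build_tree(X[boot, , drop = FALSE], y[boot],
                    mtry = cfg$mtry, max_depth = cfg$max_depth,
                    min_node = cfg$min_node)
    })
  })
  # vote threshold chosen on the training pairs (balanced accuracy)
  probs <- apply(X, 1L, function(x)
    mean(vapply(trees, rf_predict_tree, numeric(1), x = x)))
  ths <- seq(0.3, 0.7, by = 0.05)
  bal <- vapply(ths, function(th) {
    p <- probs >= th
    (mean(p[y == 1L]) + mean(!p[y == 0L])) / 2
  }, numeric(1))
  structure(list(trees = trees, config = cfg, seed = seed,
                 threshold = ths[which.max(bal)],
                 features = colnames(X), version = "1"),
            class = "neighbor_classifier")
}

#' Predict neighborship for pair features
#'
#' @param object \code{neighbor_classifier}.
#' @param features one feature vector from \code{\link{pair_features}} or a
#'   matrix of such rows.
#' @param ... unused.
#' @return logical vector: TRUE where the pair is classified as neighbors.
#' @export
predict.neighbor_classifier <- function(object, features, ...) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  probs <- apply(features, 1L, function(x) {
    mean(vapply(object$trees, rf_predict_tree, numeric(1), x = x))
  })
  unname(probs >= (object$threshold %||% 0.5))
}

#' Save / load a neighbor classifier
#'
#' @param object \code{neighbor_classifier}.
#' @param path file path.
#' @return \code{save_classifier}: the path, invisibly;
#'   \code{load_classifier}: the classifier.
#' @export
save_classifier <- function(object, path) {
  stopifnot(inherits(object, "neighbor_classifier"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "neighbor_classifier") || is.null(obj$version))
    stop("not a neighbor_classifier file")
  obj
}

#' Direct neighbors of a cell
#'
#' @param frame_tab one frame of cell records.
#' @param cell cell name.
#' @param model \code{"voronoi"} (tessellation ground truth) or a fitted
#'   \code{neighbor_classifier}.
#' @param ratio_cutoff edge-pruning cutoff for the voronoi model.
#' @return character vector of neighbor names (never includes \code{cell}).
#' @export
neighbors_of <- function(frame_tab, cell, model = "voronoi",
                         ratio_cutoff = 2.0) {
  ic <- match(cell, frame_tab$name)
  if (is.na(ic)) stop("cell '", cell, "' not in frame")
  if (identical(model, "voronoi")) {
    g <- suppressWarnings(voronoi_neighbors(frame_tab, ratio_cutoff))
    nb <- c(g$edges[g$edges[, 1L] == cell, 2L],
            g$edges[g$edges[, 2L] == cell, 1L])
    return(unique(nb))
  }
  if (!inherits(model, "neighbor_classifier"))
    stop("model must be \"voronoi\" or a neighbor_classifier")
  others <- which(frame_tab$name != cell)
  if (!length(others)) return(character())
  pairs_idx <- cbind(rep(ic, length(others)), others)
  feats <- pair_feature_matrix(frame_tab, pairs_idx)
  frame_tab$name[others][predict(model, feats)]
}

#' Secondary neighbors (neighbors of neighbors) of a cell
#'
#' The candidate pool for migration subgoals: cells adjacent to a direct
#' neighbor but not themselves direct neighbors of \code{cell}.
#'
#' @inheritParams neighbors_of
#' @return character vector of secondary-neighbor names.
#' @export
secondary_neighbors <- function(frame_tab, cell, model = "voronoi",
                                ratio_cutoff = 2.0) {
  direct <- neighbors_of(frame_tab, cell, model, ratio_cutoff)
  if (!length(direct)) return(character())
  second <- unique(unlist(lapply(direct, function(nb)
    neighbors_of(frame_tab, nb, model, ratio_cutoff))))
  setdiff(second, c(direct, cell))
}
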