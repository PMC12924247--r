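#' Migrating-to-target distance array over the migration window
#'
#' @param series embryo_series.
#' @param migrating,target cell names with a non-empty co-existence window.
#' @return list of class \code{distance_array}: \code{values} (micrometres,
#'   one per window frame), \code{timestep} (seconds), \code{embryo_id}.
#' @export
distance_array <- function(series, migrating, target) {
  win <- migration_window(series, migrating, target)
  frames <- seq(win["start"], win["end"])
  cells <- series$cells[series$cells$frame %in% frames &
                          series$cells$name %in% c(migrating, target), ]
  a <- cells[cells$name == migrating, ]
  b <- cells[cells$name == target, ]
  a <- a[order(a$frame), ]
  b <- b[order(b$frame), ]
  vals <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  structure(list(values = vals, timestep = series$frame_interval,
                 embryo_id = series$metadata$embryo_id %||% NA_character_,
                 window = win),
            class = "distance_array")
}

#' Midpoint index of a distance array
#'
#' The sample closest to the mean of the array's maximum and minimum --
#' the anchor used to align migration curves from different embryos.
#' Ties break to the earliest index.
#'
#' @param arr \code{distance_array} or numeric vector (length >= 2).
#' @return 1-based index of the midpoint sample.
#' @export
midpoint_index <- function(arr) {
  v <- if (inherits(arr, "distance_array")) arr$values else as.numeric(arr)
  if (length(v) < 2L) stop("need at least 2 samples")
  mid <- (max(v) + min(v)) / 2
  which.min(abs(v - mid))
}

#' Align distance arrays at their midpoints and average
#'
#' Shifts each embryo's distance array so the midpoints coincide, then
#' computes the per-step mean and standard deviation over the aligned
#' position range where at least two embryos overlap (the band is not
#' defined from a single curve at the ragged edges).
#'
#' @param arrays list of >= 2 \code{distance_array}s or numeric vectors.
#' @return list of class \code{standardized_curve}: \code{mean}, \code{sd},
#'   \code{n} (arrays contributing per position), \code{positions}
#'   (aligned step offsets relative to the midpoint), \code{n_embryos},
#'   \code{alignment_offsets} (midpoint index per embryo).
#' @export
align_and_average <- function(arrays) {
  if (length(arrays) < 2L) stop("need at least 2 distance arrays")
  vals <- lapply(arrays, function(a)
    if (inherits(a, "distance_array")) a$values else as.numeric(a))
  mids <- vapply(vals, midpoint_index, integer(1))
  lens <- lengths(vals)
  lo <- min(1L - mids)
  hi <- max(lens - mids)
  positions <- seq(lo, hi)
  mat <- matrix(NA_real_, length(vals), length(positions))
  for (i in seq_along(vals)) {
    offs <- (seq_len(lens[i]) - mids[i]) - lo + 1L
    mat[i, offs] <- vals[[i]]
  }
  n <- colSums(!is.na(mat))
  keep <- n >= 2L
  if (!any(keep)) stop("no overlap between arrays after midpoint alignment")
  structure(list(mean = colMeans(mat[, keep, drop = FALSE], na.rm = TRUE),
                 sd = apply(mat[, keep, drop = FALSE], 2L, stats::sd,
                            na.rm = TRUE),
                 n = n[keep], positions = positions[keep],
                 n_embryos = length(vals), alignment_offsets = mids),
            class = "standardized_curve")
}

#' Neighbor-removal influence experiment
#'
#' Measures how much the migrating cell's neighbors shape its trajectory:
#' (a) collects the union of the migrating cell's direct neighbors over the
#' migration window (excluding the migrating and target cells), (b) builds
#' a second environment from the series with those cells removed, and (c)
#' evaluates the trained policy in both environments over an ensemble of
#' greedy episodes. Without its neighbors the migrating cell is expected to
#' reach the destination earlier and/or along a more variable path.
#'
#' @param series embryo_series.
#' @param policy trained policy (see \code{\link{evaluate_policy}}).
#' @param migrating,target cell names.
#' @param config \code{\link{reward_config}}.
#' @param hypothesis environment hypothesis matching the policy.
#' @param n_runs evaluation episodes per condition (default 5).
#' @param image_size observation resolution used by the policy.
#' @param seed environment seed.
#' @param neighbor_model,ratio_cutoff neighbor model settings.
#' @return list of class \code{influence_report}: \code{with},
#'   \code{without} (\code{ensemble_result}s), \code{removed} (cell names),
#'   \code{arrival_difference} (mean arrival step, without minus with;
#'   negative = earlier without neighbors), \code{path_spread} (mean
#'   per-step sd of the 2-D path, per condition).
#' @export
neighbor_influence_experiment <- function(series, policy, migrating, target,
                                          config = reward_config(),
                                          hypothesis = "gradient",
                                          n_runs = 5L, image_size = 64L,
                                          seed = 1L,
                                          neighbor_model = "voronoi",
                                          ratio_cutoff = 2.0) {
  win <- migration_window(series, migrating, target)
  removed <- character()
  for (f in seq(win["start"], win["end"])) {
    tab <- frame_table(series, f)
    removed <- union(removed,
                     neighbors_of(tab, migrating, neighbor_model,
                                  ratio_cutoff))
  }
  removed <- setdiff(removed, c(migrating, target))
  series_wo <- remove_cells(series, removed)
  if (!target %in% series_wo$cells$name)
    stop("neighbor removal deleted the target cell")
  mk_env <- function(s) create_tissue_env(
    s, migrating, target, config, hypothesis, seed = seed,
    neighbor_model = neighbor_model, ratio_cutoff = ratio_cutoff,
    image_size = image_size)
  env_with <- mk_env(series)
  env_wo <- mk_env(series_wo)
  res_with <- evaluate_policy(env_with, policy, n_runs = n_runs)
  res_wo <- evaluate_policy(env_wo, policy, n_runs = n_runs)
  spread <- function(res) {
    len <- max(vapply(res$runs, function(r) nrow(r$path), integer(1)))
    per_axis <- sapply(1:2, function(ax) {
      m <- matrix(NA_real_, length(res$runs), len)
      for (i in seq_along(res$runs))
        m[i, seq_len(nrow(res$runs[[i]]$path))] <- res$runs[[i]]$path[, ax]
      mean(apply(m, 2L, stats::sd, na.rm = TRUE), na.rm = TRUE)
    })
    mean(per_axis)
  }
  arr_with <- mean(res_with$arrival_steps, na.rm = TRUE)
  arr_wo <- mean(res_wo$arrival_steps, na.rm = TRUE)
  structure(list(with = res_with, without = res_wo, removed = removed,
                 arrival_difference = arr_wo - arr_with,
                 path_spread = c(with = spread(res_with),
                                 without = spread(res_wo))),
            class = "influence_report")
}

#' Plot distance curves and top-view migration paths
#'
#' Writes PNG figures: per-step distance curves with the ensemble mean and
#' a +/- 1 standard-deviation shaded band, and 2-D top-view path plots.
#'
#' @param curves a \code{standardized_curve}, an \code{ensemble_result}, or
#'   a named list of them (one panel each).
#' @param paths optional list of n x >= 2 path matrices for the top view.
#' @param out_dir output directory.
#' @return character vector of files written.
#' @export
plot_outputs <- function(curves, paths = NULL, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  if (inherits(curves, c("standardized_curve", "ensemble_result")))
    curves <- list(curve = curves)
  files <- character()
  for (nm in names(curves)) {
    cv <- curves[[nm]]
    if (inherits(cv, "standardized_curve")) {
      m <- cv$mean; s <- cv$sd; xs <- cv$positions
    } else {
      m <- cv$mean_distance_curve; s <- cv$sd_band
      xs <- seq_along(m)
    }
    f <- file.path(out_dir, paste0("distance_", nm, ".png"))
    grDevices::png(f, width = 640, height = 420)
    graphics::plot(xs, m, type = "n",
                   ylim = range(c(m - s, m + s), na.rm = TRUE),
                   xlab = "timestep", ylab = "distance to target (um)",
                   main = nm)
    band <- is.finite(s) & s > 0
    if (any(band))
      graphics::polygon(c(xs[band], rev(xs[band])),
                        c((m + s)[band], rev((m - s)[band])),
                        col = grDevices::adjustcolor("steelblue", 0.3),
                        border = NA)
    graphics::lines(xs, m, col = "steelblue", lwd = 2)
    grDevices::dev.off()
    files <- c(files, f)
  }
  if (!is.null(paths)) {
    f <- file.path(out_dir, "paths_topview.png")
    grDevices::png(f, width = 480, height = 480)
    xr <- range(unlist(lapply(paths, function(p) p[, 1L])))
    yr <- range(unlist(lapply(paths, function(p) p[, 2L])))
    graphics::plot(NA, xlim = xr, ylim = yr, asp = 1,
                   xlab = "x (um)", ylab = "y (um)",
                   main = "migration paths (top view)")
    for (i in seq_along(paths))
      graphics::lines(paths[[i]][, 1L], paths[[i]][, 2L],
                      col = grDevices::rainbow(length(paths))[i])
    grDevices::dev.off()
    files <- c(files, f)
  }
  files
}
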