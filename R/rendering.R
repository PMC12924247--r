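#' Orthographic camera for tissue rendering
#'
#' @param target_position 3-vector, micrometres: world point at the image
#'   centre.
#' @param distance half-extent of the (square) orthographic window,
#'   micrometres.
#' @param view \code{"top"} (project along -z) -- the view used for the
#'   learning observations.
#' @param image_size output resolution in pixels (>= 8; default 64).
#' @return list of class \code{tissue_camera}.
#' @export
tissue_camera <- function(target_position = c(0, 0, 0), distance = 30,
                          view = "top", image_size = 64L) {
  stopifnot(length(target_position) == 3L, distance > 0, image_size >= 8L)
  structure(list(target_position = as.numeric(target_position),
                 distance = distance, view = view,
                 image_size = as.integer(image_size)),
            class = "tissue_camera")
}

#' Grayscale role palette
#'
#' After the RGB-to-grayscale collapse the four cell roles must stay
#' separable, so each role maps to a distinct intensity: migrating 1.0,
#' subgoal 0.9 ("white"), target 0.8, environment 0.5.
#'
#' @param migrating,target,subgoal,environment intensities in (0, 1].
#' @return named numeric vector.
#' @export
role_palette <- function(migrating = 1.0, target = 0.8, subgoal = 0.9,
                         environment = 0.5) {
  pal <- c(migrating = migrating, target = target, subgoal = subgoal,
           environment = environment)
  if (anyDuplicated(pal)) stop("role intensities must be pairwise distinct")
  pal
}

#' Rasterize one frame into grayscale and depth images
#'
#' Each cell is drawn as a filled disc of its projected nucleus radius at
#' its (x, y); where discs overlap, the cell nearer the (top-view) camera
#' wins. The grayscale channel encodes the role intensity (so it carries
#' x, y position and size); the depth channel encodes the normalized
#' camera-distance to the nearest sphere surface (so it carries z).
#' Background is gray 0 and depth 1; depth is normalized linearly between
#' the frame's z-extremes (including radii).
#'
#' @param frame_tab one frame of cell records (>= 1 cell).
#' @param camera \code{\link{tissue_camera}}.
#' @param palette \code{\link{role_palette}}.
#' @param annotations named character vector mapping cell names to roles
#'   (\code{"migrating"}, \code{"target"}, \code{"subgoal"}); unlisted cells
#'   are environment cells.
#' @return list with matrices \code{gray} and \code{depth} (rows = image
#'   rows, i.e. decreasing world y; columns = increasing world x).
#' @export
rasterize <- function(frame_tab, camera = NULL, palette = role_palette(),
                      annotations = character()) {
  if (nrow(frame_tab) < 1L) stop("empty frame")
  if (is.null(camera)) camera <- default_camera(frame_tab)
  S <- camera$image_size
  D <- camera$distance
  ctr <- camera$target_position
  px <- 2 * D / S                         # world units per pixel
  xs <- ctr[1L] - D + (seq_len(S) - 0.5) * px   # pixel-centre world x (cols)
  ys <- ctr[2L] + D - (seq_len(S) - 0.5) * px   # pixel-centre world y (rows)
  gray <- matrix(0, S, S)
  hmax <- matrix(-Inf, S, S)
  r <- frame_tab$diameter / 2
  zlo <- min(frame_tab$z - r)
  zhi <- max(frame_tab$z + r)
  roles <- rep("environment", nrow(frame_tab))
  hit <- match(frame_tab$name, names(annotations))
  roles[!is.na(hit)] <- annotations[hit[!is.na(hit)]]
  for (i in seq_len(nrow(frame_tab))) {
    cx <- frame_tab$x[i]; cy <- frame_tab$y[i]; cz <- frame_tab$z[i]
    cols <- which(abs(xs - cx) <= r[i])
    rows <- which(abs(ys - cy) <= r[i])
    if (!length(cols) || !length(rows)) next
    dx2 <- (xs[cols] - cx)^2
    dy2 <- (ys[rows] - cy)^2
    d2 <- outer(dy2, dx2, `+`)
    inside <- d2 <= r[i]^2
    if (!any(inside)) next
    h <- matrix(-Inf, length(rows), length(cols))
    h[inside] <- cz + sqrt(pmax(r[i]^2 - d2[inside], 0))
    sub_h <- hmax[rows, cols, drop = FALSE]
    win <- h > sub_h
    if (any(win)) {
      sub_g <- gray[rows, cols, drop = FALSE]
      sub_g[win] <- palette[[roles[i]]]
      sub_h[win] <- h[win]
      gray[rows, cols] <- sub_g
      hmax[rows, cols] <- sub_h
    }
  }
  depth <- matrix(1, S, S)
  drawn <- is.finite(hmax)
  depth[drawn] <- (zhi - hmax[drawn]) / (zhi - zlo)
  depth <- pmin(pmax(depth, 0), 1)
  list(gray = gray, depth = depth)
}

# Camera covering a frame (or series bounding box) with a small margin.
default_camera <- function(frame_tab, image_size = 64L, margin = 1.15) {
  ctr <- c(mean(range(frame_tab$x)), mean(range(frame_tab$y)),
           mean(range(frame_tab$z)))
  half <- max(diff(range(frame_tab$x)), diff(range(frame_tab$y))) / 2 +
    max(frame_tab$diameter) / 2
  tissue_camera(ctr, distance = max(half * margin, 1), image_size = image_size)
}

#' Stack grayscale and depth images into a learning observation
#'
#' @param gray,depth equal-size square matrices in [0, 1].
#' @return array of dim \code{c(2, S, S)}: channel 1 gray, channel 2 depth.
#' @export
build_observation <- function(gray, depth) {
  if (!all(dim(gray) == dim(depth)))
    stop("gray and depth must have the same size")
  if (any(gray < 0 | gray > 1) || any(depth < 0 | depth > 1))
    stop("observation values must lie in [0, 1]")
  S <- nrow(gray)
  obs <- array(0, dim = c(2L, S, ncol(gray)))
  obs[1L, , ] <- gray
  obs[2L, , ] <- depth
  obs
}

# Flatten an observation to the channel-major (C, H, W) row-major layout
# the policy networks expect.
flatten_obs <- function(obs) {
  as.vector(aperm(obs, c(3L, 2L, 1L)))
}

#' Render inspection views of an environment frame to PNG files
#'
#' Writes, per camera, the grayscale and depth top views plus an annotated
#' 2-D inspection view with the role colors (migrating red, target green,
#' subgoal white, environment blue).
#'
#' @param env tissue environment (see \code{\link{create_tissue_env}}).
#' @param cameras list of \code{\link{tissue_camera}}; default one camera
#'   covering the scene.
#' @param out_dir output directory (created if needed).
#' @return character vector of file paths written.
#' @export
render_views <- function(env, cameras = NULL, out_dir) {
  tab <- env$cell_table
  if (is.null(cameras)) cameras <- list(default_camera(tab))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  ann <- env_annotations(env)
  files <- character()
  for (k in seq_along(cameras)) {
    cam <- cameras[[k]]
    img <- rasterize(tab, cam, annotations = ann)
    for (ch in c("gray", "depth")) {
      f <- file.path(out_dir, sprintf("frame%04d_cam%d_%s.png",
                                      env$frame_index, k, ch))
      grDevices::png(f, width = cam$image_size, height = cam$image_size)
      graphics::par(mar = c(0, 0, 0, 0))
      graphics::image(t(img[[ch]])[, nrow(img[[ch]]):1],
                      col = grDevices::gray.colors(256, 0, 1),
                      axes = FALSE, useRaster = TRUE)
      grDevices::dev.off()
      files <- c(files, f)
    }
    f <- file.path(out_dir, sprintf("frame%04d_cam%d_annotated.png",
                                    env$frame_index, k))
    grDevices::png(f, width = 480, height = 480)
    graphics::par(mar = c(2, 2, 1, 1))
    role <- rep("environment", nrow(tab))
    hit <- match(tab$name, names(ann))
    role[!is.na(hit)] <- ann[hit[!is.na(hit)]]
    cols <- c(migrating = "red", target = "green3", subgoal = "white",
              environment = "steelblue")
    graphics::plot(NA, xlim = cam$target_position[1L] + c(-1, 1) * cam$distance,
                   ylim = cam$target_position[2L] + c(-1, 1) * cam$distance,
                   xlab = "x", ylab = "y", asp = 1)
    graphics::rect(graphics::par("usr")[1], graphics::par("usr")[3],
                   graphics::par("usr")[2], graphics::par("usr")[4],
                   col = "gray20")
    graphics::symbols(tab$x, tab$y, circles = tab$diameter / 2,
                      inches = FALSE, add = TRUE, bg = cols[role],
                      fg = "gray40")
    grDevices::dev.off()
    files <- c(files, f)
  }
  files
}
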