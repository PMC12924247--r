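#' Construct an embryo tracking series
#'
#' An \code{embryo_series} holds a nucleus-tracking time series: one record
#' per cell per frame with the cell's lineage name, position (micrometres),
#' and nucleus diameter (micrometres). It is the central container consumed
#' by the neighbor models, the tissue environment, and the analysis helpers.
#'
#' @param cells data.frame with columns \code{frame} (0-based integer),
#'   \code{name} (lineage string), \code{x}, \code{y}, \code{z} (micrometres)
#'   and \code{diameter} (nucleus diameter, micrometres).
#' @param frame_interval seconds between consecutive frames (default 60, the
#'   native acquisition interval of confocal lineage recordings).
#' @param voxel_scale micrometres per pixel/plane on x, y, z; defaults to the
#'   40x confocal resolution \code{c(0.254, 0.254, 0.1)}.
#' @param metadata optional list (embryo id, provenance, ...).
#' @return object of class \code{embryo_series}.
#' @export
embryo_series <- function(cells, frame_interval = 60,
                          voxel_scale = c(0.254, 0.254, 0.1),
                          metadata = list()) {
  stopifnot(is.data.frame(cells))
  required <- c("frame", "name", "x", "y", "z", "diameter")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  cells <- cells[required]
  cells$frame <- as.integer(cells$frame)
  cells$name <- as.character(cells$name)
  for (col in c("x", "y", "z", "diameter"))
    cells[[col]] <- as.numeric(cells[[col]])
  cells <- cells[order(cells$frame, cells$name), , drop = FALSE]
  rownames(cells) <- NULL
  obj <- structure(
    list(cells = cells,
         frame_interval = as.numeric(frame_interval),
         voxel_scale = as.numeric(voxel_scale),
         metadata = metadata),
    class = "embryo_series")
  validate_series(obj)
  obj
}

#' Validate an embryo series
#'
#' Checks the container invariants: positive nucleus diameters, non-empty
#' names, finite positions, unique (frame, name) pairs, frames forming a
#' consecutive 0-based run, and contiguous per-cell lifetimes (a cell absent
#' mid-life would mean a broken track; cells may only disappear for good,
#' e.g. at a division where the children take over).
#'
#' @param series embryo_series.
#' @return the series, invisibly; errors describe the first violation found.
#' @export
validate_series <- function(series) {
  if (!inherits(series, "embryo_series")) stop("not an embryo_series")
  cells <- series$cells
  if (nrow(cells) == 0L) stop("series contains no cell records")
  if (any(!nzchar(cells$name))) stop("empty cell name")
  if (any(!is.finite(as.matrix(cells[c("x", "y", "z")]))))
    stop("non-finite cell position")
  if (any(!is.finite(cells$diameter)) || any(cells$diameter <= 0))
    stop("nucleus diameter must be > 0")
  if (!is.finite(series$frame_interval) || series$frame_interval <= 0)
    stop("frame_interval must be > 0")
  if (length(series$voxel_scale) != 3L || any(series$voxel_scale <= 0))
    stop("voxel_scale must be 3 positive scales")
  key <- paste(cells$frame, cells$name, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (frame, name) record: ",
         key[duplicated(key)][1L])
  fr <- sort(unique(cells$frame))
  if (fr[1L] != 0L || !identical(fr, seq(0L, fr[length(fr)])))
    stop("frames must form a consecutive run starting at 0")
  # contiguous lifetimes
  by_cell <- split(cells$frame, cells$name)
  for (nm in names(by_cell)) {
    f <- sort(by_cell[[nm]])
    if (!identical(f, seq(f[1L], f[length(f)])))
      stop("cell '", nm, "' has a gap in its track")
  }
  invisible(series)
}

#' @export
print.embryo_series <- function(x, ...) {
  fr <- n_frames(x)
  cat("embryo_series:", fr, "frames,",
      length(unique(x$cells$name)), "cells,",
      "frame interval", x$frame_interval, "s\n")
  invisible(x)
}

#' Number of frames in a series
#' @param series embryo_series.
#' @return integer frame count.
#' @export
n_frames <- function(series) {
  max(series$cells$frame) + 1L
}

#' Extract one frame of a series
#' @param series embryo_series.
#' @param frame 0-based frame index.
#' @return data.frame of the cell records at that frame.
#' @export
frame_table <- function(series, frame) {
  frame <- as.integer(frame)
  if (frame < 0L || frame >= n_frames(series))
    stop("frame ", frame, " out of range")
  out <- series$cells[series$cells$frame == frame, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a nucleus-tracking series from disk
#'
#' Two dialects are supported: the canonical tab-separated table with columns
#' \code{frame, name, x, y, z, diameter} (one file, coordinates already in
#' micrometres), and an AceTree-like directory of per-frame CSV files
#' (columns \code{name, x, y, z, diameter}, coordinates in pixels/planes,
#' frames taken in lexicographic file order). Pixel-space input is converted
#' to micrometres with \code{voxel_scale}; z is a plane index scaled by the
#' z-resolution.
#'
#' @param path file (tsv dialect) or directory (acetree dialect).
#' @param dialect \code{"tsv"} or \code{"acetree"}.
#' @param voxel_scale micrometres per pixel/plane (x, y, z).
#' @param frame_interval seconds between frames.
#' @param units \code{"um"} (default for tsv) or \code{"px"} (default for
#'   acetree): unit of the on-disk coordinates.
#' @return validated \code{embryo_series} with frames re-indexed from 0.
#' @export
read_series <- function(path, dialect = c("tsv", "acetree"),
                        voxel_scale = c(0.254, 0.254, 0.1),
                        frame_interval = 60,
                        units = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(units)) units <- if (dialect == "tsv") "um" else "px"
  units <- match.arg(units, c("um", "px"))
  if (dialect == "tsv") {
    if (!file.exists(path)) stop("no such file: ", path)
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
    required <- c("frame", "name", "x", "y", "z", "diameter")
    missing_cols <- setdiff(required, header)
    if (length(missing_cols))
      stop("format error: missing column(s) ",
           paste(missing_cols, collapse = ", "))
    cells <- utils::read.table(path, header = TRUE, sep = "\t",
                               colClasses = c(frame = "integer",
                                              name = "character",
                                              x = "numeric", y = "numeric",
                                              z = "numeric",
                                              diameter = "numeric"),
                               quote = "", comment.char = "")
  } else {
    if (!dir.exists(path)) stop("no such directory: ", path)
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (!length(files)) stop("no per-frame CSV files in ", path)
    tabs <- lapply(seq_along(files), function(i) {
      tab <- utils::read.csv(files[i], colClasses = c(name = "character"))
      required <- c("name", "x", "y", "z", "diameter")
      missing_cols <- setdiff(required, names(tab))
      if (length(missing_cols))
        stop("format error in ", files[i], ": missing column(s) ",
             paste(missing_cols, collapse = ", "))
      tab$frame <- i - 1L
      tab[c("frame", "name", "x", "y", "z", "diameter")]
    })
    cells <- do.call(rbind, tabs)
  }
  if (anyDuplicated(paste(cells$frame, cells$name)))
    stop("duplicate (frame, name) record in input")
  fr <- sort(unique(cells$frame))
  if (any(diff(fr) <= 0)) stop("non-monotone frame indices")
  cells$frame <- match(cells$frame, fr) - 1L
  if (units == "px") {
    cells$x <- cells$x * voxel_scale[1L]
    cells$y <- cells$y * voxel_scale[2L]
    cells$z <- cells$z * voxel_scale[3L]
    cells$diameter <- cells$diameter * voxel_scale[1L]
  }
  embryo_series(cells, frame_interval = frame_interval,
                voxel_scale = voxel_scale,
                metadata = list(source = path, dialect = dialect))
}

#' Write a series to the canonical tab-separated dialect
#'
#' Numeric fields are written with 17 significant digits so that
#' \code{read_series(write_series(s))} reproduces \code{s} bit-exactly.
#'
#' @param series embryo_series.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_series <- function(series, path) {
  validate_series(series)
  cells <- series$cells
  if (nrow(cells) == 0L) stop("nothing to write: empty series")
  lines <- c(paste(c("frame", "name", "x", "y", "z", "diameter"),
                   collapse = "\t"),
             paste(cells$frame, cells$name,
                   sprintf("%.17g", cells$x), sprintf("%.17g", cells$y),
                   sprintf("%.17g", cells$z),
                   sprintf("%.17g", cells$diameter),
                   sep = "\t"))
  ok <- tryCatch({
    writeLines(lines, path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", path)
  invisible(path)
}

#' Temporally upsample a series by linear interpolation
#'
#' Refines the frame grid by an integer factor (default 10, turning the
#' native 60 s interval into 6 s) so that the per-step displacement of the
#' agent is small during reinforcement-learning training. Positions and
#' nucleus sizes are interpolated linearly per cell over intervals where the
#' cell exists at both endpoint frames; values at the original frame times
#' are preserved exactly. Cells that appear or disappear (e.g. at a
#' division) are not interpolated across the boundary: a disappearing cell's
#' last sub-frame is the copy of its last original frame, and a new cell
#' starts at the copy of its first original frame.
#'
#' @param series embryo_series with at least 2 frames.
#' @param factor positive integer refinement factor.
#' @return embryo_series with \code{factor * (N - 1) + 1} frames and
#'   \code{frame_interval / factor}.
#' @export
upsample <- function(series, factor = 10L) {
  validate_series(series)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  nf <- n_frames(series)
  if (nf < 2L) stop("need at least 2 frames to upsample")
  if (factor == 1L) return(series)
  cells <- series$cells
  pieces <- vector("list", nf - 1L)
  for (i in seq_len(nf - 1L) - 1L) {
    a <- cells[cells$frame == i, , drop = FALSE]
    b <- cells[cells$frame == i + 1L, , drop = FALSE]
    common <- intersect(a$name, b$name)
    ia <- match(common, a$name)
    ib <- match(common, b$name)
    sub <- lapply(seq_len(factor) - 1L, function(k) {
      if (k == 0L) {
        out <- a
      } else {
        w <- k / factor
        out <- data.frame(frame = 0L, name = common,
                          x = (1 - w) * a$x[ia] + w * b$x[ib],
                          y = (1 - w) * a$y[ia] + w * b$y[ib],
                          z = (1 - w) * a$z[ia] + w * b$z[ib],
                          diameter = (1 - w) * a$diameter[ia] +
                            w * b$diameter[ib],
                          stringsAsFactors = FALSE)
      }
      out$frame <- factor * i + k
      out
    })
    pieces[[i + 1L]] <- do.call(rbind, sub)
  }
  last <- cells[cells$frame == nf - 1L, , drop = FALSE]
  last$frame <- factor * (nf - 1L)
  out <- do.call(rbind, c(pieces, list(last)))
  embryo_series(out, frame_interval = series$frame_interval / factor,
                voxel_scale = series$voxel_scale,
                metadata = c(series$metadata, list(upsampled = factor)))
}

#' Admissible child names of a lineage name
#'
#' Lineage names grow by one suffix character per division; the suffix
#' alphabet encodes the division axis (anterior/posterior, dorsal/ventral,
#' left/right). \code{lineage_children("Cpaa")} therefore contains
#' \code{"Cpaaa"} and \code{"Cpaap"}.
#'
#' @param name non-empty lineage name.
#' @return character vector of the six admissible child names.
#' @export
lineage_children <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("name must be a single non-empty string")
  paste0(name, c("a", "p", "d", "v", "l", "r"))
}

#' Frame window over which two cells co-exist
#'
#' The migration window is the intersection of the two cells' lifetimes:
#' from the later of the two first appearances to the earlier of the two
#' disappearances (e.g. the migrating cell's division ends its window).
#'
#' @param series embryo_series.
#' @param migrating,target cell names, both present in the series.
#' @return integer vector \code{c(start_frame, end_frame)} (0-based,
#'   inclusive).
#' @export
migration_window <- function(series, migrating, target) {
  f1 <- series$cells$frame[series$cells$name == migrating]
  f2 <- series$cells$frame[series$cells$name == target]
  if (!length(f1)) stop("cell '", migrating, "' not in series")
  if (!length(f2)) stop("cell '", target, "' not in series")
  start <- max(min(f1), min(f2))
  end <- min(max(f1), max(f2))
  if (start > end)
    stop("empty migration window: '", migrating, "' and '", target,
         "' never co-exist")
  c(start = start, end = end)
}
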