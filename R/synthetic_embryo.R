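#' Specification of a synthetic embryo / migration scenario
#'
#' Describes the stated world that the generator emulates: cells packed
#' inside an ellipsoidal eggshell at embryo-like density (pairwise
#' distance-ratio mostly inside the acceptable 0.3--0.8 band), a migrating
#' cell with a known corridor path between two static rows of flanking
#' cells (the intercalation geometry), a 60 s native frame interval, and
#' small Gaussian positional jitter on environment cells.
#'
#' @param n_cells total cell count (>= 3; default 20).
#' @param eggshell ellipsoid semi-axes in micrometres.
#' @param corridor list: \code{n_per_row} flanking cells per row,
#'   \code{row_offset} lateral offset of the rows (units of the effective
#'   cell radius), \code{spacing} along-row spacing (same units).
#' @param migrating_name,target_name lineage names of the migrating cell and
#'   its destination.
#' @param total_time scenario duration, seconds.
#' @param frame_interval seconds per frame (default 60, the native
#'   acquisition interval).
#' @param jitter_sd per-frame Gaussian jitter of environment cells,
#'   micrometres (the migrating cell gets a quarter of it so its path length
#'   stays close to the corridor length).
#' @param seed integer; all outputs are pure functions of the spec.
#' @return list of class \code{scenario_spec}.
#' @export
scenario_spec <- function(n_cells = 20L,
                          eggshell = c(32, 12, 10),
                          corridor = list(n_per_row = 4L, row_offset = 1.0,
                                          spacing = 1.3),
                          migrating_name = "Cpaaa",
                          target_name = "ABarpaapp",
                          total_time = 2700,
                          frame_interval = 60,
                          jitter_sd = 0.2,
                          seed = 1L) {
  stopifnot(n_cells >= 3L, all(eggshell > 0),
            total_time >= 2 * frame_interval, jitter_sd >= 0)
  structure(list(n_cells = as.integer(n_cells), eggshell = eggshell,
                 corridor = corridor, migrating_name = migrating_name,
                 target_name = target_name, total_time = total_time,
                 frame_interval = frame_interval, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# Effective (tissue-tiling) radius implied by a spec: each of the n cells
# occupies an equal share of the eggshell volume.
spec_cell_radius <- function(spec) {
  vol <- 4 / 3 * pi * prod(spec$eggshell)
  (3 * vol / (4 * pi * spec$n_cells))^(1 / 3)
}

# Systematic lineage-style names: founder prefix plus division suffixes.
synth_names <- function(prefix, n) {
  suf <- c("a", "p", "d", "v", "l", "r")
  pool <- suf
  while (length(pool) < n)
    pool <- as.vector(outer(pool, suf, paste0))
  paste0(prefix, pool[seq_len(n)])
}

inside_eggshell <- function(pos, semi, margin = 1) {
  sum((pos / (semi * margin))^2) <= 1
}

clamp_eggshell <- function(pos, semi) {
  s <- sqrt(sum((pos / semi)^2))
  if (s > 0.995) pos * 0.995 / s else pos
}

# Face-centred-cubic lattice sites with nearest-neighbor spacing s,
# covering the eggshell bounding box.
fcc_sites <- function(semi, s) {
  a <- s * sqrt(2)                    # cubic cell edge
  nx <- ceiling(semi[1L] / a) + 1L
  ny <- ceiling(semi[2L] / a) + 1L
  nz <- ceiling(semi[3L] / a) + 1L
  base <- as.matrix(expand.grid(x = (-nx:nx) * a, y = (-ny:ny) * a,
                                z = (-nz:nz) * a))
  offs <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5),
                c(0, 0.5, 0.5)) * a
  do.call(rbind, lapply(seq_len(4L), function(k)
    sweep(base, 2L, offs[k, ], `+`)))
}

# Tissue-like sphere packing: cells sit on a jittered close-packed (fcc)
# lattice clipped to the eggshell -- early embryos are near close packing,
# and a lattice-like arrangement keeps adjacent-pair distance ratios
# inside the acceptable band. Candidate sites are rejected when excluded,
# outside the shell, or too close to already-placed cells; the n
# surviving sites nearest the cluster centre are used.
pack_cells <- function(n, semi, radius, existing = NULL,
                       spacing_factor = 1.0, jitter_frac = 0.04,
                       ratio_min = 0.55, exclude_fn = NULL, center = NULL) {
  s <- spacing_factor * radius
  sites <- fcc_sites(semi, s)
  keep <- apply(sites, 1L, inside_eggshell, semi = semi, margin = 0.9)
  sites <- sites[keep, , drop = FALSE]
  if (!is.null(exclude_fn))
    sites <- sites[!apply(sites, 1L, exclude_fn), , drop = FALSE]
  if (!is.null(existing) && nrow(existing)) {
    ok <- apply(sites, 1L, function(p) {
      d <- sqrt(rowSums((existing - matrix(p, nrow(existing), 3,
                                           byrow = TRUE))^2))
      all(d / (2 * radius) >= ratio_min)
    })
    sites <- sites[ok, , drop = FALSE]
  }
  if (nrow(sites) < n)
    stop("sphere packing infeasible: only ", nrow(sites),
         " admissible sites for ", n, " cells; try fewer cells or a ",
         "larger eggshell")
  if (is.null(center))
    center <- if (!is.null(existing) && nrow(existing)) colMeans(existing)
              else c(0, 0, 0)
  ord <- order(sqrt(rowSums(sweep(sites, 2L, center)^2)))
  chosen <- sites[ord[seq_len(n)], , drop = FALSE]
  chosen + matrix(stats::rnorm(3L * n, 0, jitter_frac * s), n, 3L)
}

# Assemble frames from home positions: environment cells jitter around home,
# the migrating cell (if any) follows its path with reduced jitter.
series_from_homes <- function(spec, homes, names, diam,
                              path = NULL, migrating_idx = NULL) {
  nf <- floor(spec$total_time / spec$frame_interval) + 1L
  semi <- spec$eggshell
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    pos <- homes +
      matrix(stats::rnorm(length(homes), 0, spec$jitter_sd),
             nrow(homes), 3)
    if (!is.null(path)) {
      pos[migrating_idx, ] <- path[f, ] +
        stats::rnorm(3, 0, spec$jitter_sd / 4)
    }
    pos <- t(apply(pos, 1L, clamp_eggshell, semi = semi))
    frames[[f]] <- data.frame(frame = f - 1L, name = names,
                              x = pos[, 1], y = pos[, 2], z = pos[, 3],
                              diameter = diam, stringsAsFactors = FALSE)
  }
  embryo_series(do.call(rbind, frames),
                frame_interval = spec$frame_interval,
                metadata = list(provenance = "synthetic",
                                seed = spec$seed))
}

#' Generate a synthetic embryo series (packing only)
#'
#' Cells are packed inside the eggshell by rejection-sampled sphere packing
#' at tissue density, so that most Voronoi-adjacent pairs have a
#' centre-distance to radius-sum ratio inside the acceptable (0.3, 0.8)
#' band, then jittered frame to frame. Deterministic given the spec's seed.
#'
#' @param spec \code{\link{scenario_spec}}.
#' @return \code{embryo_series}.
#' @export
generate_embryo <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_seed(spec$seed, {
    r_eff <- spec_cell_radius(spec)
    homes <- pack_cells(spec$n_cells, spec$eggshell, r_eff)
    names <- synth_names("MS", spec$n_cells)
    diam <- stats::runif(spec$n_cells, 0.70, 0.85) * 2 * r_eff
    series_from_homes(spec, homes, names, diam)
  })
}

#' Generate a migration (intercalation) scenario
#'
#' Builds an embryo in which the migrating cell traverses a straight
#' corridor flanked by two static rows of cells, ending as a neighbor of
#' the target cell at the corridor's far end -- the synthetic analogue of a
#' cell intercalating between two rows toward its destination. The
#' returned ground-truth path is the migrating cell's noise-free
#' piecewise-linear trajectory; distance to the target decreases
#' monotonically along it up to jitter.
#'
#' @param spec \code{\link{scenario_spec}}.
#' @return list with \code{series} (embryo_series) and \code{path}
#'   (frames x 3 matrix of ground-truth migrating positions).
#' @export
generate_migration_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  cor <- spec$corridor
  n_row <- 2L * cor$n_per_row
  n_fill <- spec$n_cells - n_row - 2L
  if (n_fill < 0L)
    stop("n_cells too small for the corridor: need at least ", n_row + 2L)
  with_seed(spec$seed, {
    r_eff <- spec_cell_radius(spec)
    spacing <- cor$spacing * r_eff                # along-row centre spacing
    row_y <- cor$row_offset * r_eff
    # corridor geometry along +x, target at the far end
    target_x <- 0.52 * spec$eggshell[1L]
    row_x <- target_x - seq_len(cor$n_per_row) * spacing
    gap_needed <- 0.5 * r_eff                      # migrating half-width
    if (2 * row_y <= 2 * gap_needed)
      stop("corridor blocked: row gap smaller than the migrating cell")
    x_end <- target_x - 1.5 * r_eff               # final contact ratio ~0.5
    x_start <- target_x - 3.4 * r_eff             # already between the rows
    rows <- rbind(cbind(row_x, row_y, 0), cbind(row_x, -row_y, 0))
    target_home <- c(target_x, 0, 0)
    fixed <- rbind(rows, target_home)
    # fillers keep out of the corridor tube around the migration path
    excl <- function(p) {
      sqrt(p[2L]^2 + p[3L]^2) < row_y &&
        p[1L] > min(row_x) - r_eff && p[1L] < target_x + r_eff
    }
    # fillers cluster around the corridor entrance: the migrating cell
    # starts embedded in tissue rather than at an open edge
    homes <- if (n_fill > 0L)
      rbind(fixed, pack_cells(n_fill, spec$eggshell, r_eff,
                              existing = fixed, exclude_fn = excl,
                              center = c(x_start, 0, 0)))
    else fixed
    nf <- floor(spec$total_time / spec$frame_interval) + 1L
    w <- seq(0, 1, length.out = nf)
    path <- cbind(x_start + w * (x_end - x_start), 0, 0)
    homes <- rbind(homes, path[1L, ])              # migrating home (frame 0)
    row_names <- setdiff(synth_names("ABarpaa", n_row + 2L),
                         c(spec$target_name, spec$migrating_name))
    names <- c(row_names[seq_len(n_row)], spec$target_name,
               if (n_fill > 0L) synth_names("MS", n_fill),
               spec$migrating_name)
    diam <- stats::runif(length(names), 0.70, 0.85) * 2 * r_eff
    series <- series_from_homes(spec, homes, names, diam,
                                path = path,
                                migrating_idx = length(names))
    list(series = series, path = path)
  })
}

#' Remove named cells from every frame of a series
#'
#' Used by the neighbor-influence experiment: deletes the given cells from
#' all frames and leaves every other record bit-identical.
#'
#' @param series embryo_series.
#' @param names character vector of cell names to delete (may be empty).
#' @return embryo_series without the named cells.
#' @export
remove_cells <- function(series, names) {
  validate_series(series)
  if (!length(names)) return(series)
  unknown <- setdiff(names, unique(series$cells$name))
  if (length(unknown))
    stop("unknown cell name(s): ", paste(unknown, collapse = ", "))
  out <- series
  out$cells <- series$cells[!(series$cells$name %in% names), , drop = FALSE]
  rownames(out$cells) <- NULL
  validate_series(out)
  out
}

#' Introduce a cell division into a series
#'
#' From \code{division_frame} on, the named cell is replaced by two children
#' (name + \code{"a"} and name + \code{"p"}, the lineage-suffix convention)
#' placed symmetrically about the parent position along the division axis,
#' each with the parent volume split in half. Used to emulate the optional
#' divisions of real lineage recordings.
#'
#' @param series embryo_series.
#' @param name dividing cell; must exist at \code{division_frame}.
#' @param division_frame 0-based frame of the first frame with children.
#' @param axis unit 3-vector of the division axis (default x).
#' @param separation centre-to-centre child distance in units of the parent
#'   radius.
#' @return embryo_series with the division applied.
#' @export
divide_cell <- function(series, name, division_frame, axis = c(1, 0, 0),
                        separation = 0.8) {
  validate_series(series)
  cells <- series$cells
  sel <- cells$name == name & cells$frame >= division_frame
  if (!any(sel))
    stop("cell '", name, "' is not present at frame ", division_frame)
  axis <- axis / vec_norm(axis)
  par <- cells[sel, , drop = FALSE]
  off <- separation * par$diameter / 2 / 2
  mk <- function(suffix, sgn) {
    child <- par
    child$name <- paste0(name, suffix)
    child$x <- par$x + sgn * off * axis[1L]
    child$y <- par$y + sgn * off * axis[2L]
    child$z <- par$z + sgn * off * axis[3L]
    child$diameter <- par$diameter / 2^(1 / 3)   # volume halved
    child
  }
  out <- rbind(cells[!sel, , drop = FALSE], mk("a", -1), mk("p", 1))
  embryo_series(out, frame_interval = series$frame_interval,
                voxel_scale = series$voxel_scale,
                metadata = series$metadata)
}
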