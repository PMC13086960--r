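# Trajectory-derived observables: deepest-water depth, penetration traces,
# pore occupancy, in-region net charge, density scans, water clusters.

# molecules laterally inside the pore cylinder (periodic in x, y only)
.lateral_inside <- function(com, region, box) {
  lateral_dist(com$x, com$y, region$axis, box) <= region$radius
}

# molecules fully inside the cylinder (lateral gate + z interval)
.inside_cylinder <- function(com, region, box) {
  .lateral_inside(com, region, box) &
    com$z >= region$z_bottom & com$z <= region$z_top
}

#' Deepest-water penetration depth
#'
#' For each frame, takes the minimum water center-of-mass z among waters
#' laterally inside the pore cylinder, then averages over frames. Negative
#' values indicate penetration below the wax surface; the reported depths
#' for one/two/three C12E6 surfactants are -0.42/-0.55/-0.66 nm by this
#' metric (and -0.24/-0.27/-0.31 nm for C12G1).
#'
#' @param traj a [trajectory()] containing water molecules.
#' @param region a [pore_region()].
#' @param discard fraction of initial frames to drop before averaging
#'   (default 0, i.e. average over the whole trajectory).
#' @return mean deepest-water z (nm).
#' @export
deepest_water_depth <- function(traj, region, discard = 0) {
  stopifnot(inherits(traj, "trajectory"), inherits(region, "pore_region"))
  n <- length(traj$frames)
  keep <- seq_len(n) > floor(discard * n)
  minima <- vapply(traj$frames[keep], function(f) {
    com <- molecule_com(f)
    w <- com[com$species == "water", , drop = FALSE]
    if (nrow(w) == 0) stop("trajectory frame contains no water molecules")
    w <- w[.lateral_inside(w, region, traj$box), , drop = FALSE]
    if (nrow(w) == 0) return(NA_real_)
    min(w$z)
  }, 0)
  if (all(is.na(minima))) stop("no water inside the pore cylinder in any frame")
  mean(minima, na.rm = TRUE)
}

# internal constructor shared by the generator and the extractor
penetration_trace_new <- function(times, depths, z0) {
  structure(list(times = as.numeric(times), depths = as.numeric(depths),
                 z0 = z0),
            class = "penetration_trace")
}

#' @export
print.penetration_trace <- function(x, ...) {
  cat("penetration_trace:", length(x$times), "samples, t =",
      sprintf("%g..%g ns,", x$times[1], x$times[length(x$times)]),
      "z0 =", x$z0, "nm, final z =",
      sprintf("%.3f nm\n", x$depths[length(x$depths)]))
  invisible(x)
}

#' Extract a species penetration trace z(t)
#'
#' Per frame, the minimum center-of-mass z among molecules of the species
#' laterally inside the pore cylinder. The trace anchor `z0` is the depth
#' at the first frame (the position at t = 0, on the surface).
#'
#' @param traj a [trajectory()].
#' @param species molecule species label (e.g. `"surfactant"`).
#' @param region a [pore_region()].
#' @return A `penetration_trace` with fields `times` (ns), `depths` (nm)
#'   and `z0` (nm).
#' @export
penetration_trace <- function(traj, species, region) {
  stopifnot(inherits(traj, "trajectory"), inherits(region, "pore_region"))
  depths <- vapply(traj$frames, function(f) {
    com <- molecule_com(f)
    s <- com[com$species == species, , drop = FALSE]
    if (nrow(s) == 0) stop("species '", species, "' absent from trajectory")
    s <- s[.lateral_inside(s, region, traj$box), , drop = FALSE]
    if (nrow(s) == 0) return(NA_real_)
    min(s$z)
  }, 0)
  if (anyNA(depths)) {
    stop("species '", species, "' is outside the pore cylinder in some frames")
  }
  penetration_trace_new(traj$times, depths, z0 = depths[1])
}

#' Per-species pore occupancy counts
#'
#' Number of molecules of each species whose center of mass lies inside
#' the pore cylinder at a stated time (default: the final frame) — the
#' per-species uptake count through the nanopore.
#'
#' @param traj a [trajectory()].
#' @param region a [pore_region()].
#' @param species character vector of species to count.
#' @param time frame time (ns); must match a frame time exactly.
#' @return named integer vector of counts.
#' @export
occupancy_counts <- function(traj, region, species,
                             time = traj$times[length(traj$times)]) {
  stopifnot(inherits(traj, "trajectory"), inherits(region, "pore_region"))
  i <- match(time, traj$times)
  if (is.na(i)) stop("requested time ", time, " ns is outside the trajectory")
  com <- molecule_com(traj$frames[[i]])
  inside <- com[.inside_cylinder(com, region, traj$box), , drop = FALSE]
  vapply(species, function(s) sum(inside$species == s), 0L)
}

#' Net formal charge inside a region
#'
#' Sum of molecule formal charges inside the pore cylinder at a stated
#' time. Zero indicates the charge neutrality maintained within pores
#' when cation and anion counts balance.
#'
#' @inheritParams occupancy_counts
#' @return integer net charge.
#' @export
net_charge_in_region <- function(traj, region,
                                 time = traj$times[length(traj$times)]) {
  stopifnot(inherits(traj, "trajectory"), inherits(region, "pore_region"))
  i <- match(time, traj$times)
  if (is.na(i)) stop("requested time ", time, " ns is outside the trajectory")
  com <- molecule_com(traj$frames[[i]])
  as.integer(sum(com$charge[.inside_cylinder(com, region, traj$box)]))
}

#' Molecule-location density scan
#'
#' Accumulates a 2-D occupancy histogram of molecule centers of mass over
#' all frames, one grid per species — the "scan of the location of each
#' molecule" rendered as top view (x, y) or side view (x, z).
#'
#' @param traj a [trajectory()].
#' @param plane `"top_view"` (x, y) or `"side_view"` (x, z).
#' @param bin_width bin width (nm).
#' @param species species to map (default: all present).
#' @param per_frame_average divide counts by the frame count (default
#'   FALSE: raw counts).
#' @return A `density_map` with fields `plane`, `bin_width`, `xbreaks`,
#'   `ybreaks`, `counts` (named list of matrices) and `frame_count`.
#' @export
density_scan <- function(traj, plane = c("top_view", "side_view"),
                         bin_width = 0.1, species = NULL,
                         per_frame_average = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  plane <- match.arg(plane)
  if (bin_width <= 0) stop("bin_width must be positive")
  if (any(traj$box <= 0)) stop("degenerate box")

  coms <- lapply(traj$frames, molecule_com)
  all_com <- do.call(rbind, coms)
  if (is.null(species)) species <- sort(unique(all_com$species))

  u <- all_com$x
  v <- if (plane == "top_view") all_com$y else all_com$z
  ulim <- c(0, traj$box[1])
  vlim <- if (plane == "top_view") c(0, traj$box[2]) else {
    c(floor(min(v) / bin_width) * bin_width,
      ceiling(max(v) / bin_width) * bin_width)
  }
  xbreaks <- seq(ulim[1], ulim[2] + bin_width * 0.999, by = bin_width)
  ybreaks <- seq(vlim[1], vlim[2] + bin_width * 0.999, by = bin_width)

  counts <- lapply(species, function(s) {
    sel <- all_com$species == s &
      u >= ulim[1] & u <= xbreaks[length(xbreaks)] &
      v >= vlim[1] & v <= ybreaks[length(ybreaks)]
    iu <- pmin(findInterval(u[sel], xbreaks, rightmost.closed = TRUE),
               length(xbreaks) - 1L)
    iv <- pmin(findInterval(v[sel], ybreaks, rightmost.closed = TRUE),
               length(ybreaks) - 1L)
    m <- matrix(0, nrow = length(xbreaks) - 1L, ncol = length(ybreaks) - 1L)
    if (length(iu) > 0) {
      t2 <- table(factor(iu, levels = seq_len(nrow(m))),
                  factor(iv, levels = seq_len(ncol(m))))
      m <- m + unclass(t2)
    }
    if (per_frame_average) m <- m / length(traj$frames)
    m
  })
  names(counts) <- species
  structure(list(plane = plane, bin_width = bin_width,
                 xbreaks = xbreaks, ybreaks = ybreaks,
                 counts = counts, frame_count = length(traj$frames)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat("density_map (", x$plane, "): ",
      nrow(x$counts[[1]]), " x ", ncol(x$counts[[1]]), " bins of ",
      x$bin_width, " nm, ", x$frame_count, " frames, species: ",
      paste(names(x$counts), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Render a density map
#'
#' @param x a `density_map`.
#' @param species which species grid to draw (default first).
#' @param ... passed to [graphics::image()].
#' @return invisibly, `x`.
#' @export
plot.density_map <- function(x, species = names(x$counts)[1], ...) {
  m <- x$counts[[species]]
  graphics::image(x = x$xbreaks, y = x$ybreaks, z = m,
                  xlab = "x (nm)",
                  ylab = if (x$plane == "top_view") "y (nm)" else "z (nm)",
                  main = species, useRaster = TRUE, ...)
  invisible(x)
}

#' Export a density map grid to a delimited file
#'
#' @param map a `density_map`.
#' @param path output path; one file per species with the species name
#'   appended is written when several grids are present.
#' @return invisibly, the paths written.
#' @export
write_density_map <- function(map, path) {
  paths <- character(0)
  for (s in names(map$counts)) {
    p <- if (length(map$counts) == 1) path else {
      paste0(tools::file_path_sans_ext(path), "_", s, ".",
             tools::file_ext(path))
    }
    utils::write.table(map$counts[[s]], p, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# minimal union-find over 1..n
.union_find <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  vapply(seq_len(n), find, 0L)
}

#' Detect discrete water clusters in a frame
#'
#' Connected components of the water-oxygen contact graph: two waters are
#' in contact when their O–O distance (periodic laterally, open along z)
#' is below the cutoff. A cluster is flagged `bulk_connected` when any
#' member lies in the bulk slab (z > `bulk_z`) or within the cutoff of
#' one that does; clusters inside the pore with no such path are the
#' discrete water clusters not connected to the aqueous phase above the
#' surface.
#'
#' @param frame one trajectory frame (see [trajectory()]).
#' @param cutoff O–O contact distance (nm, default 0.35, the first
#'   hydration-shell distance).
#' @param bulk_z z level above which water counts as bulk (nm, default 0,
#'   the wax surface).
#' @param box box for lateral periodic distances (or `NULL` for open
#'   boundaries).
#' @return A `cluster_set`: list with `cutoff`, `clusters` (list of
#'   molecule-id vectors, largest first), and `bulk_connected` (logical
#'   per cluster).
#' @export
water_clusters <- function(frame, cutoff = 0.35, bulk_z = 0, box = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive")
  ox <- frame[frame$species == "water" & frame$element == "O", , drop = FALSE]
  n <- nrow(ox)
  if (n == 0) {
    return(structure(list(cutoff = cutoff, clusters = list(),
                          bulk_connected = logical(0)),
                     class = "cluster_set"))
  }
  dx <- outer(ox$x, ox$x, "-")
  dy <- outer(ox$y, ox$y, "-")
  dz <- outer(ox$z, ox$z, "-")
  if (!is.null(box)) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
  }
  d2 <- dx^2 + dy^2 + dz^2
  adj <- which(upper.tri(d2) & d2 < cutoff^2, arr.ind = TRUE)
  comp <- .union_find(n, adj)
  ids <- split(ox$molecule_id, comp)
  zs <- split(ox$z, comp)
  ord <- order(-lengths(ids), vapply(ids, min, 0))
  ids <- ids[ord]; zs <- zs[ord]
  bulk <- vapply(zs, function(z) any(z > bulk_z), TRUE)
  # propagate bulk connection across the contact graph is implicit:
  # components are maximal, so any member above bulk_z marks the cluster
  structure(list(cutoff = cutoff,
                 clusters = unname(lapply(ids, function(v) sort(unname(v)))),
                 bulk_connected = unname(bulk)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$clusters), "clusters (cutoff",
      x$cutoff, "nm); sizes:",
      paste(lengths(x$clusters), collapse = ", "), "\n")
  if (length(x$clusters) > 0) {
    cat("  bulk-connected:", sum(x$bulk_connected), "of",
        length(x$clusters), "\n")
  }
  invisible(x)
}
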