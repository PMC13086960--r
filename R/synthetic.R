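#' Ground truth for synthetic penetration kinetics
#'
#' Parameters of the exponential-saturation depth law
#' `z(t) = -prefactor * (1 - exp(-A t))` used by the synthetic trajectory
#' generator: the penetration rate `A` (ns⁻¹), the lumped prefactor (nm,
#' the saturation depth M0/B), and the Gaussian depth-noise scale.
#'
#' @param A_true penetration rate (ns⁻¹), > 0.
#' @param prefactor_true saturation depth (nm), > 0.
#' @param noise_sigma Gaussian noise scale on depth (nm), >= 0.
#' @param seed integer seed.
#' @return A `kinetics_truth` list.
#' @export
kinetics_truth <- function(A_true = 0.02, prefactor_true = 3,
                           noise_sigma = 0, seed = 1L) {
  if (A_true <= 0) stop("A_true must be positive")
  if (prefactor_true <= 0) stop("prefactor_true must be positive")
  if (noise_sigma < 0) stop("noise scale must be >= 0")
  structure(list(A_true = A_true, prefactor_true = prefactor_true,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "kinetics_truth")
}

#' Simulate a penetration trajectory with known kinetics
#'
#' Emits a single tracer molecule whose depth follows the
#' exponential-saturation law plus i.i.d. Gaussian noise, as a stand-in
#' for a surfactant descending into the pore. The noise-free trace is
#' returned alongside so fitting can be validated against ground truth.
#'
#' @param truth a [kinetics_truth()].
#' @param times sampling schedule (ns), non-empty and increasing, starting
#'   at 0 or later.
#' @param axis lateral position of the tracer (nm pair).
#' @param box trajectory box (nm triple).
#' @return list with `trajectory` (the noisy [trajectory()]) and `trace`
#'   (the noise-free [penetration_trace()]).
#' @export
#' @examples
#' sim <- simulate_penetration(kinetics_truth(A = 0.02), times = 0:200)
#' tail(sim$trace$depths, 1)  # approx -3 * (1 - exp(-4))
simulate_penetration <- function(truth, times, axis = c(3, 3),
                                 box = c(6, 6, 20)) {
  if (!inherits(truth, "kinetics_truth")) truth <- do.call(kinetics_truth, truth)
  if (length(times) == 0) stop("schedule must be non-empty")
  if (any(diff(times) <= 0)) stop("schedule must be increasing")
  z_clean <- -truth$prefactor_true * (1 - exp(-truth$A_true * times))
  noise <- with_seed(truth$seed, stats::rnorm(length(times), 0, truth$noise_sigma))
  z_noisy <- z_clean + noise
  frames <- lapply(z_noisy, function(z) {
    data.frame(molecule_id = 1L, species = "surfactant", charge = 0L,
               element = "C", x = axis[1], y = axis[2], z = z,
               stringsAsFactors = FALSE)
  })
  list(
    trajectory = trajectory(frames, times, box),
    trace = penetration_trace_new(times, z_clean, z0 = 0)
  )
}

# ball of cubic-grid points (spacing < cluster cutoff) around a center,
# nearest-first, guaranteed internally connected
.cluster_offsets <- function(n, spacing = 0.28) {
  r <- 0L
  repeat {
    r <- r + 1L
    g <- expand.grid(i = -r:r, j = -r:r, k = -r:r)
    if (nrow(g) >= n) break
  }
  d <- sqrt(g$i^2 + g$j^2 + g$k^2)
  g <- g[order(d, g$i, g$j, g$k), ][seq_len(n), ]
  cbind(g$i, g$j, g$k) * spacing
}

#' Simulate a pore system with known water-cluster and ion layout
#'
#' Builds a single-frame (optionally replicated) trajectory containing
#' water clusters at prescribed positions inside the pore, an optional
#' bulk water slab above the surface, and prescribed ion counts per
#' region, so cluster detection, occupancy, and charge metrics can be
#' checked against construction.
#'
#' Cluster members are laid on a compact grid with 0.28 nm spacing (below
#' the default 0.35 nm clustering cutoff, so each cluster is internally
#' connected); clusters marked `bulk_connected` get a vertical water
#' bridge to the bulk slab. The generator errors if two clusters are
#' placed close enough to merge.
#'
#' @param layout list with elements:
#'   * `clusters`: list of `list(center = c(x, y, z), n = size,
#'     bulk_connected = FALSE)`;
#'   * `n_bulk`: waters in the bulk slab above z = 0 (default 0);
#'   * `ions`: data.frame with columns `species`, `charge`, `n`,
#'     `region` (`"pore"` or `"bulk"`), or `NULL`.
#' @param pore a [pore_region()].
#' @param seed integer seed for bulk/ion placement.
#' @param box box (nm triple).
#' @param n_frames number of (identical-roster) frames to emit; positions
#'   are static (default 1).
#' @param cutoff clustering cutoff the layout is built against (nm,
#'   default 0.35), used for the bridge spacing and the separation check.
#' @return A [trajectory()].
#' @export
simulate_pore_system <- function(layout, pore, seed = 1L, box = c(6, 6, 20),
                                 n_frames = 1L, cutoff = 0.35) {
  stopifnot(inherits(pore, "pore_region"))
  clusters <- layout$clusters %||% list()
  n_bulk <- layout$n_bulk %||% 0L
  ions <- layout$ions

  # inter-cluster separation check on bounding spheres
  if (length(clusters) >= 2) {
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        ci <- clusters[[i]]; cj <- clusters[[j]]
        ri <- 0.28 * ceiling((3 * ci$n / (4 * pi))^(1 / 3)) + 0.28
        rj <- 0.28 * ceiling((3 * cj$n / (4 * pi))^(1 / 3)) + 0.28
        d <- sqrt(sum((ci$center - cj$center)^2))
        if (d < ri + rj + cutoff) {
          stop("incompatible layout: clusters ", j, " and ", i,
               " are close enough to merge")
        }
      }
    }
  }

  # a bulk bridge is a vertical water chain; it must not thread another cluster
  if (length(clusters) >= 2) {
    for (i in seq_along(clusters)) {
      if (!isTRUE(clusters[[i]]$bulk_connected)) next
      ci <- clusters[[i]]
      for (j in seq_along(clusters)) {
        if (j == i) next
        cj <- clusters[[j]]
        rj <- 0.28 * ceiling((3 * cj$n / (4 * pi))^(1 / 3)) + 0.28
        dlat <- sqrt(sum((ci$center[1:2] - cj$center[1:2])^2))
        above <- cj$center[3] > ci$center[3]
        if (above && dlat < rj + cutoff) {
          stop("incompatible layout: bulk bridge of cluster ", i,
               " would thread cluster ", j)
        }
      }
    }
  }

  rows <- list()
  next_id <- 0L
  add_waters <- function(xyz) {
    n <- nrow(xyz)
    ids <- next_id + seq_len(n)
    next_id <<- next_id + n
    data.frame(molecule_id = ids, species = "water", charge = 0L,
               element = "O", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  }

  for (cl in clusters) {
    off <- .cluster_offsets(cl$n)
    xyz <- sweep(off, 2, cl$center, "+")
    rows <- c(rows, list(add_waters(xyz)))
    if (isTRUE(cl$bulk_connected)) {
      # vertical chain of waters from the cluster top to above z = 0
      z_from <- max(xyz[, 3]) + 0.3
      if (z_from < 0.15) {
        nstep <- ceiling((0.15 - z_from) / 0.3)
        zs <- z_from + 0.3 * (0:nstep)
        bridge <- cbind(cl$center[1], cl$center[2], zs)
        rows <- c(rows, list(add_waters(bridge)))
      }
    }
  }

  out <- with_seed(seed, {
    extra <- list()
    if (n_bulk > 0) {
      pos <- .grid_positions(n_bulk, box[1:2], c(0.05, 2))
      extra <- c(extra, list(add_waters(cbind(pos$x, pos$y, pos$z))))
    }
    if (!is.null(ions) && nrow(ions) > 0) {
      for (r in seq_len(nrow(ions))) {
        n <- ions$n[r]
        if (n == 0) next
        if (ions$region[r] == "pore") {
          th <- runif(n, 0, 2 * pi)
          rad <- pore$radius * 0.8 * sqrt(runif(n))
          xyz <- cbind(pore$axis[1] + rad * cos(th),
                       pore$axis[2] + rad * sin(th),
                       runif(n, pore$z_bottom * 0.9, pore$z_top - 0.1))
        } else {
          xyz <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
                       runif(n, 0.1, 2))
        }
        ids <- next_id + seq_len(n)
        next_id <- next_id + n
        extra <- c(extra, list(data.frame(
          molecule_id = ids, species = ions$species[r],
          charge = as.integer(ions$charge[r]), element = ions$species[r],
          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
          stringsAsFactors = FALSE
        )))
      }
    }
    extra
  })
  rows <- c(rows, out)
  frame <- do.call(rbind, rows)
  if (is.null(frame) || nrow(frame) == 0) stop("layout produced no molecules")
  rownames(frame) <- NULL
  n_frames <- max(1L, as.integer(n_frames))
  trajectory(rep(list(frame), n_frames), times = seq_len(n_frames) - 1,
             box = box)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
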