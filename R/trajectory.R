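#' Labeled multi-frame trajectory
#'
#' A `trajectory` is a time-ordered list of frames sharing one molecule
#' roster. Each frame is a `data.frame` with one row per site:
#' `molecule_id`, `species`, `charge` (molecule formal charge, repeated on
#' each site), `element`, `x`, `y`, `z` (nm).
#'
#' @param frames list of frame data.frames.
#' @param times numeric frame times (ns), strictly increasing.
#' @param box numeric length-3 box (nm), used for lateral periodic
#'   distances.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(frames, times, box) {
  if (length(frames) == 0) stop("trajectory needs at least one frame")
  if (length(frames) != length(times)) stop("frames and times lengths differ")
  if (any(diff(times) <= 0)) stop("time stamps must be strictly increasing")
  required <- c("molecule_id", "species", "charge", "element", "x", "y", "z")
  roster <- NULL
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    missing <- setdiff(required, names(f))
    if (length(missing) > 0) {
      stop("frame ", i, " is missing columns: ", paste(missing, collapse = ", "))
    }
    key <- paste(f$molecule_id, f$species)
    if (is.null(roster)) {
      roster <- key
    } else if (!identical(sort(roster), sort(key))) {
      stop("molecule roster changes at frame ", i)
    }
  }
  structure(list(frames = frames, times = as.numeric(times),
                 box = as.numeric(box)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n_mol <- length(unique(x$frames[[1]]$molecule_id))
  cat("trajectory:", length(x$frames), "frames,", n_mol, "molecules, t =",
      sprintf("%g..%g ns", x$times[1], x$times[length(x$times)]), "\n")
  invisible(x)
}

#' Cylindrical pore region
#'
#' Defines the analysis cylinder used by the trajectory metrics: a lateral
#' axis position, a radius, and a z interval. The default z interval
#' `[-15, 0]` matches a 15 nm deep pore whose mouth is at the wax surface.
#'
#' @param axis lateral (x, y) pore axis (nm).
#' @param radius pore radius (nm).
#' @param z_top upper z bound (nm, default 0, the wax surface).
#' @param z_bottom lower z bound (nm, default -15).
#' @return A `pore_region` list.
#' @export
pore_region <- function(axis, radius, z_top = 0, z_bottom = -15) {
  if (radius <= 0) stop("radius must be positive")
  if (z_bottom >= z_top) stop("z_bottom must be below z_top")
  structure(list(axis = as.numeric(axis), radius = radius,
                 z_top = z_top, z_bottom = z_bottom),
            class = "pore_region")
}

#' Per-molecule centers of mass of one frame
#'
#' Mass-weighted center of mass per molecule using standard atomic masses
#' (united-atom carbons weigh as carbon). For the geometry-only 3-site
#' water this lands near the oxygen.
#'
#' @param frame one trajectory frame (see [trajectory()]).
#' @return data.frame with one row per molecule: `molecule_id`, `species`,
#'   `charge`, `x`, `y`, `z`.
#' @export
molecule_com <- function(frame) {
  m <- atomic_mass(frame$element)
  wsum <- function(v) tapply(v * m, frame$molecule_id, sum)
  mt <- tapply(m, frame$molecule_id, sum)
  ids <- as.integer(names(mt))
  first <- match(ids, frame$molecule_id)
  data.frame(
    molecule_id = ids,
    species = frame$species[first],
    charge = frame$charge[first],
    x = as.numeric(wsum(frame$x) / mt),
    y = as.numeric(wsum(frame$y) / mt),
    z = as.numeric(wsum(frame$z) / mt),
    stringsAsFactors = FALSE
  )
}

# convert a structure_model into a single trajectory frame
model_frame <- function(model) {
  a <- model$atoms
  chg <- tapply(a$formal_charge, a$molecule_id, sum)
  data.frame(
    molecule_id = a$molecule_id,
    species = a$species,
    charge = as.integer(chg[as.character(a$molecule_id)]),
    element = a$element,
    x = a$x, y = a$y, z = a$z,
    stringsAsFactors = FALSE
  )
}
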