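# Free-energy-profile (PMF) post-processing: min-shifting, free-energy
# differences at reaction-coordinate anchors, penetration barriers, the
# ideal non-interacting two-molecule reference surface, and convergence
# root-mean-square deviations.

#' One-dimensional free-energy profile
#'
#' A PMF on a reaction-coordinate grid ξ, the center-of-mass position of a
#' molecule along the surface normal (nm), with values in kT.
#'
#' @param xi strictly monotonic grid (nm).
#' @param values finite free-energy values (kT), same length as `xi`.
#' @param species optional molecule label.
#' @return A `pmf_profile`.
#' @export
pmf_profile <- function(xi, values, species = NULL) {
  if (length(xi) != length(values)) stop("xi and values lengths differ")
  if (length(xi) < 1) stop("empty profile")
  d <- diff(xi)
  if (length(d) > 0 && !(all(d > 0) || all(d < 0))) {
    stop("xi grid must be strictly monotonic")
  }
  if (any(!is.finite(values))) stop("free-energy values must be finite")
  structure(list(xi = as.numeric(xi), values = as.numeric(values),
                 species = species),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat("pmf_profile:", length(x$xi), "points, xi in",
      sprintf("[%g, %g] nm,", min(x$xi), max(x$xi)),
      "values in", sprintf("[%.3g, %.3g] kT", min(x$values), max(x$values)))
  if (!is.null(x$species)) cat(" (", x$species, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Two-dimensional free-energy surface
#'
#' A PMF over two reaction coordinates ξ1, ξ2 (the center-of-mass
#' positions of two molecules relative to the pore entrance), values in
#' kT.
#'
#' @param xi1,xi2 strictly monotonic grids (nm).
#' @param values matrix of free energies (kT), `length(xi1)` rows and
#'   `length(xi2)` columns.
#' @param species optional label.
#' @return A `pmf_surface`.
#' @export
pmf_surface <- function(xi1, xi2, values, species = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != length(xi1) || ncol(values) != length(xi2)) {
    stop("matrix dimensions do not match the xi grids")
  }
  for (g in list(xi1, xi2)) {
    d <- diff(g)
    if (length(d) > 0 && !(all(d > 0) || all(d < 0))) {
      stop("xi grids must be strictly monotonic")
    }
  }
  if (any(!is.finite(values))) stop("free-energy values must be finite")
  structure(list(xi1 = as.numeric(xi1), xi2 = as.numeric(xi2),
                 values = values, species = species),
            class = "pmf_surface")
}

#' Shift the PMF minimum to zero
#'
#' Subtracts the global minimum so the profile (or surface) minimum is
#' exactly 0 kT; idempotent. Applied before every RMSD comparison.
#'
#' @param x a `pmf_profile` or `pmf_surface`.
#' @return the same type, min-shifted.
#' @export
shift_min_to_zero <- function(x) UseMethod("shift_min_to_zero")

#' @export
shift_min_to_zero.pmf_profile <- function(x) {
  x$values <- x$values - min(x$values)
  x
}

#' @export
shift_min_to_zero.pmf_surface <- function(x) {
  x$values <- x$values - min(x$values)
  x
}

# linear interpolation of a profile at an anchor
.pmf_at <- function(profile, xi) {
  rng <- range(profile$xi)
  if (xi < rng[1] - 1e-12 || xi > rng[2] + 1e-12) {
    stop(sprintf("anchor xi = %g nm lies outside the grid [%g, %g]",
                 xi, rng[1], rng[2]))
  }
  stats::approx(profile$xi, profile$values, xout = xi, rule = 1)$y
}

#' Free-energy difference between two anchors
#'
#' `PMF(xi_a) - PMF(xi_b)` with linear interpolation between grid points.
#' With the adsorption anchors (surface at ξ = 3.0 nm, bulk at
#' ξ = 0.25 nm) this is the adsorption free energy ΔG_ads; it is
#' antisymmetric in its anchors.
#'
#' @param profile a [pmf_profile()].
#' @param xi_a,xi_b anchors (nm) inside the grid range.
#' @return free-energy difference (kT).
#' @export
free_energy_difference <- function(profile, xi_a, xi_b) {
  stopifnot(inherits(profile, "pmf_profile"))
  .pmf_at(profile, xi_a) - .pmf_at(profile, xi_b)
}

#' Penetration free-energy barrier
#'
#' Magnitude of the free-energy change from the entrance anchor (the
#' local minimum near the pore mouth, e.g. ξ = 0.7 nm for C12E6 or
#' 0.4 nm for C12G1) to the deep-pore anchor (ξ = −3.0 nm), reported
#' positive for an uphill penetration. Anchors are caller-specified.
#'
#' @param profile a [pmf_profile()].
#' @param xi_entrance entrance anchor (nm).
#' @param xi_inside deep-pore anchor (nm, default -3.0).
#' @return barrier height (kT, non-negative).
#' @export
penetration_barrier <- function(profile, xi_entrance, xi_inside = -3.0) {
  abs(free_energy_difference(profile, xi_entrance, xi_inside))
}

#' Ideal non-interacting two-molecule reference surface
#'
#' The reference 2-D PMF for two molecules that do not interact:
#' `PMF(xi1, xi2) = PMF(xi1) + PMF(xi2)`, built as the outer sum of the
#' min-shifted 1-D profile; exactly symmetric by construction, with its
#' diagonal equal to twice the shifted 1-D profile.
#'
#' @param profile a [pmf_profile()].
#' @return a min-shifted [pmf_surface()] on the square grid.
#' @export
ideal_pair_surface <- function(profile) {
  stopifnot(inherits(profile, "pmf_profile"))
  v <- profile$values - min(profile$values)
  pmf_surface(profile$xi, profile$xi, outer(v, v, "+"),
              species = profile$species)
}

#' RMSD convergence of a PMF series against a reference
#'
#' For each profile (or surface) in a series,
#' `RMSD(t) = sqrt( sum( (PMF(xi, t) - PMF_ref(xi))^2 ) / N )` over the N
#' shared grid points, after shifting every minimum to 0 kT. Used to
#' monitor convergence of adaptive-bias free-energy runs against their
#' final profile.
#'
#' @param series a single profile/surface or a list of them, all on the
#'   reference grid.
#' @param reference the reference `pmf_profile` or `pmf_surface`.
#' @return numeric RMSD, one value per series element (kT).
#' @export
rmsd_convergence <- function(series, reference) {
  if (inherits(series, "pmf_profile") || inherits(series, "pmf_surface")) {
    series <- list(series)
  }
  ref <- shift_min_to_zero(reference)
  ref_vals <- if (inherits(ref, "pmf_surface")) ref$values else ref$values
  vapply(series, function(p) {
    if (!identical(class(p), class(reference))) {
      stop("series and reference must be the same PMF type")
    }
    same_grid <- if (inherits(p, "pmf_surface")) {
      isTRUE(all.equal(p$xi1, reference$xi1)) &&
        isTRUE(all.equal(p$xi2, reference$xi2))
    } else {
      isTRUE(all.equal(p$xi, reference$xi))
    }
    if (!same_grid) stop("grid mismatch between series and reference")
    p <- shift_min_to_zero(p)
    sqrt(sum((p$values - ref_vals)^2) / length(ref_vals))
  }, 0)
}

#' Symmetry RMSD of a two-molecule PMF surface
#'
#' For a surface whose two reaction coordinates are exchangeable,
#' `RMSD_symm = sqrt( sum( (PMF(xi1, xi2) - PMF(xi2, xi1))^2 ) / N )`
#' over all N grid points; zero for an exactly symmetric surface.
#'
#' @param surface a [pmf_surface()] on a square grid (xi1 grid equal to
#'   xi2 grid).
#' @return symmetry RMSD (kT).
#' @export
symmetry_rmsd <- function(surface) {
  stopifnot(inherits(surface, "pmf_surface"))
  if (!isTRUE(all.equal(surface$xi1, surface$xi2))) {
    stop("symmetry RMSD requires a square surface (identical xi grids)")
  }
  m <- surface$values
  sqrt(sum((m - t(m))^2) / length(m))
}

#' Read a 1-D free-energy profile from a text table
#'
#' Accepts a plain two-column table (ξ in nm, PMF in kT) or the xvg
#' dialect written by molecular-dynamics free-energy tools: lines starting
#' with `#` or `@` are skipped; a third column (error estimate) is kept
#' when present.
#'
#' @param path file path.
#' @param species optional label to attach.
#' @return a [pmf_profile()]; any third column is stored as attribute
#'   `"error"`.
#' @export
read_pmf <- function(path, species = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("no data rows in ", path)
  tab <- utils::read.table(text = lines[keep])
  if (ncol(tab) < 2) stop("expected at least two columns (xi, kT) in ", path)
  p <- pmf_profile(tab[[1]], tab[[2]], species = species)
  if (ncol(tab) >= 3) attr(p, "error") <- as.numeric(tab[[3]])
  p
}

#' Write a 1-D free-energy profile
#'
#' @param profile a [pmf_profile()].
#' @param path output path.
#' @param header write a comment header (default TRUE).
#' @return invisibly, `path`.
#' @export
write_pmf <- function(profile, path, header = TRUE) {
  stopifnot(inherits(profile, "pmf_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    writeLines(c("# free-energy profile", "# xi_nm  pmf_kT"), con)
  }
  writeLines(sprintf("%.8g %.8g", profile$xi, profile$values), con)
  invisible(path)
}

#' Read a 2-D free-energy surface from a delimited matrix file
#'
#' Format written by [write_pmf_surface()]: two comment lines carrying the
#' xi1 and xi2 grids, then the dense value matrix.
#'
#' @param path file path.
#' @return a [pmf_surface()].
#' @export
read_pmf_surface <- function(path) {
  lines <- readLines(path)
  gl <- grep("^# xi[12]:", lines, value = TRUE)
  if (length(gl) != 2) stop("missing xi grid headers in ", path)
  parse_grid <- function(s) as.numeric(strsplit(sub("^# xi[12]:", "", s), "\\s+")[[1]][-1])
  xi1 <- parse_grid(gl[1]); xi2 <- parse_grid(gl[2])
  dat <- utils::read.table(text = lines[!grepl("^#", lines)])
  pmf_surface(xi1, xi2, as.matrix(dat))
}

#' Write a 2-D free-energy surface
#'
#' @param surface a [pmf_surface()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pmf_surface <- function(surface, path) {
  stopifnot(inherits(surface, "pmf_surface"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# xi1:", paste(format(surface$xi1, digits = 10), collapse = " ")),
               paste("# xi2:", paste(format(surface$xi2, digits = 10), collapse = " "))),
             con)
  utils::write.table(surface$values, con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
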