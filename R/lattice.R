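#' Orthorhombic wax lattice specification
#'
#' Parameters of the crystalline alkane lattice used for the model
#' epicuticular wax: an orthorhombic subcell of the polyethylene type with
#' two chains per subcell in a herringbone setting, all-trans chains
#' oriented along the surface normal with terminal CH3 groups exposed on
#' the (001) surface.
#'
#' @param subcell_a,subcell_b orthorhombic subcell constants (nm). Defaults
#'   0.742 and 0.496 nm are the standard crystalline n-alkane values.
#' @param carbons_per_chain united-atom carbons per chain (default 30,
#'   matching a layer thickness of about 4 nm).
#' @param cc_bond C–C bond length (nm, default 0.154).
#' @param ccc_angle C–C–C valence angle (degrees, default 114).
#' @param layer_count number of stacked wax layers (1 for a flat slab,
#'   4 for the pore slab).
#' @param setting_angle herringbone setting angle (degrees) of the zig-zag
#'   plane; the two sublattices use +/- this angle.
#' @param interlayer_gap CH3–CH3 gap between stacked layers (nm, default
#'   0.40, two methyl van der Waals radii).
#' @return A `lattice_spec` list.
#' @export
#' @examples
#' lat <- lattice_spec()
#' axial_rise(lat)        # 0.129 nm per carbon
#' layer_thickness(lat)   # about 4 nm for C30
lattice_spec <- function(subcell_a = 0.742, subcell_b = 0.496,
                         carbons_per_chain = 30, cc_bond = 0.154,
                         ccc_angle = 114, layer_count = 1,
                         setting_angle = 45, interlayer_gap = 0.40) {
  if (subcell_a <= 0 || subcell_b <= 0) stop("subcell constants must be positive")
  if (carbons_per_chain < 1) stop("carbons_per_chain must be >= 1")
  if (cc_bond <= 0) stop("cc_bond must be positive")
  if (ccc_angle <= 0 || ccc_angle >= 180) {
    stop("ccc_angle must lie strictly between 0 and 180 degrees")
  }
  if (layer_count < 1) stop("layer_count must be >= 1")
  if (interlayer_gap < 0) stop("interlayer_gap must be >= 0")
  structure(
    list(
      subcell_a = subcell_a, subcell_b = subcell_b,
      chains_per_subcell = 2L,
      carbons_per_chain = as.integer(carbons_per_chain),
      cc_bond = cc_bond, ccc_angle = ccc_angle,
      layer_count = as.integer(layer_count),
      setting_angle = setting_angle, interlayer_gap = interlayer_gap
    ),
    class = "lattice_spec"
  )
}

#' Axial rise per carbon of an all-trans chain
#'
#' The projection of one C–C bond onto the chain axis,
#' `cc_bond * sin(ccc_angle / 2)`.
#'
#' @param lattice a [lattice_spec()].
#' @return rise in nm per carbon.
#' @export
axial_rise <- function(lattice) {
  lattice$cc_bond * sin(lattice$ccc_angle / 2 * pi / 180)
}

#' Thickness of one wax layer
#'
#' Backbone extent of an all-trans chain,
#' `(carbons_per_chain - 1) * axial_rise`, plus the CH3–CH3 interlayer gap.
#' For the default C30 lattice this is 4.15 nm, consistent with an
#' epicuticular wax layer of roughly 4 nm per 30-carbon chain.
#'
#' @param lattice a [lattice_spec()].
#' @return layer thickness in nm.
#' @export
layer_thickness <- function(lattice) {
  (lattice$carbons_per_chain - 1) * axial_rise(lattice) + lattice$interlayer_gap
}

#' Build one all-trans alkane chain
#'
#' Returns backbone carbon positions of a single all-trans zig-zag chain
#' whose long axis is the surface normal (z). The first carbon sits at the
#' origin and the chain extends downward (negative z); the zig-zag lies in
#' the x–z plane, centered laterally.
#'
#' @param lattice a [lattice_spec()].
#' @param orientation chain axis; only `"z"` (the surface normal) is
#'   supported, matching chains perpendicular to the leaf surface.
#' @return numeric matrix `carbons_per_chain` x 3 of positions (nm).
#' @export
#' @examples
#' xyz <- build_chain(lattice_spec())
#' # end-to-end backbone length of C30: about 3.74 nm
#' abs(xyz[30, 3] - xyz[1, 3])
build_chain <- function(lattice, orientation = "z") {
  if (!inherits(lattice, "lattice_spec")) lattice <- do.call(lattice_spec, lattice)
  orientation <- match.arg(orientation, "z")
  n <- lattice$carbons_per_chain
  rise <- axial_rise(lattice)
  # lateral alternation amplitude: bond projection onto the zig-zag plane
  amp <- lattice$cc_bond * cos(lattice$ccc_angle / 2 * pi / 180)
  i <- seq_len(n)
  x <- ifelse(i %% 2 == 1, -amp / 2, amp / 2)
  if (n == 1) x <- 0
  cbind(x = x, y = rep(0, n), z = -(i - 1) * rise)
}

#' Build a crystalline wax slab
#'
#' Tiles the orthorhombic subcell to approximate a requested lateral size:
#' `nx = round(target_x / subcell_a)`, `ny = round(target_y / subcell_b)`
#' subcells, two herringbone chains each, chains perpendicular to the
#' surface. The terminal CH3 layer defines z = 0 and the wax occupies
#' z <= 0. With `layer_count > 1`, identical layers are stacked downward at
#' [layer_thickness()] spacing (the pore slab uses 4 layers, about 15 nm of
#' wax in total).
#'
#' @param lateral_target length-2 target lateral box (nm); the default
#'   6 x 6 nm matches the model-leaf unit cell.
#' @param lattice a [lattice_spec()].
#' @param solution_headroom extra box height above the surface (nm)
#'   reserved for a solution phase (default 10).
#' @return A [structure_model()] whose provenance records the lattice and
#'   realized tiling.
#' @export
#' @examples
#' slab <- build_crystal_slab(c(6, 6))
#' length(unique(slab$atoms$chain_id))  # 192 chains
build_crystal_slab <- function(lateral_target = c(6, 6),
                               lattice = lattice_spec(),
                               solution_headroom = 10) {
  if (!inherits(lattice, "lattice_spec")) lattice <- do.call(lattice_spec, lattice)
  if (length(lateral_target) != 2 || any(lateral_target <= 0)) {
    stop("lateral_target must be two positive lengths (nm)")
  }
  nx <- round_half_away(lateral_target[1] / lattice$subcell_a)
  ny <- round_half_away(lateral_target[2] / lattice$subcell_b)
  if (nx < 1 || ny < 1) {
    stop("lateral target smaller than one subcell (",
         lattice$subcell_a, " x ", lattice$subcell_b, " nm)")
  }
  a <- lattice$subcell_a
  b <- lattice$subcell_b
  nlay <- lattice$layer_count
  ncarb <- lattice$carbons_per_chain
  lt <- layer_thickness(lattice)

  template <- build_chain(lattice)
  rot <- function(xyz, deg) {
    th <- deg * pi / 180
    cbind(xyz[, 1] * cos(th) - xyz[, 2] * sin(th),
          xyz[, 1] * sin(th) + xyz[, 2] * cos(th),
          xyz[, 3])
  }
  tmpl <- list(rot(template, lattice$setting_angle),
               rot(template, -lattice$setting_angle))
  # chain axis positions: sublattice 1 at (1/4, 1/4), sublattice 2 at (3/4, 3/4)
  offs <- list(c(0.25 * a, 0.25 * b), c(0.75 * a, 0.75 * b))

  cells <- expand.grid(sub = 1:2, ix = seq_len(nx), iy = seq_len(ny),
                       layer = seq_len(nlay))
  # deterministic chain order: layer, then ix, iy, sublattice
  cells <- cells[order(cells$layer, cells$ix, cells$iy, cells$sub), ]
  nchain <- nrow(cells)

  ax <- (cells$ix - 1) * a + vapply(cells$sub, function(s) offs[[s]][1], 0)
  ay <- (cells$iy - 1) * b + vapply(cells$sub, function(s) offs[[s]][2], 0)
  ztop <- -(cells$layer - 1) * lt

  idx <- rep(seq_len(nchain), each = ncarb)
  sub <- cells$sub[idx]
  base <- do.call(rbind, lapply(seq_len(nchain), function(k) tmpl[[cells$sub[k]]]))
  x <- base[, 1] + ax[idx]
  y <- base[, 2] + ay[idx]
  z <- base[, 3] + ztop[idx]

  carbon <- rep(seq_len(ncarb), times = nchain)
  terminal <- carbon == 1 | carbon == ncarb
  group <- ifelse(terminal, "CH3", "CH2")

  atoms <- data.frame(
    element = "C", name = group, x = x, y = y, z = z,
    chain_id = idx, molecule_id = idx,
    species = "wax", group_label = group,
    formal_charge = 0L, layer = cells$layer[idx],
    stringsAsFactors = FALSE
  )
  wax_depth <- (nlay - 1) * lt + (ncarb - 1) * axial_rise(lattice)
  box <- c(nx * a, ny * b, wax_depth + lattice$interlayer_gap + solution_headroom)
  structure_model(
    atoms, box,
    provenance = list(
      builder = "build_crystal_slab", lattice = unclass(lattice),
      nx = nx, ny = ny, n_chains = nchain,
      layer_thickness = lt, wax_depth = wax_depth,
      chain_axes = data.frame(chain_id = seq_len(nchain), x = ax, y = ay,
                              layer = cells$layer)
    )
  )
}
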