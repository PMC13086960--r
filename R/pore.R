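#' Nanopore specification
#'
#' Describes the cylindrical nanopore carved out of the crystalline wax
#' slab. Two modes are supported:
#'
#' * `by_count` (default, authoritative): remove exactly `n_remove` chains
#'   nearest the pore axis in every layer the pore spans. The default of 14
#'   chains corresponds to an accessible pore radius of roughly
#'   0.75–0.8 nm in the default lattice.
#' * `by_radius`: remove chains whose axis lies within
#'   `accessible_radius + methyl_radius` of the pore axis. The accessible
#'   radius convention subtracts the methyl van der Waals radius (0.20 nm)
#'   from the chain-axis cut radius.
#'
#' @param mode `"by_count"` or `"by_radius"`.
#' @param n_remove chains to remove per layer in `by_count` mode
#'   (default 14).
#' @param accessible_radius solute-accessible pore radius (nm), used in
#'   `by_radius` mode (default 0.775, mid-range of 0.75–0.8 nm).
#' @param methyl_radius CH3 van der Waals radius (nm, default 0.20).
#' @param center lateral pore axis (nm pair); `NULL` means the lateral box
#'   center.
#' @param depth pore depth (nm, default 15; spans four default layers).
#' @return A `pore_spec` list.
#' @export
pore_spec <- function(mode = c("by_count", "by_radius"), n_remove = 14,
                      accessible_radius = 0.775, methyl_radius = 0.20,
                      center = NULL, depth = 15) {
  mode <- match.arg(mode)
  if (n_remove < 0) stop("n_remove must be >= 0")
  if (accessible_radius < 0) stop("accessible_radius must be >= 0")
  if (methyl_radius < 0) stop("methyl_radius must be >= 0")
  if (depth <= 0) stop("depth must be positive")
  structure(
    list(mode = mode, n_remove = as.integer(n_remove),
         accessible_radius = accessible_radius,
         methyl_radius = methyl_radius, center = center, depth = depth),
    class = "pore_spec"
  )
}

#' Carve a cylindrical nanopore from a wax slab
#'
#' Deletes whole chains around the pore axis; carving is a pure deletion
#' (no surviving atom moves). In `by_count` mode exactly `n_remove` chains
#' nearest the axis are removed in every layer spanned by `depth`, ties
#' broken by distance then ascending chain id. In `by_radius` mode all
#' chains whose axis lies within `accessible_radius + methyl_radius` of
#' the pore axis are removed. Lateral distances honor periodic boundaries.
#'
#' @param slab a [structure_model()] from [build_crystal_slab()].
#' @param spec a [pore_spec()].
#' @return list with elements `model` (the carved [structure_model()], with
#'   the pore geometry recorded in its provenance) and `removed` (integer
#'   vector of removed-chain counts per spanned layer).
#' @export
#' @examples
#' slab <- build_crystal_slab(c(6, 6), lattice_spec(layer_count = 4))
#' carved <- carve_pore(slab, pore_spec())
#' carved$removed  # 14 chains removed in each of the 4 layers
carve_pore <- function(slab, spec = pore_spec()) {
  stopifnot(inherits(slab, "structure_model"))
  if (!inherits(spec, "pore_spec")) spec <- do.call(pore_spec, spec)
  prov <- slab$provenance
  axes <- prov$chain_axes
  if (is.null(axes)) stop("slab provenance carries no chain axes; build it with build_crystal_slab()")
  lt <- prov$layer_thickness
  nlay <- max(axes$layer)
  total_depth <- nlay * lt
  if (spec$depth > total_depth + 1e-9) {
    stop(sprintf("pore depth %.2f nm exceeds slab thickness %.2f nm",
                 spec$depth, total_depth))
  }
  n_span <- min(nlay, ceiling(spec$depth / lt - 1e-9))
  center <- spec$center
  if (is.null(center)) center <- slab$box[1:2] / 2

  d <- lateral_dist(axes$x, axes$y, center, slab$box)
  removed_ids <- integer(0)
  removed <- integer(n_span)
  for (k in seq_len(n_span)) {
    in_layer <- which(axes$layer == k)
    if (spec$mode == "by_count") {
      if (spec$n_remove > length(in_layer)) {
        stop("n_remove exceeds the number of chains per layer")
      }
      ord <- in_layer[order(d[in_layer], axes$chain_id[in_layer])]
      sel <- ord[seq_len(spec$n_remove)]
    } else {
      cut <- spec$accessible_radius + spec$methyl_radius
      sel <- in_layer[d[in_layer] <= cut]
    }
    removed[k] <- length(sel)
    removed_ids <- c(removed_ids, axes$chain_id[sel])
  }

  keep <- !(slab$atoms$chain_id %in% removed_ids)
  atoms <- slab$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  prov$pore <- list(center = center, depth = spec$depth,
                    layers_spanned = n_span, spec = unclass(spec),
                    removed_chain_ids = removed_ids)
  out <- structure_model(atoms, slab$box, prov)
  list(model = out, removed = removed)
}
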