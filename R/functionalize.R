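#' Surface functionalization specification
#'
#' Replacement of terminal CH3 groups by carboxylate (COO⁻, formal charge
#' −1) or carboxyl (COOH, neutral) groups. The replacement fraction is
#' expressed relative to ALL CH3/CH2 carbon groups in the slab — the model
#' systems use 0.5% and 1.5% — but replacements are realized only at
#' terminal CH3 sites of the chosen face.
#'
#' @param group `"COO_minus"` or `"COOH"`.
#' @param fraction fraction of all CH3/CH2 carbon groups to replace
#'   (e.g. 0.005 or 0.015).
#' @param face `"top"` (surface CH3 layer), `"bottom"`, or `"pore_wall"`
#'   (terminal CH3 sites of chains bordering the pore, all spanned layers).
#' @param seed integer seed for the uniform-random site selection.
#' @return A `functionalization_spec` list.
#' @export
functionalization_spec <- function(group = c("COO_minus", "COOH"),
                                   fraction = 0.015,
                                   face = c("top", "bottom", "pore_wall"),
                                   seed = 1L) {
  group <- match.arg(group)
  face <- match.arg(face)
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  structure(
    list(group = group, fraction = fraction, face = face,
         seed = as.integer(seed)),
    class = "functionalization_spec"
  )
}

# indices (into model$atoms) of terminal CH3 sites eligible on a face
.face_sites <- function(model, face, wall_shell = 0.5) {
  a <- model$atoms
  ch3 <- which(a$species == "wax" & a$group_label == "CH3")
  if (face == "top") {
    # topmost carbon of each first-layer chain
    cand <- ch3[a$layer[ch3] == 1]
    top_z <- tapply(a$z[cand], a$chain_id[cand], max)
    cand[a$z[cand] >= top_z[as.character(a$chain_id[cand])] - 1e-9]
  } else if (face == "bottom") {
    nlay <- max(a$layer, na.rm = TRUE)
    cand <- ch3[a$layer[ch3] == nlay]
    bot_z <- tapply(a$z[cand], a$chain_id[cand], min)
    cand[a$z[cand] <= bot_z[as.character(a$chain_id[cand])] + 1e-9]
  } else { # pore_wall
    pore <- model$provenance$pore
    if (is.null(pore)) stop("face = 'pore_wall' requires a carved slab")
    cut <- pore$spec$accessible_radius + pore$spec$methyl_radius + wall_shell
    d <- lateral_dist(a$x[ch3], a$y[ch3], pore$center, model$box)
    ch3[d <= cut & a$layer[ch3] <= pore$layers_spanned]
  }
}

#' Functionalize the wax surface with COO⁻ or COOH groups
#'
#' Relabels `n_replace = round(fraction * total CH3/CH2 carbon count)`
#' terminal CH3 sites on the chosen face as COO⁻ (formal charge −1) or
#' COOH (neutral). Site selection is uniform-random under the spec seed.
#' In the simulated systems these replaced groups are the only wax sites
#' allowed to move; everything else stays frozen, so a geometric relabeling
#' suffices.
#'
#' @param slab a [structure_model()] (carved or flat).
#' @param spec a [functionalization_spec()].
#' @return The functionalized [structure_model()]; the indices of replaced
#'   sites are recorded in the provenance.
#' @export
#' @examples
#' slab <- build_crystal_slab(c(6, 6))
#' f <- functionalize_surface(slab, functionalization_spec(fraction = 0.015))
#' total_charge(f)  # -86 for the default 192-chain C30 slab
functionalize_surface <- function(slab, spec = functionalization_spec()) {
  stopifnot(inherits(slab, "structure_model"))
  if (!inherits(spec, "functionalization_spec")) {
    spec <- do.call(functionalization_spec, spec)
  }
  a <- slab$atoms
  n_carbons <- sum(a$species == "wax" & a$group_label %in% c("CH3", "CH2"))
  n_replace <- as.integer(round_half_away(spec$fraction * n_carbons))
  if (n_replace == 0) return(slab)

  sites <- .face_sites(slab, spec$face)
  if (n_replace > length(sites)) {
    stop(sprintf(
      "fraction %.4f demands %d replacements but face '%s' has only %d terminal CH3 sites",
      spec$fraction, n_replace, spec$face, length(sites)
    ))
  }
  sel <- with_seed(spec$seed, sort(sample(sites, n_replace)))

  if (spec$group == "COO_minus") {
    a$group_label[sel] <- "COO"
    a$name[sel] <- "COO"
    a$formal_charge[sel] <- -1L
  } else {
    a$group_label[sel] <- "COOH"
    a$name[sel] <- "COOH"
    a$formal_charge[sel] <- 0L
  }
  prov <- slab$provenance
  prov$functionalization <- list(spec = unclass(spec), n_replace = n_replace,
                                 sites = sel)
  structure_model(a, slab$box, prov)
}
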