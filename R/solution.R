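# Built-in fully dissociating salts: cation/anion element, charge, stoichiometry.
.SALTS <- list(
  NaCl  = list(cation = "Na", zc = 1L, nc = 1L, anion = "Cl", za = -1L, na = 1L),
  KCl   = list(cation = "K",  zc = 1L, nc = 1L, anion = "Cl", za = -1L, na = 1L),
  CaCl2 = list(cation = "Ca", zc = 2L, nc = 1L, anion = "Cl", za = -1L, na = 2L),
  MgCl2 = list(cation = "Mg", zc = 2L, nc = 1L, anion = "Cl", za = -1L, na = 2L)
)

# bead architecture of the coarse surfactant models: alkyl tail beads (C)
# plus head beads (O-rich units); enough for counting, density and charge
# analyses — force-field topologies are out of scope.
.SURFACTANTS <- list(
  C12E6 = list(n_tail = 12L, n_head = 6L),
  C12G1 = list(n_tail = 12L, n_head = 1L),
  C12G2 = list(n_tail = 12L, n_head = 2L)
)

#' Solution composition specification
#'
#' Describes the aqueous phase placed above the wax: surfactant monolayers
#' at a target surface excess Γ, hydrophilic active ingredient (AI) at a
#' stated AI:surfactant molar ratio, salts in mol per liter of water,
#' water, and neutralizing counterions. Defaults reproduce the reference
#' composition: C12E6 at Γ = 3.5e-6 mol/m² on both interfaces, methyl
#' glucose at 8:3, c_AI ≈ 2.2 mol per liter of water.
#'
#' @param gamma_per_interface surface excess per interface (mol/m²).
#' @param interfaces `"both"`, `"top"` (air/solution) or `"bottom"`
#'   (wax/solution).
#' @param surfactant one of `"C12E6"`, `"C12G1"`, `"C12G2"`.
#' @param ai_species `"MG"` (3-O-methyl-glucose, modeled as a single
#'   neutral site) or `"none"`.
#' @param ai_to_surfactant_ratio integer pair (AI : surfactant); the
#'   surfactant count is taken over all interfaces. Reference ratios are
#'   8:3 (C12E6), 1:1 (C12G1), 5:2 (C12G2).
#' @param c_ai target AI concentration in mol per liter of water (default
#'   2.2); sets the water count via `n_water = round(n_ai * 55.5 / c_ai)`.
#' @param salts data.frame with columns `species` (a name in
#'   `"NaCl" "KCl" "CaCl2" "MgCl2"`) and `conc` (mol per liter of water),
#'   or `NULL`.
#' @param n_water optional explicit water count overriding the `c_ai`
#'   derivation (required when `ai_species = "none"` unless
#'   `water_height` is used).
#' @param water_height fallback water-slab height (nm) used to pick a
#'   water count when neither AI nor `n_water` fixes it (default 3).
#' @param counterion counterion species used to neutralize wax COO⁻
#'   charges (`"Ca"` or `"Na"`); `NULL` picks Ca if a calcium salt is
#'   present, else Na.
#' @param min_insert_dist minimum heavy-atom insertion distance (nm,
#'   default 0.25).
#' @param seed integer seed controlling all insertion randomness.
#' @return A `solution_spec` list.
#' @export
solution_spec <- function(gamma_per_interface = 3.5e-6,
                          interfaces = c("both", "top", "bottom"),
                          surfactant = c("C12E6", "C12G1", "C12G2"),
                          ai_species = c("MG", "none"),
                          ai_to_surfactant_ratio = c(8L, 3L),
                          c_ai = 2.2, salts = NULL, n_water = NULL,
                          water_height = 3, counterion = NULL,
                          min_insert_dist = 0.25, seed = 1L) {
  interfaces <- match.arg(interfaces)
  surfactant <- match.arg(surfactant)
  ai_species <- match.arg(ai_species)
  if (gamma_per_interface < 0) stop("gamma must be >= 0")
  if (length(ai_to_surfactant_ratio) != 2 || any(ai_to_surfactant_ratio < 1)) {
    stop("ai_to_surfactant_ratio must be two positive integers")
  }
  if (!is.null(salts)) {
    if (!all(c("species", "conc") %in% names(salts))) {
      stop("salts must have columns 'species' and 'conc'")
    }
    unknown <- setdiff(salts$species, names(.SALTS))
    if (length(unknown) > 0) stop("unknown salts: ", paste(unknown, collapse = ", "))
    if (any(salts$conc < 0)) stop("salt concentrations must be >= 0")
  }
  if (c_ai <= 0) stop("c_ai must be positive")
  structure(
    list(gamma_per_interface = gamma_per_interface, interfaces = interfaces,
         surfactant = surfactant, ai_species = ai_species,
         ai_to_surfactant_ratio = as.integer(ai_to_surfactant_ratio),
         c_ai = c_ai, salts = salts, n_water = n_water,
         water_height = water_height, counterion = counterion,
         min_insert_dist = min_insert_dist, seed = as.integer(seed)),
    class = "solution_spec"
  )
}

#' Surfactant molecule count from a surface excess
#'
#' Converts a surface excess Γ (mol/m²) and an interfacial area (nm²) into
#' an integer molecule count, `round(gamma * area * N_A)`; the inverse map
#' is [realized_gamma()]. At Γ = 3.5e-6 mol/m² on a 36 nm² interface this
#' gives 76 molecules.
#'
#' @param gamma surface excess (mol/m²).
#' @param area_nm2 interfacial area (nm²).
#' @return integer molecule count.
#' @export
surfactant_count_from_gamma <- function(gamma, area_nm2) {
  if (gamma < 0 || area_nm2 < 0) stop("gamma and area must be >= 0")
  as.integer(round_half_away(gamma * area_nm2 * 1e-18 * .AVOGADRO))
}

#' Surface excess realized by an integer molecule count
#'
#' @param count molecules at the interface.
#' @param area_nm2 interfacial area (nm²).
#' @return realized surface excess (mol/m²).
#' @export
realized_gamma <- function(count, area_nm2) {
  count / (area_nm2 * 1e-18 * .AVOGADRO)
}

#' Ionic strength of fully dissociated salts
#'
#' `I = 1/2 * sum(c_i * z_i^2)` over all ions produced by dissociation.
#' 1.1 mol/L CaCl2 gives I = 3.3 mol/L, the reference hard-water condition
#' matched by 3.3 mol/L NaCl.
#'
#' @param species character vector of salt names (see [solution_spec()]).
#' @param conc matching concentrations (mol/L).
#' @return ionic strength (mol/L).
#' @export
#' @examples
#' ionic_strength("CaCl2", 1.1)  # 3.3
ionic_strength <- function(species, conc) {
  if (length(species) != length(conc)) stop("species and conc lengths differ")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  total <- 0
  for (i in seq_along(species)) {
    s <- .SALTS[[species[i]]]
    if (is.null(s)) stop("unknown salt: ", species[i])
    if (s$zc * s$nc + s$za * s$na != 0) stop("salt formula is not neutral: ", species[i])
    total <- total + conc[i] * (s$nc * s$zc^2 + s$na * s$za^2)
  }
  total / 2
}

# jittered-grid positions guaranteeing a minimum pairwise separation:
# grid spacing 0.31 nm with +/-0.015 nm jitter per axis keeps all points
# >= 0.25 nm apart by construction, with no O(n^2) checking.
.grid_positions <- function(n, box_xy, z_range, spacing = 0.31, jitter = 0.015) {
  nx <- max(1L, floor(box_xy[1] / spacing))
  ny <- max(1L, floor(box_xy[2] / spacing))
  nz <- ceiling(n / (nx * ny))
  g <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  pick <- sample(nrow(g), n)
  g <- g[pick, ]
  data.frame(
    x = (g$i - 0.5) * (box_xy[1] / nx) + runif(n, -jitter, jitter),
    y = (g$j - 0.5) * (box_xy[2] / ny) + runif(n, -jitter, jitter),
    z = z_range[1] + (g$k - 0.5) * spacing + runif(n, -jitter, jitter)
  )
}

# rigid 3-site water (geometry-only): O at the anchor, two H at the
# gas-phase geometry, random azimuthal orientation
.water_sites <- function(pos) {
  n <- nrow(pos)
  roh <- 0.09572
  half <- 104.52 / 2 * pi / 180
  phi <- runif(n, 0, 2 * pi)
  h1 <- cbind(pos$x + roh * sin(half) * cos(phi),
              pos$y + roh * sin(half) * sin(phi),
              pos$z + roh * cos(half))
  h2 <- cbind(pos$x - roh * sin(half) * cos(phi),
              pos$y - roh * sin(half) * sin(phi),
              pos$z + roh * cos(half))
  list(h1 = h1, h2 = h2)
}

#' Compose the solution phase above a wax slab
#'
#' Places oriented surfactant monolayers (tails toward wax or air, heads
#' toward water) at the requested interfaces at the target surface excess,
#' the AI at the stated molar ratio to the total surfactant count, water
#' so that the realized AI concentration (mol per liter of water) meets
#' the target, salts at their stated molality, and counterions so the
#' total system charge is exactly zero. All insertions are random but
#' reproducible under the spec seed and respect the minimum heavy-atom
#' separation.
#'
#' @param slab a [structure_model()] (typically carved and/or
#'   functionalized).
#' @param spec a [solution_spec()].
#' @return list with elements `model` (the composed [structure_model()])
#'   and `report` (a `composition_report` whose realized Γ and c_AI are
#'   recomputed from the integer counts, not echoed from the spec).
#' @export
compose_solution <- function(slab, spec = solution_spec()) {
  stopifnot(inherits(slab, "structure_model"))
  if (!inherits(spec, "solution_spec")) spec <- do.call(solution_spec, spec)

  box <- slab$box
  area <- box[1] * box[2]
  n_if <- if (spec$interfaces == "both") 2L else 1L
  n_surf_if <- surfactant_count_from_gamma(spec$gamma_per_interface, area)
  n_surf_total <- n_if * n_surf_if

  ratio <- spec$ai_to_surfactant_ratio
  n_ai <- if (spec$ai_species == "none") 0L else {
    as.integer(round_half_away(n_surf_total * ratio[1] / ratio[2]))
  }

  if (!is.null(spec$n_water)) {
    n_water <- as.integer(spec$n_water)
  } else if (n_ai > 0) {
    n_water <- as.integer(round_half_away(n_ai * .WATER_MOLARITY / spec$c_ai))
  } else {
    # fall back to a water slab of the requested height at bulk density
    n_water <- as.integer(round_half_away(33.37 * area * spec$water_height))
  }

  # salts: mol per liter of water -> formula units
  salt_units <- integer(0)
  if (!is.null(spec$salts) && nrow(spec$salts) > 0) {
    salt_units <- as.integer(round_half_away(spec$salts$conc * n_water / .WATER_MOLARITY))
    names(salt_units) <- spec$salts$species
  }

  # wax neutralization
  a <- slab$atoms
  wax_charge <- total_charge(slab)
  counter <- spec$counterion
  if (is.null(counter)) {
    has_ca <- !is.null(spec$salts) && any(spec$salts$species %in% c("CaCl2", "MgCl2"))
    counter <- if (has_ca) "Ca" else "Na"
  }
  zc <- if (counter %in% c("Ca", "Mg")) 2L else 1L
  n_counter <- 0L
  if (wax_charge < 0) {
    if ((-wax_charge) %% zc != 0L) {
      # re-protonate one COO- so a divalent counterion can neutralize exactly
      coo <- which(a$group_label == "COO" & a$formal_charge == -1L)
      if (length(coo) == 0) stop("impossible neutralization: odd charge and no COO- site")
      warning("odd COO- count: re-protonating one COO- to COOH to allow ",
              counter, " neutralization")
      i <- coo[1]
      a$group_label[i] <- "COOH"; a$name[i] <- "COOH"; a$formal_charge[i] <- 0L
      wax_charge <- wax_charge + 1L
    }
    n_counter <- as.integer(-wax_charge / zc)
  } else if (wax_charge > 0) {
    stop("impossible neutralization: positively charged wax with no anion species declared")
  }

  surf <- .SURFACTANTS[[spec$surfactant]]
  n_beads <- surf$n_tail + surf$n_head
  bead_sp <- 0.13
  chain_len <- n_beads * bead_sp

  # vertical layout: bottom monolayer above the wax surface, then the
  # water region, then the top monolayer (tails toward air)
  z_bot0 <- 0.10
  water_lo <- z_bot0 + (if (spec$interfaces %in% c("both", "bottom")) chain_len else 0) + 0.15
  spacing <- 0.31
  nxg <- max(1L, floor(box[1] / spacing))
  nyg <- max(1L, floor(box[2] / spacing))
  n_insert <- n_water + n_ai + sum(salt_units * vapply(names(salt_units), function(s) {
    .SALTS[[s]]$nc + .SALTS[[s]]$na
  }, 0L)) + n_counter
  nzg <- ceiling(max(1L, n_insert) / (nxg * nyg))
  water_hi <- water_lo + nzg * spacing
  z_top_if <- water_hi + 0.15

  box_needed <- z_top_if + chain_len + 0.5 - min(0, min(a$z))
  box_out <- box
  if (box[3] < box_needed) box_out[3] <- box_needed

  out <- with_seed(spec$seed, {
    mol0 <- max(a$molecule_id, 0L)
    pieces <- list(a)
    next_mol <- mol0

    add_rows <- function(element, name, pos, species, group, charge, mol_ids) {
      data.frame(element = element, name = name,
                 x = pos[, 1], y = pos[, 2], z = pos[, 3],
                 chain_id = NA_integer_, molecule_id = mol_ids,
                 species = species, group_label = group,
                 formal_charge = as.integer(charge), layer = NA_integer_,
                 stringsAsFactors = FALSE)
    }

    # --- surfactant monolayers ---
    place_monolayer <- function(n, at_top) {
      if (n == 0) return(NULL)
      nside <- ceiling(sqrt(n))
      sx <- box[1] / nside; sy <- box[2] / nside
      if (min(sx, sy) < spec$min_insert_dist + 0.03) {
        stop("requested surfactant density geometrically unplaceable")
      }
      g <- expand.grid(i = seq_len(nside), j = seq_len(nside))
      g <- g[sample(nrow(g), n), ]
      lx <- (g$i - 0.5) * sx + runif(n, -0.015, 0.015)
      ly <- (g$j - 0.5) * sy + runif(n, -0.015, 0.015)
      ids <- next_mol + seq_len(n)
      next_mol <<- next_mol + n
      bead <- seq_len(n_beads)
      # bead 1..n_tail: tail (C); rest: head (O)
      is_head <- bead > surf$n_tail
      if (at_top) {
        # heads adjacent to the water surface, tails pointing up toward air
        zs <- ifelse(is_head,
                     z_top_if + (bead - surf$n_tail - 0.5) * bead_sp,
                     z_top_if + (surf$n_head + (surf$n_tail - bead) + 0.5) * bead_sp)
      } else {
        # tails sit on the wax (low z), heads point up toward the water
        zs <- z_bot0 + (bead - 0.5) * bead_sp
      }
      pos <- cbind(rep(lx, each = n_beads) ,
                   rep(ly, each = n_beads),
                   rep(zs, times = n))
      add_rows(
        element = rep(ifelse(is_head, "O", "C"), times = n),
        name = rep(ifelse(is_head, "HB", "TB"), times = n),
        pos = pos, species = "surfactant", group = "surfactant-atom",
        charge = 0L, mol_ids = rep(ids, each = n_beads)
      )
    }
    if (spec$interfaces %in% c("both", "bottom")) {
      pieces <- c(pieces, list(place_monolayer(n_surf_if, at_top = FALSE)))
    }
    if (spec$interfaces %in% c("both", "top")) {
      pieces <- c(pieces, list(place_monolayer(n_surf_if, at_top = TRUE)))
    }

    # --- bulk insertions on one shared jittered grid ---
    if (n_insert > 0) {
      pos <- .grid_positions(n_insert, box[1:2], c(water_lo, water_hi),
                             spacing = spacing)
      off <- 0L
      take <- function(n) {
        p <- pos[off + seq_len(n), , drop = FALSE]
        off <<- off + n
        p
      }
      # water (3 sites)
      if (n_water > 0) {
        pw <- take(n_water)
        hh <- .water_sites(pw)
        ids <- next_mol + seq_len(n_water); next_mol <- next_mol + n_water
        ow <- add_rows("O", "OW", cbind(pw$x, pw$y, pw$z), "water", "water-O",
                       0L, ids)
        h1 <- add_rows("H", "HW1", hh$h1, "water", "water-H", 0L, ids)
        h2 <- add_rows("H", "HW2", hh$h2, "water", "water-H", 0L, ids)
        w <- rbind(ow, h1, h2)
        w <- w[order(w$molecule_id), ]
        pieces <- c(pieces, list(w))
      }
      # AI (single neutral site)
      if (n_ai > 0) {
        pa <- take(n_ai)
        ids <- next_mol + seq_len(n_ai); next_mol <- next_mol + n_ai
        pieces <- c(pieces, list(
          add_rows("C", "MG", cbind(pa$x, pa$y, pa$z), "ai", "AI-atom", 0L, ids)
        ))
      }
      # salt ions
      for (s in names(salt_units)) {
        def <- .SALTS[[s]]
        nf <- salt_units[[s]]
        if (nf == 0) next
        for (ion in list(list(el = def$cation, z = def$zc, n = nf * def$nc),
                         list(el = def$anion, z = def$za, n = nf * def$na))) {
          pi_ <- take(ion$n)
          ids <- next_mol + seq_len(ion$n); next_mol <- next_mol + ion$n
          pieces <- c(pieces, list(
            add_rows(ion$el, toupper(ion$el), cbind(pi_$x, pi_$y, pi_$z),
                     ion$el, "ion", ion$z, ids)
          ))
        }
      }
      # counterions for wax COO-
      if (n_counter > 0) {
        pc <- take(n_counter)
        ids <- next_mol + seq_len(n_counter); next_mol <- next_mol + n_counter
        pieces <- c(pieces, list(
          add_rows(counter, toupper(counter), cbind(pc$x, pc$y, pc$z),
                   counter, "ion", zc, ids)
        ))
      }
    }
    do.call(rbind, pieces[!vapply(pieces, is.null, TRUE)])
  })
  rownames(out) <- NULL

  prov <- slab$provenance
  prov$solution <- unclass(spec)
  model <- structure_model(out, box_out, prov)

  n_ions <- integer(0)
  sol <- out[out$group_label == "ion", ]
  if (nrow(sol) > 0) {
    t1 <- table(sol$species)
    n_ions <- stats::setNames(as.integer(t1), names(t1))
  }
  report <- structure(
    list(
      n_surfactant_per_interface = n_surf_if,
      interfaces = n_if,
      n_ai = n_ai,
      n_water = n_water,
      n_ions = n_ions,
      n_counterions = n_counter,
      counterion = if (n_counter > 0) counter else NA_character_,
      realized_gamma = realized_gamma(n_surf_if, area),
      realized_ai_concentration =
        if (n_water > 0) n_ai * .WATER_MOLARITY / n_water else NA_real_,
      net_charge = total_charge(model)
    ),
    class = "composition_report"
  )
  if (report$net_charge != 0L) stop("internal error: composed system is not neutral")
  list(model = model, report = report)
}

#' @export
print.composition_report <- function(x, ...) {
  cat("composition_report\n")
  cat(sprintf("  surfactants/interface: %d (x%d interfaces)\n",
              x$n_surfactant_per_interface, x$interfaces))
  cat(sprintf("  AI: %d   water: %d   counterions: %d %s\n",
              x$n_ai, x$n_water, x$n_counterions,
              ifelse(is.na(x$counterion), "", x$counterion)))
  if (length(x$n_ions) > 0) {
    cat("  ions:", paste(sprintf("%s=%d", names(x$n_ions), x$n_ions),
                         collapse = ", "), "\n")
  }
  cat(sprintf("  realized gamma: %.3e mol/m^2\n", x$realized_gamma))
  if (!is.na(x$realized_ai_concentration)) {
    cat(sprintf("  realized c_AI: %.3f mol/(L water)\n",
                x$realized_ai_concentration))
  }
  cat("  net charge:", x$net_charge, "\n")
  invisible(x)
}
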