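# Independent brute-force oracles and randomized fixtures used across the
# suite. The oracles deliberately use different algorithms from the
# package (plain loops / BFS instead of vectorized scans / union-find).

# shortest lateral displacement honoring x/y periodicity (same definition
# the metrics use, applied molecule by molecule)
oracle_lat_dist <- function(x, y, axis, box) {
  dx <- x - axis[1]; dy <- y - axis[2]
  dx <- dx - box[1] * round(dx / box[1])
  dy <- dy - box[2] * round(dy / box[2])
  sqrt(dx^2 + dy^2)
}

oracle_com <- function(frame) {
  ids <- unique(frame$molecule_id)
  out <- data.frame(molecule_id = ids, species = NA_character_,
                    charge = NA_integer_, x = NA_real_, y = NA_real_,
                    z = NA_real_)
  masses <- c(H = 1.008, C = 12.011, O = 15.999, Na = 22.990, Mg = 24.305,
              Cl = 35.453, K = 39.098, Ca = 40.078)
  for (k in seq_along(ids)) {
    rows <- frame[frame$molecule_id == ids[k], ]
    m <- masses[rows$element]; m[is.na(m)] <- 1
    out$species[k] <- rows$species[1]
    out$charge[k] <- rows$charge[1]
    out$x[k] <- sum(rows$x * m) / sum(m)
    out$y[k] <- sum(rows$y * m) / sum(m)
    out$z[k] <- sum(rows$z * m) / sum(m)
  }
  out
}

# per-frame deepest water z among waters laterally inside the cylinder
oracle_min_water_z <- function(frame, region, box) {
  com <- oracle_com(frame)
  best <- NA_real_
  for (k in seq_len(nrow(com))) {
    if (com$species[k] != "water") next
    if (oracle_lat_dist(com$x[k], com$y[k], region$axis, box) > region$radius) next
    if (is.na(best) || com$z[k] < best) best <- com$z[k]
  }
  best
}

oracle_occupancy <- function(frame, region, box, species) {
  com <- oracle_com(frame)
  counts <- stats::setNames(integer(length(species)), species)
  for (k in seq_len(nrow(com))) {
    if (oracle_lat_dist(com$x[k], com$y[k], region$axis, box) > region$radius) next
    if (com$z[k] < region$z_bottom || com$z[k] > region$z_top) next
    s <- com$species[k]
    if (s %in% species) counts[s] <- counts[s] + 1L
  }
  counts
}

oracle_net_charge <- function(frame, region, box) {
  com <- oracle_com(frame)
  q <- 0L
  for (k in seq_len(nrow(com))) {
    if (oracle_lat_dist(com$x[k], com$y[k], region$axis, box) > region$radius) next
    if (com$z[k] < region$z_bottom || com$z[k] > region$z_top) next
    q <- q + com$charge[k]
  }
  as.integer(q)
}

# connected components of the O-O contact graph by breadth-first search
oracle_clusters <- function(frame, cutoff, box = NULL) {
  ox <- frame[frame$species == "water" & frame$element == "O", ]
  n <- nrow(ox)
  if (n == 0) return(list())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dx <- ox$x[i] - ox$x[j]; dy <- ox$y[i] - ox$y[j]; dz <- ox$z[i] - ox$z[j]
      if (!is.null(box)) {
        dx <- dx - box[1] * round(dx / box[1])
        dy <- dy - box[2] * round(dy / box[2])
      }
      if (dx^2 + dy^2 + dz^2 < cutoff^2) adj[i, j] <- TRUE
    }
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; members <- integer(0)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      members <- c(members, v)
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps <- c(comps, list(sort(ox$molecule_id[members])))
  }
  comps
}

# canonical form of a partition for comparison
canon_partition <- function(parts) {
  parts <- lapply(parts, function(v) sort(as.integer(v)))
  unname(parts[order(vapply(parts, min, 0L))])
}

# randomized mixed-species single/multi-site frame with waters guaranteed
random_frame <- function(seed, n_molecules = 60, box = c(6, 6, 20)) {
  set.seed(seed)
  species_pool <- c("water", "water", "water", "Na", "Cl", "Ca", "ai",
                    "surfactant")
  charges <- c(water = 0L, Na = 1L, Cl = -1L, Ca = 2L, ai = 0L,
               surfactant = 0L)
  elements <- c(water = "O", Na = "Na", Cl = "Cl", Ca = "Ca", ai = "C",
                surfactant = "C")
  sp <- c("water", sample(species_pool, n_molecules - 1, replace = TRUE))
  data.frame(
    molecule_id = seq_len(n_molecules),
    species = sp,
    charge = unname(charges[sp]),
    element = unname(elements[sp]),
    x = runif(n_molecules, 0, box[1]),
    y = runif(n_molecules, 0, box[2]),
    z = runif(n_molecules, -10, 2),
    stringsAsFactors = FALSE
  )
}

# small slabs reused across tests (cheap to build, kept lazy)
default_flat_slab <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_crystal_slab(c(6, 6))
    cache
  }
})

default_pore_slab <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_crystal_slab(c(6, 6), lattice_spec(layer_count = 4))
    }
    cache
  }
})
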