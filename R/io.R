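# File formats. Internal units are nm; PDB is written/read in Angstrom.
# GRO fixed columns are authoritative for round trips (0.001 nm precision).

.RESNAME <- c(wax = "WAX", water = "SOL", surfactant = "SUR", ai = "AI")

.species_from_resname <- function(resname) {
  rev_map <- stats::setNames(names(.RESNAME), .RESNAME)
  out <- rev_map[resname]
  # ion resnames are the uppercase element symbols
  ions <- c("NA", "CL", "CA", "MG", "K")
  ion_el <- c("Na", "Cl", "Ca", "Mg", "K")
  miss <- is.na(out)
  out[miss] <- ion_el[match(resname[miss], ions)]
  if (anyNA(out)) {
    stop("unknown residue names: ",
         paste(unique(resname[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

.default_ion_charge <- c(Na = 1L, K = 1L, Ca = 2L, Mg = 2L, Cl = -1L)

# site name -> (element, group_label, site formal charge)
.decode_name <- function(name, species) {
  n <- length(name)
  element <- character(n); group <- character(n); charge <- integer(n)
  for (i in seq_len(n)) {
    nm <- name[i]; sp <- species[i]
    if (sp == "wax") {
      element[i] <- "C"
      group[i] <- nm
      charge[i] <- if (nm == "COO") -1L else 0L
    } else if (sp == "water") {
      if (startsWith(nm, "O")) {
        element[i] <- "O"; group[i] <- "water-O"
      } else {
        element[i] <- "H"; group[i] <- "water-H"
      }
      charge[i] <- 0L
    } else if (sp == "surfactant") {
      element[i] <- if (nm == "HB") "O" else "C"
      group[i] <- "surfactant-atom"; charge[i] <- 0L
    } else if (sp == "ai") {
      element[i] <- "C"; group[i] <- "AI-atom"; charge[i] <- 0L
    } else {
      element[i] <- sp; group[i] <- "ion"
      charge[i] <- .default_ion_charge[[sp]]
    }
  }
  list(element = element, group = group, charge = charge)
}

.gro_atom_lines <- function(resid, resname, name, x, y, z) {
  sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
          resid %% 100000L, substr(resname, 1, 5), substr(name, 1, 5),
          seq_along(x) %% 100000L, x, y, z)
}

#' Write a structure in GRO format
#'
#' Fixed-column GROMACS coordinate file, positions in nm.
#'
#' @param model a [structure_model()].
#' @param path output path.
#' @param title title line.
#' @return invisibly, `path`.
#' @export
write_gro <- function(model, path, title = "waxpore structure") {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  resname <- .RESNAME[a$species]
  resname[is.na(resname)] <- toupper(a$species[is.na(resname)])
  lines <- c(
    title,
    sprintf("%d", nrow(a)),
    .gro_atom_lines(a$molecule_id, resname, a$name, a$x, a$y, a$z),
    sprintf("%10.5f%10.5f%10.5f", model$box[1], model$box[2], model$box[3])
  )
  writeLines(lines, path)
  invisible(path)
}

# parse one GRO frame starting at line `at`; returns fields + next line index
.parse_gro_block <- function(lines, at, path) {
  if (at > length(lines)) stop("truncated GRO file ", path, ": expected title at line ", at)
  title <- lines[at]
  if (at + 1 > length(lines)) stop("truncated GRO file ", path, ": missing atom count at line ", at + 1)
  nat <- suppressWarnings(as.integer(trimws(lines[at + 1])))
  if (is.na(nat)) stop("malformed atom count at line ", at + 1, " of ", path)
  last <- at + 1 + nat + 1
  if (last > length(lines)) {
    stop("truncated GRO file ", path, ": frame needs lines through ", last,
         " but file has ", length(lines))
  }
  al <- lines[at + 1 + seq_len(nat)]
  resid <- suppressWarnings(as.integer(substr(al, 1, 5)))
  if (anyNA(resid)) {
    bad <- at + 1 + which(is.na(resid))[1]
    stop("malformed fixed-column record at line ", bad, " of ", path)
  }
  x <- as.numeric(substr(al, 21, 28))
  y <- as.numeric(substr(al, 29, 36))
  z <- as.numeric(substr(al, 37, 44))
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("malformed coordinates in ", path, " near line ", at + 2)
  }
  box <- as.numeric(strsplit(trimws(lines[last]), "\\s+")[[1]])[1:3]
  if (anyNA(box)) stop("missing box line at line ", last, " of ", path)
  list(title = title, resid = resid,
       resname = trimws(substr(al, 6, 10)), name = trimws(substr(al, 11, 15)),
       x = x, y = y, z = z, box = box, next_at = last + 1)
}

#' Read a structure file
#'
#' Reads GRO (nm), PDB (Angstrom, converted to nm, box from CRYST1) or
#' XYZ (with the extended comment line carrying the box) into a
#' [structure_model()]. Species, group labels and formal charges are
#' recovered from residue/site names (GRO/PDB) or from a sidecar species
#' map (XYZ, see [write_species_map()]).
#'
#' @param path file path.
#' @param format `"gro"`, `"pdb"` or `"xyz"`; default from the extension.
#' @param map optional species-map data.frame (required for XYZ).
#' @return a [structure_model()].
#' @export
read_structure <- function(path, format = tools::file_ext(path), map = NULL) {
  format <- tolower(format)
  if (format == "gro") {
    lines <- readLines(path)
    b <- .parse_gro_block(lines, 1L, path)
    species <- .species_from_resname(b$resname)
    dec <- .decode_name(b$name, species)
    atoms <- data.frame(
      element = dec$element, name = b$name, x = b$x, y = b$y, z = b$z,
      chain_id = ifelse(species == "wax", b$resid, NA_integer_),
      molecule_id = b$resid, species = species,
      group_label = dec$group, formal_charge = dec$charge,
      layer = NA_integer_, stringsAsFactors = FALSE
    )
    structure_model(atoms, b$box, provenance = list(source = path))
  } else if (format == "pdb") {
    read_pdb(path)
  } else if (format == "xyz") {
    if (is.null(map)) stop("XYZ structures need a sidecar species map")
    fr <- read_trajectory(path, format = "xyz", map = map)
    f <- fr$frames[[1]]
    dec <- .decode_name(f$element, f$species)
    atoms <- data.frame(
      element = f$element, name = f$element, x = f$x, y = f$y, z = f$z,
      chain_id = NA_integer_, molecule_id = f$molecule_id,
      species = f$species, group_label = dec$group,
      formal_charge = dec$charge, layer = NA_integer_,
      stringsAsFactors = FALSE
    )
    structure_model(atoms, fr$box, provenance = list(source = path))
  } else {
    stop("unsupported structure format: ", format)
  }
}

#' Write a structure in PDB format
#'
#' Positions converted to Angstrom; the orthorhombic box is recorded in a
#' CRYST1 record with 90 degree angles.
#'
#' @param model a [structure_model()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  resname <- .RESNAME[a$species]
  resname[is.na(resname)] <- toupper(a$species[is.na(resname)])
  lines <- c(
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
            model$box[1] * 10, model$box[2] * 10, model$box[3] * 10,
            90, 90, 90),
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            seq_len(nrow(a)) %% 100000L, substr(a$name, 1, 4),
            substr(resname, 1, 3), a$molecule_id %% 10000L,
            a$x * 10, a$y * 10, a$z * 10, substr(a$element, 1, 2)),
    "END"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a PDB structure
#'
#' @param path file path.
#' @return a [structure_model()] with positions in nm.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0) stop("missing CRYST1 record (box) in ", path)
  box <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                      substr(cl[1], 25, 33))) / 10
  al <- grep("^(ATOM|HETATM)", lines, value = TRUE)
  if (length(al) == 0) stop("no ATOM records in ", path)
  name <- trimws(substr(al, 13, 16))
  resname <- trimws(substr(al, 18, 20))
  resid <- as.integer(substr(al, 23, 26))
  x <- as.numeric(substr(al, 31, 38)) / 10
  y <- as.numeric(substr(al, 39, 46)) / 10
  z <- as.numeric(substr(al, 47, 54)) / 10
  if (anyNA(x) || anyNA(y) || anyNA(z) || anyNA(resid)) {
    stop("malformed ATOM record in ", path)
  }
  species <- .species_from_resname(resname)
  dec <- .decode_name(name, species)
  atoms <- data.frame(
    element = dec$element, name = name, x = x, y = y, z = z,
    chain_id = ifelse(species == "wax", resid, NA_integer_),
    molecule_id = resid, species = species, group_label = dec$group,
    formal_charge = dec$charge, layer = NA_integer_,
    stringsAsFactors = FALSE
  )
  structure_model(atoms, box, provenance = list(source = path))
}

#' Write the sidecar species map of a trajectory or structure
#'
#' Tab-separated table mapping each site to its molecule, species and
#' molecule formal charge; the authoritative species/charge source for
#' XYZ files, which carry no residue information.
#'
#' @param x a [trajectory()] or [structure_model()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_species_map <- function(x, path) {
  if (inherits(x, "trajectory")) {
    f <- x$frames[[1]]
    tab <- data.frame(site = seq_len(nrow(f)), molecule_id = f$molecule_id,
                      species = f$species, charge = f$charge,
                      element = f$element)
  } else {
    a <- x$atoms
    chg <- tapply(a$formal_charge, a$molecule_id, sum)
    tab <- data.frame(site = seq_len(nrow(a)), molecule_id = a$molecule_id,
                      species = a$species,
                      charge = as.integer(chg[as.character(a$molecule_id)]),
                      element = a$element)
  }
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sidecar species map
#'
#' @param path path written by [write_species_map()].
#' @return data.frame with columns site, molecule_id, species, charge,
#'   element.
#' @export
read_species_map <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a trajectory
#'
#' Multi-frame GRO (site names derived from species) or XYZ with an
#' extended comment line carrying the time and box; XYZ needs the sidecar
#' species map ([write_species_map()]) to be read back.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @param format `"gro"` or `"xyz"`.
#' @return invisibly, `path`.
#' @export
write_trajectory <- function(traj, path, format = c("gro", "xyz")) {
  stopifnot(inherits(traj, "trajectory"))
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    f <- traj$frames[[i]]
    if (format == "gro") {
      resname <- .RESNAME[f$species]
      resname[is.na(resname)] <- toupper(f$species[is.na(resname)])
      name <- ifelse(f$species == "water", ifelse(f$element == "O", "OW", "HW"),
              ifelse(f$species == "surfactant", ifelse(f$element == "O", "HB", "TB"),
              ifelse(f$species == "ai", "MG", toupper(f$element))))
      writeLines(c(
        sprintf("t= %.6f", traj$times[i]),
        sprintf("%d", nrow(f)),
        .gro_atom_lines(f$molecule_id, resname, name, f$x, f$y, f$z),
        sprintf("%10.5f%10.5f%10.5f", traj$box[1], traj$box[2], traj$box[3])
      ), con)
    } else {
      writeLines(c(
        sprintf("%d", nrow(f)),
        sprintf("t= %.6f box= %.5f %.5f %.5f units=nm", traj$times[i],
                traj$box[1], traj$box[2], traj$box[3]),
        sprintf("%-2s %12.6f %12.6f %12.6f", f$element, f$x, f$y, f$z)
      ), con)
    }
  }
  invisible(path)
}

#' Read a multi-frame trajectory
#'
#' GRO frames carry times in their title lines (`t= <ns>`); XYZ frames in
#' the extended comment line. If no time stamps are found, a uniform
#' `stride` is applied. The molecule roster must be constant across
#' frames.
#'
#' @param path file path.
#' @param format `"gro"` or `"xyz"`; default from the extension.
#' @param map sidecar species map (required for XYZ; optional for GRO,
#'   where it overrides charges).
#' @param stride frame spacing (ns) used when no time stamps are present.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, format = tools::file_ext(path), map = NULL,
                            stride = 1) {
  format <- tolower(format)
  lines <- readLines(path)
  frames <- list()
  times <- numeric(0)
  box <- NULL
  if (format == "gro") {
    at <- 1L
    while (at <= length(lines)) {
      b <- .parse_gro_block(lines, at, path)
      species <- .species_from_resname(b$resname)
      dec <- .decode_name(b$name, species)
      chg <- tapply(dec$charge, b$resid, sum)
      f <- data.frame(
        molecule_id = b$resid, species = species,
        charge = as.integer(chg[as.character(b$resid)]),
        element = dec$element, x = b$x, y = b$y, z = b$z,
        stringsAsFactors = FALSE
      )
      tm <- regmatches(b$title, regexpr("t=\\s*[-0-9.eE+]+", b$title))
      times <- c(times, if (length(tm) == 1) {
        as.numeric(sub("t=\\s*", "", tm))
      } else {
        (length(frames)) * stride
      })
      frames <- c(frames, list(f))
      box <- b$box
      at <- b$next_at
    }
  } else if (format == "xyz") {
    if (is.null(map)) stop("XYZ trajectories need a sidecar species map")
    at <- 1L
    while (at <= length(lines)) {
      nat <- suppressWarnings(as.integer(trimws(lines[at])))
      if (is.na(nat)) stop("malformed XYZ atom count at line ", at, " of ", path)
      if (at + 1 + nat > length(lines)) {
        stop("truncated XYZ file ", path, ": frame needs lines through ",
             at + 1 + nat)
      }
      comment <- lines[at + 1]
      tm <- regmatches(comment, regexpr("t=\\s*[-0-9.eE+]+", comment))
      bm <- regmatches(comment, regexpr("box=\\s*([-0-9.eE+]+\\s+){2}[-0-9.eE+]+", comment))
      if (length(bm) == 1) {
        box <- as.numeric(strsplit(trimws(sub("box=", "", bm)), "\\s+")[[1]])
      }
      al <- lines[at + 1 + seq_len(nat)]
      parts <- do.call(rbind, strsplit(trimws(al), "\\s+"))
      if (nat != nrow(map)) {
        stop("species map has ", nrow(map), " sites but frame has ", nat)
      }
      f <- data.frame(
        molecule_id = map$molecule_id, species = map$species,
        charge = as.integer(map$charge), element = parts[, 1],
        x = as.numeric(parts[, 2]), y = as.numeric(parts[, 3]),
        z = as.numeric(parts[, 4]), stringsAsFactors = FALSE
      )
      times <- c(times, if (length(tm) == 1) {
        as.numeric(sub("t=\\s*", "", tm))
      } else {
        (length(frames)) * stride
      })
      frames <- c(frames, list(f))
      at <- at + 2L + nat
    }
    if (is.null(box)) stop("no box found in XYZ comment lines of ", path)
  } else {
    stop("unsupported trajectory format: ", format)
  }
  if (!is.null(map) && format == "gro") {
    for (i in seq_along(frames)) {
      frames[[i]]$charge <- as.integer(
        map$charge[match(seq_len(nrow(frames[[i]])), map$site)]
      )
    }
  }
  trajectory(frames, times, box)
}

#' Write a penetration trace as a two-column table
#'
#' @param trace a `penetration_trace`.
#' @param path output path (tab-separated: time_ns, z_nm).
#' @return invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "penetration_trace"))
  utils::write.table(
    data.frame(time_ns = trace$times, z_nm = trace$depths),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a penetration trace
#'
#' @param path two-column table written by [write_trace()] (or any
#'   headerless/headered time, depth table).
#' @param z0 surface anchor; default: the first depth.
#' @return a `penetration_trace`.
#' @export
read_trace <- function(path, z0 = NULL) {
  first <- readLines(path, n = 1)
  header <- grepl("[A-Za-z]", first)
  tab <- utils::read.table(path, header = header)
  if (ncol(tab) < 2) stop("expected two columns (time, depth) in ", path)
  penetration_trace_new(tab[[1]], tab[[2]],
                        z0 = if (is.null(z0)) tab[[2]][1] else z0)
}
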