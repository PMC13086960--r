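#' Molecular structure container
#'
#' A `structure_model` holds an ordered atom table, an orthorhombic box and
#' the builder provenance. Atoms are stored as a plain `data.frame` with one
#' row per site:
#'
#' * `element` — chemical symbol (united-atom carbons are `"C"`);
#' * `name`    — short site name used by the GRO/PDB writers (e.g. `"CH3"`,
#'   `"OW"`, `"CA"`);
#' * `x`, `y`, `z` — Cartesian position in nm. The wax surface plane is at
#'   z = 0 and wax occupies z < 0, so penetration depths are negative;
#' * `chain_id` — wax chain index (`NA` for solution molecules);
#' * `molecule_id` — molecule index, contiguous over the whole model;
#' * `species` — molecule-level label (`"wax"`, `"water"`, `"surfactant"`,
#'   `"ai"`, ion names such as `"Na"`, `"Ca"`, `"Cl"`);
#' * `group_label` — site-level group: one of `CH3`, `CH2`, `COO`, `COOH`,
#'   `water-O`, `water-H`, `ion`, `surfactant-atom`, `AI-atom`;
#' * `formal_charge` — integer formal charge of the site (COO⁻ = −1,
#'   Ca²⁺ = +2, Na⁺ = +1, Cl⁻ = −1, otherwise 0);
#' * `layer` — wax layer index counted from the surface (`NA` for solution).
#'
#' @param atoms data.frame with the columns described above.
#' @param box numeric length-3 box (nm).
#' @param provenance list of builder parameters used to create the model.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, box, provenance = list()) {
  required <- c("element", "name", "x", "y", "z", "chain_id", "molecule_id",
                "species", "group_label", "formal_charge", "layer")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    stop("atoms table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    stop("box must be three positive lengths (nm)")
  }
  bad <- setdiff(unique(atoms$formal_charge), -2:2)
  if (length(bad) > 0) {
    stop("formal charges outside {-2..2}: ", paste(bad, collapse = ", "))
  }
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, box = as.numeric(box), provenance = provenance),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$molecule_id)), "molecules\n")
  cat(sprintf("  box: %.3f x %.3f x %.3f nm\n",
              x$box[1], x$box[2], x$box[3]))
  tab <- table(x$atoms$species)
  cat("  species:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  q <- total_charge(x)
  cat("  net formal charge:", q, "\n")
  invisible(x)
}

#' Total formal charge of a structure
#'
#' @param model a `structure_model`.
#' @return integer sum of all site formal charges.
#' @export
total_charge <- function(model) {
  as.integer(sum(model$atoms$formal_charge))
}

#' Check net formal charge
#'
#' Sums site formal charges over the whole model. Every output of
#' [compose_solution()] is net-neutral; a bare functionalized slab carries
#' one negative charge per COO⁻ group.
#'
#' @param model a `structure_model`.
#' @return integer net charge (0 for a neutral system).
#' @export
neutrality_check <- function(model) {
  total_charge(model)
}

# empty atom table with the canonical columns
empty_atoms <- function() {
  data.frame(
    element = character(0), name = character(0),
    x = numeric(0), y = numeric(0), z = numeric(0),
    chain_id = integer(0), molecule_id = integer(0),
    species = character(0), group_label = character(0),
    formal_charge = integer(0), layer = integer(0),
    stringsAsFactors = FALSE
  )
}
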