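# Internal physical constants and unit helpers.
# Internal units are fixed package-wide: nm, ns, kT, mol/m^2,
# concentrations in mol per liter of water.

.AVOGADRO <- 6.02214076e23          # 1/mol
.WATER_MOLARITY <- 55.5             # mol of water per liter of water

# united-atom / atomic masses (g/mol) used for center-of-mass weighting
.ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  Na = 22.990, Mg = 24.305, Cl = 35.453, K = 39.098, Ca = 40.078
)

atomic_mass <- function(element) {
  m <- .ATOMIC_MASS[element]
  m[is.na(m)] <- 1.0
  unname(m)
}

#' Round half away from zero
#'
#' All count conversions in the package (molecule counts from surface excess,
#' replacement counts from fractions, water counts from molar ratios) use
#' round-half-away-from-zero rather than R's banker's rounding, so that e.g.
#' 28.5 -> 29 and -28.5 -> -29.
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, ties away from zero.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 2.4))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# run `expr` with a private RNG stream seeded by `seed`,
# restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  expr
}

# shortest lateral (x, y) displacement honoring periodic boundaries;
# z is never wrapped (the wax slab breaks z periodicity)
lateral_delta <- function(dx, dy, box = NULL) {
  if (!is.null(box)) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
  }
  list(dx = dx, dy = dy)
}

lateral_dist <- function(x, y, axis, box = NULL) {
  d <- lateral_delta(x - axis[1], y - axis[2], box)
  sqrt(d$dx^2 + d$dy^2)
}
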