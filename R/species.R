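# Species table and pure lookups shared by every other module.

# Integer species codes used throughout the package and the C++ kernels.
SPECIES_ALPHA <- 1L
SPECIES_BETA <- 2L
SPECIES_GAMMA <- 3L

.SPECIES_NAMES <- c("alpha", "beta", "gamma")
.SPECIES_RC <- c(0.25, 0.5, 1)
.SPECIES_RI <- c(1, 2, 3)
.SPECIES_MASS <- c(1, 2, 4)
.SPECIES_DRAG <- c(1, 2, 4)
.SPECIES_MAXB <- c(0L, 2L, 4L)

#' Physical properties of the three particle species
#'
#' Alpha-particles are the inert food substrate (no bonds), beta-particles
#' are chain links with up to 2 bonds, and gamma-particles are catalytic
#' hubs with up to 4 bonds. Collision radii set bond rest lengths and hard
#' contact; interaction radii set the neighbourhood within which particles
#' can react or stay bonded.
#'
#' @return A data frame with one row per species and columns `species`,
#'   `r_c` (collision radius, length units), `r_i` (interaction radius,
#'   length units), `mass` (mass units; also the alpha-equivalent mass),
#'   `drag` (linear drag coefficient, 1/s) and `max_bonds`.
#' @examples
#' species_params()
#' @export
species_params <- function() {
  data.frame(
    species = .SPECIES_NAMES,
    r_c = .SPECIES_RC,
    r_i = .SPECIES_RI,
    mass = .SPECIES_MASS,
    drag = .SPECIES_DRAG,
    max_bonds = .SPECIES_MAXB,
    stringsAsFactors = FALSE
  )
}

#' Equilibrium inter-bond angle of the torsion spring
#'
#' A particle with `n_b` bound neighbours drives each pair of its bonds
#' toward the angle that spreads the bonds maximally: linear (180 degrees)
#' for 2 neighbours, trigonal planar (120) for 3, and tetrahedral
#' (109.4712) for 4.
#'
#' @param n_b Integer number of bound neighbours, in `{2, 3, 4}`.
#' @return Target angle in degrees (vectorised over `n_b`).
#' @examples
#' target_angle(2:4)
#' @export
target_angle <- function(n_b) {
  if (!is.numeric(n_b) || any(is.na(n_b)) || !all(n_b %in% c(2, 3, 4))) {
    stop("`n_b` must contain only 2, 3 or 4 (a torsion spring needs >= 2 bonds)")
  }
  c(`2` = 180, `3` = 120, `4` = 109.4712)[as.character(n_b)]
}

species_code <- function(species) {
  if (is.numeric(species)) {
    sp <- as.integer(species)
  } else {
    sp <- match(species, .SPECIES_NAMES)
  }
  if (any(is.na(sp)) || any(sp < 1L | sp > 3L)) {
    stop("unknown species; use 'alpha', 'beta', 'gamma' or codes 1:3")
  }
  sp
}

species_mass <- function(species) .SPECIES_MASS[species_code(species)]
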