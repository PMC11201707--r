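# The single mutable world object: particle arrays, bond lists, container,
# time index. Positions, velocities and random-walk force memories are
# n x 3 matrices; bonds and unbound-neighbour lists hold particle ids.

#' Construct a simulation state
#'
#' Low-level constructor used by [initialize_state()] and by tests that
#' need hand-built configurations.
#'
#' @param species Character (`"alpha"`, `"beta"`, `"gamma"`) or integer
#'   codes 1:3, one per particle.
#' @param pos Numeric `n x 3` matrix of positions inside `[0, side]^3`.
#' @param color Integer colour values: `+1` (red), `-1` (blue) for
#'   beta/gamma, `0` for alpha. Defaults to `0` for alpha and `+1`
#'   otherwise.
#' @param vel,rwf Optional `n x 3` matrices of velocities and random-walk
#'   force memories; default zero.
#' @param bonds Optional list of integer id vectors (symmetric).
#' @param side Container side length, length units.
#' @param dt Timestep in seconds (50 steps per second by default).
#' @return An object of class `sim_state`.
#' @export
new_sim_state <- function(species, pos, color = NULL, vel = NULL, rwf = NULL,
                          bonds = NULL, side = 40, dt = 0.02) {
  sp <- species_code(species)
  n <- length(sp)
  pos <- as.matrix(pos)
  if (!is.numeric(pos) || ncol(pos) != 3 || nrow(pos) != n) {
    stop("`pos` must be a numeric n x 3 matrix")
  }
  if (any(pos < 0) || any(pos > side)) {
    stop("all positions must lie inside the container [0, side]^3")
  }
  if (is.null(color)) color <- ifelse(sp == SPECIES_ALPHA, 0L, 1L)
  color <- as.integer(color)
  if (any(color[sp == SPECIES_ALPHA] != 0L)) {
    stop("alpha-particles carry no colour (use 0)")
  }
  if (any(!color[sp != SPECIES_ALPHA] %in% c(-1L, 1L))) {
    stop("beta/gamma particles must be red (+1) or blue (-1)")
  }
  zero <- matrix(0, n, 3)
  vel <- if (is.null(vel)) zero else as.matrix(vel)
  rwf <- if (is.null(rwf)) zero else as.matrix(rwf)
  id <- seq_len(n)
  if (is.null(bonds)) bonds <- rep(list(integer(0)), n)
  state <- structure(
    list(
      id = id, species = sp, color = color, pos = unname(pos),
      vel = unname(vel), rwf = unname(rwf), bonds = bonds,
      unbound = rep(list(integer(0)), n),
      side = as.numeric(side), dt = as.numeric(dt), step = 0L,
      next_id = n + 1L
    ),
    class = "sim_state"
  )
  check_state(state)
  state
}

as_sim_state <- function(x) {
  class(x) <- "sim_state"
  x$id <- as.integer(x$id)
  x
}

#' Consistency checks for a simulation state
#'
#' Verifies bond symmetry, bond-capacity limits, the no-bonds rule for
#' alpha-particles, and that positions lie inside the sealed container.
#' Called by constructors; exported because property tests use it after
#' every mutating operation.
#'
#' @param state A `sim_state`.
#' @return `state`, invisibly; errors on any violation.
#' @export
check_state <- function(state) {
  sp <- state$species
  nb <- lengths(state$bonds)
  if (any(nb > .SPECIES_MAXB[sp])) stop("bond capacity exceeded")
  if (any(nb[sp == SPECIES_ALPHA] > 0)) stop("alpha-particles cannot form bonds")
  for (i in seq_along(state$id)) {
    for (j_id in state$bonds[[i]]) {
      j <- match(j_id, state$id)
      if (is.na(j) || !(state$id[[i]] %in% state$bonds[[j]])) {
        stop("asymmetric bond detected: ", state$id[[i]], "-", j_id)
      }
    }
  }
  if (any(state$pos < 0) || any(state$pos > state$side)) {
    stop("particle escaped the sealed container")
  }
  invisible(state)
}

#' Total alpha-equivalent mass of a state or frame
#'
#' Mass is conserved by every reaction mechanism (alpha = 1, beta = 2,
#' gamma = 4 mass units), so this quantity is a run-long invariant.
#'
#' @param x A `sim_state` or a trajectory frame.
#' @return Total mass in mass units.
#' @export
total_mass <- function(x) sum(.SPECIES_MASS[x$species])

#' @export
print.sim_state <- function(x, ...) {
  counts <- tabulate(x$species, 3)
  cat(
    "<sim_state>", length(x$id), "particles (",
    counts[1], "alpha,", counts[2], "beta,", counts[3], "gamma )",
    "at t =", x$step * x$dt, "s;",
    sum(lengths(x$bonds)) / 2, "bonds; side", x$side, "\n"
  )
  invisible(x)
}
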