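# Physics layer: neighbour-list maintenance and the four force
# contributions (random walk, linear bond springs, three-body torsion
# springs, soft-sphere collisions), plus semi-implicit Euler integration
# with linear drag and reflective container walls. All kernels are
# compiled; these wrappers define the module surface and are what the
# unit tests exercise.

#' Rebuild neighbour lists and sever over-stretched bonds
#'
#' Two particles are (unbound) neighbours when their centre distance is at
#' most the sum of their interaction radii. A bond whose endpoints exceed
#' that distance is severed symmetrically: bonded particles that leave
#' each other's interaction volumes lose the bond.
#'
#' @param state A `sim_state`.
#' @return The state with fresh `unbound` lists (sorted ids) and any
#'   stretched bonds removed.
#' @export
update_neighbor_lists <- function(state) {
  as_sim_state(cpp_build_neighbors(state))
}

#' Correlated random-walk (Brownian) force update
#'
#' One step of the AR(1) process `F <- c * F_prev + (1 - c) * g` with
#' `g ~ N(0, w I3)` per particle, approximating Brownian agitation by the
#' implicit ether. Stationary per-axis variance is `w (1 - c) / (1 + c)`.
#'
#' @param f_prev Numeric `n x 3` matrix, previous random-walk forces.
#' @param c Temporal correlation in `[0, 1]`.
#' @param w Rate constant: variance of each Gaussian innovation component.
#' @return An `n x 3` matrix of updated forces. Uses the R RNG.
#' @export
random_walk_force <- function(f_prev, c = 0.5, w = 25) {
  f_prev <- as.matrix(f_prev)
  stopifnot(is.numeric(f_prev), ncol(f_prev) == 3)
  if (c < 0 || c > 1) stop("`c` must lie in [0, 1]")
  if (w <= 0) stop("`w` must be positive")
  cpp_rw_step(f_prev, c, w)
}

#' Linear bond-spring forces
#'
#' Each bond is an ideal spring with rest length equal to the sum of the
#' two collision radii: the force on A from bond (A, B) is
#' `K_L (|s_AB| - (r_C(A) + r_C(B))) s_hat_AB`, and B feels the negation.
#'
#' @param state A `sim_state` (bond list must be symmetric).
#' @param k_l Linear spring constant.
#' @return An `n x 3` force matrix.
#' @export
linear_spring_forces <- function(state, k_l = 100) {
  cpp_spring_forces(state, k_l)
}

#' Three-body torsion-spring forces
#'
#' For every particle B with at least two bonds and every unordered pair
#' (A, C) of its bound neighbours, a torque of magnitude
#' `K_T * (angle(ABC) - target(N_B))` (angle error in degrees) drives the
#' bond pair toward the target angle. The force on A has magnitude
#' torque / |BA|, acts perpendicular to BA in the ABC plane, and likewise
#' for C; B receives minus their sum, so each triple's forces close to
#' zero. Degenerate (collinear or zero-length) geometry contributes no
#' force.
#'
#' @param state A `sim_state`.
#' @param k_t Torsion spring constant.
#' @param target_angles Target angles in degrees for 2, 3 and 4 bound
#'   neighbours.
#' @return An `n x 3` force matrix.
#' @export
torsion_forces <- function(state, k_t = 3, target_angles = target_angle(2:4)) {
  cpp_torsion_forces(state, k_t, as.numeric(target_angles))
}

#' Soft-sphere collision forces
#'
#' Pairs whose centre distance falls below the sum of their collision
#' radii repel linearly along the centre line with stiffness `k_coll`,
#' equal and opposite. This replaces a rigid-body contact solver with the
#' standard soft-sphere model used in bead-spring simulations.
#'
#' @param state A `sim_state`.
#' @param k_coll Repulsion stiffness (default twice the bond spring).
#' @return An `n x 3` force matrix.
#' @export
collision_forces <- function(state, k_coll = 200) {
  cpp_collision_forces(state, k_coll)
}

#' Advance positions and velocities by one timestep
#'
#' Semi-implicit Euler: `v <- v + dt (F/m - D v)` (linear drag enters the
#' net force as `-m D v`), then `x <- x + dt v`. Wall crossings are
#' reflected back into the sealed container with the normal velocity
#' component negated. Errors if the step produces non-finite positions.
#'
#' @param state A `sim_state`.
#' @param forces Numeric `n x 3` matrix of net non-drag forces.
#' @param overdamped_rw Add the overdamped random-walk drift
#'   `F_R / (m D)` (from the state's force memory) to the velocity used
#'   for the position update? This is the `"drift"` random-walk coupling
#'   of [schema_params()]; with `FALSE` the caller is expected to have
#'   summed the random-walk force into `forces` (`"force"` coupling).
#' @return The advanced state (`step` incremented).
#' @export
integrate_step <- function(state, forces, overdamped_rw = FALSE) {
  as_sim_state(cpp_integrate(state, as.matrix(forces), overdamped_rw))
}

#' One full physics update (forces + integration)
#'
#' Convenience composition used by tests and small-scale exploration; the
#' production loop in [run_simulation()] runs the same sequence in
#' compiled code. Neighbour lists are refreshed, the random-walk force
#' memory is advanced (unless disabled), all force contributions are
#' accumulated, and the state is integrated one step.
#'
#' @param state A `sim_state`.
#' @param schema A [schema_params()] object supplying constants.
#' @param random_walk Set `FALSE` to switch off Brownian agitation (used
#'   when checking deterministic relaxation).
#' @return The advanced state.
#' @export
physics_step <- function(state, schema = schema_params("I"), random_walk = TRUE) {
  state <- update_neighbor_lists(state)
  drift <- FALSE
  if (random_walk) {
    state$rwf <- random_walk_force(state$rwf, schema$c, schema$w)
    drift <- identical(schema$rw_coupling, "drift")
  }
  f <- linear_spring_forces(state, schema$K_L) +
    torsion_forces(state, schema$K_T, schema$target_angles) +
    collision_forces(state, schema$K_coll)
  if (random_walk && !drift) f <- f + state$rwf
  integrate_step(state, f, overdamped_rw = drift)
}
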