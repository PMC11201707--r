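# Fixture builders: all test states are generated in code.

# A state with the given species at the given positions, optionally bonded.
# `bonds` is a two-column matrix of particle indices (= ids here).
make_state <- function(species, pos, bonds = NULL, color = NULL, side = 40) {
  st <- new_sim_state(species, pos, color = color, side = side)
  if (!is.null(bonds)) {
    bl <- rep(list(integer(0)), length(st$id))
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]
      j <- bonds[k, 2]
      bl[[i]] <- c(bl[[i]], j)
      bl[[j]] <- c(bl[[j]], i)
    }
    st$bonds <- bl
    check_state(st)
  }
  st
}

# n particles of random species placed uniformly; no bonds.
random_state <- function(n, side = 40) {
  species <- sample(1:3, n, replace = TRUE)
  color <- ifelse(species == 1, 0L, sample(c(-1L, 1L), n, replace = TRUE))
  new_sim_state(species, matrix(runif(3 * n, 0, side), n, 3),
    color = color, side = side
  )
}

# Brute-force all-pairs neighbour oracle: list (by particle index) of the
# ids within summed interaction radii, excluding bonded partners.
brute_force_neighbors <- function(st) {
  ri <- species_params()$r_i[st$species]
  n <- length(st$id)
  d <- as.matrix(dist(st$pos))
  lapply(seq_len(n), function(i) {
    js <- setdiff(which(d[i, ] <= ri[i] + ri), i)
    sort(setdiff(st$id[js], st$bonds[[i]]))
  })
}

# A schema with every reaction switched off (physics constants untouched);
# named overrides in ... re-enable individual mechanisms.
inert_schema <- function(experiment = "I", ...) {
  off <- list(
    pA1 = rep(0, 5), pB = rep(0, 5), pC = 0, pD1 = 0,
    pE = rep(0, 3), pF = rep(0, 5)
  )
  do.call(schema_params, c(list(experiment), utils::modifyList(off, list(...))))
}

# Total system force from the three internal (pairwise/triple) forces.
internal_force_sum <- function(st, schema = schema_params("I")) {
  f <- linear_spring_forces(st, schema$K_L) +
    torsion_forces(st, schema$K_T, schema$target_angles) +
    collision_forces(st, schema$K_coll)
  colSums(f)
}
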