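# Forces, neighbour lists, and integration.

test_that("neighbour lists match the brute-force all-pairs oracle", {
  set.seed(42)
  for (rep in 1:5) {
    st <- update_neighbor_lists(random_state(100))
    oracle <- brute_force_neighbors(st)
    expect_equal(lapply(st$unbound, sort), oracle)
  }
})

test_that("two betas just inside interaction range become mutual neighbours", {
  st <- make_state(c("beta", "beta"), rbind(c(10, 10, 10), c(13.9, 10, 10)))
  st <- update_neighbor_lists(st)
  expect_equal(st$unbound, list(2L, 1L))
})

test_that("a bond stretched past the interaction volumes is severed", {
  st <- make_state(c("beta", "gamma"), rbind(c(10, 10, 10), c(15.1, 10, 10)),
    bonds = cbind(1, 2)
  )
  st <- update_neighbor_lists(st)
  expect_equal(st$bonds, list(integer(0), integer(0)))
  expect_equal(st$unbound, list(integer(0), integer(0)))
})

test_that("random-walk force keeps full memory at c = 1 and is white at c = 0", {
  f0 <- matrix(rnorm(30), 10, 3)
  expect_equal(random_walk_force(f0, c = 1, w = 25), f0)
  set.seed(7)
  draws <- random_walk_force(matrix(0, 1e5, 3), c = 0, w = 25)
  expect_equal(var(c(draws)), 25, tolerance = 0.05)
})

test_that("random-walk stationary variance matches the AR(1) closed form", {
  # Var = w (1 - c) / (1 + c) = 25/3 at c = 0.5, w = 25
  set.seed(11)
  f <- matrix(0, 2e4, 3)
  for (k in 1:40) f <- random_walk_force(f, c = 0.5, w = 25)
  expect_equal(var(c(f)), 25 / 3, tolerance = 0.05)
})

test_that("bond springs pull and push toward the collision-radius rest length", {
  at_sep <- function(d) {
    make_state(c("beta", "gamma"),
      rbind(c(10, 10, 10), c(10 + d, 10, 10)),
      bonds = cbind(1, 2)
    )
  }
  expect_equal(linear_spring_forces(at_sep(1.5)), matrix(0, 2, 3))
  f <- linear_spring_forces(at_sep(2.0)) # stretched: pulls together
  expect_equal(f[1, ], c(50, 0, 0))
  expect_equal(f[2, ], c(-50, 0, 0))
  f <- linear_spring_forces(at_sep(1.0)) # compressed: pushes apart
  expect_equal(f[1, ], c(-50, 0, 0))
  expect_equal(f[2, ], c(50, 0, 0))
})

bent_chain <- function(angle_deg, arm = 2) {
  # gamma(A) - gamma(B) - gamma(C) with the given ABC angle at B
  a <- angle_deg * pi / 180
  make_state(
    rep("gamma", 3),
    rbind(
      c(20 + arm, 20, 20),
      c(20, 20, 20),
      c(20 + arm * cos(a), 20 + arm * sin(a), 20)
    ),
    bonds = rbind(c(1, 2), c(2, 3))
  )
}

test_that("torsion spring vanishes at the target angle", {
  expect_equal(torsion_forces(bent_chain(180)), matrix(0, 3, 3))
})

test_that("torsion forces open a bent chain and close over the triple", {
  f <- torsion_forces(bent_chain(90))
  # A sits along +x, C along +y: opening the angle pushes A toward -y, C toward -x
  expect_lt(f[1, 2], 0)
  expect_lt(f[3, 1], 0)
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-12)
  # forces are perpendicular to the bond arms
  expect_equal(sum(f[1, ] * c(1, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(sum(f[3, ] * c(0, 1, 0)), 0, tolerance = 1e-12)
})

test_that("restoring torque is linear in the angle error with slope K_T", {
  for (delta in c(-5, -1, 1, 5)) {
    st <- bent_chain(180 + delta)
    f <- torsion_forces(st, k_t = 3)
    torque <- sqrt(sum(f[1, ]^2)) * 2 # |F_A| * |BA|
    expect_equal(torque, 3 * abs(delta), tolerance = 1e-6)
  }
})

test_that("collision force is a linear soft-sphere repulsion", {
  st <- make_state(c("alpha", "alpha"), rbind(c(10, 10, 10), c(10.4, 10, 10)))
  f <- collision_forces(st, k_coll = 200)
  expect_equal(f[1, ], c(-20, 0, 0)) # overlap 0.1, pushed apart
  expect_equal(f[2, ], c(20, 0, 0))
  apart <- make_state(c("alpha", "alpha"), rbind(c(10, 10, 10), c(10.6, 10, 10)))
  expect_equal(collision_forces(apart, 200), matrix(0, 2, 3))
})

test_that("internal forces sum to zero over random bonded clusters", {
  set.seed(3)
  for (rep in 1:5) {
    n <- 20
    st <- new_sim_state(
      rep(c("beta", "gamma"), n / 2),
      matrix(20 + runif(3 * n, -2, 2), n, 3),
      color = rep(1L, n)
    )
    # chain bonds: 1-2, 2-3, ... within capacity
    bl <- rep(list(integer(0)), n)
    for (i in seq_len(n - 1)) {
      if (length(bl[[i]]) < c(0, 2, 4)[st$species[i]] &&
        length(bl[[i + 1]]) < c(0, 2, 4)[st$species[i + 1]]) {
        bl[[i]] <- c(bl[[i]], i + 1L)
        bl[[i + 1]] <- c(bl[[i + 1]], i)
      }
    }
    st$bonds <- bl
    st <- update_neighbor_lists(st)
    expect_equal(internal_force_sum(st), c(0, 0, 0), tolerance = 1e-9)
  }
})

test_that("a free particle's speed decays geometrically under drag alone", {
  st <- make_state("beta", rbind(c(20, 20, 20)))
  st$vel[1, ] <- c(3, 0, 0)
  for (k in 1:10) st <- integrate_step(st, matrix(0, 1, 3))
  # beta drag D = 2: factor (1 - D dt) = 0.96 per step
  expect_equal(st$vel[1, 1], 3 * 0.96^10, tolerance = 1e-12)
  expect_equal(st$step, 10L)
})

test_that("zero force and zero velocity leave a particle in place", {
  st <- make_state("alpha", rbind(c(5, 5, 5)))
  st2 <- integrate_step(st, matrix(0, 1, 3))
  expect_equal(st2$pos, st$pos)
})

test_that("wall crossings reflect position and negate normal velocity", {
  st <- make_state("alpha", rbind(c(39.9, 20, 20)))
  st$vel[1, ] <- c(10, 0, 0)
  st2 <- integrate_step(st, matrix(0, 1, 3))
  expect_lt(st2$pos[1, 1], 40)
  expect_lt(st2$vel[1, 1], 0)
  expect_equal(abs(st2$vel[1, 1]), 10 * (1 - 0.02), tolerance = 1e-12)
})

test_that("an isolated bonded pair relaxes to the collision-radius rest length", {
  st <- make_state(c("beta", "gamma"), rbind(c(20, 20, 20), c(22.5, 20, 20)),
    bonds = cbind(1, 2)
  )
  sc <- schema_params("I")
  for (k in 1:2000) st <- physics_step(st, sc, random_walk = FALSE)
  expect_equal(dist(st$pos)[1], 1.5, tolerance = 1e-3)
  expect_equal(st$bonds, list(2L, 1L)) # still bonded
})

test_that("an isolated 3-chain of gammas straightens to 180 degrees", {
  st <- bent_chain(90)
  sc <- schema_params("I")
  for (k in 1:6000) st <- physics_step(st, sc, random_walk = FALSE)
  u <- st$pos[1, ] - st$pos[2, ]
  v <- st$pos[3, ] - st$pos[2, ]
  ct <- max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))
  ang <- acos(ct) * 180 / pi
  expect_equal(ang, 180, tolerance = 0.5 / 180)
})
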