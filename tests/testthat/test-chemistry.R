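# Stochastic reaction mechanisms A-F and their arbitration.

# Schema in which only the named overrides can fire.
only <- function(...) {
  inert_schema("I", ...)
}

chem <- function(st, schema) {
  arbitrate_chemistry(update_neighbor_lists(st), schema)
}

test_that("an inert schema leaves the state untouched", {
  set.seed(1)
  st <- random_state(30)
  out <- chem(st, only())
  expect_equal(nrow(out$events), 0)
  expect_equal(out$state$id, st$id)
  expect_equal(out$state$pos, st$pos)
})

test_that("beta synthesis consumes two alphas and inherits the catalyst colour", {
  st <- make_state(c("gamma", "alpha", "alpha"),
    rbind(c(20, 20, 20), c(21, 20, 20), c(20, 21.5, 20)),
    color = c(-1L, 0L, 0L)
  )
  set.seed(5)
  out <- chem(st, only(pA1 = rep(1, 5), pA2 = rep(0, 5))) # forced ejection
  expect_equal(out$events$mechanism, "A")
  s <- out$state
  expect_equal(sort(s$species), c(2L, 3L))
  beta <- which(s$species == 2L)
  expect_equal(s$color[beta], -1L) # colour of the catalysing gamma
  expect_equal(total_mass(s), total_mass(st))
  expect_equal(s$bonds[[beta]], integer(0)) # ejected: unbonded
  # the nearer alpha was transformed in place
  expect_equal(s$pos[beta, ], c(21, 20, 20))
})

test_that("beta synthesis can incorporate the product at rest length", {
  st <- make_state(c("gamma", "alpha", "alpha"),
    rbind(c(20, 20, 20), c(21, 20, 20), c(20, 21.5, 20))
  )
  set.seed(5)
  out <- chem(st, only(pA1 = rep(1, 5), pA2 = rep(1, 5)))
  s <- out$state
  beta <- which(s$species == 2L)
  gamma <- which(s$species == 3L)
  expect_equal(s$bonds[[gamma]], s$id[beta])
  expect_equal(sqrt(sum((s$pos[beta, ] - s$pos[gamma, ])^2)), 1.5)
})

test_that("a saturated gamma still catalyses but must eject", {
  # gamma with 4 bound betas (no free site) plus two alphas in range
  pos <- rbind(
    c(20, 20, 20),
    c(21.5, 20, 20), c(18.5, 20, 20), c(20, 21.5, 20), c(20, 18.5, 20),
    c(20, 20, 21), c(20, 20, 19)
  )
  st <- make_state(c("gamma", rep("beta", 4), "alpha", "alpha"), pos,
    bonds = cbind(1, 2:5)
  )
  set.seed(2)
  out <- chem(st, only(pA1 = rep(1, 5), pA2 = rep(1, 5)))
  expect_equal(out$events$mechanism, "A")
  s <- out$state
  newbeta <- which(s$species == 2L)[5]
  expect_equal(s$bonds[[newbeta]], integer(0))
  expect_equal(lengths(s$bonds)[s$species == 3L], 4L)
})

test_that("two gammas sharing the same two alphas produce exactly one event", {
  st <- make_state(c("gamma", "gamma", "alpha", "alpha"),
    rbind(c(19, 20, 20), c(21, 20, 20), c(20, 20.5, 20), c(20, 19.5, 20))
  )
  sc <- only(pA1 = rep(1, 5), pA2 = rep(0, 5))
  for (seed in 1:20) { # both visit orders occur across seeds
    set.seed(seed)
    out <- chem(st, sc)
    expect_equal(nrow(out$events), 1)
    expect_equal(sum(out$state$species == 2L), 1)
    expect_equal(total_mass(out$state), 10)
  }
})

test_that("gamma splitting consumes two bound betas and colours both daughters", {
  st <- make_state(c("gamma", "beta", "beta"),
    rbind(c(20, 20, 20), c(21.5, 20, 20), c(18.5, 20, 20)),
    bonds = rbind(c(1, 2), c(1, 3)),
    color = c(-1L, 1L, 1L)
  )
  set.seed(3)
  out <- chem(st, only(pB = rep(1, 5)))
  expect_equal(out$events$mechanism, "B")
  s <- out$state
  expect_equal(s$species, c(3L, 3L))
  expect_equal(s$color, c(-1L, -1L)) # parent colour, not the betas'
  expect_equal(total_mass(s), 8)
  expect_equal(s$bonds[[1]], s$id[2]) # daughters bound to each other
  expect_equal(s$bonds[[2]], s$id[1])
})

test_that("gamma splitting reassigns surviving neighbours within capacity", {
  st <- make_state(c("gamma", "beta", "beta", "gamma"),
    rbind(c(20, 20, 20), c(21.5, 20, 20), c(18.5, 20, 20), c(20, 22, 20)),
    bonds = rbind(c(1, 2), c(1, 3), c(1, 4))
  )
  set.seed(4)
  out <- chem(st, only(pB = rep(1, 5)))
  s <- out$state
  expect_equal(sort(s$species), c(3L, 3L, 3L))
  # the surviving gamma neighbour is bonded to exactly one daughter
  old <- which(s$id == 4L)
  expect_equal(lengths(s$bonds)[old], 1L)
  check_state(s)
})

test_that("a gamma with fewer than two bound betas never splits", {
  st <- make_state(c("gamma", "beta"),
    rbind(c(20, 20, 20), c(21.5, 20, 20)),
    bonds = cbind(1, 2)
  )
  set.seed(6)
  out <- chem(st, only(pB = rep(1, 5)))
  expect_equal(nrow(out$events), 0)
})

test_that("partially bonded beta addition forms one symmetric bond", {
  st <- make_state(c("beta", "beta", "beta"),
    rbind(c(13, 10, 10), c(10, 10, 10), c(16.5, 10, 10)),
    bonds = cbind(1, 2)
  )
  set.seed(7)
  out <- chem(st, only(pC = 1))
  expect_equal(out$events$mechanism, "C")
  s <- out$state
  expect_equal(sort(s$bonds[[1]]), c(2L, 3L))
  expect_equal(s$bonds[[3]], 1L)
})

test_that("fully bonded betas cannot initiate addition", {
  st <- make_state(rep("beta", 3),
    rbind(c(10, 10, 10), c(13, 10, 10), c(16, 10, 10)),
    bonds = rbind(c(1, 2), c(2, 3))
  )
  set.seed(8)
  out <- chem(st, only(pC = 1))
  expect_equal(nrow(out$events), 0) # middle is full, ends see no candidate
})

test_that("free beta bonding adds to an unsaturated target", {
  st <- make_state(c("beta", "beta"), rbind(c(10, 10, 10), c(13, 10, 10)))
  set.seed(9)
  out <- chem(st, only(pD1 = 1)) # NA(beta) = 0 -> pD2 = 1, always addition
  expect_equal(out$events$mechanism, "D")
  expect_equal(out$state$bonds[[1]], 2L)
  expect_equal(out$state$bonds[[2]], 1L)
})

test_that("free beta bonding inserts into a saturated gamma's bond", {
  # bound betas sit off the approach axis so the free beta (id 6) sees only
  # the gamma as a candidate
  pos <- rbind(
    c(20, 20, 20),
    c(20, 21.5, 20), c(20, 18.5, 20), c(20, 20, 21.5), c(20, 20, 18.5),
    c(24.4, 20, 20)
  )
  st <- make_state(c("gamma", rep("beta", 5)), pos, bonds = cbind(1, 2:5))
  set.seed(10)
  out <- chem(st, only(pD1 = 1)) # NA(gamma) = 4 -> pD2 = 0, always insertion
  expect_equal(out$events$mechanism, "D")
  s <- out$state
  free <- which(s$id == 6L)
  # inserted between the gamma and its neighbour nearest the free beta (id 2)
  expect_equal(sort(s$bonds[[free]]), c(1L, 2L))
  expect_false(2L %in% s$bonds[[1]])
  expect_equal(lengths(s$bonds)[1], 4L) # net bond count +1, capacity kept
  expect_equal(sum(lengths(s$bonds)) / 2, 5)
  check_state(s)
})

test_that("beta decay frees its partner and conserves mass", {
  st <- make_state(c("beta", "gamma"),
    rbind(c(20, 20, 20), c(21.5, 20, 20)),
    bonds = cbind(1, 2)
  )
  set.seed(11)
  out <- chem(st, only(pE = rep(1, 3)))
  expect_equal(out$events$mechanism, "E")
  s <- out$state
  expect_equal(sort(s$species), c(1L, 1L, 3L))
  expect_equal(s$bonds[[which(s$species == 3L)]], integer(0))
  expect_equal(total_mass(s), total_mass(st))
})

test_that("gamma decay yields four alphas", {
  st <- make_state("gamma", rbind(c(20, 20, 20)), color = -1L)
  set.seed(12)
  out <- chem(st, only(pF = rep(1, 5)))
  expect_equal(out$events$mechanism, "F")
  expect_equal(out$state$species, rep(1L, 4))
  expect_equal(out$state$color, rep(0L, 4))
  expect_equal(total_mass(out$state), 4)
})

test_that("the event stream is reproducible under a fixed seed", {
  mk <- function() {
    set.seed(99)
    st <- random_state(80, side = 15) # dense enough to react
    chem(st, schema_params("I"))
  }
  a <- mk()
  b <- mk()
  expect_identical(a$events, b$events)
  expect_identical(a$state, b$state)
})

test_that("repeated reactive timesteps preserve capacity, symmetry and mass", {
  set.seed(13)
  st <- random_state(120, side = 12)
  sc <- schema_params("I", pA1 = rep(1, 5), pB = rep(0.2, 5), pD1 = 1, pC = 1)
  m0 <- total_mass(st)
  for (k in 1:30) {
    out <- chem(st, sc)
    st <- out$state
    check_state(st)
    expect_equal(total_mass(st), m0)
    st <- physics_step(st, sc)
  }
})
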