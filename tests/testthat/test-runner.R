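# Orchestration: initial conditions, main loop, sampling, reproducibility.

test_that("default initial conditions hold 1008 alpha-equivalent mass units", {
  set.seed(1)
  st <- initialize_state(experiment_config("I"))
  expect_equal(length(st$id), 1002L)
  expect_equal(total_mass(st), 1008)
  expect_equal(sum(st$species == 3L), 2L)
  expect_setequal(st$color[st$species == 3L], c(1L, -1L))
  expect_equal(st$vel, matrix(0, 1002, 3))
  expect_equal(sum(lengths(st$bonds)), 0)
  expect_true(all(st$pos >= 0 & st$pos <= 40))
})

test_that("a seed-only configuration is a single particle of mass 4", {
  set.seed(1)
  st <- initialize_state(experiment_config("I", n_alpha = 0, n_gamma_blue = 0))
  expect_equal(length(st$id), 1L)
  expect_equal(total_mass(st), 4)
})

test_that("identical seeds give bit-identical initial states", {
  cfg <- experiment_config("II", seed = 3)
  set.seed(cfg$seed)
  a <- initialize_state(cfg)
  set.seed(cfg$seed)
  b <- initialize_state(cfg)
  expect_identical(a, b)
})

test_that("a 1 s run executes 50 steps and samples frames at 0 and 1 s", {
  cfg <- experiment_config("I",
    n_alpha = 50, duration_s = 1, seed = 2,
    retry_until_coexistence = FALSE
  )
  res <- run_simulation(cfg)
  expect_equal(length(res$frames), 2L)
  expect_equal(vapply(res$frames, `[[`, numeric(1), "t"), c(0, 1))
  expect_equal(res$final_state$step, 50L)
})

test_that("with all chemistry off the particle count never changes", {
  cfg <- experiment_config("I",
    schema = inert_schema(), n_alpha = 80,
    duration_s = 3, seed = 4, retry_until_coexistence = FALSE
  )
  res <- run_simulation(cfg)
  counts <- vapply(res$frames, function(fr) length(fr$id), integer(1))
  expect_equal(counts, rep(82L, 4))
})

test_that("runs are bit-reproducible for identical configurations", {
  cfg <- experiment_config("II", n_alpha = 150, duration_s = 4, seed = 5)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$final_state, b$final_state)
})

test_that("mass stays at its initial value in every sampled frame", {
  for (exp in c("I", "II", "III")) {
    res <- run_simulation(experiment_config(exp,
      duration_s = 6, seed = 6,
      retry_until_coexistence = FALSE
    ))
    masses <- vapply(res$frames, total_mass, numeric(1))
    expect_equal(masses, rep(1008, length(res$frames)))
  }
})

test_that("the reaction-event log accounts for every particle change", {
  cfg <- experiment_config("I",
    duration_s = 4, seed = 8, record_events = TRUE,
    retry_until_coexistence = FALSE
  )
  res <- run_simulation(cfg)
  expect_gt(nrow(res$events), 0)
  expect_true(all(res$events$mechanism %in% c("A", "B", "C", "D", "E", "F")))
  # net particle creation implied by the log matches the final state
  n_created <- sum(lengths(regmatches(
    res$events$created,
    gregexpr(",", res$events$created)
  ))) + sum(nzchar(res$events$created))
  n_consumed <- sum(lengths(regmatches(
    res$events$consumed,
    gregexpr(",", res$events$consumed)
  ))) + sum(nzchar(res$events$consumed))
  expect_equal(
    length(res$final_state$id) - 1002L,
    n_created - n_consumed
  )
})

test_that("trajectories round-trip through JSON lines", {
  res <- run_simulation(experiment_config("I",
    n_alpha = 40, duration_s = 2,
    seed = 9, retry_until_coexistence = FALSE
  ))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_trajectory(res$frames, path)
  back <- read_trajectory(path)
  expect_equal(length(back), length(res$frames))
  for (k in seq_along(back)) {
    expect_equal(back[[k]]$id, res$frames[[k]]$id)
    expect_equal(back[[k]]$species, res$frames[[k]]$species)
    expect_equal(back[[k]]$bonds, lapply(res$frames[[k]]$bonds, as.integer))
    expect_equal(back[[k]]$pos, res$frames[[k]]$pos, tolerance = 1e-3)
  }
  # metrics recomputed from the round-tripped trajectory agree exactly
  expect_equal(metrics_series(back), res$metrics)
})

test_that("event logs serialise to JSON lines", {
  res <- run_simulation(experiment_config("I",
    duration_s = 2, seed = 10,
    record_events = TRUE, retry_until_coexistence = FALSE
  ))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_events(res$events, path)
  lines <- readLines(path)
  expect_equal(length(lines), nrow(res$events))
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("step", "mechanism", "initiator") %in% names(rec)))
})

test_that("extended-XYZ export writes one block per frame", {
  res <- run_simulation(experiment_config("I",
    n_alpha = 10, duration_s = 1,
    seed = 11, retry_until_coexistence = FALSE
  ))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(res$frames, path)
  lines <- readLines(path)
  expect_equal(lines[1], "12")
  expect_equal(sum(lines == "12"), 2)
  expect_true(all(grepl("^(He|C|N) ", lines[3:14])))
})
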