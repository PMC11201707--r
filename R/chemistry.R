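# Chemistry layer: stochastic per-timestep application of the six
# reaction mechanisms, executed before the physics update. Each particle
# may initiate at most one mechanism per timestep; particles consumed
# earlier in the same timestep are ineligible as initiators or reagents.

#' Run one chemistry timestep
#'
#' Visits the particles present at the start of the timestep in a fresh
#' uniform random order. Each eligible particle rolls its mechanisms with
#' the schema's per-timestep probabilities (gamma: A beta-synthesis, B
#' splitting, then F decay; beta: C addition or D free bonding depending
#' on its bond count, then E decay); the first success is the particle's
#' single initiated reaction. All creations, deletions and bond changes
#' are applied atomically before the physics update. Alpha-equivalent
#' mass (alpha 1, beta 2, gamma 4) is conserved by every mechanism.
#'
#' Neighbour eligibility is read from the state's current `unbound` and
#' `bonds` lists, so call [update_neighbor_lists()] first if positions
#' have changed since the lists were built.
#'
#' @param state A `sim_state` with current neighbour lists.
#' @param schema A [schema_params()] object.
#' @param record_events Keep a per-event log?
#' @return A list with the updated `state` and an `events` data frame
#'   (columns `step`, `mechanism`, `initiator`, `consumed`, `created`,
#'   `bonds_formed`, `bonds_severed`; id lists comma-separated, bond pairs
#'   as `"i-j"` semicolon-separated). Uses the R RNG.
#' @export
arbitrate_chemistry <- function(state, schema = schema_params("I"),
                                record_events = TRUE) {
  stopifnot(inherits(schema, "schema_params"))
  out <- cpp_chemistry(state, unclass(schema), record_events)
  list(state = as_sim_state(out$state), events = out$events)
}

#' Write a reaction-event log as JSON lines
#'
#' One event per line for audit or debugging:
#' `{"step":..,"mechanism":"A","initiator":..,"consumed":[..],
#' "created":[..],"bonds_formed":[[i,j],..],"bonds_severed":[..]}`.
#'
#' @param events Event data frame from [arbitrate_chemistry()] or
#'   [run_simulation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  split_ids <- function(s) {
    if (!nzchar(s)) integer(0) else as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  }
  split_bonds <- function(s) {
    if (!nzchar(s)) {
      list()
    } else {
      lapply(
        strsplit(s, ";", fixed = TRUE)[[1]],
        function(p) as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      )
    }
  }
  for (k in seq_len(nrow(events))) {
    rec <- list(
      step = events$step[[k]],
      mechanism = events$mechanism[[k]],
      initiator = events$initiator[[k]],
      consumed = split_ids(events$consumed[[k]]),
      created = split_ids(events$created[[k]]),
      bonds_formed = split_bonds(events$bonds_formed[[k]]),
      bonds_severed = split_bonds(events$bonds_severed[[k]])
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}
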