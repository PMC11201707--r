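# Trajectory input/output: JSON-lines frames (one frame per line) and an
# extended-XYZ export for molecular viewers.

#' Write or read a trajectory as JSON lines
#'
#' One frame per line:
#' `{"t":0,"particles":[{"id":1,"sp":"a","col":0,"x":[..],"bonds":[..]},..]}`
#' with species coded `"a"`, `"b"`, `"g"`. The reverse reader returns the
#' in-memory frame list used by [metrics_series()] and friends.
#'
#' @param frames Frame list from [run_simulation()].
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a list of frames.
#' @export
write_trajectory <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sp_code <- c("a", "b", "g")
  for (fr in frames) {
    particles <- lapply(seq_along(fr$id), function(i) {
      list(
        id = fr$id[[i]],
        sp = sp_code[[fr$species[[i]]]],
        col = fr$color[[i]],
        x = round(fr$pos[i, ], 4),
        bonds = fr$bonds[[i]]
      )
    })
    writeLines(
      jsonlite::toJSON(list(t = fr$t, particles = particles),
        auto_unbox = TRUE, digits = NA
      ),
      con
    )
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  sp_code <- c(a = SPECIES_ALPHA, b = SPECIES_BETA, g = SPECIES_GAMMA)
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    ps <- rec$particles
    n <- length(ps)
    pos <- matrix(0, n, 3)
    for (i in seq_len(n)) pos[i, ] <- unlist(ps[[i]]$x)
    list(
      t = rec$t,
      id = vapply(ps, function(p) as.integer(p$id), integer(1)),
      species = unname(sp_code[vapply(ps, function(p) p$sp, character(1))]),
      color = vapply(ps, function(p) as.integer(p$col), integer(1)),
      pos = pos,
      bonds = lapply(ps, function(p) as.integer(unlist(p$bonds)))
    )
  })
}

#' Export a trajectory in extended-XYZ format
#'
#' For molecular viewers only: species are mapped to arbitrary element
#' symbols (alpha to He, beta to C, gamma to N) with no chemical meaning.
#'
#' @param frames Frame list from [run_simulation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  elem <- c("He", "C", "N")
  for (fr in frames) {
    side <- attr(fr, "side") %||% 40
    writeLines(as.character(length(fr$id)), con)
    writeLines(sprintf(
      'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3 Time=%g',
      side, side, side, fr$t
    ), con)
    writeLines(sprintf(
      "%s %.4f %.4f %.4f",
      elem[fr$species], fr$pos[, 1], fr$pos[, 2], fr$pos[, 3]
    ), con)
  }
  invisible(path)
}
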