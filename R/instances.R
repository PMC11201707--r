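# Instance identification: connected components of the bond graph are
# candidate individuals; a component is a viable instance only if it
# contains at least one gamma-particle (closure under entailment -- the
# ability to keep producing its own components). Majority colour
# classifies each instance by which seed lineage contributes more
# gamma-particles.

#' Connected components of the bond graph
#'
#' Treats particles as nodes and bonds as edges and returns the maximal
#' connected components — the bonded subgraphs from which individual
#' instances are drawn. Implemented as an iterative depth-first traversal
#' (an explicit stack avoids recursion-depth limits on large instances).
#' Unbonded particles appear as singleton components. The partition is
#' invariant under particle reordering.
#'
#' @param x A `sim_state` or a trajectory frame (any list with `id` and
#'   `bonds`).
#' @return A list of integer id vectors, each sorted ascending; every
#'   particle appears in exactly one component. Errors on an asymmetric
#'   bond list.
#' @examples
#' st <- new_sim_state(c("gamma", "beta", "beta"),
#'   pos = cbind(c(10, 11.5, 13), 10, 10)
#' )
#' st$bonds <- list(2L, c(1L, 3L), 2L)
#' find_components(st)
#' @export
find_components <- function(x) {
  id <- x$id
  bonds <- x$bonds
  n <- length(id)
  if (n == 0) {
    return(list())
  }
  # one hashed match over the concatenated bond lists (not one per particle)
  flat <- match(unlist(bonds), id)
  if (anyNA(flat)) stop("bond references unknown particle id")
  adj <- unname(split(
    flat,
    factor(rep.int(seq_len(n), lengths(bonds)), levels = seq_len(n))
  ))
  for (i in seq_len(n)) {
    js <- adj[[i]]
    for (j in js) {
      if (!i %in% adj[[j]]) {
        stop("asymmetric bond detected: ", id[[i]], "-", id[[j]])
      }
    }
  }
  visited <- logical(n)
  comps <- vector("list", n)
  ncomp <- 0L
  for (root in seq_len(n)) {
    if (visited[[root]]) next
    stack <- root
    visited[[root]] <- TRUE
    members <- integer(0)
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      members <- c(members, v)
      for (u in adj[[v]]) {
        if (!visited[[u]]) {
          visited[[u]] <- TRUE
          stack <- c(stack, u)
        }
      }
    }
    ncomp <- ncomp + 1L
    comps[[ncomp]] <- sort(id[members])
  }
  comps[seq_len(ncomp)]
}

#' Viable individual instances of a frame
#'
#' Filters the bonded components down to viable instances (at least one
#' gamma member) and tabulates each one: size, alpha-equivalent mass,
#' per-species mass, gamma and beta colour counts, and the majority-colour
#' classification (`"red"` if red gammas outnumber blue gammas, `"blue"`
#' for the converse, `"excluded"` on a tie — excluded instances still
#' count toward the overall instance number but toward neither colour).
#'
#' @param x A `sim_state` or trajectory frame.
#' @param components Optional precomputed output of [find_components()].
#' @return A data frame with one row per viable instance and columns
#'   `size`, `mass`, `mass_beta`, `mass_gamma`, `n_gamma`, `n_gamma_red`,
#'   `n_gamma_blue`, `n_beta`, `n_beta_red`, `n_beta_blue`, `majority`,
#'   plus a `members` list-column of particle ids.
#' @export
viable_instances <- function(x, components = find_components(x)) {
  idx_flat <- match(unlist(components), x$id)
  idx_split <- unname(split(
    idx_flat,
    factor(rep.int(seq_along(components), lengths(components)),
      levels = seq_along(components)
    )
  ))
  rows <- lapply(seq_along(components), function(ci) {
    members <- components[[ci]]
    idx <- idx_split[[ci]]
    sp <- x$species[idx]
    if (!any(sp == SPECIES_GAMMA)) {
      return(NULL)
    }
    col <- x$color[idx]
    ngr <- sum(sp == SPECIES_GAMMA & col == 1L)
    ngb <- sum(sp == SPECIES_GAMMA & col == -1L)
    data.frame(
      size = length(members),
      mass = sum(.SPECIES_MASS[sp]),
      mass_beta = 2 * sum(sp == SPECIES_BETA),
      mass_gamma = 4 * sum(sp == SPECIES_GAMMA),
      n_gamma = ngr + ngb,
      n_gamma_red = ngr,
      n_gamma_blue = ngb,
      n_beta = sum(sp == SPECIES_BETA),
      n_beta_red = sum(sp == SPECIES_BETA & col == 1L),
      n_beta_blue = sum(sp == SPECIES_BETA & col == -1L),
      majority = if (ngr > ngb) "red" else if (ngb > ngr) "blue" else "excluded",
      stringsAsFactors = FALSE
    )
  })
  rows <- Filter(Negate(is.null), rows)
  keep <- vapply(idx_split, function(idx) {
    any(x$species[idx] == SPECIES_GAMMA)
  }, logical(1))
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      size = integer(0), mass = numeric(0), mass_beta = numeric(0),
      mass_gamma = numeric(0), n_gamma = integer(0),
      n_gamma_red = integer(0), n_gamma_blue = integer(0),
      n_beta = integer(0), n_beta_red = integer(0), n_beta_blue = integer(0),
      majority = character(0), stringsAsFactors = FALSE
    )
  }
  out$members <- components[keep]
  out
}
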