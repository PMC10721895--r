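#' Define a helix-turn-helix repeat topology
#'
#' A repeat topology describes one repeat unit of a designed helical repeat
#' (DHR) protein: two alpha-helices joined by short loops, tandemly repeated
#' `n_repeats` times. Helix lengths are restricted to the 16-30 residue range
#' explored for these designs unless `override_range = TRUE`.
#'
#' @param name Label for the design (e.g. `"FD31"`).
#' @param helix_lengths Integer vector of residues per helix (length 2).
#' @param loop_lengths Integer vector of residues per connector (length 2);
#'   the second loop joins a repeat to the next one.
#' @param n_repeats Number of tandem repeats (>= 1).
#' @param override_range Allow helix lengths outside 16-30 residues (used for
#'   small test systems).
#'
#' @return An object of class `repeat_topology`.
#' @examples
#' repeat_topology("FD31", c(22, 22), c(3, 3), n_repeats = 6)
#' @export
repeat_topology <- function(name, helix_lengths = c(20L, 20L),
                            loop_lengths = c(3L, 3L), n_repeats = 6L,
                            override_range = FALSE) {
  helix_lengths <- as.integer(helix_lengths)
  loop_lengths <- as.integer(loop_lengths)
  n_repeats <- as.integer(n_repeats)
  if (length(helix_lengths) != 2L) {
    stop("`helix_lengths` must have length 2 (two helices per repeat).")
  }
  if (!override_range && any(helix_lengths < 16L | helix_lengths > 30L)) {
    stop("helix lengths must lie in 16..30 residues (set `override_range = TRUE` to bypass).")
  }
  if (any(helix_lengths < 2L)) stop("helices need at least 2 residues.")
  if (any(loop_lengths < 1L)) stop("loops need at least 1 residue.")
  if (n_repeats < 1L) stop("`n_repeats` must be >= 1.")
  structure(
    list(
      name = name,
      helices_per_repeat = 2L,
      helix_lengths = helix_lengths,
      loop_lengths = loop_lengths,
      n_repeats = n_repeats,
      residues_per_repeat = sum(helix_lengths) + sum(loop_lengths)
    ),
    class = "repeat_topology"
  )
}

#' @export
print.repeat_topology <- function(x, ...) {
  cat(sprintf(
    "<repeat_topology> %s: %d repeats x (H%d-L%d-H%d-L%d) = %d residues/repeat\n",
    x$name, x$n_repeats, x$helix_lengths[1], x$loop_lengths[1],
    x$helix_lengths[2], x$loop_lengths[2], x$residues_per_repeat
  ))
  invisible(x)
}

#' Superhelical parameters for a flat repeat protein
#'
#' Parameter targets for idealized flat repeat proteins: a very large
#' superhelical radius (default 500 nm, i.e. effectively straight), zero rise
#' and zero curvature per repeat, plus the inter-repeat distance `d_rep` that
#' sets the spacing of the repeating surface lattice.
#'
#' @param d_rep Inter-repeat distance in Angstrom (5-20 A supported).
#' @param superhelical_radius Superhelical radius bias target, Angstrom
#'   (default 5000 A = 500 nm, flat).
#' @param rise_per_repeat Rise per repeat along the superhelical axis,
#'   Angstrom (default 0).
#' @param curvature Curvature per repeat, radians (default 0).
#'
#' @return An object of class `helical_params`.
#' @export
helical_params <- function(d_rep, superhelical_radius = 5000,
                           rise_per_repeat = 0, curvature = 0) {
  if (!is.numeric(d_rep) || d_rep <= 0) stop("`d_rep` must be > 0.")
  structure(
    list(
      d_rep = as.numeric(d_rep),
      superhelical_radius = superhelical_radius,
      rise_per_repeat = rise_per_repeat,
      curvature = curvature
    ),
    class = "helical_params"
  )
}

# Packaged design topologies. Repeat counts and carboxylate totals follow the
# published designs; helix/loop lengths within each repeat are representative
# choices in the sampled 16-30 residue range (exact per-design lengths are not
# part of the packaged surface definitions, which pin slot counts instead).
design_topologies <- function() {
  list(
    "FD15" = list(
      topology = repeat_topology("FD15", c(18L, 18L), c(3L, 3L), 6L),
      d_rep = 8.7, d_rep_design = 8.7, slots_per_repeat = 4L
    ),
    "FD31" = list(
      topology = repeat_topology("FD31", c(22L, 22L), c(3L, 3L), 6L),
      d_rep = 11.4, d_rep_design = 10.9, slots_per_repeat = 6L
    ),
    "DHR49-Neg" = list(
      topology = repeat_topology("DHR49-Neg", c(24L, 24L), c(3L, 3L), 6L),
      d_rep = 10.6, d_rep_design = 10.6, slots_per_repeat = 7L
    )
  )
}
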