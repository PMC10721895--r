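#' Coarse-grained interface energy model
#'
#' An explicit simplification used for surface docking: screened Coulomb
#' (Debye-Hueckel) electrostatics between anchor and ion point charges plus
#' a soft Lennard-Jones term. This is a coarse-grained interface score for
#' ranking poses, not a reimplementation of any all-atom force field; its
#' absolute values are not comparable to all-atom energies.
#'
#' @param lj_sigma,lj_epsilon Lennard-Jones parameters (Angstrom, energy
#'   units).
#' @param debye_length Electrostatic screening length, Angstrom (default 8 A,
#'   appropriate for ~10 mM ionic strength).
#' @param dielectric_scale Relative dielectric scaling of the Coulomb term.
#' @param coulomb_k Coulomb constant, energy A / e^2.
#' @param cutoff Pair interaction cutoff, Angstrom.
#' @param hard_core Hard-sphere contact distance, Angstrom; pairs closer
#'   than this are scored at the clamped contact value and flagged.
#' @return An `energy_model` list.
#' @export
energy_model <- function(lj_sigma = 3.2, lj_epsilon = 0.1, debye_length = 8,
                         dielectric_scale = 80, coulomb_k = 332.06,
                         cutoff = 15, hard_core = 2.0) {
  structure(
    list(lj_sigma = lj_sigma, lj_epsilon = lj_epsilon,
         debye_length = debye_length, dielectric_scale = dielectric_scale,
         coulomb_k = coulomb_k, cutoff = cutoff, hard_core = hard_core),
    class = "energy_model"
  )
}

# pair energy for distance vector r (already cutoff-filtered, clamped)
#' @noRd
pair_energy <- function(r, qq, em) {
  elec <- em$coulomb_k * qq * exp(-r / em$debye_length) / (em$dielectric_scale * r)
  sr6 <- (em$lj_sigma / r)^6
  lj <- 4 * em$lj_epsilon * (sr6^2 - sr6)
  elec + lj
}

#' A rigid-body pose of a template over a surface slab
#'
#' @param x,y,z Translation, Angstrom (z is height of the array centroid
#'   above the surface plane).
#' @param rot In-plane rotation, degrees.
#' @param tilt Two small tilt angles about x and y, degrees (bounded +-10).
#' @return A `pose` list.
#' @export
pose <- function(x = 0, y = 0, z = 5, rot = 0, tilt = c(0, 0)) {
  if (any(abs(tilt) > 10)) stop("tilt angles are bounded to +-10 degrees.")
  structure(list(x = x, y = y, z = z, rot = rot, tilt = tilt), class = "pose")
}

# centered dock points of an array: anchors with the surface normal mapped
# to -z so the functional groups face the slab below
#' @noRd
dock_points <- function(array) {
  xyz <- as.matrix(array[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  x0 <- sweep(xyz, 2, ctr)
  sv <- svd(x0)
  # third principal direction = surface normal of the (flat) anchor sheet
  basis <- sv$v
  if (det(basis) < 0) basis[, 3] <- -basis[, 3]
  pts <- x0 %*% basis
  pts[, 3] <- -abs(pts[, 3]) # anchors face downwards
  pts
}

#' @noRd
apply_pose <- function(pts, p) {
  R <- rotation_about_axis(c(0, 0, 1), deg2rad(p$rot)) %*%
    rotation_about_axis(c(1, 0, 0), deg2rad(p$tilt[1])) %*%
    rotation_about_axis(c(0, 1, 0), deg2rad(p$tilt[2]))
  sweep(pts %*% t(R), 2, c(p$x, p$y, p$z), FUN = "+")
}

#' Score a pose of a template array on a surface slab
#'
#' Sum of screened-Coulomb plus soft Lennard-Jones terms over anchor-ion
#' pairs within the model cutoff, found with a cell-list neighbor search.
#' Deterministic. Pairs below the hard-sphere contact distance are clamped
#' to the contact energy and flagged via the `clamped` attribute rather
#' than raising an error.
#'
#' @param array A `surface_array`.
#' @param slab A `surface_slab`.
#' @param pose A [pose()].
#' @param model An [energy_model()].
#' @return Energy (numeric scalar) with attribute `clamped` (logical).
#' @export
score_pose <- function(array, slab, pose, model = energy_model()) {
  pts <- apply_pose(dock_points(array), pose)
  interaction_energy(pts, array$charge, as.matrix(slab[, c("x", "y", "z")]),
                     slab$charge, model)
}

# cell-list neighbor energy between two point sets
#' @noRd
interaction_energy <- function(pts_a, q_a, pts_b, q_b, em) {
  cut <- em$cutoff
  keyify <- function(ix) paste(ix[, 1], ix[, 2], ix[, 3])
  bin_b <- floor(pts_b / cut)
  bins <- split(seq_len(nrow(pts_b)), keyify(bin_b))
  total <- 0
  clamped <- FALSE
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  bin_a <- floor(pts_a / cut)
  for (i in seq_len(nrow(pts_a))) {
    if (q_a[i] == 0 && em$lj_epsilon == 0) next
    neigh <- integer(0)
    for (o in seq_len(nrow(offs))) {
      key <- paste(bin_a[i, 1] + offs[o, 1], bin_a[i, 2] + offs[o, 2],
                   bin_a[i, 3] + offs[o, 3])
      hit <- bins[[key]]
      if (!is.null(hit)) neigh <- c(neigh, hit)
    }
    if (length(neigh) == 0) next
    dv <- sweep(pts_b[neigh, , drop = FALSE], 2, pts_a[i, ])
    r <- sqrt(rowSums(dv^2))
    sel <- r <= cut
    if (!any(sel)) next
    r <- r[sel]
    if (any(r < em$hard_core)) {
      clamped <- TRUE
      r <- pmax(r, em$hard_core)
    }
    total <- total + sum(pair_energy(r, q_a[i] * q_b[neigh[sel]], em))
  }
  attr(total, "clamped") <- clamped
  total
}

# discrete anchor-offset library mimicking a coarse carboxylate rotamer
# sweep; state 1 is always the identity offset
#' @noRd
offset_library <- function(library_size, radius = 0.5) {
  stopifnot(library_size >= 1)
  out <- matrix(0, nrow = library_size, ncol = 3)
  if (library_size > 1) {
    ang <- 2 * pi * (seq_len(library_size - 1) - 1) / (library_size - 1)
    out[-1, ] <- cbind(radius * cos(ang), radius * sin(ang), -radius / 2)
  }
  out
}

#' Repeat-symmetric sidechain state sampling
#'
#' Chooses one discrete anchor-offset state per within-repeat slot and
#' applies it identically at every repeat (repeat symmetry is enforced by
#' construction). Slots are visited in a seeded random order and the state
#' minimizing the pose energy is kept greedily for each slot.
#'
#' @param array A `surface_array`.
#' @param slab A `surface_slab` the states are optimized against.
#' @param pose A [pose()].
#' @param library_size Number of offset states (default 5); state 1 is the
#'   identity offset.
#' @param seed Integer seed (slot visit order).
#' @param model An [energy_model()].
#' @return A list with `states` (integer per slot), `array` (the
#'   offset-adjusted `surface_array`) and `energy`.
#' @export
sample_sidechain_states <- function(array, slab, pose, library_size = 5L,
                                    seed = 1L, model = energy_model()) {
  stopifnot(library_size >= 1)
  set.seed(as.integer(seed))
  lib <- offset_library(library_size)
  slots <- sort(unique(array$slot))
  states <- stats::setNames(rep(1L, length(slots)), slots)
  if (library_size == 1L) {
    return(list(states = states, array = array,
                energy = as.numeric(score_pose(array, slab, pose, model))))
  }
  order_slots <- sample(slots)
  cur <- array
  for (s in order_slots) {
    idx <- which(cur$slot == s)
    base <- as.matrix(array[idx, c("x", "y", "z")])
    energies <- vapply(seq_len(library_size), function(k) {
      trial <- cur
      trial$x[idx] <- base[, 1] + lib[k, 1]
      trial$y[idx] <- base[, 2] + lib[k, 2]
      trial$z[idx] <- base[, 3] + lib[k, 3]
      as.numeric(score_pose(trial, slab, pose, model))
    }, numeric(1))
    k_best <- which.min(energies)
    states[as.character(s)] <- k_best
    cur$x[idx] <- base[, 1] + lib[k_best, 1]
    cur$y[idx] <- base[, 2] + lib[k_best, 2]
    cur$z[idx] <- base[, 3] + lib[k_best, 3]
  }
  list(states = states, array = cur,
       energy = as.numeric(score_pose(cur, slab, pose, model)))
}

#' Baseline-subtracted binding score
#'
#' The binding score is the complex energy minus the median energy of an
#' ensemble of configurations with protein and surface separated by 10 nm.
#'
#' @param e_complex Energy of the docked complex.
#' @param baseline Numeric vector of separated-state energies (>= 1).
#' @return `e_complex - median(baseline)`.
#' @examples
#' binding_score(-5, c(0, 0, 0)) # -5
#' @export
binding_score <- function(e_complex, baseline) {
  if (length(baseline) < 1) stop("baseline ensemble must be non-empty.")
  as.numeric(e_complex) - stats::median(baseline)
}

#' Monte-Carlo rigid-body docking with a baseline-subtracted score
#'
#' Each trajectory starts from a random in-plane rotation of the template
#' over the surface, then Metropolis Monte-Carlo samples rigid-body moves
#' (translation sd 0.5 A, rotation sd 5 deg, tilt sd 1 deg per step) under a
#' geometric temperature schedule, keeping the best pose seen. The baseline
#' ensemble holds the protein at 10 nm separation under random in-plane
#' rotations; the binding score subtracts its median from the best complex
#' energy.
#'
#' @param array A `surface_array`.
#' @param slab A `surface_slab`.
#' @param model An [energy_model()].
#' @param steps Monte-Carlo steps (>= 1).
#' @param seed Integer seed; identical seeds give identical results.
#' @param temp_start,temp_end Geometric temperature schedule endpoints.
#' @param baseline_n Number of separated-baseline poses (forced odd so the
#'   median is an ensemble member; default 15).
#' @param start_pose Optional fixed starting [pose()] (otherwise random
#'   rotation at contact height).
#' @param move_sd Named numeric: `translation` (A), `rotation` (deg),
#'   `tilt` (deg).
#' @return A `dock_result`: list with `best_pose`, `e_complex`, `e_start`,
#'   `baseline` (vector), `e_binding`, `trajectory` (tibble of step,
#'   energy, best-so-far), `seed`.
#' @export
mc_dock <- function(array, slab, model = energy_model(), steps = 500L,
                    seed = 1L, temp_start = 1.0, temp_end = 0.01,
                    baseline_n = 15L, start_pose = NULL,
                    move_sd = c(translation = 0.5, rotation = 5, tilt = 1)) {
  stopifnot(steps >= 1)
  set.seed(as.integer(seed))
  baseline_n <- as.integer(baseline_n)
  if (baseline_n %% 2L == 0L) baseline_n <- baseline_n + 1L

  pts0 <- dock_points(array)
  top_z <- max(slab$z)
  contact_z <- top_z + max(-pts0[, 3]) + 3.0

  p_cur <- if (is.null(start_pose)) {
    pose(x = stats::runif(1, 0, 10), y = stats::runif(1, 0, 10),
         z = contact_z, rot = stats::runif(1, 0, 360))
  } else start_pose
  e_cur <- as.numeric(score_pose(array, slab, p_cur, model))
  e_start <- e_cur
  p_best <- p_cur; e_best <- e_cur

  temps <- if (temp_start <= 0) rep(0, steps) else {
    temp_start * (temp_end / temp_start)^((seq_len(steps) - 1) / max(1, steps - 1))
  }
  traj_e <- numeric(steps); traj_best <- numeric(steps)
  z_floor <- top_z + 1.0

  for (s in seq_len(steps)) {
    p_try <- p_cur
    p_try$x <- p_try$x + stats::rnorm(1, 0, move_sd["translation"])
    p_try$y <- p_try$y + stats::rnorm(1, 0, move_sd["translation"])
    p_try$z <- max(z_floor, p_try$z + stats::rnorm(1, 0, move_sd["translation"]))
    p_try$rot <- (p_try$rot + stats::rnorm(1, 0, move_sd["rotation"])) %% 360
    p_try$tilt <- pmax(-10, pmin(10, p_try$tilt + stats::rnorm(2, 0, move_sd["tilt"])))
    e_try <- as.numeric(score_pose(array, slab, p_try, model))
    accept <- e_try <= e_cur ||
      (temps[s] > 0 && stats::runif(1) < exp(-(e_try - e_cur) / temps[s]))
    if (accept) { p_cur <- p_try; e_cur <- e_try }
    if (e_cur < e_best) { p_best <- p_cur; e_best <- e_cur }
    traj_e[s] <- e_cur; traj_best[s] <- e_best
  }

  baseline <- vapply(seq_len(baseline_n), function(i) {
    pb <- pose(x = stats::runif(1, 0, 10), y = stats::runif(1, 0, 10),
               z = top_z + 100, rot = stats::runif(1, 0, 360))
    as.numeric(score_pose(array, slab, pb, model))
  }, numeric(1))

  structure(
    list(
      best_pose = p_best,
      e_complex = e_best,
      e_start = e_start,
      baseline = baseline,
      e_binding = binding_score(e_best, baseline),
      trajectory = tibble::tibble(step = seq_len(steps), energy = traj_e,
                                  best = traj_best),
      seed = as.integer(seed)
    ),
    class = "dock_result"
  )
}

#' @export
print.dock_result <- function(x, ...) {
  cat(sprintf(
    "<dock_result> e_complex %.4g, baseline median %.4g (n=%d), binding score %.4g\n",
    x$e_complex, stats::median(x$baseline), length(x$baseline), x$e_binding
  ))
  invisible(x)
}
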