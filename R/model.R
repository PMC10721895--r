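#' Build an idealized flat helical-repeat backbone
#'
#' Generates backbone coordinates (N, CA, C, O) for a flat helix-turn-helix
#' repeat protein. Helices are built with ideal alpha-helical geometry
#' (1.5 A rise and 100 deg twist per residue); loop residues are straight-line
#' placeholders between helix termini and are excluded from scoring in
#' downstream protocols. Successive repeats are related by a pure translation
#' of magnitude `d_rep` along the repeat axis (x), so the repeat transform has
#' zero rotation and the protein surface is perfectly flat and repetitive.
#'
#' The two helices of a repeat sit in two layers separated by `layer_sep`
#' along z; the solvent-facing surface used for carboxylate arrays is the
#' z > 0 face of the top helix layer.
#'
#' @param topology A [repeat_topology()].
#' @param params A [helical_params()], or `d_rep` may be given directly.
#' @param d_rep Inter-repeat distance in Angstrom (5-20 A); overrides
#'   `params$d_rep` if both are given.
#' @param seed Integer seed (kept for interface symmetry with the stochastic
#'   operations; the ideal builder is deterministic).
#' @param layer_sep Distance between the two helix layers, Angstrom.
#'
#' @return An object of class `backbone_model`: a list with `atoms` (a tibble
#'   with columns `res_id`, `repeat_index`, `res_in_repeat`, `segment`,
#'   `atom`, `x`, `y`, `z`), `topology` and `params`.
#' @examples
#' topo <- repeat_topology("FD31", c(22, 22), c(3, 3), 6)
#' mod <- build_repeat_model(topo, d_rep = 11.4)
#' measure_repeat_spacing(mod)
#' @export
build_repeat_model <- function(topology, params = NULL, d_rep = NULL,
                               seed = 1L, layer_sep = 10) {
  stopifnot(inherits(topology, "repeat_topology"))
  if (is.null(params) && is.null(d_rep)) stop("give `params` or `d_rep`.")
  if (is.null(params)) params <- helical_params(d_rep)
  if (!is.null(d_rep)) params$d_rep <- as.numeric(d_rep)
  d <- params$d_rep
  if (d < 5 || d > 20) stop("`d_rep` must lie in 5..20 Angstrom.")

  unit <- build_repeat_unit(topology, d, layer_sep)
  n_rep <- topology$n_repeats
  nr_unit <- nrow(unit)

  atoms <- dplyr::bind_rows(lapply(seq_len(n_rep), function(r) {
    u <- unit
    u$x <- u$x + (r - 1) * d
    u$repeat_index <- r
    u$res_id <- u$res_in_repeat + (r - 1) * topology$residues_per_repeat
    u
  }))
  atoms <- atoms[, c("res_id", "repeat_index", "res_in_repeat", "segment",
                     "atom", "x", "y", "z")]

  model <- structure(
    list(atoms = tibble::as_tibble(atoms), topology = topology, params = params),
    class = "backbone_model"
  )
  check_backbone_clashes(model)
  model
}

# One repeat unit at the origin. Helix 1 runs along +y in the z = 0 layer;
# helix 2 runs along -y in the z = -layer_sep layer, offset d/2 in x
# (staggered packing). Loops are straight-line placeholders.
#' @noRd
build_repeat_unit <- function(topology, d, layer_sep) {
  h1 <- topology$helix_lengths[1]
  h2 <- topology$helix_lengths[2]
  l1 <- topology$loop_lengths[1]
  l2 <- topology$loop_lengths[2]

  helix1 <- ideal_helix(h1, origin = c(0, 0, 0), dir = +1)
  y_top2 <- (h2 - 1) * 1.5
  helix2 <- ideal_helix(h2, origin = c(d / 2, y_top2, -layer_sep), dir = -1)

  a_end <- helix_ca(helix1, h1)
  b_start <- helix_ca(helix2, 1)
  loop1 <- loop_placeholder(l1, a_end, b_start, bow_dir = c(0, 1, 0))
  b_end <- helix_ca(helix2, h2)
  next_a_start <- c(d, 0, 0)
  loop2 <- loop_placeholder(l2, b_end, next_a_start, bow_dir = c(0, -1, 0))

  seg <- function(df, segment, offset) {
    df$segment <- segment
    df$res_in_repeat <- df$res_local + offset
    df$res_local <- NULL
    df
  }
  out <- rbind(
    seg(helix1, "H1", 0L),
    seg(loop1, "L1", h1),
    seg(helix2, "H2", h1 + l1),
    seg(loop2, "L2", h1 + l1 + h2)
  )
  out$repeat_index <- 1L
  out$res_id <- out$res_in_repeat
  out
}

# Ideal alpha-helix backbone along +/- y. Per-atom cylindrical placement
# (radius A, phase offset deg, axial offset A) is a coarse idealization;
# only CA geometry is load-bearing downstream.
.helix_atom_geom <- data.frame(
  atom = c("N", "CA", "C", "O"),
  radius = c(1.55, 2.27, 1.66, 1.95),
  dphase = c(-28.0, 0.0, 21.0, 23.0),
  dz = c(-0.90, 0.0, 1.05, 2.25),
  stringsAsFactors = FALSE
)

#' @noRd
ideal_helix <- function(n_res, origin, dir = +1, rise = 1.5, twist = 100) {
  g <- .helix_atom_geom
  idx <- rep(seq_len(n_res), each = 4L)
  atom <- rep(g$atom, times = n_res)
  radius <- rep(g$radius, times = n_res)
  dphase <- rep(g$dphase, times = n_res)
  dz <- rep(g$dz, times = n_res)
  ang <- deg2rad(dir * ((idx - 1) * twist + dphase))
  y <- origin[2] + dir * ((idx - 1) * rise + dz)
  data.frame(
    res_local = idx,
    atom = atom,
    x = origin[1] + radius * cos(ang),
    y = y,
    z = origin[3] + radius * sin(ang),
    stringsAsFactors = FALSE
  )
}

#' @noRd
helix_ca <- function(helix_df, res_local) {
  row <- helix_df[helix_df$res_local == res_local & helix_df$atom == "CA", ]
  c(row$x, row$y, row$z)
}

# Loop placeholder between two CA anchor points: straight-line interpolation
# bowed outwards past the helix ends so the connector clears the helix body;
# N/C/O ride alongside CA so every residue carries four backbone atoms.
#' @noRd
loop_placeholder <- function(n_res, from, to, bow_dir = c(0, 1, 0), bow = 2.5) {
  step <- (to - from) / (n_res + 1)
  u <- step / sqrt(sum(step^2))
  perp <- c(-u[3], 0, u[1])
  pn <- sqrt(sum(perp^2))
  perp <- if (pn > 1e-8) perp / pn else c(0, 0, 1)
  rows <- lapply(seq_len(n_res), function(i) {
    ca <- from + i * step + bow * sin(pi * i / (n_res + 1)) * bow_dir
    data.frame(
      res_local = i,
      atom = c("N", "CA", "C", "O"),
      x = c(ca[1] - 0.45 * u[1], ca[1], ca[1] + 0.45 * u[1], ca[1] + 0.45 * u[1] + 1.2 * perp[1]),
      y = c(ca[2] - 0.45 * u[2], ca[2], ca[2] + 0.45 * u[2], ca[2] + 0.45 * u[2] + 1.2 * perp[2]),
      z = c(ca[3] - 0.45 * u[3], ca[3], ca[3] + 0.45 * u[3], ca[3] + 0.45 * u[3] + 1.2 * perp[3]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Hard-sphere CA clash check; |res_id| difference of 1 (bonded neighbours)
# is exempt. Errors name the offending residue pair.
#' @noRd
check_backbone_clashes <- function(model, cutoff = 3.0) {
  ca <- model$atoms[model$atoms$atom == "CA", ]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n < 3) return(invisible(TRUE))
  dmat <- as.matrix(stats::dist(xyz))
  resid <- ca$res_id
  sep <- abs(outer(resid, resid, "-"))
  bad <- which(dmat < cutoff & sep > 1, arr.ind = TRUE)
  bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "invalid geometry: CA atoms of residues %d and %d are %.2f A apart (< %.1f A hard-sphere cutoff)",
      resid[i], resid[j], dmat[i, j], cutoff
    ))
  }
  invisible(TRUE)
}

#' @export
print.backbone_model <- function(x, ...) {
  sp <- tryCatch(
    sprintf(", spacing %.2f A", as.numeric(measure_repeat_spacing(x))),
    error = function(e) ""
  )
  cat(sprintf(
    "<backbone_model> %s: %d repeats, %d residues, %d atoms%s\n",
    x$topology$name, x$topology$n_repeats,
    x$topology$n_repeats * x$topology$residues_per_repeat, nrow(x$atoms), sp
  ))
  invisible(x)
}

#' @noRd
model_xyz <- function(model, atom = NULL) {
  a <- model$atoms
  if (!is.null(atom)) a <- a[a$atom %in% atom, ]
  as.matrix(a[, c("x", "y", "z")])
}

#' Measure the inter-repeat helix-axis spacing of a model
#'
#' For each helix slot in each repeat a least-squares axis is fitted through
#' the helix CA atoms; the spacing is the mean perpendicular distance between
#' the axes of corresponding helices in adjacent repeats.
#'
#' @param model A `backbone_model` with at least two repeats.
#' @return A numeric scalar (mean spacing, Angstrom) with attributes `sd`
#'   (standard deviation over axis pairs) and `pairs` (a tibble of
#'   per-pair distances).
#' @export
measure_repeat_spacing <- function(model) {
  stopifnot(inherits(model, "backbone_model"))
  n_rep <- max(model$atoms$repeat_index)
  if (n_rep < 2) stop("spacing is undefined for a single-repeat model.")
  ca <- model$atoms[model$atoms$atom == "CA" & model$atoms$segment %in% c("H1", "H2"), ]
  axes <- list()
  for (r in seq_len(n_rep)) {
    for (h in c("H1", "H2")) {
      sel <- ca[ca$repeat_index == r & ca$segment == h, ]
      axes[[paste(r, h)]] <- fit_axis(as.matrix(sel[, c("x", "y", "z")]))
    }
  }
  pairs <- expand.grid(r = seq_len(n_rep - 1), h = c("H1", "H2"),
                       stringsAsFactors = FALSE)
  pairs$distance <- vapply(seq_len(nrow(pairs)), function(i) {
    r <- pairs$r[i]; h <- pairs$h[i]
    line_distance(axes[[paste(r, h)]], axes[[paste(r + 1, h)]])
  }, numeric(1))
  out <- mean(pairs$distance)
  attr(out, "sd") <- stats::sd(pairs$distance)
  attr(out, "pairs") <- tibble::as_tibble(pairs)
  out
}

# Rigid transform relating adjacent repeats, averaged over all adjacent
# pairs; returns list(R, t, rotation_deg, translation).
#' @noRd
repeat_transform <- function(model) {
  n_rep <- max(model$atoms$repeat_index)
  if (n_rep < 2) stop("need >= 2 repeats to measure the repeat transform.")
  a <- model$atoms
  fits <- lapply(seq_len(n_rep - 1), function(r) {
    u1 <- as.matrix(a[a$repeat_index == r, c("x", "y", "z")])
    u2 <- as.matrix(a[a$repeat_index == r + 1, c("x", "y", "z")])
    kabsch(u2, u1) # transform mapping repeat r onto repeat r+1
  })
  R <- fits[[1]]$R
  t <- Reduce(`+`, lapply(fits, `[[`, "t")) / length(fits)
  list(R = R, t = t, rotation_deg = rotation_angle_deg(R),
       translation = sqrt(sum(t^2)))
}

#' Change the number of repeats of a model
#'
#' The internal repeat unit (the first repeat) is propagated by the measured
#' repeat transform to produce a model with `n_new` repeats. Surface arrays
#' extracted from the resized model scale proportionally.
#'
#' @param model A `backbone_model`.
#' @param n_new Target number of repeats (>= 1).
#' @return A `backbone_model` with `n_new` repeats.
#' @examples
#' topo <- repeat_topology("FD31", c(22, 22), c(3, 3), 6)
#' mod9 <- resize_repeats(build_repeat_model(topo, d_rep = 11.4), 9)
#' @export
resize_repeats <- function(model, n_new) {
  stopifnot(inherits(model, "backbone_model"))
  n_new <- as.integer(n_new)
  if (n_new < 1) stop("`n_new` must be >= 1.")
  n_old <- max(model$atoms$repeat_index)
  if (n_new == n_old) return(model)

  unit <- model$atoms[model$atoms$repeat_index == 1, ]
  rpr <- model$topology$residues_per_repeat
  if (n_old >= 2) {
    tr <- repeat_transform(model)
  } else {
    stop("cannot resize a single-repeat model: repeat transform is undefined.")
  }
  xyz <- as.matrix(unit[, c("x", "y", "z")])
  out <- vector("list", n_new)
  cur <- xyz
  for (r in seq_len(n_new)) {
    u <- unit
    u$x <- cur[, 1]; u$y <- cur[, 2]; u$z <- cur[, 3]
    u$repeat_index <- r
    u$res_id <- u$res_in_repeat + (r - 1L) * rpr
    out[[r]] <- u
    cur <- cur %*% t(tr$R) + matrix(tr$t, nrow(cur), 3, byrow = TRUE)
  }
  topo <- model$topology
  topo$n_repeats <- n_new
  structure(
    list(atoms = dplyr::bind_rows(out), topology = topo, params = model$params),
    class = "backbone_model"
  )
}

#' Least-squares rigid superposition RMSD of two models
#'
#' Superposes the CA atoms (by default) of `model_b` onto `model_a` with the
#' Kabsch algorithm (proper rotation, determinant +1) and returns the RMSD.
#'
#' @param model_a,model_b `backbone_model` objects with equal numbers of
#'   selected atoms, paired by sequence position.
#' @param atom Atom selection (default `"CA"`).
#' @return RMSD in Angstrom.
#' @export
superpose <- function(model_a, model_b, atom = "CA") {
  xa <- model_xyz(model_a, atom)
  xb <- model_xyz(model_b, atom)
  if (nrow(xa) != nrow(xb)) {
    stop(sprintf("atom selections differ in length (%d vs %d); supply a pairing map by trimming the models.",
                 nrow(xa), nrow(xb)))
  }
  kabsch(xa, xb)$rmsd
}

#' Bend a flat model to introduce curvature (synthetic test inputs)
#'
#' Rotates each repeat about a y-parallel axis so that successive repeats are
#' related by a rotation of `angle_per_repeat` degrees while the chord length
#' between corresponding atoms stays close to the original spacing. Used to
#' generate bent inputs for the flattening protocol.
#'
#' @param model A flat `backbone_model`.
#' @param angle_per_repeat Curvature, degrees per repeat.
#' @return A bent `backbone_model`.
#' @export
bend_model <- function(model, angle_per_repeat) {
  stopifnot(inherits(model, "backbone_model"))
  theta <- deg2rad(angle_per_repeat)
  if (abs(theta) < 1e-12) return(model)
  d <- model$params$d_rep
  rc <- d / (2 * sin(abs(theta) / 2))
  # bend about the model mid-plane so chord lengths stay ~d on average
  center <- c(0, 0, rc + mean(model$atoms$z))
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  for (r in seq_len(max(a$repeat_index))) {
    idx <- which(a$repeat_index == r)
    local <- xyz[idx, , drop = FALSE]
    local[, 1] <- local[, 1] - (r - 1) * d # recover the shared repeat unit
    R <- rotation_about_axis(c(0, 1, 0), (r - 1) * theta)
    rot <- sweep(local, 2, center) %*% t(R)
    xyz[idx, ] <- sweep(rot, 2, center, FUN = "+")
  }
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  model$atoms <- a
  model
}
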