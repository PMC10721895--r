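#' Supercell row-spacing mismatch between a template array and a net
#'
#' For each row family of the net, finds the supercell pair (m, n) with
#' 1 <= m, n <= `max_supercell` minimizing the mismatch strain
#' epsilon = |m * s_array - n * s_net| / (n * s_net), where s_array is the
#' template row spacing and s_net the net row spacing.
#'
#' @param array_spacing Template row spacing, nm.
#' @param net A `surface_net`.
#' @param max_supercell Maximum supercell multiplier (default 4).
#' @return A `match_result`: list with `rotation` (NA for the rotation-free
#'   row comparison), `m`, `n`, `mismatch_strain`, `matched_fraction` (NA
#'   here), `row` (the best row family p, q) and `rows` (per-family tibble).
#' @examples
#' net <- extract_net(build_slab(calcite_cell(), c(1, 0, 4), 2, 10))
#' row_mismatch(1.1, net)$mismatch_strain
#' @export
row_mismatch <- function(array_spacing, net, max_supercell = 4L) {
  stopifnot(array_spacing > 0, max_supercell >= 1)
  rows <- net_row_spacings(net)
  m <- seq_len(max_supercell)
  per_row <- lapply(seq_len(nrow(rows)), function(i) {
    s_net <- rows$spacing_nm[i]
    eps <- abs(outer(m * array_spacing, m * s_net, "-")) /
      outer(rep(1, max_supercell), m * s_net)
    best <- arrayInd(which.min(eps), dim(eps))
    m_best <- m[best[1]]; n_best <- m[best[2]]
    tibble::tibble(p = rows$p[i], q = rows$q[i], s_net = s_net,
                   m = m_best, n = n_best, strain = min(eps))
  })
  per_row <- dplyr::bind_rows(per_row)
  bi <- which.min(per_row$strain)
  structure(
    list(rotation = NA_real_, m = per_row$m[bi], n = per_row$n[bi],
         mismatch_strain = per_row$strain[bi], matched_fraction = NA_real_,
         row = c(p = per_row$p[bi], q = per_row$q[bi]), rows = per_row),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> strain %.4f at (m,n) = (%d,%d)%s%s\n",
    x$mismatch_strain, x$m, x$n,
    if (is.na(x$rotation)) "" else sprintf(", rotation %.1f deg", x$rotation),
    if (is.na(x$matched_fraction)) "" else sprintf(", matched %.2f", x$matched_fraction)
  ))
  invisible(x)
}

# distance from 2D points to the nearest net site (lattice + motif)
#' @noRd
net_nearest_distance <- function(pts, net) {
  P <- rbind(net$a1, net$a2) # rows are lattice vectors
  Pinv <- solve(P)
  best <- rep(Inf, nrow(pts))
  shifts <- expand.grid(s1 = -1:1, s2 = -1:1)
  for (k in seq_len(nrow(net$motif))) {
    rel <- cbind(pts[, 1] - net$motif$u[k], pts[, 2] - net$motif$v[k])
    fr <- rel %*% Pinv
    fr0 <- fr - round(fr)
    for (s in seq_len(nrow(shifts))) {
      fs <- cbind(fr0[, 1] + shifts$s1[s], fr0[, 2] + shifts$s2[s])
      cart <- fs %*% t(P)
      d <- sqrt(rowSums(cart^2))
      best <- pmin(best, d)
    }
  }
  best
}

# anchors of a surface array projected to 2D (nm), centered. The in-plane
# basis is built from the global axes projected onto the array plane (not
# from the array content), so the in-plane orientation of the template is
# preserved and square arrays pose no PCA degeneracy.
#' @noRd
array_points_2d <- function(array) {
  xyz <- as.matrix(array[, c("x", "y", "z")]) / 10
  ctr <- colMeans(xyz)
  x0 <- sweep(xyz, 2, ctr)
  sv <- svd(x0)
  nrm <- sv$v[, 3]
  key <- which.max(abs(nrm))
  if (nrm[key] < 0) nrm <- -nrm
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * nrm) * nrm
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- crossprod3(nrm, e1)
  cbind(x0 %*% e1, x0 %*% e2)
}

#' Scan in-plane rotations of a template array against a surface net
#'
#' For each rotation of the array (step `rotation_step`), the in-plane
#' translation is optimized on a coarse grid over the net cell (1/10 cell
#' steps) with a local refinement, and the matched fraction is the share of
#' anchors within `capture_radius` of the nearest net site. The best
#' rotation maximizes the matched fraction, tie-broken by the lower row
#' mismatch strain.
#'
#' @param array A `surface_array` (or an n x 2 matrix of 2D points, nm).
#' @param net A `surface_net`.
#' @param rotation_step Rotation step, degrees; must divide 360.
#' @param capture_radius Capture radius, nm (default 0.1).
#' @param max_supercell Passed to [row_mismatch()] for the strain tie-break.
#' @return A `match_result` with `rotation`, `matched_fraction`,
#'   `mismatch_strain` (best row strain), `translation` and the full
#'   per-rotation `scan` tibble.
#' @export
scan_orientations <- function(array, net, rotation_step = 10,
                              capture_radius = 0.1, max_supercell = 4L) {
  if (360 %% rotation_step != 0) stop("`rotation_step` must divide 360.")
  if (capture_radius <= 0) stop("`capture_radius` must be > 0.")
  area <- abs(net$a1[1] * net$a2[2] - net$a1[2] * net$a2[1])
  if (area < 1e-12) stop("degenerate net: lattice vectors are collinear.")
  pts <- if (inherits(array, "surface_array")) array_points_2d(array) else as.matrix(array)

  rots <- seq(0, 360 - rotation_step, by = rotation_step)
  P <- rbind(net$a1, net$a2)
  frac_grid <- expand.grid(f1 = seq(0, 0.9, by = 0.1), f2 = seq(0, 0.9, by = 0.1))
  trans_grid <- as.matrix(frac_grid) %*% P

  eval_rot <- function(theta_deg) {
    th <- deg2rad(theta_deg)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    rp <- pts %*% R
    scores <- vapply(seq_len(nrow(trans_grid)), function(i) {
      d <- net_nearest_distance(sweep(rp, 2, trans_grid[i, ], FUN = "+"), net)
      mean(d <= capture_radius)
    }, numeric(1))
    i0 <- which.max(scores)
    # local refinement around the best coarse translation
    refine <- expand.grid(df1 = seq(-0.05, 0.05, by = 0.025),
                          df2 = seq(-0.05, 0.05, by = 0.025))
    ref_trans <- sweep(as.matrix(refine) %*% P, 2, trans_grid[i0, ], FUN = "+")
    ref_scores <- vapply(seq_len(nrow(ref_trans)), function(i) {
      d <- net_nearest_distance(sweep(rp, 2, ref_trans[i, ], FUN = "+"), net)
      mean(d <= capture_radius)
    }, numeric(1))
    j <- which.max(ref_scores)
    c(matched = ref_scores[j], tx = ref_trans[j, 1], ty = ref_trans[j, 2])
  }

  scan <- t(vapply(rots, eval_rot, numeric(3)))
  spacing <- attr(array, "row_spacing_nm")
  strain <- if (!is.null(spacing) && is.finite(spacing)) {
    row_mismatch(spacing, net, max_supercell)$mismatch_strain
  } else NA_real_
  best <- which(scan[, "matched"] == max(scan[, "matched"]))[1]
  structure(
    list(rotation = rots[best], m = NA_integer_, n = NA_integer_,
         mismatch_strain = strain,
         matched_fraction = unname(scan[best, "matched"]),
         translation = unname(scan[best, c("tx", "ty")]),
         scan = tibble::tibble(rotation = rots,
                               matched_fraction = scan[, "matched"])),
    class = "match_result"
  )
}

#' Rank candidate mineral surfaces by epitaxial match to a template
#'
#' @param array A `surface_array`.
#' @param nets A list of `surface_net` objects.
#' @param ... Passed to [scan_orientations()].
#' @return A tibble sorted by decreasing matched fraction (ties broken by
#'   increasing mismatch strain, then stable input order), with columns
#'   `net_name`, `matched_fraction`, `mismatch_strain`, `rotation` and a
#'   list-column `result`.
#' @export
rank_surfaces <- function(array, nets, ...) {
  if (length(nets) < 1) stop("supply at least one net.")
  res <- lapply(nets, function(n) scan_orientations(array, n, ...))
  tbl <- tibble::tibble(
    net_name = vapply(nets, function(n) n$name %||% "net", character(1)),
    matched_fraction = vapply(res, `[[`, numeric(1), "matched_fraction"),
    mismatch_strain = vapply(res, `[[`, numeric(1), "mismatch_strain"),
    rotation = vapply(res, `[[`, numeric(1), "rotation"),
    input_order = seq_along(nets),
    result = res
  )
  strain_key <- ifelse(is.na(tbl$mismatch_strain), Inf, tbl$mismatch_strain)
  tbl[order(-tbl$matched_fraction, strain_key, tbl$input_order), ]
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
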