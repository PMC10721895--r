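#' Crystallographic unit cell for a CaCO3 polymorph
#'
#' @param a,b,c Cell lengths, Angstrom.
#' @param alpha,beta,gamma Cell angles, degrees.
#' @param sites Data frame with columns `species` (one of `"Ca"`,
#'   `"C_carbonate"`, `"O_carbonate"`), `fx`, `fy`, `fz` (fractional
#'   coordinates) and `charge` (point charge used for docking: Ca +2,
#'   carbonate C 0, carbonate O -2/3, so carbonate carries -2 in total and
#'   the cell is neutral).
#' @param name Cell label.
#' @param source Free-text provenance annotation for the constants.
#' @param centering Lattice centering: `"P"` (primitive) or `"R"`
#'   (rhombohedral centering of a triple hexagonal cell, as for calcite).
#'   Centering translations are honoured when surface lattices are built.
#' @return A `unit_cell` object (list with the cell matrix in `$M`, columns
#'   are the a, b, c vectors).
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90, sites,
                      name = "cell", source = "", centering = c("P", "R")) {
  centering <- match.arg(centering)
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("species", "fx", "fy", "fz", "charge") %in% names(sites)))
  n_ca <- sum(sites$species == "Ca")
  n_c <- sum(sites$species == "C_carbonate")
  if (n_ca != n_c) stop("stoichiometry must be Ca:CO3 = 1:1.")
  if (abs(sum(sites$charge)) > 1e-8) stop("unit cell must be charge neutral.")
  al <- deg2rad(alpha); be <- deg2rad(beta); ga <- deg2rad(gamma)
  cz <- sqrt(1 - cos(be)^2 - ((cos(al) - cos(be) * cos(ga)) / sin(ga))^2)
  M <- cbind(
    c(a, 0, 0),
    c(b * cos(ga), b * sin(ga), 0),
    c(c * cos(be), c * (cos(al) - cos(be) * cos(ga)) / sin(ga), c * cz)
  )
  if (det(M) <= 0) stop("cell volume must be positive.")
  # fractional generators of the translation lattice (columns); for R
  # centering the conventional cell is a triple cell of the primitive
  # rhombohedral lattice
  Pf <- if (centering == "R") {
    cbind(c(1, 0, 0), c(0, 1, 0), c(2 / 3, 1 / 3, 1 / 3))
  } else diag(3)
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         M = M, sites = sites, name = name, source = source,
         centering = centering, Pf = Pf),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> %s: a=%.3f b=%.3f c=%.3f A, angles %g/%g/%g, %d sites\n",
              x$name, x$a, x$b, x$c, x$alpha, x$beta, x$gamma, nrow(x$sites)))
  invisible(x)
}

#' Calcite unit cell (hexagonal setting)
#'
#' Standard 25 C calcite cell, space group R-3c in the hexagonal setting
#' (a = 4.988 A, c = 17.061 A), with the 6 Ca + 6 CO3 of the hexagonal cell
#' placed explicitly. These are standard external constants, not values from
#' any single templating experiment.
#'
#' @return A [unit_cell()].
#' @export
calcite_cell <- function() {
  cent <- rbind(c(0, 0, 0), c(2 / 3, 1 / 3, 1 / 3), c(1 / 3, 2 / 3, 2 / 3))
  ca_base <- rbind(c(0, 0, 0), c(0, 0, 0.5))
  c_base <- rbind(c(0, 0, 0.25), c(0, 0, 0.75))
  x <- 0.2567
  o_base <- rbind(
    c(x, 0, 0.25), c(0, x, 0.25), c(-x, -x, 0.25),
    c(-x, 0, 0.75), c(0, -x, 0.75), c(x, x, 0.75)
  )
  expand <- function(base) {
    out <- do.call(rbind, lapply(seq_len(nrow(cent)), function(i) {
      sweep(base, 2, cent[i, ], FUN = "+")
    }))
    out %% 1
  }
  ca <- expand(ca_base); cc <- expand(c_base); oo <- expand(o_base)
  sites <- tibble::tibble(
    species = c(rep("Ca", nrow(ca)), rep("C_carbonate", nrow(cc)),
                rep("O_carbonate", nrow(oo))),
    fx = c(ca[, 1], cc[, 1], oo[, 1]),
    fy = c(ca[, 2], cc[, 2], oo[, 2]),
    fz = c(ca[, 3], cc[, 3], oo[, 3]),
    charge = c(rep(2, nrow(ca)), rep(0, nrow(cc)), rep(-2 / 3, nrow(oo)))
  )
  unit_cell(4.988, 4.988, 17.061, 90, 90, 120, sites, name = "calcite",
            source = "standard 25 C calcite cell, R-3c hexagonal setting",
            centering = "R")
}

#' Synthetic orthorhombic vaterite approximant
#'
#' Vaterite's structure is polymorphically ambiguous in the literature; this
#' bundled cell is a SYNTHETIC orthorhombic approximant (two formula units,
#' planar carbonates in the ab plane) intended only to expose a {010}-type
#' ion net for matching. Substitute a literature cell via [unit_cell()] for
#' structure-sensitive work.
#'
#' @return A [unit_cell()].
#' @export
vaterite_cell_synthetic <- function() {
  a <- 4.13; b <- 7.15; c <- 8.48
  carb <- function(fc, phase_deg) {
    ccart <- c(a * fc[1], b * fc[2], c * fc[3])
    ang <- deg2rad(phase_deg + c(0, 120, 240))
    o <- t(vapply(ang, function(t_) ccart + 1.28 * c(cos(t_), sin(t_), 0),
                  numeric(3)))
    cbind(o[, 1] / a, o[, 2] / b, o[, 3] / c)
  }
  c1 <- c(0.5, 0, 0.25); c2 <- c(0, 0.5, 0.75)
  o1 <- carb(c1, 0); o2 <- carb(c2, 60)
  sites <- tibble::tibble(
    species = c("Ca", "Ca", "C_carbonate", "C_carbonate",
                rep("O_carbonate", 6)),
    fx = c(0, 0.5, c1[1], c2[1], o1[, 1], o2[, 1]) %% 1,
    fy = c(0, 0.5, c1[2], c2[2], o1[, 2], o2[, 2]) %% 1,
    fz = c(0, 0.5, c1[3], c2[3], o1[, 3], o2[, 3]) %% 1,
    charge = c(2, 2, 0, 0, rep(-2 / 3, 6))
  )
  unit_cell(a, b, c, sites = sites, name = "vaterite-synthetic",
            source = "synthetic orthorhombic approximant; vaterite structure is ambiguous")
}

#' Miller index, gcd-reduced on construction
#'
#' @param h,k,l Integers, not all zero.
#' @return A `miller_index` (integer vector of length 3).
#' @export
miller_index <- function(h, k, l) {
  hkl <- as.integer(c(h, k, l))
  if (all(hkl == 0L)) stop("Miller index (0,0,0) is invalid.")
  g <- Reduce(function(x, y) if (y == 0) x else Recall(y, x %% y), abs(hkl[hkl != 0]))
  structure(hkl %/% g, class = "miller_index")
}

#' Interplanar d-spacing via the reciprocal-lattice metric
#'
#' @param cell A [unit_cell()].
#' @param hkl A [miller_index()] or integer vector of length 3.
#' @return Spacing in Angstrom.
#' @examples
#' d_spacing(calcite_cell(), miller_index(1, 0, 4))
#' @export
d_spacing <- function(cell, hkl) {
  stopifnot(inherits(cell, "unit_cell"))
  hkl <- as.integer(hkl)
  if (all(hkl == 0L)) stop("Miller index (0,0,0) is invalid.")
  G <- crossprod(cell$M)
  1 / sqrt(as.numeric(t(hkl) %*% solve(G, hkl)))
}

# Shortest basis of the 2D sublattice { v integer : hkl . v = 0 }, plus a
# stacking vector S with hkl . S = 1 (so [A1, A2, S] is unimodular).
#' @noRd
plane_lattice_basis <- function(hkl, M, nmax = 5L) {
  rng <- -nmax:nmax
  cand <- as.matrix(expand.grid(rng, rng, rng))
  dots <- cand %*% hkl
  inplane <- cand[dots == 0 & rowSums(abs(cand)) > 0, , drop = FALSE]
  if (nrow(inplane) < 2) stop("no lattice points found in the plane; increase search range.")
  cart <- inplane %*% t(M)
  len <- sqrt(rowSums(cart^2))
  ord <- order(len)
  v1 <- inplane[ord[1], ]
  v1c <- cart[ord[1], ]
  v2 <- NULL
  for (i in ord[-1]) {
    cr <- crossprod3(v1c, cart[i, ])
    if (sqrt(sum(cr^2)) > 1e-8) { v2 <- inplane[i, ]; break }
  }
  if (is.null(v2)) stop("degenerate plane lattice.")
  stack <- cand[dots == 1, , drop = FALSE]
  if (nrow(stack) == 0) stop("no stacking vector with hkl.S = 1; is hkl gcd-reduced?")
  slen <- sqrt(rowSums((stack %*% t(M))^2))
  S <- stack[which.min(slen), ]
  list(A1 = v1, A2 = v2, S = S)
}

#' @noRd
crossprod3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# Lagrange-Gauss reduction of a 2D basis given as rows of a 2x2 matrix.
#' @noRd
gauss_reduce_2d <- function(B) {
  a1 <- B[1, ]; a2 <- B[2, ]
  repeat {
    if (sum(a2^2) < sum(a1^2)) { tmp <- a1; a1 <- a2; a2 <- tmp }
    mu <- round(sum(a1 * a2) / sum(a1^2))
    if (mu == 0) break
    a2 <- a2 - mu * a1
  }
  rbind(a1, a2)
}

#' Build a Miller-indexed surface slab
#'
#' Cuts a slab from the crystal with outward normal along +z and the
#' topmost layer at z = 0 (solution side z > 0). The termination is chosen
#' as the densest single layer of the stacking period, tie-broken towards a
#' Ca-containing layer; if the depth cut leaves a net charge beyond one
#' formula unit (|q| > 2), bottom layers are trimmed until balanced.
#'
#' @param cell A [unit_cell()].
#' @param hkl A [miller_index()] or integer triple.
#' @param lateral_extent Minimum lateral size, nm.
#' @param depth Slab thickness, Angstrom.
#' @return A `surface_slab`: tibble of ions (`species`, `charge`, `x`, `y`,
#'   `z`, Angstrom) with attributes `plane`, `in_plane` (2x2 matrix, rows
#'   are the in-plane cell vectors in Angstrom), `d_spacing`, `n_cells`,
#'   `cell_name`.
#' @examples
#' slab <- build_slab(calcite_cell(), miller_index(1, 0, 4),
#'                    lateral_extent = 3, depth = 10)
#' @export
build_slab <- function(cell, hkl, lateral_extent = 10, depth = 15) {
  stopifnot(inherits(cell, "unit_cell"))
  if (lateral_extent <= 0 || depth <= 0) stop("extent and depth must be positive.")
  hkl <- as.integer(hkl)
  hkl <- as.integer(miller_index(hkl[1], hkl[2], hkl[3]))

  # work in the primitive translation lattice (honours R centering):
  # Mp columns are the primitive lattice vectors in Cartesian Angstrom,
  # hp is the plane normal expressed in primitive (integer) indices
  Mp <- cell$M %*% cell$Pf
  hp_raw <- as.numeric(t(cell$Pf) %*% hkl)
  den <- which(vapply(1:6, function(q) all(abs(hp_raw * q - round(hp_raw * q)) < 1e-9),
                      logical(1)))[1]
  hp <- as.integer(round(hp_raw * den))
  hp <- as.integer(miller_index(hp[1], hp[2], hp[3]))

  # sites expressed in primitive fractional coordinates, deduplicated
  # (a centred conventional cell lists each primitive-cell site multiple times)
  frac_hex <- as.matrix(cell$sites[, c("fx", "fy", "fz")])
  sp <- t(solve(cell$Pf) %*% t(frac_hex))
  sp <- sp - floor(sp + 1e-9)
  dup <- duplicated(round(sp, 6))
  sp <- sp[!dup, , drop = FALSE]
  site_species <- cell$sites$species[!dup]
  site_charge <- cell$sites$charge[!dup]

  basis <- plane_lattice_basis(hp, Mp)
  Gp <- crossprod(Mp)
  d_hkl <- 1 / sqrt(as.numeric(t(hp) %*% solve(Gp, hp)))

  A1c <- as.numeric(basis$A1 %*% t(Mp))
  A2c <- as.numeric(basis$A2 %*% t(Mp))
  nrm <- crossprod3(A1c, A2c)
  nrm <- nrm / sqrt(sum(nrm^2))
  # orient the frame so increasing hp.x maps to increasing z
  Sc <- as.numeric(basis$S %*% t(Mp))
  if (sum(Sc * nrm) < 0) nrm <- -nrm
  ex <- A1c / sqrt(sum(A1c^2))
  ey <- crossprod3(nrm, ex)

  frac <- sp
  t_site <- as.numeric(frac %*% hp)

  # termination: densest layer of the stacking period, tie-break towards Ca
  t_mod <- round((t_site %% 1), 6)
  groups <- split(seq_along(t_mod), t_mod)
  dens <- vapply(groups, length, integer(1))
  has_ca <- vapply(groups, function(i) any(site_species[i] == "Ca"), logical(1))
  best <- which(dens == max(dens))
  if (length(best) > 1 && any(has_ca[best])) best <- best[has_ca[best]]
  delta <- as.numeric(names(groups)[best[1]])

  ext_A <- lateral_extent * 10
  n1 <- max(1L, ceiling(ext_A / sqrt(sum(A1c^2))))
  n2 <- max(1L, ceiling(ext_A / sqrt(sum(A2c^2))))
  depth_t <- depth / d_hkl
  n3_range <- seq(floor(delta - depth_t - max(t_site)) - 1L,
                  ceiling(delta - min(t_site)) + 1L)

  blocks <- expand.grid(i1 = 0:(n1 - 1), i2 = 0:(n2 - 1), i3 = n3_range)
  rows <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    shift <- blocks$i1[b] * basis$A1 + blocks$i2[b] * basis$A2 +
      blocks$i3[b] * basis$S
    t_tot <- t_site + blocks$i3[b]
    keep <- t_tot <= delta + 1e-9 & t_tot > delta - depth_t - 1e-9
    if (!any(keep)) next
    fr <- sweep(frac[keep, , drop = FALSE], 2, shift, FUN = "+")
    cart <- fr %*% t(Mp)
    rows[[b]] <- tibble::tibble(
      species = site_species[keep],
      charge = site_charge[keep],
      x = as.numeric(cart %*% ex),
      y = as.numeric(cart %*% ey),
      z = (t_tot[keep] - delta) * d_hkl
    )
  }
  ions <- dplyr::bind_rows(rows)
  if (nrow(ions) == 0) stop("plane has no lattice points within the requested extent.")

  # charge balance within one formula unit: trim bottom layers if needed
  net <- sum(ions$charge)
  if (abs(net) > 2 + 1e-6) {
    zl <- sort(unique(round(ions$z, 4)))
    for (cut_below in zl) {
      cand <- ions[round(ions$z, 4) > cut_below - 1e-9, ]
      if (abs(sum(cand$charge)) <= 2 + 1e-6) { ions <- cand; break }
    }
  }

  inplane2d <- rbind(
    c(sum(A1c * ex), sum(A1c * ey)),
    c(sum(A2c * ex), sum(A2c * ey))
  )
  structure(
    ions,
    plane = hkl,
    in_plane = inplane2d,
    d_spacing = d_hkl,
    n_cells = c(n1, n2),
    cell_name = cell$name,
    class = c("surface_slab", class(tibble::tibble()))
  )
}

#' Extract the 2D surface ion net from a slab
#'
#' The motif is the set of ions within `layer_tolerance` of the surface
#' (z >= -layer_tolerance); the net lattice vectors are the Lagrange-Gauss
#' reduced (shortest) basis of the slab's in-plane cell. Re-extracting a net
#' returns it unchanged.
#'
#' @param slab A `surface_slab` (or a `surface_net`, returned as-is).
#' @param layer_tolerance Depth of the surface layer, Angstrom.
#' @return A `surface_net`: list with `a1`, `a2` (2D lattice vectors, nm),
#'   `motif` (tibble `species`, `u`, `v` in nm, `charge`) and `name`.
#' @export
extract_net <- function(slab, layer_tolerance = 0.5) {
  if (inherits(slab, "surface_net")) return(slab)
  stopifnot(inherits(slab, "surface_slab"))
  top <- slab[slab$z >= -layer_tolerance, ]
  if (nrow(top) == 0) {
    stop(sprintf("no ions within %.2f A of the surface; increase `layer_tolerance`.",
                 layer_tolerance))
  }
  B <- gauss_reduce_2d(attr(slab, "in_plane")) / 10 # nm
  # reduce motif to one 2D cell (positions modulo the net lattice)
  P <- t(B) # columns are a1, a2
  uv <- cbind(top$x, top$y) / 10
  fr <- uv %*% t(solve(P))
  fr <- fr - floor(fr)
  inside <- fr %*% P
  motif <- tibble::tibble(species = top$species, u = inside[, 1],
                          v = inside[, 2], charge = top$charge)
  motif <- motif[!duplicated(round(cbind(motif$u, motif$v), 4)), ]
  structure(
    list(a1 = B[1, ], a2 = B[2, ], motif = motif,
         name = paste0(attr(slab, "cell_name"), "(",
                       paste(attr(slab, "plane"), collapse = ""), ")")),
    class = "surface_net"
  )
}

#' @export
print.surface_net <- function(x, ...) {
  cat(sprintf("<surface_net> %s: a1=(%.3f, %.3f) a2=(%.3f, %.3f) nm, %d motif ions\n",
              x$name, x$a1[1], x$a1[2], x$a2[1], x$a2[2], nrow(x$motif)))
  invisible(x)
}

#' Inter-row spacings of a 2D net
#'
#' Spacing between lattice rows along direction (p, q) (coprime integers):
#' the cell area divided by the length of p*a1 + q*a2.
#'
#' @param net A `surface_net`.
#' @param max_index Maximum |p|, |q| enumerated.
#' @return A tibble (`p`, `q`, `spacing_nm`) sorted by decreasing spacing.
#' @export
net_row_spacings <- function(net, max_index = 3L) {
  stopifnot(inherits(net, "surface_net"))
  area <- abs(net$a1[1] * net$a2[2] - net$a1[2] * net$a2[1])
  combs <- expand.grid(p = -max_index:max_index, q = 0:max_index)
  combs <- combs[!(combs$p == 0 & combs$q == 0), ]
  combs <- combs[!(combs$q == 0 & combs$p < 0), ]
  keep <- mapply(function(p, q) {
    g <- if (q == 0) abs(p) else if (p == 0) q else {
      x <- abs(p); y <- q
      while (y != 0) { t_ <- y; y <- x %% y; x <- t_ }
      x
    }
    g == 1
  }, combs$p, combs$q)
  combs <- combs[keep, ]
  v <- cbind(combs$p, combs$q) %*% rbind(net$a1, net$a2)
  out <- tibble::tibble(p = combs$p, q = combs$q,
                        spacing_nm = area / sqrt(rowSums(v^2)))
  out[order(-out$spacing_nm), ]
}
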