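# Small shared builders for the test suite. All fixtures are generated in
# code; the "toy" topology uses the shortest helices in the sampled range so
# flattening and docking tests stay fast.

toy_topology <- function(n_repeats = 4L) {
  repeat_topology("toy", c(16L, 16L), c(2L, 2L), n_repeats)
}

toy_model <- function(d_rep = 10, n_repeats = 4L) {
  build_repeat_model(toy_topology(n_repeats), d_rep = d_rep)
}

# a primitive rectangular net with a single site motif
simple_net <- function(s1, s2 = s1, name = "net") {
  structure(
    list(a1 = c(s1, 0), a2 = c(0, s2),
         motif = tibble::tibble(species = "Ca", u = 0, v = 0, charge = 2),
         name = name),
    class = "surface_net"
  )
}

# rectangular grid surface array (spacings in nm, coordinates stored in A)
grid_array <- function(n_rows, n_cols, s_row, s_col, z = 0) {
  g <- expand.grid(r = seq_len(n_rows), s = seq_len(n_cols))
  surface_array(tibble::tibble(
    repeat_index = g$r, slot = g$s,
    x = (g$r - 1) * s_row * 10, y = (g$s - 1) * s_col * 10, z = z,
    residue = "GLU"
  ), name = "grid")
}

# small calcite (104) slab reused across docking tests
small_slab <- function(extent = 3, depth = 6) {
  build_slab(calcite_cell(), miller_index(1, 0, 4),
             lateral_extent = extent, depth = depth)
}

# simple cubic one-site cell for conservation checks
cubic_ca_cell <- function(a = 5) {
  unit_cell(a, a, a, sites = tibble::tibble(
    species = c("Ca", "C_carbonate"),
    fx = c(0, 0.5), fy = c(0, 0.5), fz = c(0, 0.5),
    charge = c(2, -2)
  ), name = "cubic-toy")
}

# brute-force O(N^2) interaction energy oracle (same cutoff/clamp rules)
energy_oracle <- function(pts_a, q_a, pts_b, q_b, em) {
  total <- 0
  for (i in seq_len(nrow(pts_a))) {
    for (j in seq_len(nrow(pts_b))) {
      r <- sqrt(sum((pts_a[i, ] - pts_b[j, ])^2))
      if (r <= em$cutoff) {
        r <- max(r, em$hard_core)
        total <- total + calcitile:::pair_energy(r, q_a[i] * q_b[j], em)
      }
    }
  }
  total
}
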