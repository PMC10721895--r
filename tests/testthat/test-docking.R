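test_that("pair interactions vanish beyond the cutoff and attract at contact", {
  fx <- load_fixture("FD31-Rep3")
  slab <- small_slab()
  em <- energy_model()
  # 10 nm separation with a 15 A cutoff: exactly zero
  expect_equal(as.numeric(score_pose(fx$array, slab, pose(z = 100), em)), 0)
  # single Ca2+ directly above one carboxylate anchor near the LJ minimum:
  # negative energy (sign check on a minimal system)
  em1 <- em
  a1 <- matrix(c(0, 0, 0), 1, 3)
  b1 <- matrix(c(0, 0, em$lj_sigma * 2^(1 / 6)), 1, 3)
  e <- calcitile:::interaction_energy(a1, -1, b1, 2, em1)
  expect_lt(as.numeric(e), 0)
})

test_that("cell-list energies equal the O(N^2) oracle", {
  em <- energy_model()
  set.seed(8)
  for (trial in 1:3) {
    na_ <- sample(10:25, 1); nb <- sample(100:400, 1)
    A <- matrix(runif(na_ * 3, 0, 30), ncol = 3)
    B <- matrix(runif(nb * 3, 0, 30), ncol = 3)
    qa <- runif(na_, -1, 0)
    qb <- sample(c(2, -2 / 3), nb, replace = TRUE)
    expect_equal(as.numeric(calcitile:::interaction_energy(A, qa, B, qb, em)),
                 energy_oracle(A, qa, B, qb, em), tolerance = 1e-9)
  }
})

test_that("overlapping pairs clamp and flag rather than error", {
  em <- energy_model()
  a1 <- matrix(0, 1, 3)
  b1 <- matrix(c(0, 0, 0.5), 1, 3)
  e <- calcitile:::interaction_energy(a1, -1, b1, 2, em)
  expect_true(attr(e, "clamped"))
  expect_true(is.finite(as.numeric(e)))
})

test_that("binding score is the median-subtracted complex energy", {
  expect_equal(binding_score(-5, c(0, 0, 0)), -5)
  expect_equal(binding_score(2.5, c(2.5, 2.5, 2.5)), 0)
  expect_equal(binding_score(0, c(1, 2, 100)), -2) # median robust to outlier
  expect_error(binding_score(1, numeric(0)), "non-empty")
})

test_that("a never-approaching trajectory has zero binding score", {
  fx <- load_fixture("FD31-Rep3")
  slab <- small_slab()
  far <- pose(z = max(slab$z) + 100)
  dk <- mc_dock(fx$array, slab, steps = 30, seed = 2, start_pose = far)
  expect_equal(dk$e_binding, 0, tolerance = 1e-12)
  expect_true(all(dk$baseline == 0))
  expect_gte(length(dk$baseline), 11)
  expect_equal(length(dk$baseline) %% 2, 1)
})

test_that("docking is deterministic under a fixed seed", {
  fx <- load_fixture("FD31-Rep3")
  slab <- small_slab()
  d1 <- mc_dock(fx$array, slab, steps = 40, seed = 7)
  d2 <- mc_dock(fx$array, slab, steps = 40, seed = 7)
  expect_identical(d1$e_complex, d2$e_complex)
  expect_identical(d1$best_pose, d2$best_pose)
  expect_identical(d1$baseline, d2$baseline)
})

test_that("Monte-Carlo docking improves on the random starting pose", {
  fx <- load_fixture("FD31-Rep3")
  slab <- small_slab()
  for (s in 1:6) {
    dk <- mc_dock(fx$array, slab, steps = 50, seed = s)
    expect_lte(dk$e_complex, dk$e_start)
  }
})

test_that("pose energy is near-periodic under full lattice translations", {
  fx <- load_fixture("FD31-Rep3")
  slab <- build_slab(calcite_cell(), c(1, 0, 4), lateral_extent = 8, depth = 6)
  em <- energy_model()
  ip <- attr(slab, "in_plane")
  pts <- calcitile:::dock_points(fx$array)
  z0 <- max(slab$z) + max(-pts[, 3]) + 4
  ctr <- c(mean(range(slab$x)), mean(range(slab$y)))
  p1 <- pose(x = ctr[1] - ip[1, 1] / 2, y = ctr[2] - ip[1, 2] / 2, z = z0)
  p2 <- pose(x = ctr[1] + ip[1, 1] / 2, y = ctr[2] + ip[1, 2] / 2, z = z0)
  e1 <- as.numeric(score_pose(fx$array, slab, p1, em))
  e2 <- as.numeric(score_pose(fx$array, slab, p2, em))
  expect_equal(e1, e2, tolerance = 0.01 * max(1e-9, abs(e1)))
})

test_that("sidechain states are repeat-symmetric and identity for library size 1", {
  fx <- load_fixture("FD31-Rep3")
  slab <- small_slab()
  p <- pose(z = max(slab$z) + 6)
  ss1 <- sample_sidechain_states(fx$array, slab, p, library_size = 1, seed = 1)
  expect_true(all(ss1$states == 1L))
  expect_equal(ss1$array$x, fx$array$x)
  ss3 <- sample_sidechain_states(fx$array, slab, p, library_size = 3, seed = 1)
  # every repeat carries the same offset at equivalent slot positions
  lib <- calcitile:::offset_library(3)
  for (s in unique(fx$array$slot)) {
    idx <- which(fx$array$slot == s)
    off <- cbind(ss3$array$x[idx] - fx$array$x[idx],
                 ss3$array$y[idx] - fx$array$y[idx],
                 ss3$array$z[idx] - fx$array$z[idx])
    expect_lt(max(abs(sweep(off, 2, lib[ss3$states[as.character(s)], ]))), 1e-12)
  }
})

test_that("greedy state selection matches exhaustive enumeration on separated slots", {
  # a toy array whose slots are far apart (> cutoff) interacts with
  # independent ion clusters, so per-slot greedy selection is exact
  em <- energy_model(cutoff = 10)
  n_slots <- 3
  arr <- surface_array(tibble::tibble(
    repeat_index = rep(1:2, each = n_slots),
    slot = rep(1:n_slots, 2),
    x = rep(c(0, 200), each = n_slots),
    y = rep(seq(0, by = 60, length.out = n_slots), 2),
    z = 3, residue = "GLU"))
  ions <- tibble::tibble(
    species = "Ca", charge = 2,
    x = rep(c(0, 200), each = n_slots) + 0.3,
    y = rep(seq(0, by = 60, length.out = n_slots), 2) + 0.2,
    z = 0)
  slab <- structure(ions, plane = c(0L, 0L, 1L),
                    in_plane = diag(2) * 400, d_spacing = 1,
                    n_cells = c(1L, 1L), cell_name = "toy",
                    class = c("surface_slab", class(tibble::tibble())))
  p <- pose(x = 0, y = 0, z = 0, rot = 0)
  # exhaustive enumeration over all state assignments
  lib <- calcitile:::offset_library(3)
  combos <- expand.grid(s1 = 1:3, s2 = 1:3, s3 = 1:3)
  pts0 <- calcitile:::dock_points(arr)
  exh_best <- Inf
  for (i in seq_len(nrow(combos))) {
    trial <- arr
    for (s in 1:n_slots) {
      idx <- which(trial$slot == s)
      k <- as.integer(combos[i, s])
      trial$x[idx] <- arr$x[idx] + lib[k, 1]
      trial$y[idx] <- arr$y[idx] + lib[k, 2]
      trial$z[idx] <- arr$z[idx] + lib[k, 3]
    }
    e <- as.numeric(calcitile:::interaction_energy(
      as.matrix(trial[, c("x", "y", "z")]), trial$charge,
      as.matrix(slab[, c("x", "y", "z")]), slab$charge, em))
    if (e < exh_best) exh_best <- e
  }
  # greedy on the same raw coordinates (bypassing the pose transform)
  greedy_best <- Inf
  states <- rep(1L, n_slots)
  cur <- arr
  for (s in 1:n_slots) {
    energies <- vapply(1:3, function(k) {
      trial <- cur
      idx <- which(trial$slot == s)
      trial$x[idx] <- arr$x[idx] + lib[k, 1]
      trial$y[idx] <- arr$y[idx] + lib[k, 2]
      trial$z[idx] <- arr$z[idx] + lib[k, 3]
      as.numeric(calcitile:::interaction_energy(
        as.matrix(trial[, c("x", "y", "z")]), trial$charge,
        as.matrix(slab[, c("x", "y", "z")]), slab$charge, em))
    }, numeric(1))
    k <- which.min(energies)
    idx <- which(cur$slot == s)
    cur$x[idx] <- arr$x[idx] + lib[k, 1]
    cur$y[idx] <- arr$y[idx] + lib[k, 2]
    cur$z[idx] <- arr$z[idx] + lib[k, 3]
    greedy_best <- energies[k]
  }
  expect_equal(greedy_best, exh_best, tolerance = 1e-9)
})
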