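test_that("row mismatch is exact for commensurate spacings and scale-invariant", {
  net <- simple_net(1.10)
  rm0 <- row_mismatch(1.10, net, 4)
  expect_equal(rm0$mismatch_strain, 0, tolerance = 1e-12)
  expect_equal(c(rm0$m, rm0$n), c(1L, 1L))
  # doubling the array spacing is absorbed by the supercell search
  rm1 <- row_mismatch(1.07, net, 8)
  rm2 <- row_mismatch(2.14, net, 8)
  expect_equal(rm2$mismatch_strain, rm1$mismatch_strain, tolerance = 1e-12)
})

test_that("supercell mismatch equals brute-force enumeration on random cases", {
  set.seed(21)
  oracle <- function(s_a, s_n, maxsc) {
    best <- Inf
    for (m in 1:maxsc) for (n in 1:maxsc) {
      e <- abs(m * s_a - n * s_n) / (n * s_n)
      if (e < best) best <- e
    }
    best
  }
  for (i in 1:100) {
    s_a <- runif(1, 0.5, 2)
    s_n <- runif(1, 0.3, 1.5)
    maxsc <- sample(2:6, 1)
    net <- simple_net(s_n)
    got <- row_mismatch(s_a, net, maxsc)
    rows <- got$rows
    # compare per primitive row family against the oracle
    for (j in seq_len(nrow(rows))) {
      expect_equal(rows$strain[j], oracle(s_a, rows$s_net[j], maxsc),
                   tolerance = 1e-12)
    }
  }
})

test_that("a congruent array reaches full matched fraction at some rotation", {
  net <- simple_net(1.1)
  arr <- grid_array(4, 4, 1.1, 1.1)
  sc <- scan_orientations(arr, net, rotation_step = 30, capture_radius = 0.1)
  expect_equal(sc$matched_fraction, 1.0)
})

test_that("matched fraction is invariant under joint rotation of array and net", {
  arr <- grid_array(3, 4, 1.0, 0.7)
  net <- simple_net(1.0, 0.7)
  base <- scan_orientations(arr, net, rotation_step = 15, capture_radius = 0.08)
  rotate_net <- function(net, deg) {
    th <- calcitile:::deg2rad(deg)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    out <- net
    out$a1 <- as.numeric(net$a1 %*% R)
    out$a2 <- as.numeric(net$a2 %*% R)
    uv <- as.matrix(net$motif[, c("u", "v")]) %*% R
    out$motif$u <- uv[, 1]; out$motif$v <- uv[, 2]
    out
  }
  rotate_array <- function(arr, deg) {
    R <- calcitile:::rotation_about_axis(c(0, 0, 1), calcitile:::deg2rad(deg))
    xyz <- as.matrix(arr[, c("x", "y", "z")]) %*% t(R)
    arr$x <- xyz[, 1]; arr$y <- xyz[, 2]; arr$z <- xyz[, 3]
    arr
  }
  # rotating both template and surface by the same angle (37 deg) leaves the
  # relative geometry, hence the match, unchanged
  joint <- scan_orientations(rotate_array(arr, 37), rotate_net(net, 37),
                             rotation_step = 15, capture_radius = 0.08)
  expect_equal(joint$matched_fraction, base$matched_fraction, tolerance = 1e-9)
  # rotating the template alone by an on-grid angle shifts the best
  # rotation but not the matched fraction
  arr_only <- scan_orientations(rotate_array(arr, 30), net,
                                rotation_step = 15, capture_radius = 0.08)
  expect_equal(arr_only$matched_fraction, base$matched_fraction, tolerance = 1e-9)
  # a net rotation on the scan grid is recovered at the matching rotation
  on_grid <- scan_orientations(arr, rotate_net(net, 30),
                               rotation_step = 15, capture_radius = 0.08)
  expect_equal(on_grid$matched_fraction, base$matched_fraction, tolerance = 1e-9)
})

test_that("a random incommensurate array matches poorly at tight capture radius", {
  set.seed(5)
  pts <- cbind(runif(30, 0, 4), runif(30, 0, 4))
  net <- simple_net(0.53, 0.71)
  sc <- scan_orientations(pts, net, rotation_step = 45, capture_radius = 0.05)
  # direct nearest-neighbour bound at the best reported pose
  expect_lt(sc$matched_fraction, 0.5)
})

test_that("surface ranking recovers the generating net against decoys", {
  net_true <- simple_net(1.05, 0.62, name = "true")
  decoys <- list(simple_net(1.31, 0.83, "d1"), simple_net(0.47, 0.99, "d2"),
                 simple_net(1.77, 0.58, "d3"), simple_net(0.86, 0.41, "d4"))
  hits <- 0
  for (i in 1:20) {
    set.seed(i)
    g <- expand.grid(r = 1:4, s = 1:5)
    arr <- surface_array(tibble::tibble(
      repeat_index = g$r, slot = g$s,
      x = (g$r - 1) * 10.5 + rnorm(20, 0, 0.05),
      y = (g$s - 1) * 6.2 + rnorm(20, 0, 0.05),
      z = 0, residue = "GLU"))
    rk <- rank_surfaces(arr, c(decoys[1:2], list(net_true), decoys[3:4]),
                        rotation_step = 45, capture_radius = 0.08)
    if (rk$net_name[1] == "true") hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("ranking is deterministic with stable tie-breaks", {
  net <- simple_net(1.0)
  arr <- grid_array(3, 3, 1.0, 1.0)
  rk <- rank_surfaces(arr, list(net, net), rotation_step = 90)
  expect_equal(rk$matched_fraction[1], rk$matched_fraction[2])
  expect_equal(rk$input_order, c(1L, 2L)) # stable input order preserved
  rk1 <- rank_surfaces(arr, list(net), rotation_step = 90)
  expect_equal(nrow(rk1), 1)
})

test_that("orientation scans validate their inputs", {
  net <- simple_net(1.0)
  expect_error(scan_orientations(grid_array(2, 2, 1, 1), net, rotation_step = 7),
               "divide 360")
  bad <- net
  bad$a2 <- bad$a1
  expect_error(scan_orientations(grid_array(2, 2, 1, 1), bad, rotation_step = 90),
               "degenerate")
})
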