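test_that("built models reproduce the requested inter-repeat spacing", {
  # design values plus random draws across the sampled range
  set.seed(42)
  targets <- c(8.7, 10.6, 11.4, runif(8, 8, 15))
  topo <- toy_topology(4)
  for (d in targets) {
    m <- build_repeat_model(topo, d_rep = d)
    expect_equal(as.numeric(measure_repeat_spacing(m)), d, tolerance = 0.1 / d)
  }
})

test_that("the repeat transform of a built model is a pure translation", {
  m <- toy_model(11.4, 6)
  tr <- calcitile:::repeat_transform(m)
  expect_lt(tr$rotation_deg, 0.5)
  expect_equal(tr$translation, 11.4, tolerance = 1e-6)
})

test_that("single-repeat models build without error but have no spacing", {
  topo <- toy_topology(1)
  m <- build_repeat_model(topo, d_rep = 10)
  expect_s3_class(m, "backbone_model")
  expect_error(measure_repeat_spacing(m), "single-repeat")
})

test_that("steric clashes in generated backbones name the residue pair", {
  expect_error(build_repeat_model(toy_topology(3), d_rep = 5.0),
               "residues [0-9]+ and [0-9]+")
})

test_that("spacing measurement matches an explicit axis-distance oracle", {
  # two parallel synthetic helices 10 A apart, plus a jittered model checked
  # against the mean of the per-pair axis distances
  m <- toy_model(10, 3)
  sp <- measure_repeat_spacing(m)
  pairs <- attr(sp, "pairs")
  expect_equal(as.numeric(sp), mean(pairs$distance))
  set.seed(7)
  mj <- m
  mj$atoms$x <- mj$atoms$x + rnorm(nrow(mj$atoms), 0, 0.05)
  mj$atoms$z <- mj$atoms$z + rnorm(nrow(mj$atoms), 0, 0.05)
  spj <- measure_repeat_spacing(mj)
  expect_equal(as.numeric(spj), mean(attr(spj, "pairs")$distance))
  expect_equal(as.numeric(spj), 10, tolerance = 0.02)
})

test_that("resizing propagates the repeat unit and preserves identity", {
  fx <- load_fixture("FD31")
  m9 <- resize_repeats(fx$model, 9)
  expect_equal(max(m9$atoms$repeat_index), 9)
  expect_equal(nrow(extract_surface_array(m9)), 54)
  m3 <- resize_repeats(fx$model, 3)
  expect_equal(nrow(extract_surface_array(m3)), 18)
  m6 <- resize_repeats(fx$model, 6)
  expect_identical(m6$atoms$x, fx$model$atoms$x)
})

test_that("superposition is rigid-invariant and matches the single-atom closed form", {
  m <- toy_model(10, 3)
  expect_equal(superpose(m, m), 0, tolerance = 1e-10)
  # arbitrary rigid motion
  R <- calcitile:::rotation_about_axis(c(1, 2, 3), pi / 2)
  m2 <- m
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(R)
  m2$atoms$x <- xyz[, 1] + 12; m2$atoms$y <- xyz[, 2] - 4; m2$atoms$z <- xyz[, 3] + 7
  expect_equal(superpose(m, m2), 0, tolerance = 1e-10)
  # one CA displaced by delta: RMSD ~ delta * sqrt((n-1)/n) / sqrt(n) after
  # re-centering; for small delta relative to the model extent the
  # superposition stays near identity and RMSD ~ delta / sqrt(n)
  ca_idx <- which(m$atoms$atom == "CA")
  n <- length(ca_idx)
  m3 <- m
  m3$atoms$x[ca_idx[5]] <- m3$atoms$x[ca_idx[5]] + 1.0
  expect_equal(superpose(m, m3), 1.0 / sqrt(n), tolerance = 0.05)
  # mismatched lengths error
  expect_error(superpose(m, toy_model(10, 4)), "pairing")
})

test_that("the flattening grid is inclusive and misordered bounds error", {
  m <- toy_model(10, 3)
  fr <- flatten_model(m, 8, 15, 0.1, seed = 1, mc_steps = 0)
  expect_equal(nrow(fr$grid), 71)
  expect_error(flatten_model(m, 15, 8, 0.1), "grid_min")
  expect_error(flatten_model(toy_model(10, 2), 8, 15, 0.1), ">= 3 repeats")
})

test_that("an already-ideal model is a fixed point of flattening", {
  m <- toy_model(11.4, 3)
  fr <- flatten_model(m, 10.5, 12.5, 0.1, seed = 2, mc_steps = 30)
  expect_equal(fr$selected_d_rep, 11.4, tolerance = 1e-9)
  expect_lt(max(abs(calcitile:::model_xyz(fr$model, "CA") -
                      calcitile:::model_xyz(m, "CA"))), 0.05)
})

test_that("flattening a bent model restores flatness and recovers the spacing", {
  m <- toy_model(10.8, 4)
  mb <- bend_model(m, 10)
  fr <- flatten_model(mb, 8, 15, 0.1, seed = 4, mc_steps = 25)
  expect_true(all(fr$grid$angle_deg >= 179))
  expect_true(all(fr$grid$dihedral_deg <= 1))
  expect_equal(fr$selected_d_rep, 10.8, tolerance = 0.2)
  # rotation component of every adjacent repeat transform below 0.5 deg
  tr <- calcitile:::repeat_transform(fr$model)
  expect_lt(tr$rotation_deg, 0.5)
  # direct geometric verification of the first/middle/last constraint
  ca <- fr$model$atoms[fr$model$atoms$atom == "CA", ]
  p <- function(r) unlist(ca[ca$repeat_index == r, c("x", "y", "z")][1, ])
  expect_gte(calcitile:::angle_deg(p(1), p(2), p(4)), 179)
})

test_that("identical seeds give bit-identical flatten results", {
  mb <- bend_model(toy_model(10, 3), 6)
  f1 <- flatten_model(mb, 9, 11, 0.5, seed = 99, mc_steps = 40)
  f2 <- flatten_model(mb, 9, 11, 0.5, seed = 99, mc_steps = 40)
  expect_identical(f1$grid, f2$grid)
  expect_identical(f1$model$atoms, f2$model$atoms)
  expect_identical(f1$trajectory, f2$trajectory)
})

test_that("the accepted flattening trajectory is non-increasing at zero temperature", {
  mb <- bend_model(toy_model(10, 3), 6)
  fr <- flatten_model(mb, 9.8, 10.2, 0.2, seed = 5, mc_steps = 60,
                      temp_start = 0, temp_end = 0)
  expect_true(all(diff(fr$trajectory) <= 1e-12))
})

test_that("candidate models can be reconstructed for any grid value", {
  mb <- bend_model(toy_model(10, 3), 4)
  fr <- flatten_model(mb, 9, 11, 1, seed = 1, mc_steps = 10)
  m9 <- flatten_candidate_model(fr, 9)
  expect_equal(as.numeric(measure_repeat_spacing(m9)), 9, tolerance = 0.15)
  expect_error(flatten_candidate_model(fr, 9.37), "not a grid candidate")
})
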