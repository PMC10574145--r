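test_that("radius of gyration agrees with hand and pairwise oracles", {
  # symmetric dimer of unit masses 2 A apart: R_g = 1 A
  dimer <- frame_from_rows(
    list("C", -1, 0, 0, 1, "m1", "solute"),
    list("C", 1, 0, 0, 1, "m1", "solute"))
  expect_equal(radius_of_gyration(dimer), 1)

  # pairwise-sum oracle on random frames
  set.seed(1)
  for (i in 1:50) {
    fr <- random_frame(n = sample(5:40, 1))
    expect_equal(radius_of_gyration(fr), rg_pairwise_oracle(fr),
                 tolerance = 1e-12)
  }
})

test_that("radius of gyration is rigid-motion invariant and scales linearly", {
  set.seed(2)
  for (i in 1:10) {
    fr <- random_frame()
    rg <- radius_of_gyration(fr)
    expect_equal(radius_of_gyration(random_rigid_motion(fr)), rg,
                 tolerance = 1e-9)
    fr2 <- fr
    fr2$atoms[, c("x", "y", "z")] <- fr$atoms[, c("x", "y", "z")] * 3.7
    expect_equal(radius_of_gyration(fr2), 3.7 * rg, tolerance = 1e-12)
  }
  # translation by a fixed offset
  fr <- random_frame()
  fr3 <- fr
  fr3$atoms$x <- fr$atoms$x + 10
  fr3$atoms$y <- fr$atoms$y - 5
  fr3$atoms$z <- fr$atoms$z + 3
  expect_equal(radius_of_gyration(fr3), radius_of_gyration(fr),
               tolerance = 1e-12)
  expect_error(radius_of_gyration(fr, selection = "solvent"), "empty")
})

test_that("rg_series summarises frames and separates compactness", {
  fr <- random_frame()
  s <- rg_series(list(fr, fr, fr))
  expect_equal(s$se, 0)
  expect_equal(s$mean, radius_of_gyration(fr))

  # frozen chain with jittered solvent: solute R_g constant
  solv <- data.frame(element = "O", x = rnorm(5), y = rnorm(5), z = rnorm(5),
                     mass = 15.999, molecule_id = paste0("w", 1:5),
                     role = "solvent")
  f1 <- molecular_frame(rbind(fr$atoms, solv))
  solv2 <- solv; solv2[, c("x", "y", "z")] <- solv[, c("x", "y", "z")] + rnorm(15)
  f2 <- molecular_frame(rbind(fr$atoms, solv2))
  rs <- rg_series(list(f1, f2), "solute")
  expect_equal(rs$se, 0, tolerance = 1e-12)

  # compact vs extended generator chains: ordering over 20 seeded repetitions
  means <- vapply(1:20, function(s) {
    ext <- generate_chain_frame(synthetic_frame_spec(
      kappa = 0, n_bridge_waters = 0, n_bulk_waters = 0, seed = 300 + s))
    cmp <- generate_chain_frame(synthetic_frame_spec(
      kappa = 1, n_bridge_waters = 0, n_bulk_waters = 0, seed = 300 + s))
    radius_of_gyration(ext) - radius_of_gyration(cmp)
  }, numeric(1))
  expect_gt(mean(means), 0)
  ord <- vapply(1:20, function(s) {
    rg_ext <- mean(rg_series(generate_frame_series(synthetic_frame_spec(
      kappa = 0.1, n_bridge_waters = 0, n_bulk_waters = 0, n_frames = 5,
      seed = 400 + s)))$rg)
    rg_cmp <- mean(rg_series(generate_frame_series(synthetic_frame_spec(
      kappa = 0.9, n_bridge_waters = 0, n_bulk_waters = 0, n_frames = 5,
      seed = 400 + s)))$rg)
    rg_cmp < rg_ext
  }, logical(1))
  expect_true(all(ord))
})

test_that("end-to-end distance takes the first and last heavy atoms", {
  # straight 10-bond chain of 1.5 A bonds spans 15 A
  chain <- molecular_frame(data.frame(
    element = "C", x = seq(0, 15, by = 1.5), y = 0, z = 0,
    mass = 12.011, molecule_id = "m1", role = "solute"))
  expect_equal(end_to_end_distance(chain, "m1"), 15)

  # closed ring: first and last positions coincide
  ring <- chain
  ring$atoms[nrow(ring$atoms), c("x", "y", "z")] <- ring$atoms[1, c("x", "y", "z")]
  expect_equal(end_to_end_distance(ring, "m1"), 0)

  # random chain matches the direct norm of the endpoint difference
  set.seed(3)
  fr <- random_frame(12)
  p <- as.matrix(fr$atoms[, c("x", "y", "z")])
  expect_equal(end_to_end_distance(fr, "m1"),
               sqrt(sum((p[12, ] - p[1, ])^2)), tolerance = 1e-12)

  tiny <- frame_from_rows(list("C", 0, 0, 0, 12, "m1", "solute"))
  expect_error(end_to_end_distance(tiny, "m1"), "at least 2")
})

test_that("characteristic viscosity follows the R_g^3 rho / M convention", {
  base <- viscosity_input(rg = 10, density = 1, molar_mass = 1000)
  doubled <- viscosity_input(rg = 20, density = 1, molar_mass = 1000)
  expect_equal(characteristic_viscosity(doubled) /
                 characteristic_viscosity(base), 8, tolerance = 1e-12)
  expect_equal(characteristic_viscosity(base) /
                 characteristic_viscosity(base), 1)
  expect_error(viscosity_input(-1, 1, 1))
})

test_that("normalized viscosity reproduces the MD condition ratios", {
  inputs <- list(
    water = viscosity_input(9.48, 0.991, 1015),
    pH3 = viscosity_input(12.27, 0.983, 1015),
    pH11 = viscosity_input(7, 0.989, 1015))
  ratios <- normalized_viscosity(inputs, reference = "water")
  expect_identical(ratios[["water"]], 1)
  expect_equal(round(ratios[["pH3"]], 3), 2.151)
  # permuting the map leaves the ratios unchanged
  ratios2 <- normalized_viscosity(inputs[c(2, 3, 1)], reference = "water")
  expect_equal(ratios2[names(ratios)], ratios)
  expect_error(normalized_viscosity(inputs, reference = "pH7"), "missing")
})
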