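test_that("FJC extension matches the Langevin function and its limits", {
  p <- two_state_parameters()
  kbt <- thermal_energy()

  expect_identical(fjc_extension(0, p), 0)
  # force chosen so F * l_k / k_BT = 1; oracle: coth(1) - 1 = 0.3130353
  f1 <- kbt / p$kuhn_length
  expect_equal(fjc_extension(f1, p), 1 / tanh(1) - 1, tolerance = 1e-12)
  # saturation from below at very high force (inextensible backbone)
  z_hi <- fjc_extension(1e6, p)
  expect_lt(z_hi, 1)
  expect_gt(z_hi, 0.9999)
  expect_error(fjc_extension(-5, p), "non-negative")
})

test_that("series branch of the Langevin function is continuous", {
  p <- two_state_parameters()
  kbt <- thermal_energy()
  f <- c(0.9e-3, 1.1e-3) * kbt / p$kuhn_length  # straddle the switch point
  z <- fjc_extension(f, p)
  expect_equal(z[1] / (f[1] * p$kuhn_length / kbt),
               z[2] / (f[2] * p$kuhn_length / kbt), tolerance = 1e-6)
})

test_that("effective unit length interpolates between the two states", {
  p0 <- two_state_parameters(delta_g = 0)
  expect_equal(effective_unit_length(0, p0), 0.495, tolerance = 1e-12)

  p <- two_state_parameters(delta_g = 5.53)
  expect_equal(effective_unit_length(1e7, p), 0.54, tolerance = 1e-9)
  # midpoint force gives equal populations, hence the mean length
  expect_equal(effective_unit_length(transition_force(p), p), 0.495,
               tolerance = 1e-12)
  # bounds hold everywhere
  l <- effective_unit_length(seq(0, 1e4, length.out = 500), p)
  expect_true(all(l >= 0.45 & l <= 0.54))
  expect_error(effective_unit_length(-1, p), "non-negative")
})

test_that("two-state extension dominates the plain FJC and saturates at l_f/l_u", {
  p <- two_state_parameters(delta_g = 5.53)
  f <- seq(0, 1e4, length.out = 400)
  expect_identical(tsqm_fjc_extension(0, p), 0)
  expect_true(all(tsqm_fjc_extension(f, p) >= fjc_extension(f, p)))
  expect_equal(tsqm_fjc_extension(1e5, p), 0.54 / 0.45, tolerance = 1e-3)

  # unreachable long state: reduces to the plain FJC
  p_inf <- two_state_parameters(delta_g = 1e3)
  expect_equal(tsqm_fjc_extension(f, p_inf), fjc_extension(f, p_inf),
               tolerance = 1e-12)
})

test_that("model curves are monotone non-decreasing in force", {
  for (dg in c(0, 1.5, 5.53)) {
    p <- two_state_parameters(delta_g = dg)
    f <- seq(0, 1e4, length.out = 2000)
    tol <- -1e-12  # saturation plateaus are flat to machine precision
    expect_true(all(diff(fjc_extension(f, p)) >= tol))
    expect_true(all(diff(effective_unit_length(f, p)) >= tol))
    expect_true(all(diff(tsqm_fjc_extension(f, p)) >= tol))
  }
})

test_that("large delta_g collapses the two-state model onto the FJC", {
  f <- seq(0, 1500, length.out = 300)
  gaps <- vapply(c(50, 200, 1000), function(dg) {
    p <- two_state_parameters(delta_g = dg)
    max(abs(tsqm_fjc_extension(f, p) - fjc_extension(f, p)))
  }, numeric(1))
  expect_true(all(diff(gaps) <= 0))
  expect_lt(gaps[3], 1e-12)
})

test_that("extension inversion round-trips against the forward model", {
  p <- two_state_parameters(delta_g = 1.5)
  expect_identical(invert_extension_to_force(0, p), 0)
  z300 <- tsqm_fjc_extension(300, p)
  expect_equal(invert_extension_to_force(z300, p), 300, tolerance = 1e-6)

  set.seed(42)
  z <- runif(100, 1e-4, 1.1)
  f <- invert_extension_to_force(z, p, tolerance = 1e-9)
  expect_true(all(abs(tsqm_fjc_extension(f, p) - z) < 1e-6))

  expect_error(invert_extension_to_force(1.2, p), "unreachable")
})

test_that("transition force marks equal state populations", {
  p <- two_state_parameters(delta_g = 5.53)
  ft <- transition_force(p)
  expect_equal(ft, 5.53 * thermal_energy() / 0.09, tolerance = 1e-12)
  # population fraction of the long state at the transition force
  kbt <- thermal_energy()
  a <- ft * delta_l(p) / kbt - p$delta_g
  expect_equal(plogis(a), 0.5, tolerance = 1e-12)

  expect_equal(transition_force(two_state_parameters(delta_g = 0)), 0)
  # pH 5 value: about 156 pN
  expect_equal(transition_force(two_state_parameters(delta_g = 3.412)),
               155.98, tolerance = 1e-4)
})

test_that("energy conversions follow the 2.5 kJ/mol reporting factor", {
  expect_equal(convert_energy(1.50, "kBT", "kJ/mol"), 3.75)
  expect_equal(convert_energy(5.53, "kBT", "kJ/mol"), 13.825)
  expect_equal(convert_energy(0, "kBT", "kJ/mol"), 0)
  expect_equal(convert_energy(3.75, "kJ/mol", "kBT"), 1.50)
  # mechanics conversion uses the exact thermal energy
  expect_equal(convert_energy(1, "kBT", "pN.nm"), 0.0138065 * 298)
  expect_equal(convert_energy(convert_energy(2.7, "kJ/mol", "pN.nm"),
                              "pN.nm", "kJ/mol"), 2.7, tolerance = 1e-12)
  expect_error(convert_energy(1, "eV", "kBT"))
})

test_that("parameter validation rejects unphysical inputs", {
  expect_error(two_state_parameters(unit_length_forced = 0.4), "exceed")
  expect_error(two_state_parameters(kuhn_length = -1), "positive")
  expect_error(two_state_parameters(delta_g = Inf), "finite")
  expect_error(two_state_parameters(temperature = 0), "positive")
  # backbone stretch raises the extension at a given force
  p_ext <- two_state_parameters(backbone_modulus = 3e4)
  p_fix <- two_state_parameters()
  expect_gt(fjc_extension(1500, p_ext), fjc_extension(1500, p_fix))
})
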