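test_that("the TSV curve dialect round-trips with metadata", {
  curves <- noiseless_ensemble(1.5, n_curves = 3, seed = 2)
  curves[[1]]$environment <- "pH3"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_curves(curves, path)
  back <- load_curves(path)
  expect_length(back, 3)
  expect_identical(vapply(back, `[[`, character(1), "id"),
                   vapply(curves, `[[`, character(1), "id"))
  expect_identical(back[[1]]$environment, "pH3")
  expect_equal(back[[2]]$samples, curves[[2]]$samples, tolerance = 1e-15)
})

test_that("malformed curve files raise errors naming the line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#id: c1", "extension_nm\tforce_pN", "1.0\t2.0", "oops\tx"),
             path)
  expect_error(load_curves(path), "line 4")
  writeLines(c("#id: c1", "wrong\theader", "1.0\t2.0"), path)
  expect_error(load_curves(path), "header")
  expect_error(load_curves(tempfile()), "not found")
})

test_that("segmentation recovers generator ground truth on noiseless curves", {
  curves <- noiseless_ensemble(5.53, n_curves = 4, seed = 11, samples = 400)
  for (cv in curves) {
    seg <- segment_curve(cv)
    expect_false(seg$unruptured)
    expect_lte(abs(seg$adhesion_end_index - cv$metadata$true_adhesion_end_index), 2)
    expect_lte(abs(seg$detachment_index - cv$metadata$true_detachment_index), 2)
    expect_lte(seg$adhesion_end_index, seg$stretch_start_index)
    expect_lt(seg$stretch_start_index, seg$detachment_index)
  }
})

test_that("segmentation handles edge-case traces", {
  # monotone noise-free model curve with an appended drop to zero
  p <- two_state_parameters()
  f <- seq(10, 1800, length.out = 200)
  x <- 50 * 0.45 * tsqm_fjc_extension(f, p)
  cv <- fe_curve(c(x, x[200] + 1:5 * 0.1), c(f, rep(0, 5)))
  seg <- segment_curve(cv)
  expect_identical(seg$adhesion_end_index, 0L)
  expect_identical(seg$detachment_index, 201L)

  # flat zero-force trace: no detachment
  flat <- fe_curve(seq(0.1, 10, length.out = 50), rep(0, 50))
  seg_flat <- segment_curve(flat)
  expect_true(seg_flat$unruptured)

  # the global force maximum is never assigned to the adhesion region
  curves <- generate_fec(synthetic_curve_spec(
    params = p, n_curves = 3, noise_sd = 10, samples_per_curve = 300,
    adhesion_height = 400, seed = 4))
  for (cv in curves) {
    seg <- segment_curve(cv)
    expect_gt(which.max(cv$samples$force_pN), seg$adhesion_end_index)
  }
})

test_that("extension interpolation is linear on the monotonized stretch region", {
  # hand-built curve: exact sample at 1500 pN and a midpoint case
  cv <- fe_curve(c(seq(1, 99, length.out = 48), 100, 102),
                 c(seq(10, 1300, length.out = 48), 1400, 1600))
  seg <- segment_curve(cv)
  expect_equal(extension_at_force(cv, seg, 1400), 100)
  expect_equal(extension_at_force(cv, seg, 1500), 101)
  expect_error(extension_at_force(cv, seg, 2000), "does not reach")

  # noiseless synthetic curve matches the forward model within 0.1%
  curves <- noiseless_ensemble(1.5, n_curves = 1, seed = 3, samples = 400)
  cv <- curves[[1]]
  seg <- segment_curve(cv)
  n <- cv$metadata$n_units
  expected <- n * 0.45 *
    tsqm_fjc_extension(1500, two_state_parameters(delta_g = 1.5))
  expect_equal(extension_at_force(cv, seg, 1500), expected,
               tolerance = 1e-3)
})

test_that("normalization pins the reference point and is scale invariant", {
  cv <- noiseless_ensemble(1.5, n_curves = 1, seed = 5)[[1]]
  nc <- normalize_curve(cv)
  z_ref <- approx(nc$samples$force_pN, nc$samples$z, xout = 1500)$y
  expect_equal(z_ref, 1, tolerance = 1e-6)
  expect_true(all(nc$samples$force_pN > 0 & nc$samples$force_pN <= 1500))

  # doubling all raw extensions changes nothing after normalization
  cv2 <- cv
  cv2$samples$extension_nm <- cv$samples$extension_nm * 2
  nc2 <- normalize_curve(cv2)
  expect_equal(nc2$samples$z, nc$samples$z, tolerance = 1e-12)

  # normalizing a normalized curve is the identity
  expect_identical(normalize_curve(nc), nc)
})

test_that("normalized curves are invariant to contour length", {
  p <- two_state_parameters(delta_g = 1.5)
  make <- function(n_units) {
    spec <- synthetic_curve_spec(params = p, n_units = n_units,
                                 n_units_jitter = 0, noise_sd = 0,
                                 n_curves = 1, samples_per_curve = 500,
                                 seed = 6)
    normalize_curve(generate_fec(spec)[[1]])
  }
  n50 <- make(50); n200 <- make(200)
  grid <- seq(50, 1500, by = 25)
  z50 <- approx(n50$samples$force_pN, n50$samples$z, xout = grid)$y
  z200 <- approx(n200$samples$force_pN, n200$samples$z, xout = grid)$y
  expect_lt(max(abs(z50 - z200)), 1e-3)
})

test_that("overlay dispersion separates shared from differing elasticity", {
  nc <- normalized_ensemble(1.5, n_curves = 1, seed = 8)
  expect_equal(overlay_dispersion(c(nc, nc)), 0)
  expect_error(overlay_dispersion(nc), "at least 2")

  # noisy replicates of one parameter set overlap tightly
  spec <- synthetic_curve_spec(params = two_state_parameters(delta_g = 1.5),
                               n_curves = 20, noise_sd = 10,
                               samples_per_curve = 300, seed = 9)
  reps <- lapply(generate_fec(spec), normalize_curve)
  disp_same <- overlay_dispersion(reps)
  expect_lt(disp_same, 0.05)

  # two noiseless curves from different delta_g disperse more
  pair <- c(normalized_ensemble(1.5, n_curves = 1, seed = 10),
            normalized_ensemble(5.53, n_curves = 1, seed = 10))
  expect_gt(overlay_dispersion(pair), disp_same)

  # grid outside a curve's range names the offender
  short <- reps[[1]]
  short$samples <- short$samples[short$samples$force_pN > 200, ]
  short$id <- "short_curve"
  expect_error(overlay_dispersion(list(short, reps[[2]])), "short_curve")
})
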