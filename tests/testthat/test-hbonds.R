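test_that("textbook donor geometry is detected and cutoffs enforced", {
  fr <- water_donor_fixture(dist = 2.8, angle_deg = 170)
  rec <- detect_hbonds(fr)
  expect_identical(nrow(rec), 1L)
  expect_equal(rec$distance, 2.8, tolerance = 1e-9)
  expect_equal(rec$angle, 170, tolerance = 1e-6)
  expect_identical(rec$class, "inter")

  # same geometry beyond the distance cutoff
  expect_identical(nrow(detect_hbonds(water_donor_fixture(dist = 4.2))), 0L)
  # same distance below the angle cutoff
  expect_identical(nrow(detect_hbonds(water_donor_fixture(angle_deg = 120))), 0L)
  # a tighter angle criterion rejects the 170-degree bond only when raised
  expect_identical(
    nrow(detect_hbonds(fr, hbond_criteria(min_dha_angle = 175))), 0L)
})

test_that("a bridging water donating to two adjacent units gives 2 inter records", {
  fr <- generate_chain_frame(synthetic_frame_spec(
    n_units = 5, kappa = 0, n_bridge_waters = 1, n_bulk_waters = 0,
    seed = 21))
  rec <- detect_hbonds(fr)
  inter <- rec[rec$class == "inter", ]
  expect_identical(nrow(inter), 2L)
  expect_true(all(inter$donor_molecule == "bw1"))
  expect_identical(length(unique(inter$acceptor)), 2L)
  expect_true(all(inter$distance <= 3.5))
  expect_true(all(inter$angle >= 130))
})

test_that("classification counts a constructed mixed fixture correctly", {
  fr <- generate_chain_frame(synthetic_frame_spec(
    n_units = 8, kappa = 0.2, n_bridge_waters = 3, n_bulk_waters = 4,
    n_intra_hbonds = 3, seed = 22))
  counts <- classify_hbonds(detect_hbonds(fr))
  expect_identical(unname(counts), c(3L, 6L))

  # all-solute frame has no intermolecular bonds
  solo <- generate_chain_frame(synthetic_frame_spec(
    n_units = 8, kappa = 0.2, n_bridge_waters = 0, n_bulk_waters = 0,
    n_intra_hbonds = 2, seed = 23))
  expect_identical(classify_hbonds(detect_hbonds(solo))[["inter"]], 0L)

  # solvated solute without internal donors has no intramolecular bonds
  wet <- generate_chain_frame(synthetic_frame_spec(
    n_units = 8, kappa = 0.2, n_bridge_waters = 2, n_bulk_waters = 4,
    n_intra_hbonds = 0, seed = 24))
  expect_identical(classify_hbonds(detect_hbonds(wet))[["intra"]], 0L)
})

test_that("detection is invariant under rigid motion", {
  fr <- generate_chain_frame(synthetic_frame_spec(
    n_units = 8, kappa = 0.2, n_bridge_waters = 3, n_bulk_waters = 5,
    n_intra_hbonds = 1, seed = 25))
  rec <- detect_hbonds(fr)
  set.seed(26)
  for (i in 1:5) {
    rec2 <- detect_hbonds(random_rigid_motion(fr))
    expect_identical(rec2[, c("donor", "hydrogen", "acceptor", "class")],
                     rec[, c("donor", "hydrogen", "acceptor", "class")])
    expect_equal(rec2$distance, rec$distance, tolerance = 1e-9)
    expect_equal(rec2$angle, rec$angle, tolerance = 1e-7)
  }
})

test_that("counts are monotone in the geometric cutoffs", {
  fr <- generate_chain_frame(synthetic_frame_spec(
    n_units = 10, kappa = 0.6, n_bridge_waters = 4, n_bulk_waters = 10,
    n_intra_hbonds = 1, seed = 27))
  n_at <- function(dist, ang) {
    nrow(detect_hbonds(fr, hbond_criteria(dist, ang)))
  }
  dists <- c(2.5, 3.0, 3.5, 4.0, 4.5)
  expect_true(all(diff(vapply(dists, n_at, numeric(1), ang = 130)) >= 0))
  angles <- c(100, 120, 140, 160)
  expect_true(all(diff(vapply(angles, n_at, numeric(1), dist = 3.5)) <= 0))
})

test_that("intra and inter partition the solute-involving records", {
  for (s in 31:35) {
    fr <- generate_chain_frame(synthetic_frame_spec(
      n_units = 8, kappa = 0.4, n_bridge_waters = 2, n_bulk_waters = 8,
      n_intra_hbonds = 1, seed = s))
    rec <- detect_hbonds(fr)
    counts <- classify_hbonds(rec)
    a <- fr$atoms
    solute_involving <- sum(a$role[rec$donor] == "solute" |
                              a$role[rec$acceptor] == "solute")
    expect_identical(sum(counts), solute_involving)
  }
})

test_that("frame-series ratios behave as constructed", {
  fr <- generate_chain_frame(synthetic_frame_spec(
    n_units = 13, kappa = 0.2, n_bridge_waters = 12, n_bulk_waters = 5,
    n_intra_hbonds = 1, seed = 36))
  one <- hbond_ratio_over_frames(list(fr))
  # 12 bridges contribute 2 inter bonds each against 1 intra bond
  expect_equal(one$ratio, 24)
  # duplicating frames leaves the ratio unchanged
  expect_equal(hbond_ratio_over_frames(list(fr, fr, fr))$ratio, one$ratio)

  # zero-solvent frames: no inter bonds, infinite inter:intra ratio
  dry <- generate_chain_frame(synthetic_frame_spec(
    n_units = 8, kappa = 0.2, n_bridge_waters = 0, n_bulk_waters = 0,
    n_intra_hbonds = 0, seed = 37))
  dry_stats <- hbond_ratio_over_frames(list(dry))
  expect_identical(dry_stats$mean_inter, 0)
  expect_true(is.nan(dry_stats$ratio))
})

test_that("hydrogens without attachable donors demand a bond list", {
  fr <- frame_from_rows(
    list("H", 0, 0, 0, 1.008, "m1", "solute"),
    list("C", 1.0, 0, 0, 12.011, "m1", "solute"),
    list("O", 3.0, 0, 0, 15.999, "m2", "solvent"))
  expect_error(detect_hbonds(fr), "bond list")
})
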