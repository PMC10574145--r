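# Synthetic-data generators: SMFS-like force-extension retraction curves
# driven by the TSQM-FJC forward model, and solvated single-chain frames
# with controllable compactness and water bridging.  All generators are
# fully deterministic from their seed.

#' Specification of a synthetic force-extension ensemble
#'
#' Curves are built on an extension grid up to the detachment point, with
#' force from the TSQM-FJC model scaled by the free-state contour length
#' N l_u, additive Gaussian force noise, a triangular adhesion spike near
#' zero extension, and an abrupt terminal force drop.  N is resampled per
#' curve within +/- `n_units_jitter` of `n_units`, emulating the
#' molecular-weight variation between picked chains.
#'
#' @param params Generating [two_state_parameters()].
#' @param n_units Mean saccharide unit count N (>= 10).
#' @param n_units_jitter Relative half-width of the per-curve N range.
#' @param noise_sd Gaussian force noise sigma, pN (default 10).
#' @param adhesion_height,adhesion_width Triangular adhesion spike height
#'   (pN) and extension width (nm).
#' @param detachment_force Detachment force in pN, a scalar or a
#'   `c(min, max)` range sampled per curve; must exceed the 1500 pN
#'   normalization reference for normalizable curves.
#' @param samples_per_curve Samples on the stretch grid.  The default of
#'   1000 matches typical AFM acquisition density; interpolation and
#'   normalization discretization errors shrink quadratically with it.
#' @param n_curves Number of curves.
#' @param environment Environment label stamped on each curve.
#' @param seed RNG seed.
#' @return A list of class `synthetic_curve_spec`.
#' @export
synthetic_curve_spec <- function(params = two_state_parameters(),
                                 n_units = 50,
                                 n_units_jitter = 0.2,
                                 noise_sd = 10,
                                 adhesion_height = 300,
                                 adhesion_width = 5,
                                 detachment_force = 1800,
                                 samples_per_curve = 1000,
                                 n_curves = 20,
                                 environment = "DI",
                                 seed = 1L) {
  if (!(n_units >= 10)) stop("n_units must be at least 10")
  if (!(noise_sd >= 0)) stop("noise_sd must be non-negative")
  if (!all(detachment_force > 0)) stop("detachment_force must be positive")
  if (any(detachment_force <= 1500)) {
    warning("detachment below 1500 pN produces curves that cannot be normalized")
  }
  if (!(samples_per_curve >= 50)) stop("samples_per_curve must be at least 50")
  structure(
    list(params = params, n_units = n_units, n_units_jitter = n_units_jitter,
         noise_sd = noise_sd, adhesion_height = adhesion_height,
         adhesion_width = adhesion_width, detachment_force = detachment_force,
         samples_per_curve = samples_per_curve, n_curves = n_curves,
         environment = environment, seed = as.integer(seed)),
    class = "synthetic_curve_spec"
  )
}

#' Generate a synthetic force-extension ensemble
#'
#' @param spec A [synthetic_curve_spec()].
#' @return List of [fe_curve()] objects.  Each curve's `metadata` records
#'   the generating ground truth: `n_units`, `detachment_force_pN`,
#'   `true_adhesion_end_index` (last sample inside the adhesion spike) and
#'   `true_detachment_index` (first post-rupture sample).
#' @export
generate_fec <- function(spec) {
  stopifnot(inherits(spec, "synthetic_curve_spec"))
  p <- spec$params
  old <- set_local_seed(spec$seed)
  on.exit(restore_seed(old))
  lapply(seq_len(spec$n_curves), function(ci) {
    n_i <- round(stats::runif(1, spec$n_units * (1 - spec$n_units_jitter),
                              spec$n_units * (1 + spec$n_units_jitter)))
    f_det <- if (length(spec$detachment_force) == 2) {
      stats::runif(1, spec$detachment_force[1], spec$detachment_force[2])
    } else spec$detachment_force
    l0 <- n_i * p$unit_length_free
    x_det <- l0 * tsqm_fjc_extension(f_det, p)
    x <- seq(x_det / spec$samples_per_curve, x_det,
             length.out = spec$samples_per_curve)
    force <- invert_extension_to_force(x / l0, p, tolerance = 1e-9,
                                       upper = f_det * 2)
    # triangular adhesion spike over [0, width], peaking at width/2
    in_spike <- x <= spec$adhesion_width
    spike <- ifelse(in_spike,
                    spec$adhesion_height *
                      (1 - abs(2 * x / spec$adhesion_width - 1)), 0)
    force <- force + spike
    # post-rupture baseline tail
    dx <- x[2] - x[1]
    n_tail <- 10
    x_tail <- x_det + dx * seq_len(n_tail)
    force <- c(force, rep(0, n_tail))
    x <- c(x, x_tail)
    if (spec$noise_sd > 0) {
      force <- force + stats::rnorm(length(force), 0, spec$noise_sd)
    }
    fe_curve(
      x, force,
      id = sprintf("%s_%03d", spec$environment, ci),
      environment = spec$environment,
      metadata = list(
        n_units = n_i,
        detachment_force_pN = f_det,
        pulling_velocity_um_s = 1,
        true_adhesion_end_index = max(which(in_spike)),
        true_detachment_index = spec$samples_per_curve + 1L))
  })
}

#' Specification of a synthetic solvated-chain frame
#'
#' The solute is a freely rotating chain of point saccharide units (mass 203
#' amu, the GlcNAc residue mass) whose bond-direction correlation and soft
#' confinement are set by the compactness parameter `kappa` (0 = extended
#' rod-like, 1 = collapsed random walk in a shrinking sphere).  Bridging
#' waters are placed to hydrogen-bond to two adjacent units; intra-chain
#' hydrogen bonds are built from a donor hydrogen on one unit aimed at a
#' side-group acceptor oxygen; bulk waters fill the box outside
#' hydrogen-bonding range of the chain.
#'
#' @param n_units Chain unit count (>= 3).
#' @param bond_length Unit-unit bond length, Angstrom.
#' @param kappa Compactness in [0, 1].
#' @param n_bridge_waters Bridging waters, each donating to two adjacent
#'   units (2 inter hydrogen bonds per bridge).
#' @param n_bulk_waters Bulk waters (outside hydrogen-bonding range).
#' @param n_intra_hbonds Constructed intramolecular hydrogen bonds.
#' @param box Cubic box edge, Angstrom.
#' @param n_frames Frames for [generate_frame_series()].
#' @param seed RNG seed.
#' @return A list of class `synthetic_frame_spec`.
#' @export
synthetic_frame_spec <- function(n_units = 10,
                                 bond_length = 4.5,
                                 kappa = 0.5,
                                 n_bridge_waters = 4,
                                 n_bulk_waters = 20,
                                 n_intra_hbonds = 0,
                                 box = 40,
                                 n_frames = 10,
                                 seed = 1L) {
  stopifnot(n_units >= 3, bond_length > 0, kappa >= 0, kappa <= 1,
            n_bridge_waters >= 0, n_bulk_waters >= 0, n_intra_hbonds >= 0,
            box > 0, n_frames >= 1)
  if (n_bridge_waters > 0 && bond_length > 6) {
    stop("bridging requires unit spacing <= 6 A (both units within 3 A reach)")
  }
  structure(
    list(n_units = n_units, bond_length = bond_length, kappa = kappa,
         n_bridge_waters = n_bridge_waters, n_bulk_waters = n_bulk_waters,
         n_intra_hbonds = n_intra_hbonds, box = box, n_frames = n_frames,
         seed = as.integer(seed)),
    class = "synthetic_frame_spec"
  )
}

UNIT_MASS <- 203.19   # GlcNAc residue (monomer minus water), amu
WATER_OH <- 0.96      # O-H bond length, Angstrom
WATER_ANGLE <- 104.5  # H-O-H angle, degrees

# Freely rotating chain with direction correlation (1 - kappa) and a soft
# confinement sphere shrinking with kappa; positions relative to unit 1.
chain_positions <- function(n, b, kappa) {
  r_ext <- b * n
  r_comp <- b * n^(1 / 3)
  r_conf <- (1 - kappa) * r_ext + kappa * r_comp
  pos <- matrix(0, n, 3)
  dir <- random_unit_vec()
  for (i in 2:n) {
    best <- NULL
    for (try in 1:50) {
      d <- unit_vec((1 - kappa) * dir + kappa * random_unit_vec())
      cand <- pos[i - 1, ] + b * d
      rad <- vec_norm(cand)
      if (is.null(best) || rad < best$rad) best <- list(p = cand, d = d, rad = rad)
      if (rad <= r_conf) break
    }
    pos[i, ] <- best$p
    dir <- best$d
  }
  pos
}

# Rigid 3-point water at position o with first O-H along e1.
water_atoms <- function(o, e1, e2, mol_id) {
  ang <- WATER_ANGLE * pi / 180
  h1 <- o + WATER_OH * e1
  h2 <- o + WATER_OH * (cos(ang) * e1 + sin(ang) * e2)
  data.frame(element = c("O", "H", "H"),
             x = c(o[1], h1[1], h2[1]),
             y = c(o[2], h1[2], h2[2]),
             z = c(o[3], h1[3], h2[3]),
             mass = c(15.999, 1.008, 1.008),
             molecule_id = mol_id,
             role = "solvent")
}

# A unit vector perpendicular to v, rotated by angle phi about v.
perp_vec <- function(v, phi) {
  v <- unit_vec(v)
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit_vec(a - sum(a * v) * v)
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  cos(phi) * e1 + sin(phi) * e2
}

min_dist_to <- function(point, mat) {
  if (is.null(mat) || nrow(mat) == 0) return(Inf)
  min(row_norms(sweep(mat, 2, point)))
}

# Build one frame's geometry; internal, called by generate_chain_frame with
# retry-on-verification-failure semantics.
build_chain_frame <- function(spec, time) {
  n <- spec$n_units
  b <- spec$bond_length
  pos <- chain_positions(n, b, spec$kappa)
  pos <- sweep(pos, 2, colMeans(pos))            # COM at origin
  pos <- sweep(pos, 2, rep(spec$box / 2, 3), `+`)  # then at box center

  atoms <- list()
  bonds <- list()
  unit_row <- integer(n)  # atom index of each chain unit
  row_count <- 0L

  add_atoms <- function(df) {
    atoms[[length(atoms) + 1]] <<- df
    first <- row_count + 1L
    row_count <<- row_count + nrow(df)
    first
  }

  # intra hydrogen bonds: donor H on unit a aimed at a side-group acceptor
  # oxygen placed 2.9 A from the donor unit along the same direction
  intra_targets <- if (spec$n_intra_hbonds > 0) {
    if (n < 4) stop("intra hydrogen bonds need at least 4 units")
    donors <- 1 + (seq_len(spec$n_intra_hbonds) - 1L) %% (n - 2L) + 1L
    donors
  } else integer(0)

  for (i in seq_len(n)) {
    unit_row[i] <- add_atoms(data.frame(
      element = "OU", x = pos[i, 1], y = pos[i, 2], z = pos[i, 3],
      mass = UNIT_MASS, molecule_id = "chain1", role = "solute"))
    if (i > 1) bonds[[length(bonds) + 1]] <- c(unit_row[i - 1], unit_row[i])
    for (k in which(intra_targets == i)) {
      placed <- FALSE
      for (try in 1:60) {
        dirv <- random_unit_vec()
        h <- pos[i, ] + WATER_OH * dirv
        os <- pos[i, ] + 2.9 * dirv
        other_units <- pos[-i, , drop = FALSE]
        if (min_dist_to(os, other_units) > 3.6 &&
            min_dist_to(h, other_units) > 2.6) {
          hrow <- add_atoms(data.frame(
            element = "H", x = h[1], y = h[2], z = h[3],
            mass = 1.008, molecule_id = "chain1", role = "solute"))
          add_atoms(data.frame(
            element = "O", x = os[1], y = os[2], z = os[3],
            mass = 15.999, molecule_id = "chain1", role = "solute"))
          bonds[[length(bonds) + 1]] <- c(unit_row[i], hrow)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place an intra hydrogen bond; lower kappa or unit count")
    }
  }

  all_coords <- function() {
    df <- do.call(rbind, atoms)
    as.matrix(df[, c("x", "y", "z")])
  }

  # bridging waters: O placed off the midpoint of an adjacent unit pair so
  # both O-H arms reach their units at 3.0 A with 180-degree D-H-A angles
  bridge_ids <- character(0)
  if (spec$n_bridge_waters > 0) {
    d_target <- 3.0
    for (j in seq_len(spec$n_bridge_waters)) {
      i <- (j - 1L) %% (n - 1L) + 1L
      u1 <- pos[i, ]; u2 <- pos[i + 1, ]
      axis <- u2 - u1
      l <- vec_norm(axis)
      if (d_target <= l / 2) stop("units too far apart to bridge")
      h_off <- sqrt(d_target^2 - (l / 2)^2)
      mid <- (u1 + u2) / 2
      placed <- FALSE
      for (try in 1:60) {
        phi <- stats::runif(1, 0, 2 * pi)
        o <- mid + h_off * perp_vec(axis, phi)
        if (min_dist_to(o, all_coords()) >= 2) {
          e1 <- unit_vec(u1 - o)
          e2 <- unit_vec(u2 - o)
          mol <- sprintf("bw%d", j)
          orow <- add_atoms(data.frame(
            element = c("O", "H", "H"),
            x = c(o[1], (o + WATER_OH * e1)[1], (o + WATER_OH * e2)[1]),
            y = c(o[2], (o + WATER_OH * e1)[2], (o + WATER_OH * e2)[2]),
            z = c(o[3], (o + WATER_OH * e1)[3], (o + WATER_OH * e2)[3]),
            mass = c(15.999, 1.008, 1.008),
            molecule_id = mol, role = "solvent"))
          bonds[[length(bonds) + 1]] <- c(orow, orow + 1L)
          bonds[[length(bonds) + 1]] <- c(orow, orow + 2L)
          bridge_ids <- c(bridge_ids, mol)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place a bridging water; use a larger box or fewer bridges")
    }
  }

  # bulk waters: uniform in the box, >= 4.5 A from solute (outside
  # hydrogen-bonding range of the chain) and >= 2 A from everything
  if (spec$n_bulk_waters > 0) {
    solute_mat <- all_coords()[seq_len(row_count)[
      do.call(rbind, atoms)$role == "solute"], , drop = FALSE]
    for (j in seq_len(spec$n_bulk_waters)) {
      placed <- FALSE
      for (try in 1:200) {
        o <- stats::runif(3, 0, spec$box)
        if (min_dist_to(o, solute_mat) >= 4.5 &&
            min_dist_to(o, all_coords()) >= 2) {
          e1 <- random_unit_vec()
          e2 <- perp_vec(e1, stats::runif(1, 0, 2 * pi))
          orow <- add_atoms(water_atoms(o, e1, e2, sprintf("w%d", j)))
          bonds[[length(bonds) + 1]] <- c(orow, orow + 1L)
          bonds[[length(bonds) + 1]] <- c(orow, orow + 2L)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place a bulk water; use a larger box")
    }
  }

  molecular_frame(
    do.call(rbind, atoms),
    bonds = if (length(bonds)) do.call(rbind, bonds) else NULL,
    time = time,
    metadata = list(spec = spec, bridge_molecules = bridge_ids))
}

#' Generate a solvated single-chain frame
#'
#' Builds the geometry and then verifies it against [detect_hbonds()] at the
#' default criteria: the frame must contain exactly `n_intra_hbonds`
#' intramolecular bonds and `2 * n_bridge_waters` solute-water bonds, all of
#' the latter involving bridge waters.  Failed geometries (possible for
#' crowded, collapsed chains) are rebuilt deterministically up to 20 times.
#'
#' @param spec A [synthetic_frame_spec()].
#' @param time Frame time stamp, ns.
#' @param seed Seed override (defaults to `spec$seed`).
#' @return A verified [molecular_frame()]; `metadata$bridge_molecules` lists
#'   the bridge water molecule ids.
#' @export
generate_chain_frame <- function(spec, time = 0, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_frame_spec"))
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  last_err <- NULL
  for (attempt in 1:20) {
    frame <- tryCatch(build_chain_frame(spec, time), error = identity)
    if (inherits(frame, "error")) { last_err <- frame; next }
    rec <- detect_hbonds(frame)
    counts <- classify_hbonds(rec)
    inter_ok <- counts[["inter"]] == 2L * spec$n_bridge_waters &&
      all(rec$donor_molecule[rec$class == "inter"] %in%
            frame$metadata$bridge_molecules)
    if (counts[["intra"]] == spec$n_intra_hbonds && inter_ok) return(frame)
    last_err <- simpleError("hydrogen-bond verification failed")
  }
  stop(sprintf("could not generate a valid frame after 20 attempts (%s); use a larger box",
               conditionMessage(last_err)))
}

#' Generate an independent frame series
#'
#' Frames are generated from per-frame seeds derived deterministically from
#' the spec's master seed, emulating statistically independent snapshots of
#' an equilibrated trajectory.
#'
#' @param spec A [synthetic_frame_spec()]; `spec$n_frames` frames are built.
#' @return List of [molecular_frame()] objects with times spanning 0-20 ns.
#' @export
generate_frame_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_frame_spec"))
  old <- set_local_seed(spec$seed)
  frame_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_frames)
  restore_seed(old)
  times <- if (spec$n_frames == 1) 0 else
    seq(0, 20, length.out = spec$n_frames)
  lapply(seq_len(spec$n_frames), function(i) {
    generate_chain_frame(spec, time = times[i], seed = frame_seeds[i])
  })
}
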