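# Shared fixtures built in code.

# A quick noiseless synthetic ensemble for a given delta_g (k_BT).
noiseless_ensemble <- function(delta_g, n_curves = 3, seed = 1,
                               samples = 300) {
  spec <- synthetic_curve_spec(
    params = two_state_parameters(delta_g = delta_g),
    n_curves = n_curves, noise_sd = 0,
    samples_per_curve = samples, seed = seed)
  generate_fec(spec)
}

normalized_ensemble <- function(delta_g, ...) {
  lapply(noiseless_ensemble(delta_g, ...), normalize_curve)
}

# A bare frame from an atom table (element, xyz, mass, molecule, role rows).
frame_from_rows <- function(..., bonds = NULL) {
  rows <- list(...)
  atoms <- do.call(rbind, lapply(rows, function(r) {
    data.frame(element = r[[1]], x = r[[2]], y = r[[3]], z = r[[4]],
               mass = r[[5]], molecule_id = r[[6]], role = r[[7]])
  }))
  molecular_frame(atoms, bonds = bonds)
}

# Water donating one O-H toward an acceptor oxygen at distance `dist` with
# D-H-A angle `angle_deg`; acceptor belongs to the solute.
water_donor_fixture <- function(dist = 2.8, angle_deg = 170) {
  o <- c(0, 0, 0)
  h1 <- c(0.96, 0, 0)
  h2 <- c(-0.24, -0.93, 0)  # second O-H arm pointing away
  # place acceptor so that |O-A| = dist and the angle at h1 is angle_deg
  theta <- (180 - angle_deg) * pi / 180  # off the +x axis at the hydrogen
  u <- c(cos(theta), sin(theta), 0)
  # solve |h1 + d*u| = dist for d > 0
  b <- 2 * sum(h1 * u); cc <- sum(h1^2) - dist^2
  d <- (-b + sqrt(b^2 - 4 * cc)) / 2
  a <- h1 + d * u
  frame_from_rows(
    list("O", o[1], o[2], o[3], 15.999, "w1", "solvent"),
    list("H", h1[1], h1[2], h1[3], 1.008, "w1", "solvent"),
    list("H", h2[1], h2[2], h2[3], 1.008, "w1", "solvent"),
    list("O", a[1], a[2], a[3], 15.999, "chain1", "solute"),
    list("C", a[1] + 5, a[2], a[3], 12.011, "chain1", "solute"),
    bonds = rbind(c(1, 2), c(1, 3)))
}

# Random rigid motion applied to a frame (rotation + translation).
random_rigid_motion <- function(frame) {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  t <- stats::rnorm(3, 0, 10)
  r <- as.matrix(frame$atoms[, c("x", "y", "z")]) %*% q
  frame$atoms$x <- r[, 1] + t[1]
  frame$atoms$y <- r[, 2] + t[2]
  frame$atoms$z <- r[, 3] + t[3]
  frame
}

# A frame of random atoms with random masses (single solute molecule).
random_frame <- function(n = 30) {
  molecular_frame(data.frame(
    element = "C",
    x = stats::rnorm(n, 0, 5), y = stats::rnorm(n, 0, 5),
    z = stats::rnorm(n, 0, 5),
    mass = stats::runif(n, 1, 20),
    molecule_id = "m1", role = "solute"))
}

# Independent pairwise-sum oracle for the radius of gyration:
# Rg^2 = sum_ij m_i m_j |r_i - r_j|^2 / (2 (sum m)^2)
rg_pairwise_oracle <- function(frame) {
  m <- frame$atoms$mass
  r <- as.matrix(frame$atoms[, c("x", "y", "z")])
  n <- length(m)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- acc + m[i] * m[j] * sum((r[i, ] - r[j, ])^2)
    }
  }
  sqrt(acc / (2 * sum(m)^2))
}
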