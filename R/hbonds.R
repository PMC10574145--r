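# Geometric hydrogen-bond detection and intra/intermolecular classification.
# Donors: N/O heavy atoms with a covalently bonded hydrogen (bond list, or
# inferred from a 1.25 A distance cutoff).  Acceptors: all N/O atoms.

#' Hydrogen-bond geometric criteria
#'
#' Conventional MD-analysis defaults: donor-acceptor distance at most 3.5 A
#' and donor-hydrogen-acceptor angle at least 130 degrees.
#'
#' @param max_da_distance Maximum donor-acceptor distance, Angstrom.
#' @param min_dha_angle Minimum D-H-A angle, degrees, in (0, 180].
#' @return A list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_distance = 3.5, min_dha_angle = 130) {
  stopifnot(max_da_distance > 0,
            min_dha_angle > 0, min_dha_angle <= 180)
  structure(list(max_da_distance = max_da_distance,
                 min_dha_angle = min_dha_angle),
            class = "hbond_criteria")
}

is_no_like <- function(element) {
  substr(toupper(element), 1, 1) %in% c("N", "O")
}

is_hydrogen <- function(element) toupper(element) == "H"

# Covalent donor-hydrogen attachments: from the frame's bond list when
# present, else inferred by a 1.25 A heavy-atom-to-H distance cutoff.
donor_hydrogen_pairs <- function(frame) {
  a <- frame$atoms
  h_idx <- which(is_hydrogen(a$element))
  if (length(h_idx) == 0) return(matrix(integer(0), ncol = 2))
  heavy_no <- which(is_no_like(a$element))
  if (!is.null(frame$bonds)) {
    b <- frame$bonds
    hb <- rbind(b, b[, 2:1, drop = FALSE])
    keep <- hb[, 2] %in% h_idx & hb[, 1] %in% heavy_no
    return(hb[keep, , drop = FALSE])
  }
  if (length(heavy_no) == 0) {
    stop("no N/O atoms to attach hydrogens to; supply a bond list")
  }
  r <- coords_matrix(frame)
  pairs <- matrix(integer(0), ncol = 2)
  unattached <- 0L
  for (h in h_idx) {
    d2 <- rowSums(sweep(r[heavy_no, , drop = FALSE], 2, r[h, ])^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) <= 1.25) {
      pairs <- rbind(pairs, c(heavy_no[j], h))
    } else {
      unattached <- unattached + 1L
    }
  }
  if (unattached == length(h_idx)) {
    stop("could not infer any donor-hydrogen attachment; supply a bond list")
  }
  pairs
}

#' Detect hydrogen bonds in a molecular frame
#'
#' Enumerates all (donor, hydrogen, acceptor) triples satisfying the
#' geometric criteria, excluding the donor itself and atoms covalently
#' bonded to the donor.  Records are classified as `intra` (donor and
#' acceptor both solute), `inter` (exactly one side solute; solvent and ion
#' partners both count) or `solvent` (no solute involvement), and ordered by
#' (donor, acceptor) index.
#'
#' @param frame A [molecular_frame()]; hydrogens must be attachable to N/O
#'   donors via the bond list or the 1.25 A inference rule.
#' @param criteria An [hbond_criteria()].
#' @return Data frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `distance`, `angle`, `class`, plus donor/acceptor molecule ids.
#' @export
detect_hbonds <- function(frame, criteria = hbond_criteria()) {
  a <- frame$atoms
  r <- coords_matrix(frame)
  dh <- donor_hydrogen_pairs(frame)
  acceptors <- which(is_no_like(a$element))
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0), class = character(0),
                      donor_molecule = character(0),
                      acceptor_molecule = character(0))
  if (nrow(dh) == 0 || length(acceptors) == 0) return(empty)

  covalent <- if (!is.null(frame$bonds)) {
    rbind(frame$bonds, frame$bonds[, 2:1, drop = FALSE])
  } else NULL

  recs <- vector("list", nrow(dh))
  for (k in seq_len(nrow(dh))) {
    d <- dh[k, 1]; h <- dh[k, 2]
    cand <- setdiff(acceptors, d)
    if (!is.null(covalent)) {
      bonded_to_d <- covalent[covalent[, 1] == d, 2]
      cand <- setdiff(cand, bonded_to_d)
    }
    if (length(cand) == 0) next
    dvec <- sweep(r[cand, , drop = FALSE], 2, r[d, ])
    dist_da <- row_norms(dvec)
    ok <- dist_da <= criteria$max_da_distance & dist_da > 1e-6
    if (!any(ok)) next
    cand <- cand[ok]; dist_da <- dist_da[ok]
    hd <- r[d, ] - r[h, ]
    ha <- sweep(r[cand, , drop = FALSE], 2, r[h, ])
    # D-H-A angle at the hydrogen, between H->D and H->A
    cosang <- (ha %*% hd) / (row_norms(ha) * vec_norm(hd))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    ok2 <- ang >= criteria$min_dha_angle
    if (!any(ok2)) next
    cand <- cand[ok2]
    recs[[k]] <- data.frame(donor = d, hydrogen = h, acceptor = cand,
                            distance = dist_da[ok2], angle = ang[ok2])
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0) return(empty)
  out <- do.call(rbind, recs)
  d_solute <- a$role[out$donor] == "solute"
  a_solute <- a$role[out$acceptor] == "solute"
  out$class <- ifelse(d_solute & a_solute, "intra",
                      ifelse(xor(d_solute, a_solute), "inter", "solvent"))
  out$donor_molecule <- as.character(a$molecule_id[out$donor])
  out$acceptor_molecule <- as.character(a$molecule_id[out$acceptor])
  out[order(out$donor, out$acceptor), , drop = FALSE]
}

#' Count intra- and intermolecular hydrogen bonds
#'
#' `intra`: donor and acceptor heavy atoms both in a solute molecule;
#' `inter`: exactly one side solute.  Solvent-solvent records are excluded
#' from both counts.
#'
#' @param records Output of [detect_hbonds()].
#' @return Named integer vector `c(intra = ..., inter = ...)`.
#' @export
classify_hbonds <- function(records) {
  c(intra = sum(records$class == "intra"),
    inter = sum(records$class == "inter"))
}

#' Hydrogen-bond counts and inter:intra ratio over a frame series
#'
#' @param frames List of [molecular_frame()] objects.
#' @param criteria An [hbond_criteria()].
#' @return A list with the per-frame count table, `mean_intra`,
#'   `mean_inter`, and `ratio` = mean inter / mean intra (`Inf` when the
#'   intra mean is 0 and inter is positive; `NaN` when both are 0).
#' @export
hbond_ratio_over_frames <- function(frames, criteria = hbond_criteria()) {
  if (inherits(frames, "molecular_frame")) frames <- list(frames)
  if (length(frames) < 1) stop("need at least one frame")
  counts <- t(vapply(frames, function(fr) {
    classify_hbonds(detect_hbonds(fr, criteria))
  }, c(intra = 0L, inter = 0L)))
  per_frame <- data.frame(frame = seq_len(nrow(counts)),
                          intra = counts[, "intra"],
                          inter = counts[, "inter"])
  per_frame$ratio <- ifelse(per_frame$intra > 0,
                            per_frame$inter / per_frame$intra, Inf)
  mi <- mean(per_frame$intra); me <- mean(per_frame$inter)
  list(per_frame = per_frame,
       mean_intra = mi, mean_inter = me,
       ratio = if (mi > 0) me / mi else if (me > 0) Inf else NaN)
}
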