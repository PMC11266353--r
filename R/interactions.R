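# Geometric detection of hydrogen bonds and aromatic pi-pi interactions.
#
# Neither criterion set is force-field derived: the hydrogen-bond thresholds
# follow the common geometric convention (H...A <= 2.5 A, D-H...A >= 120 deg,
# D...A <= 3.5 A) and the pi-pi thresholds (ring-COM distance <= 7 A,
# parallel <= 30 deg, T-shaped >= 60 deg) are chosen so a ~5 A,
# near-perpendicular aromatic pair classifies as T-shaped. Both are
# configurable and documented as assumptions.

#' Hydrogen-bond geometric criteria
#'
#' @param max_ha maximum H...acceptor distance (Angstrom, default 2.5).
#' @param min_angle minimum donor-H...acceptor angle (degrees, default 120).
#' @param max_da maximum donor...acceptor distance (Angstrom, default 3.5).
#' @return list of class `"hbond_criteria"`.
#' @export
hbond_criteria <- function(max_ha = 2.5, min_angle = 120, max_da = 3.5) {
  stopifnot(max_ha > 0, max_da > 0, min_angle >= 0, min_angle <= 180)
  structure(list(max_ha = max_ha, min_angle = min_angle, max_da = max_da),
            class = "hbond_criteria")
}

#' Aromatic pi-pi geometric criteria
#'
#' @param max_dist maximum ring COM-COM distance (Angstrom, default 7.0).
#' @param parallel_max interplanar angle at or below which the pair is
#'   parallel (degrees, default 30).
#' @param tshaped_min interplanar angle at or above which the pair is
#'   T-shaped (degrees, default 60); angles in between are oblique.
#' @return list of class `"pipi_criteria"`.
#' @export
pipi_criteria <- function(max_dist = 7.0, parallel_max = 30, tshaped_min = 60) {
  stopifnot(max_dist > 0, parallel_max >= 0, tshaped_min <= 90,
            parallel_max < tshaped_min)
  structure(list(max_dist = max_dist, parallel_max = parallel_max,
                 tshaped_min = tshaped_min), class = "pipi_criteria")
}

# Donor-H pairs: N/O heavy atoms with a hydrogen within `attach` Angstrom in
# the given frame (PDB input has no bond records, so attachment is geometric).
.donor_hydrogens <- function(top, xyz, box, attach = 1.2) {
  a <- top$atoms
  dh <- which(toupper(a$element) %in% c("N", "O") & !a$is_hydrogen)
  hy <- which(a$is_hydrogen)
  if (!length(dh) || !length(hy)) return(cbind(donor = integer(0), hydrogen = integer(0)))
  D <- .pair_dist_matrix(xyz[dh, , drop = FALSE], xyz[hy, , drop = FALSE], box)
  hit <- which(D <= attach, arr.ind = TRUE)
  cbind(donor = dh[hit[, 1]], hydrogen = hy[hit[, 2]])
}

#' Detect hydrogen bonds in one frame
#'
#' All N/O donors carrying a hydrogen (attachment: H within 1.2 Angstrom of
#' the heavy atom) are tested against all N/O acceptors. A record is emitted
#' when H...A and D...A distances and the D-H...A angle satisfy the criteria;
#' donor and acceptor in the same residue are never paired. Requires explicit
#' hydrogens in the topology.
#'
#' @param traj an [md_trajectory()].
#' @param frame 1-based frame index.
#' @param criteria an [hbond_criteria()].
#' @return data.frame with one row per hydrogen bond: `frame`, `donor`,
#'   `hydrogen`, `acceptor` (atom indices), `donor_res`, `acceptor_res`
#'   (residue serial indices), `dist_ha`, `dist_da` (Angstrom), `angle`
#'   (degrees).
#' @export
detect_hbonds <- function(traj, frame, criteria = hbond_criteria()) {
  stopifnot(inherits(criteria, "hbond_criteria"))
  top <- traj$topology
  if (!any(top$atoms$is_hydrogen))
    stop("topology contains no hydrogens: hydrogen-bond analysis needs explicit hydrogens")
  xyz <- frame_coords(traj, frame)
  box <- traj$box
  dh <- .donor_hydrogens(top, xyz, box)
  empty <- data.frame(frame = integer(0), donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), donor_res = integer(0),
                      acceptor_res = integer(0), dist_ha = numeric(0),
                      dist_da = numeric(0), angle = numeric(0))
  if (!nrow(dh)) return(empty)
  acc <- which(toupper(top$atoms$element) %in% c("N", "O") & !top$atoms$is_hydrogen)
  Dha <- .pair_dist_matrix(xyz[dh[, "hydrogen"], , drop = FALSE],
                           xyz[acc, , drop = FALSE], box)
  Dda <- .pair_dist_matrix(xyz[dh[, "donor"], , drop = FALSE],
                           xyz[acc, , drop = FALSE], box)
  resid <- top$atoms$resid
  same_res <- outer(resid[dh[, "donor"]], resid[acc], "==")
  same_atom <- outer(dh[, "donor"], acc, "==")
  cand <- which(Dha <= criteria$max_ha & Dda <= criteria$max_da &
                  !same_res & !same_atom, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  di <- dh[cand[, 1], "donor"]; hi <- dh[cand[, 1], "hydrogen"]; ai <- acc[cand[, 2]]
  # D-H...A angle at the hydrogen (minimum-image displacement vectors)
  v1 <- xyz[di, , drop = FALSE] - xyz[hi, , drop = FALSE]
  v2 <- xyz[ai, , drop = FALSE] - xyz[hi, , drop = FALSE]
  if (!is.null(box)) {
    for (k in 1:3) {
      v1[, k] <- v1[, k] - box[k] * round(v1[, k] / box[k])
      v2[, k] <- v2[, k] - box[k] * round(v2[, k] / box[k])
    }
  }
  cosang <- rowSums(v1 * v2) / sqrt(rowSums(v1^2) * rowSums(v2^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  keep <- ang >= criteria$min_angle
  if (!any(keep)) return(empty)
  out <- data.frame(frame = as.integer(frame), donor = di[keep],
                    hydrogen = hi[keep], acceptor = ai[keep],
                    donor_res = resid[di[keep]], acceptor_res = resid[ai[keep]],
                    dist_ha = Dha[cand][keep], dist_da = Dda[cand][keep],
                    angle = ang[keep], row.names = NULL)
  out[order(out$donor, out$acceptor), , drop = FALSE]
}

# Built-in aromatic ring templates: residue name -> list of atom-name vectors.
.RING_TEMPLATES <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CE2", "CD2", "CE3", "CZ3", "CH2", "CZ2")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  HID = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  HIE = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  HIP = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  # FLK: this package's name for a phenylalanine-conjugated lysine side
  # chain; its phenyl ring uses PHE-style atom names
  FLK = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")))

#' Find aromatic rings in a topology
#'
#' Standard templates cover PHE/TYR (6-ring), TRP (5- and 6-ring) and
#' HIS/HID/HIE/HIP (5-ring). Nonstandard aromatic residues (e.g. a lysine
#' side chain conjugated to phenylalanine) are matched through
#' `extra_templates`. Rings with missing atoms are skipped with a warning.
#'
#' @param top a `topology`.
#' @param extra_templates named list: residue name -> list of atom-name
#'   vectors (each of length 5 or 6) describing additional ring templates.
#' @return list of rings, each a list with `residue` (serial index),
#'   `resname`, `atom_names`, `atoms` (atom indices).
#' @export
find_aromatic_rings <- function(top, extra_templates = NULL) {
  stopifnot(inherits(top, "topology"))
  templates <- .RING_TEMPLATES
  if (!is.null(extra_templates)) templates[names(extra_templates)] <- extra_templates
  rings <- list()
  a <- top$atoms; r <- top$residues
  for (ri in seq_len(nrow(r))) {
    tpl <- templates[[r$name[ri]]]
    if (is.null(tpl)) next
    ridx <- r$first_atom[ri]:r$last_atom[ri]
    nm <- trimws(a$name[ridx])
    for (atoms_needed in tpl) {
      if (!(length(atoms_needed) %in% c(5L, 6L)))
        stop("ring templates must have 5 or 6 atoms")
      pos <- match(atoms_needed, nm)
      if (anyNA(pos)) {
        warning("residue ", r$name[ri], " ", r$chain[ri], r$resno[ri],
                " missing ring atom(s) ", paste(atoms_needed[is.na(pos)], collapse = ","),
                "; ring skipped")
        next
      }
      ai <- ridx[pos]
      if (any(a$is_hydrogen[ai])) {
        warning("ring template matched hydrogen atoms; ring skipped")
        next
      }
      rings[[length(rings) + 1L]] <- list(residue = ri, resname = r$name[ri],
                                          atom_names = atoms_needed, atoms = ai)
    }
  }
  rings
}

#' Classify a pi-pi interaction between two rings in one frame
#'
#' Computes the ring center-of-mass distance and the unsigned interplanar
#' angle (folded to [0, 90] degrees). Returns NULL beyond the distance
#' cutoff; otherwise the pair is `parallel` (angle <= parallel_max),
#' `T-shaped` (angle >= tshaped_min) or `oblique`.
#'
#' @param ring_a,ring_b ring descriptors from [find_aromatic_rings()], from
#'   distinct residues.
#' @param traj an [md_trajectory()].
#' @param frame 1-based frame index.
#' @param criteria a [pipi_criteria()].
#' @return one-row data.frame (`frame`, `res_a`, `res_b`, `dist`, `angle`,
#'   `class`) or NULL.
#' @export
classify_pipi <- function(ring_a, ring_b, traj, frame, criteria = pipi_criteria()) {
  stopifnot(inherits(criteria, "pipi_criteria"))
  if (ring_a$residue == ring_b$residue)
    stop("pi-pi classification requires rings from distinct residues")
  top <- traj$topology
  xyz <- frame_coords(traj, frame)
  ca <- xyz[ring_a$atoms, , drop = FALSE]
  cb <- xyz[ring_b$atoms, , drop = FALSE]
  ma <- element_mass(top$atoms$element[ring_a$atoms])
  mb <- element_mass(top$atoms$element[ring_b$atoms])
  da <- minimum_image_distance(center_of_mass(ca, ma), center_of_mass(cb, mb),
                               traj$box)
  if (da > criteria$max_dist) return(NULL)
  ang <- .interplanar_angle(ring_plane_normal(ca), ring_plane_normal(cb))
  cls <- if (ang <= criteria$parallel_max) "parallel"
         else if (ang >= criteria$tshaped_min) "T-shaped"
         else "oblique"
  data.frame(frame = as.integer(frame),
             res_a = min(ring_a$residue, ring_b$residue),
             res_b = max(ring_a$residue, ring_b$residue),
             dist = da, angle = ang, class = cls, stringsAsFactors = FALSE)
}

#' Detect all pi-pi interactions in one frame
#'
#' @param traj an [md_trajectory()].
#' @param frame 1-based frame index.
#' @param criteria a [pipi_criteria()].
#' @param rings optional precomputed ring list; default
#'   `find_aromatic_rings(traj$topology)`.
#' @return data.frame of pi-pi records (possibly zero rows).
#' @export
detect_pipi <- function(traj, frame, criteria = pipi_criteria(), rings = NULL) {
  if (is.null(rings)) rings <- find_aromatic_rings(traj$topology)
  recs <- list()
  if (length(rings) >= 2L) {
    for (i in seq_len(length(rings) - 1L)) {
      for (j in (i + 1L):length(rings)) {
        if (rings[[i]]$residue == rings[[j]]$residue) next
        r <- classify_pipi(rings[[i]], rings[[j]], traj, frame, criteria)
        if (!is.null(r)) recs[[length(recs) + 1L]] <- r
      }
    }
  }
  if (!length(recs))
    return(data.frame(frame = integer(0), res_a = integer(0), res_b = integer(0),
                      dist = numeric(0), angle = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  do.call(rbind, recs)
}

#' Count hydrogen bonds and pi-pi interactions over a trajectory
#'
#' @param traj an [md_trajectory()].
#' @param hbond an [hbond_criteria()].
#' @param pipi a [pipi_criteria()].
#' @param ring_templates optional extra ring templates passed to
#'   [find_aromatic_rings()].
#' @return object of class `"interaction_counts"`: data.frame with columns
#'   `frame`, `n_hbond`, `n_pipi` and attributes `mean_hbond`, `mean_pipi`.
#' @export
count_interactions <- function(traj, hbond = hbond_criteria(),
                               pipi = pipi_criteria(), ring_templates = NULL) {
  rings <- find_aromatic_rings(traj$topology, ring_templates)
  nf <- n_frames(traj)
  nh <- np <- integer(nf)
  for (f in seq_len(nf)) {
    nh[f] <- nrow(detect_hbonds(traj, f, hbond))
    np[f] <- nrow(detect_pipi(traj, f, pipi, rings))
  }
  structure(data.frame(frame = seq_len(nf), n_hbond = nh, n_pipi = np),
            class = c("interaction_counts", "data.frame"),
            mean_hbond = mean(nh), mean_pipi = mean(np))
}

#' @export
print.interaction_counts <- function(x, ...) {
  cat(sprintf("interaction_counts: %d frame(s); mean %.2f H-bond(s), %.2f pi-pi per frame\n",
              nrow(x), attr(x, "mean_hbond"), attr(x, "mean_pipi")))
  invisible(x)
}
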