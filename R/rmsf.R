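# Trajectory superposition and per-residue root-mean-square fluctuation.

# Resolve an atom-selection keyword to atom indices.
#  "calpha" - one CA per residue; "heavy" - all non-hydrogen atoms;
#  "all" - every atom; an integer vector is taken as atom indices.
.selection_atoms <- function(top, selection) {
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (any(idx < 1L | idx > nrow(top$atoms))) stop("atom index out of range")
    return(idx)
  }
  switch(match.arg(selection, c("calpha", "heavy", "all")),
         calpha = { i <- calpha_atoms(top); i[!is.na(i)] },
         heavy = heavy_atoms(top),
         all = seq_len(nrow(top$atoms)))
}

#' Remove global rigid-body motion by superposition
#'
#' Every frame is superposed (unit-weight Kabsch fit on the selection atoms)
#' onto the mean structure; the mean is then recomputed from the aligned
#' frames and the alignment repeated once (two passes). The fitted transform
#' is applied to all atoms.
#'
#' @param traj an [md_trajectory()].
#' @param selection `"calpha"` (default), `"heavy"`, `"all"`, or an integer
#'   vector of atom indices; must resolve to at least 3 atoms.
#' @return aligned [md_trajectory()] (box dropped: coordinates are no longer
#'   wrapped consistently after superposition).
#' @export
align_trajectory <- function(traj, selection = "calpha") {
  stopifnot(inherits(traj, "md_trajectory"))
  sel <- .selection_atoms(traj$topology, selection)
  if (length(sel) < 3L) stop("alignment selection must contain at least 3 atoms")
  coords <- traj$coords
  nf <- dim(coords)[3]
  for (pass in 1:2) {
    ref <- apply(coords[sel, , , drop = FALSE], c(1, 2), mean)
    for (f in seq_len(nf)) {
      fit <- kabsch_superpose(coords[sel, , f, drop = TRUE], ref)
      coords[, , f] <- apply_fit(fit, coords[, , f, drop = TRUE])
    }
  }
  md_trajectory(traj$topology, coords, box = NULL)
}

#' Per-residue root-mean-square fluctuation
#'
#' For each residue, RMSF = sqrt(mean over frames of the squared displacement
#' of its selection atom(s) from their time-mean position). Multi-atom
#' selections combine atoms by the mass-weighted mean of per-atom squared
#' RMSF. The trajectory should already be aligned (see
#' [align_trajectory()]); residues lacking a selection atom get NA and are
#' flagged.
#'
#' @param traj an aligned [md_trajectory()].
#' @param selection `"calpha"` (default) or `"heavy"`.
#' @return object of class `"rmsf_profile"`: data.frame with columns
#'   `serial_index`, `chain`, `resno`, `resname`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, selection = "calpha") {
  stopifnot(inherits(traj, "md_trajectory"))
  top <- traj$topology
  selection <- match.arg(selection, c("calpha", "heavy"))
  coords <- traj$coords
  mean_xyz <- apply(coords, c(1, 2), mean)
  # per-atom mean squared displacement from the time-mean position
  msd <- rowMeans(apply(coords, 3, function(fr) rowSums((fr - mean_xyz)^2)))
  R <- n_residues(traj)
  out <- numeric(R)
  a <- top$atoms
  for (ri in seq_len(R)) {
    rng <- top$residues$first_atom[ri]:top$residues$last_atom[ri]
    if (selection == "calpha") {
      idx <- rng[trimws(a$name[rng]) == "CA" & !a$is_hydrogen[rng]]
    } else {
      idx <- rng[!a$is_hydrogen[rng]]
    }
    if (!length(idx)) {
      out[ri] <- NA_real_
      warning("residue ", residue_labels(top)[ri], " lacks selection atom(s); RMSF set to NA")
    } else {
      w <- element_mass(a$element[idx])
      out[ri] <- sqrt(sum(w * msd[idx]) / sum(w))
    }
  }
  r <- top$residues
  structure(data.frame(serial_index = r$serial_index, chain = r$chain,
                       resno = r$resno, resname = r$name, rmsf = out,
                       stringsAsFactors = FALSE),
            class = c("rmsf_profile", "data.frame"),
            selection = selection, n_frames = n_frames(traj))
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("rmsf_profile (%s, %d frames): %d residues, mean %.3f A, max %.3f A at %s\n",
              attr(x, "selection"), attr(x, "n_frames"), nrow(x),
              mean(x$rmsf, na.rm = TRUE), max(x$rmsf, na.rm = TRUE),
              paste0(x$chain[which.max(x$rmsf)], x$resno[which.max(x$rmsf)])))
  invisible(x)
}

#' @export
plot.rmsf_profile <- function(x, ...) {
  graphics::plot(x$serial_index, x$rmsf, type = "l",
                 xlab = "residue serial index", ylab = "RMSF (A)", ...)
  invisible(x)
}

#' Write an RMSF profile as TSV
#' @param profile an `rmsf_profile`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_rmsf <- function(profile, path) {
  lines <- c("serial_index\tchain\tresnum\tresname\trmsf_A",
             sprintf("%d\t%s\t%d\t%s\t%.6g", profile$serial_index,
                     profile$chain, profile$resno, profile$resname,
                     profile$rmsf))
  writeLines(lines, path)
  invisible(path)
}
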