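#' @keywords internal
"_PACKAGE"

# Residue names treated as solvent/ions and dropped unless keep_solvent = TRUE.
.SOLVENT_NAMES <- c("HOH", "WAT", "TIP", "TIP3", "TP3", "SOL", "SPC",
                    "NA", "NA+", "CL", "CL-", "K", "K+", "MG", "CA2", "ZN")

# Standard atomic masses (Da) used for centers of mass.
.ATOMIC_MASS <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974, SE = 78.971, F = 18.998,
                  CL = 35.45, BR = 79.904, I = 126.904, FE = 55.845,
                  ZN = 65.38, MG = 24.305, `NA` = 22.990, K = 39.098)

#' Atomic mass lookup by element symbol
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in Da; unknown elements get 12.011 with a
#'   warning (treated as carbon-like for COM purposes).
#' @export
element_mass <- function(element) {
  key <- toupper(trimws(element))
  m <- .ATOMIC_MASS[key]
  if (anyNA(m)) {
    warning("unknown element(s) ", paste(unique(key[is.na(m)]), collapse = ", "),
            "; using carbon mass")
    m[is.na(m)] <- 12.011
  }
  unname(m)
}

#' Construct a topology object
#'
#' A topology is the static atom/residue bookkeeping shared by all frames of a
#' trajectory: an ordered atom table, an ordered residue table with
#' chain-concatenated serial indices 1..R, and the chain list.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`, `resid`
#'   (1-based index into `residues`), `is_hydrogen`, `het`.
#' @param residues data.frame with columns `serial_index`, `name`, `chain`,
#'   `resno`, `first_atom`, `last_atom`.
#' @return an object of class `"topology"`.
#' @export
topology <- function(atoms, residues) {
  stopifnot(is.data.frame(atoms), is.data.frame(residues))
  need_a <- c("serial", "name", "element", "resid", "is_hydrogen", "het")
  need_r <- c("serial_index", "name", "chain", "resno", "first_atom", "last_atom")
  if (!all(need_a %in% names(atoms))) stop("atoms table missing columns")
  if (!all(need_r %in% names(residues))) stop("residues table missing columns")
  if (anyDuplicated(atoms$serial)) stop("atom serial numbers must be unique")
  if (any(!nzchar(atoms$element))) stop("every atom needs a non-empty element")
  if (!identical(residues$serial_index, seq_len(nrow(residues))))
    stop("residue serial_index must be 1..R in order")
  if (any(atoms$resid < 1 | atoms$resid > nrow(residues)))
    stop("atom residue index out of range")
  structure(list(atoms = atoms, residues = residues,
                 chains = unique(residues$chain)),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", nrow(x$atoms), "atoms,", nrow(x$residues), "residues,",
      length(x$chains), "chain(s) [", paste(x$chains, collapse = " "), "]\n")
  invisible(x)
}

#' Number of atoms in a topology or trajectory
#' @param x a `topology` or `md_trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "md_trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' Number of residues in a topology or trajectory
#' @param x a `topology` or `md_trajectory`.
#' @return integer residue count.
#' @export
n_residues <- function(x) {
  if (inherits(x, "md_trajectory")) x <- x$topology
  nrow(x$residues)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "md_trajectory"))
  dim(traj$coords)[3]
}

#' Chain-concatenated residue serial map
#'
#' Residues are numbered 1..R in file (chain-concatenated) order, independent
#' of gaps in author numbering. For an insulin-like topology with a 21-residue
#' A chain followed by a 30-residue B chain, A1 maps to 1, A21 to 21, B1 to 22
#' and B30 to 51.
#'
#' @param top a `topology`.
#' @return data.frame with columns `chain`, `resno`, `name`, `serial_index`;
#'   one row per residue in serial order.
#' @export
residue_serial_map <- function(top) {
  stopifnot(inherits(top, "topology"))
  r <- top$residues
  key <- paste(r$chain, r$resno)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (chain, residue number): ", dup)
  }
  data.frame(chain = r$chain, resno = r$resno, name = r$name,
             serial_index = r$serial_index, stringsAsFactors = FALSE)
}

#' Look up a residue serial index by chain and author number
#'
#' @param top a `topology`.
#' @param chain chain identifier.
#' @param resno author residue number as in the PDB file.
#' @return integer serial index (1..R).
#' @export
residue_serial <- function(top, chain, resno) {
  m <- residue_serial_map(top)
  i <- which(m$chain == chain & m$resno == resno)
  if (length(i) != 1L)
    stop("no residue ", chain, resno, " in topology")
  m$serial_index[i]
}

#' Residue labels of the form serial:chain:resnum:resname
#' @param top a `topology`.
#' @return character vector of length R.
#' @export
residue_labels <- function(top) {
  r <- top$residues
  paste(r$serial_index, r$chain, r$resno, r$name, sep = ":")
}

# Indices of heavy (non-hydrogen) atoms.
heavy_atoms <- function(top) which(!top$atoms$is_hydrogen)

# Indices of CA atoms in residue order; NA for residues lacking one.
calpha_atoms <- function(top) {
  a <- top$atoms
  idx <- rep(NA_integer_, nrow(top$residues))
  ca <- which(trimws(a$name) == "CA" & !a$is_hydrogen)
  idx[a$resid[ca]] <- ca
  idx
}

#' Construct a trajectory object
#'
#' @param top a `topology`.
#' @param coords numeric array of dimension N x 3 x F (atoms x xyz x frames),
#'   coordinates in Angstrom. A single N x 3 matrix is promoted to one frame.
#' @param box optional numeric(3) orthorhombic box lengths (Angstrom).
#' @return an object of class `"md_trajectory"`.
#' @export
md_trajectory <- function(top, coords, box = NULL) {
  stopifnot(inherits(top, "topology"))
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3L, 1L))
  d <- dim(coords)
  if (length(d) != 3L || d[2] != 3L) stop("coords must be N x 3 x F")
  if (d[1] != nrow(top$atoms)) stop("coordinate atom count does not match topology")
  if (d[3] < 1L) stop("trajectory needs at least one frame")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(box <= 0)) stop("box must be three positive lengths")
  }
  structure(list(topology = top, coords = coords, box = box),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", n_frames(x), "frame(s) of", n_atoms(x), "atoms,",
      n_residues(x), "residues",
      if (is.null(x$box)) "(no box)" else
        sprintf("(box %.2f x %.2f x %.2f A)", x$box[1], x$box[2], x$box[3]), "\n")
  invisible(x)
}

#' Extract one frame's coordinates
#' @param traj an `md_trajectory`.
#' @param frame 1-based frame index.
#' @return N x 3 coordinate matrix.
#' @export
frame_coords <- function(traj, frame) {
  stopifnot(inherits(traj, "md_trajectory"))
  f <- as.integer(frame)
  if (f < 1L || f > n_frames(traj)) stop("frame index out of range: ", frame)
  traj$coords[, , f, drop = TRUE]
}

#' Subset a trajectory by frame indices
#' @param traj an `md_trajectory`.
#' @param frames integer vector of frame indices to keep, in order.
#' @return a new `md_trajectory`.
#' @export
subset_frames <- function(traj, frames) {
  stopifnot(inherits(traj, "md_trajectory"))
  frames <- as.integer(frames)
  if (any(frames < 1L | frames > n_frames(traj))) stop("frame index out of range")
  md_trajectory(traj$topology, traj$coords[, , frames, drop = FALSE], traj$box)
}
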