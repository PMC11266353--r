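# Residue-residue heavy-atom contact analysis: per-frame contacts,
# trajectory-averaged contact-population maps, and difference maps between
# two systems.

#' Residue contacts in one frame
#'
#' Residues i and j (i < j) are in contact when ANY pair of their non-hydrogen
#' atoms lies within the cutoff (minimum-image when the trajectory carries a
#' box). Self-pairs are excluded; sequence-adjacent pairs are included.
#'
#' @param traj an [md_trajectory()].
#' @param frame 1-based frame index.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.5).
#' @return integer matrix with columns `i`, `j` of residue serial indices in
#'   contact (i < j); zero rows if none.
#' @export
frame_contacts <- function(traj, frame, cutoff = 4.5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  top <- traj$topology
  hv <- heavy_atoms(top)
  xyz <- frame_coords(traj, frame)[hv, , drop = FALSE]
  resid <- top$atoms$resid[hv]
  D <- .pair_dist_matrix(xyz, xyz, traj$box)
  hit <- which(D <= cutoff, arr.ind = TRUE)
  ri <- resid[hit[, 1]]; rj <- resid[hit[, 2]]
  sel <- ri < rj
  pairs <- unique(cbind(i = ri[sel], j = rj[sel]))
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

#' Trajectory-averaged contact-population map
#'
#' Entry (i, j) is the fraction of (strided) frames in which residues i and j
#' are in heavy-atom contact; graded from 1.0 (always) to 0.0 (never). The
#' matrix is symmetric with zero diagonal.
#'
#' @param traj an [md_trajectory()].
#' @param cutoff heavy-atom cutoff in Angstrom (default 4.5).
#' @param stride frame stride (default 1 = every frame).
#' @return a matrix of class `"contact_map"` with residue labels as dimnames
#'   and attributes `cutoff`, `n_frames`, `labels`.
#' @export
contact_population <- function(traj, cutoff = 4.5, stride = 1L) {
  stopifnot(inherits(traj, "md_trajectory"))
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  frames <- seq(1L, n_frames(traj), by = stride)
  R <- n_residues(traj)
  counts <- matrix(0, R, R)
  for (f in frames) {
    p <- frame_contacts(traj, f, cutoff)
    if (nrow(p)) counts[p] <- counts[p] + 1
  }
  vals <- counts / length(frames)
  vals <- vals + t(vals)
  labs <- residue_labels(traj$topology)
  dimnames(vals) <- list(labs, labs)
  structure(vals, class = c("contact_map", "matrix"),
            cutoff = cutoff, n_frames = length(frames), labels = labs)
}

#' @export
print.contact_map <- function(x, ...) {
  nz <- sum(x[upper.tri(x)] > 0)
  cat(sprintf("contact_map: %d residues, cutoff %.2f A over %d frame(s); %d nonzero pair(s)\n",
              nrow(x), attr(x, "cutoff"), attr(x, "n_frames"), nz))
  invisible(x)
}

#' @export
plot.contact_map <- function(x, main = "Contact population", ...) {
  z <- unclass(x)
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), z, zlim = c(0, 1),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "residue serial index", ylab = "residue serial index",
                  main = main, ...)
  invisible(x)
}

#' Difference of two contact-population maps
#'
#' Elementwise variant minus reference (positive entries mark contacts
#' strengthened in the variant). The two maps must have the same residue
#' count; labels may differ only in residue names (a chemically modified
#' residue is matched positionally by serial index).
#'
#' @param c_variant,c_reference `contact_map` objects of equal dimension.
#' @return a matrix of class `"diff_contact_map"` with entries in [-1, 1].
#' @export
diff_contact_map <- function(c_variant, c_reference) {
  stopifnot(inherits(c_variant, "contact_map"), inherits(c_reference, "contact_map"))
  if (!identical(dim(c_variant), dim(c_reference)))
    stop("contact maps have different dimensions: ",
         nrow(c_variant), " vs ", nrow(c_reference), " residues")
  d <- unclass(c_variant) - unclass(c_reference)
  structure(d, class = c("diff_contact_map", "matrix"),
            labels_variant = attr(c_variant, "labels"),
            labels_reference = attr(c_reference, "labels"))
}

#' @export
print.diff_contact_map <- function(x, ...) {
  up <- x[upper.tri(x)]
  cat(sprintf("diff_contact_map: %d residues; %d strengthened, %d weakened pair(s); range [%.3f, %.3f]\n",
              nrow(x), sum(up > 0), sum(up < 0), min(x), max(x)))
  invisible(x)
}

#' @export
plot.diff_contact_map <- function(x, main = "Contact population difference", ...) {
  z <- unclass(x)
  m <- max(abs(z), 1e-12)
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), z, zlim = c(-m, m),
                  col = grDevices::hcl.colors(64, "Blue-Red"),
                  xlab = "residue serial index", ylab = "residue serial index",
                  main = main, ...)
  invisible(x)
}

#' Contact partners of one residue above a population threshold
#'
#' Reports the residues whose contact population with the focal residue meets
#' the threshold, sorted by population (descending). The default threshold of
#' 0.5 corresponds to a contact present for most of the trajectory.
#'
#' @param cmap a `contact_map`.
#' @param serial_index focal residue serial index (1..R).
#' @param threshold population threshold in [0, 1] (default 0.5).
#' @return data.frame with columns `partner` (serial index), `label`,
#'   `population`, sorted by descending population.
#' @export
contacts_of_residue <- function(cmap, serial_index, threshold = 0.5) {
  stopifnot(inherits(cmap, "contact_map"))
  R <- nrow(cmap)
  si <- as.integer(serial_index)
  if (si < 1L || si > R) stop("serial index out of range: ", serial_index)
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  pop <- unclass(cmap)[si, ]
  sel <- which(pop >= threshold & pop > 0 & seq_len(R) != si)
  sel <- sel[order(pop[sel], decreasing = TRUE)]
  data.frame(partner = sel, label = attr(cmap, "labels")[sel],
             population = unname(pop[sel]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a contact or difference map as TSV
#'
#' First row and column carry `serial:chain:resnum:resname` labels.
#'
#' @param cmap a `contact_map` or `diff_contact_map`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_contact_map <- function(cmap, path) {
  z <- unclass(cmap)
  labs <- rownames(z)
  lines <- c(paste(c("residue", labs), collapse = "\t"),
             vapply(seq_len(nrow(z)), function(i)
               paste(c(labs[i], sprintf("%.6g", z[i, ])), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}
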