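# Pairwise nonbonded energetics: Coulomb and Lennard-Jones totals per frame.
#
# These are cutoff-free pair sums with Lorentz-Berthelot combining and a
# minimal exclusion scheme; they are a self-consistent comparative metric
# between two systems analysed with identical settings, not a reproduction
# of any simulation engine's bookkeeping (no 1-4 scaling, no Ewald, no
# solvent terms).

# Coulomb constant in kcal*A/(mol*e^2), the AMBER-family value.
.KE <- 332.0636

#' Default nonbonded exclusion list
#'
#' With no bond table available, excludes every intra-residue atom pair plus
#' the peptide-bond-bridging pairs between backbone atoms (C, O, N, H, CA) of
#' consecutive residues within a chain. This removes the dominant bonded
#' Coulomb terms without requiring full bond topology.
#'
#' @param top a `topology`.
#' @return integer matrix with columns `i`, `j` (i < j) of excluded atom pairs.
#' @export
default_exclusions <- function(top) {
  stopifnot(inherits(top, "topology"))
  a <- top$atoms; r <- top$residues
  ex <- list()
  for (ri in seq_len(nrow(r))) {
    rng <- r$first_atom[ri]:r$last_atom[ri]
    if (length(rng) > 1L) {
      cmb <- t(utils::combn(rng, 2L))
      ex[[length(ex) + 1L]] <- cmb
    }
    if (ri < nrow(r) && r$chain[ri + 1L] == r$chain[ri]) {
      bb <- c("C", "O", "N", "H", "CA")
      i1 <- rng[trimws(a$name[rng]) %in% bb]
      rng2 <- r$first_atom[ri + 1L]:r$last_atom[ri + 1L]
      i2 <- rng2[trimws(a$name[rng2]) %in% bb]
      if (length(i1) && length(i2))
        ex[[length(ex) + 1L]] <- as.matrix(expand.grid(i = i1, j = i2))
    }
  }
  if (!length(ex)) return(cbind(i = integer(0), j = integer(0)))
  m <- do.call(rbind, ex)
  m <- cbind(i = pmin(m[, 1], m[, 2]), j = pmax(m[, 1], m[, 2]))
  unique(m)
}

#' Construct nonbonded parameters
#'
#' @param q per-atom partial charges (elementary charges).
#' @param sigma per-atom Lennard-Jones sigma (Angstrom, > 0).
#' @param epsilon per-atom Lennard-Jones epsilon (kcal/mol, >= 0).
#' @param exclusions integer matrix (i, j) of excluded atom pairs.
#' @param n_atoms expected atom count (for validation).
#' @return object of class `"nonbonded_params"`.
#' @export
nonbonded_params <- function(q, sigma, epsilon, exclusions, n_atoms = length(q)) {
  stopifnot(length(q) == n_atoms, length(sigma) == n_atoms,
            length(epsilon) == n_atoms)
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(epsilon < 0)) stop("epsilon must be non-negative")
  exclusions <- rbind(exclusions)
  if (nrow(exclusions) && (any(exclusions < 1) || any(exclusions > n_atoms)))
    stop("exclusion pairs reference invalid atoms")
  structure(list(q = as.numeric(q), sigma = as.numeric(sigma),
                 epsilon = as.numeric(epsilon), exclusions = exclusions),
            class = "nonbonded_params")
}

#' @export
print.nonbonded_params <- function(x, ...) {
  cat(sprintf("nonbonded_params: %d atoms, total charge %+.3f e, %d excluded pair(s)\n",
              length(x$q), sum(x$q), nrow(x$exclusions)))
  invisible(x)
}

#' Read a nonbonded parameter table
#'
#' Tab-separated table with header `chain resnum atom_name q sigma epsilon`;
#' `*` wildcards are allowed in `chain` and `resnum` (a wildcard row applies
#' to every atom of that name not matched by a more specific row). Every
#' topology atom must end up parameterised.
#'
#' @param path TSV file path.
#' @param top the `topology` the parameters are for.
#' @param exclusions exclusion pairs; default [default_exclusions()].
#' @return a [nonbonded_params()] object covering all atoms.
#' @export
read_params_table <- function(path, top, exclusions = default_exclusions(top)) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", strip.white = TRUE)
  need <- c("chain", "resnum", "atom_name", "q", "sigma", "epsilon")
  if (!all(need %in% names(tab)))
    stop("parameter table must have columns: ", paste(need, collapse = " "))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v))
      stop("non-numeric ", col, " in parameter table row ",
           which(is.na(v))[1], call. = FALSE)
    v
  }
  qv <- num("q"); sv <- num("sigma"); ev <- num("epsilon")
  a <- top$atoms; r <- top$residues
  chain <- r$chain[a$resid]; resno <- r$resno[a$resid]
  nm <- trimws(a$name)
  N <- nrow(a)
  q <- sigma <- epsilon <- rep(NA_real_, N)
  # specificity: exact chain+resnum rows first, then wildcard rows
  spec <- (tab$chain != "*") + (tab$resnum != "*")
  for (ord in c(2, 1, 0)) {
    for (i in which(spec == ord)) {
      hit <- nm == tab$atom_name[i] &
        (tab$chain[i] == "*" | chain == tab$chain[i]) &
        (tab$resnum[i] == "*" | resno == suppressWarnings(as.integer(tab$resnum[i])))
      hit <- hit & is.na(q)
      q[hit] <- qv[i]; sigma[hit] <- sv[i]; epsilon[hit] <- ev[i]
    }
  }
  if (anyNA(q)) {
    miss <- which(is.na(q))
    stop("no parameters for atom(s): ",
         paste(utils::head(paste0(chain[miss], resno[miss], ":", nm[miss]), 10),
               collapse = ", "),
         if (length(miss) > 10) sprintf(" (+%d more)", length(miss) - 10))
  }
  nonbonded_params(q, sigma, epsilon, exclusions, N)
}

#' Write a nonbonded parameter table as TSV
#' @param top a `topology`.
#' @param params a `nonbonded_params` covering its atoms.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_params_table <- function(top, params, path) {
  a <- top$atoms; r <- top$residues
  lines <- c("chain\tresnum\tatom_name\tq\tsigma\tepsilon",
             sprintf("%s\t%d\t%s\t%.6g\t%.6g\t%.6g",
                     r$chain[a$resid], r$resno[a$resid], trimws(a$name),
                     params$q, params$sigma, params$epsilon))
  writeLines(lines, path)
  invisible(path)
}

# Pairwise machinery shared by both energies: returns list(r, qq, sig, eps)
# over all non-excluded i<j pairs.
.pair_terms <- function(xyz, params, box) {
  N <- nrow(xyz)
  D <- .pair_dist_matrix(xyz, xyz, box)
  mask <- upper.tri(D)
  if (nrow(params$exclusions)) {
    exm <- params$exclusions
    mask[cbind(exm[, 1], exm[, 2])] <- FALSE
    mask[cbind(exm[, 2], exm[, 1])] <- FALSE
  }
  idx <- which(mask, arr.ind = TRUE)
  r <- D[mask]
  if (any(r < 0.1))
    stop(sprintf("atomic clash: non-excluded pair %d-%d at %.3f A",
                 idx[which(r < 0.1)[1], 1], idx[which(r < 0.1)[1], 2],
                 min(r)))
  list(r = r,
       qq = params$q[idx[, 1]] * params$q[idx[, 2]],
       sig = (params$sigma[idx[, 1]] + params$sigma[idx[, 2]]) / 2,
       eps = sqrt(params$epsilon[idx[, 1]] * params$epsilon[idx[, 2]]))
}

#' Coulomb energy of one frame
#'
#' Cutoff-free sum of k_e q_i q_j / r_ij over all non-excluded atom pairs,
#' with k_e = 332.0636 kcal*A/(mol*e^2) and minimum-image distances.
#'
#' @param traj an [md_trajectory()].
#' @param frame 1-based frame index.
#' @param params a [nonbonded_params()].
#' @return energy in kcal/mol.
#' @export
coulomb_energy <- function(traj, frame, params) {
  t_ <- .pair_terms(frame_coords(traj, frame), params, traj$box)
  sum(.KE * t_$qq / t_$r)
}

#' Lennard-Jones energy of one frame
#'
#' Cutoff-free sum of 4 eps_ij [(sig_ij/r)^12 - (sig_ij/r)^6] with
#' Lorentz-Berthelot combining (arithmetic-mean sigma, geometric-mean
#' epsilon).
#'
#' @inheritParams coulomb_energy
#' @return energy in kcal/mol.
#' @export
lj_energy <- function(traj, frame, params) {
  t_ <- .pair_terms(frame_coords(traj, frame), params, traj$box)
  sr6 <- (t_$sig / t_$r)^6
  sum(4 * t_$eps * (sr6^2 - sr6))
}

#' Per-frame nonbonded energy report
#'
#' @param traj an [md_trajectory()].
#' @param params a [nonbonded_params()].
#' @return object of class `"energy_report"`: data.frame with columns
#'   `frame`, `e_elec`, `e_vdw` (kcal/mol) and attributes `mean_elec`,
#'   `mean_vdw`, `sd_elec`, `sd_vdw`.
#' @export
energy_report <- function(traj, params) {
  nf <- n_frames(traj)
  ee <- ev <- numeric(nf)
  for (f in seq_len(nf)) {
    t_ <- .pair_terms(frame_coords(traj, f), params, traj$box)
    ee[f] <- sum(.KE * t_$qq / t_$r)
    sr6 <- (t_$sig / t_$r)^6
    ev[f] <- sum(4 * t_$eps * (sr6^2 - sr6))
  }
  structure(data.frame(frame = seq_len(nf), e_elec = ee, e_vdw = ev),
            class = c("energy_report", "data.frame"),
            mean_elec = mean(ee), mean_vdw = mean(ev),
            sd_elec = stats::sd(ee), sd_vdw = stats::sd(ev))
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("energy_report: %d frame(s); E_elec %.2f +/- %.2f, E_vdw %.2f +/- %.2f kcal/mol\n",
              nrow(x), attr(x, "mean_elec"),
              ifelse(is.na(attr(x, "sd_elec")), 0, attr(x, "sd_elec")),
              attr(x, "mean_vdw"),
              ifelse(is.na(attr(x, "sd_vdw")), 0, attr(x, "sd_vdw"))))
  invisible(x)
}
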