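# Multi-model PDB reading and writing.
#
# The reader builds the topology from the first model; every later model must
# present the same atoms in the same order. Only orthorhombic CRYST1 boxes are
# honoured (any non-90 angle drops the box). Waters and monatomic ions are
# stripped by default; HETATM records on protein chains (e.g. a chemically
# modified residue) are always kept.

.elem_from_name <- function(name) {
  # PDB atom-name heuristic when the element column is absent: strip leading
  # digits (e.g. "1HB2"), take the first alphabetic character; a leading H is
  # hydrogen even in four-character names like "HG12".
  nm <- gsub("^[0-9 ]+", "", name)
  first <- toupper(substr(nm, 1L, 1L))
  two <- toupper(substr(nm, 1L, 2L))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "SE", "NA") &
           nchar(trimws(nm)) <= 2, two, first)
}

.parse_atom_line <- function(line, lineno) {
  xs <- substr(line, 31, 38); ys <- substr(line, 39, 46); zs <- substr(line, 47, 54)
  x <- suppressWarnings(as.numeric(xs))
  y <- suppressWarnings(as.numeric(ys))
  z <- suppressWarnings(as.numeric(zs))
  if (anyNA(c(x, y, z)))
    stop("unparseable coordinate field at line ", lineno, ": '",
         trimws(line), "'", call. = FALSE)
  list(record = substr(line, 1, 6),
       serial = suppressWarnings(as.integer(substr(line, 7, 11))),
       name = substr(line, 13, 16),
       resname = trimws(substr(line, 18, 20)),
       chain = substr(line, 22, 22),
       resno = suppressWarnings(as.integer(substr(line, 23, 26))),
       x = x, y = y, z = z,
       element = trimws(substr(line, 77, 78)))
}

#' Read a multi-model PDB file as a trajectory
#'
#' The topology (atoms, residues, chains) is taken from the first MODEL (or
#' the whole file when no MODEL records are present); each further model
#' contributes one coordinate frame and must match the first model's atom
#' count and order. A CRYST1 record with 90-degree angles populates the
#' orthorhombic box; other angles are ignored with a warning.
#'
#' @param path path to a PDB file (LF or CRLF line endings).
#' @param keep_solvent keep water/ion residues (default FALSE drops them).
#' @return an [md_trajectory()].
#' @export
read_multimodel_pdb <- function(path, keep_solvent = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  rec <- substr(lines, 1, 6)

  box <- NULL
  cry <- which(rec == "CRYST1")
  if (length(cry)) {
    l <- lines[cry[1]]
    abc <- suppressWarnings(as.numeric(c(substr(l, 7, 15), substr(l, 16, 24),
                                         substr(l, 25, 33))))
    ang <- suppressWarnings(as.numeric(c(substr(l, 34, 40), substr(l, 41, 47),
                                         substr(l, 48, 54))))
    if (!anyNA(abc) && all(abc > 0)) {
      if (!anyNA(ang) && all(abs(ang - 90) < 1e-6)) box <- abc
      else warning("non-orthorhombic CRYST1 box ignored")
    }
  }

  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_no <- integer(length(lines))
  starts <- which(rec == "MODEL ")
  if (length(starts) == 0L) {
    model_no[is_atom] <- 1L
    nmodels <- 1L
  } else {
    endmdl <- cumsum(rec == "ENDMDL")
    running <- cumsum(rec == "MODEL ") - c(0L, endmdl[-length(endmdl)])
    # atoms outside MODEL blocks (running == 0) are ignored
    midx <- cumsum(rec == "MODEL ")
    model_no[is_atom & running > 0L] <- midx[is_atom & running > 0L]
    nmodels <- max(model_no)
    if (nmodels == 0L) stop("no ATOM/HETATM records inside MODEL blocks")
  }

  keep <- is_atom & model_no > 0L
  idx <- which(keep)
  if (!length(idx)) stop("no ATOM/HETATM records in file")
  parsed <- lapply(idx, function(i) .parse_atom_line(lines[i], i))
  resname <- vapply(parsed, `[[`, "", "resname")
  if (!keep_solvent) {
    solv <- toupper(resname) %in% .SOLVENT_NAMES
    parsed <- parsed[!solv]
    idx <- idx[!solv]
    resname <- resname[!solv]
  }
  if (!length(parsed)) stop("no non-solvent atoms in file")
  mno <- model_no[idx]

  per_model <- split(seq_along(parsed), mno)
  n0 <- length(per_model[[1]])
  for (m in seq_along(per_model)) {
    if (length(per_model[[m]]) != n0)
      stop("atom-count mismatch in model ", names(per_model)[m], ": ",
           length(per_model[[m]]), " atoms vs ", n0, " in model ",
           names(per_model)[1], call. = FALSE)
  }

  first <- parsed[per_model[[1]]]
  name <- vapply(first, `[[`, "", "name")
  elem <- vapply(first, `[[`, "", "element")
  no_elem <- !nzchar(elem)
  if (any(no_elem)) {
    elem[no_elem] <- .elem_from_name(name[no_elem])
    message("element column absent for ", sum(no_elem),
            " atom(s); inferred from atom names")
  }
  chain <- vapply(first, `[[`, "", "chain")
  resno <- vapply(first, function(p) p$resno, 0L)
  rnam <- vapply(first, `[[`, "", "resname")
  het <- vapply(first, `[[`, "", "record") == "HETATM"

  res_key <- paste(chain, resno, rnam)
  res_change <- c(TRUE, res_key[-1] != res_key[-length(res_key)])
  resid <- cumsum(res_change)
  firsts <- which(res_change)
  lasts <- c(firsts[-1] - 1L, length(resid))
  residues <- data.frame(serial_index = seq_along(firsts),
                         name = rnam[firsts], chain = chain[firsts],
                         resno = resno[firsts],
                         first_atom = firsts, last_atom = lasts,
                         stringsAsFactors = FALSE)
  atoms <- data.frame(serial = seq_along(first),
                      name = name, element = elem, resid = resid,
                      is_hydrogen = toupper(elem) %in% c("H", "D"),
                      het = het, stringsAsFactors = FALSE)
  top <- topology(atoms, residues)

  coords <- array(NA_real_, c(n0, 3L, length(per_model)))
  for (m in seq_along(per_model)) {
    pm <- parsed[per_model[[m]]]
    coords[, 1, m] <- vapply(pm, `[[`, 0, "x")
    coords[, 2, m] <- vapply(pm, `[[`, 0, "y")
    coords[, 3, m] <- vapply(pm, `[[`, 0, "z")
  }
  md_trajectory(top, coords, box)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame with fixed-width ATOM/HETATM records; a
#' CRYST1 record is written when the trajectory carries a box.
#'
#' @param traj an [md_trajectory()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_multimodel_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (any(traj$coords > 9999.999) || any(traj$coords < -999.999))
    stop("coordinates exceed PDB fixed-column field width (must be in [-999.999, 9999.999])")
  top <- traj$topology
  a <- top$atoms; r <- top$residues
  # atom names of <= 3 characters start in column 14 by convention
  nm <- trimws(a$name)
  nm_fmt <- ifelse(nchar(nm) <= 3, sprintf(" %-3s", nm), sprintf("%-4s", nm))
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  chain <- r$chain[a$resid]
  resno <- r$resno[a$resid]
  rnam <- r$name[a$resid]
  con <- file(path, open = "wb")
  on.exit(close(con))
  out <- character(0)
  if (!is.null(traj$box))
    out <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   traj$box[1], traj$box[2], traj$box[3], 90, 90, 90)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f, drop = TRUE]
    body <- sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    rec, a$serial %% 100000L, nm_fmt, "",
                    substr(rnam, 1, 3), chain, resno %% 10000L, "",
                    xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
                    toupper(substr(a$element, 1, 2)))
    out <- c(out, sprintf("MODEL     %4d", f), body, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, con, sep = "\n")
  invisible(path)
}
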