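# Shared helpers: tiny hand-built topologies/trajectories and independent
# brute-force oracles the implementation is checked against.

# Build a topology from a compact atom table:
# data.frame(chain, resno, resname, atom, element) in file order.
toy_topology <- function(df, het = FALSE) {
  key <- paste(df$chain, df$resno, df$resname)
  change <- c(TRUE, key[-1] != key[-length(key)])
  resid <- cumsum(change)
  firsts <- which(change)
  lasts <- c(firsts[-1] - 1L, nrow(df))
  atoms <- data.frame(serial = seq_len(nrow(df)), name = df$atom,
                      element = df$element, resid = resid,
                      is_hydrogen = toupper(df$element) %in% c("H", "D"),
                      het = rep_len(het, nrow(df)), stringsAsFactors = FALSE)
  residues <- data.frame(serial_index = seq_along(firsts),
                         name = df$resname[firsts], chain = df$chain[firsts],
                         resno = df$resno[firsts],
                         first_atom = firsts, last_atom = lasts,
                         stringsAsFactors = FALSE)
  topology(atoms, residues)
}

# One-atom-per-residue trajectory: coords is N x 3 x F.
toy_traj <- function(coords, chain = "A", element = "C", atom = "CA",
                     box = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3, 1))
  n <- dim(coords)[1]
  df <- data.frame(chain = chain, resno = seq_len(n), resname = "GLY",
                   atom = atom, element = element, stringsAsFactors = FALSE)
  md_trajectory(toy_topology(df), coords, box)
}

# Explicit 27-image brute-force minimum distance.
brute_min_image <- function(a, b, box) {
  if (is.null(box)) return(sqrt(sum((a - b)^2)))
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- a - (b + c(i, j, k) * box)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# Per-frame residue-contact recount: direct loop over residue pairs and
# heavy-atom pairs.
brute_frame_contacts <- function(traj, frame, cutoff) {
  top <- traj$topology
  xyz <- frame_coords(traj, frame)
  R <- n_residues(traj)
  out <- NULL
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    ai <- top$residues$first_atom[i]:top$residues$last_atom[i]
    aj <- top$residues$first_atom[j]:top$residues$last_atom[j]
    ai <- ai[!top$atoms$is_hydrogen[ai]]
    aj <- aj[!top$atoms$is_hydrogen[aj]]
    hit <- FALSE
    for (p in ai) {
      for (q in aj) {
        if (brute_min_image(xyz[p, ], xyz[q, ], traj$box) <= cutoff) {
          hit <- TRUE; break
        }
      }
      if (hit) break
    }
    if (hit) out <- rbind(out, c(i, j))
  }
  if (is.null(out)) out <- matrix(integer(0), 0, 2)
  colnames(out) <- c("i", "j")
  out
}

# Exhaustive donor/hydrogen/acceptor triple loop for hydrogen bonds.
brute_hbonds <- function(traj, frame, crit) {
  top <- traj$topology
  xyz <- frame_coords(traj, frame)
  a <- top$atoms
  don <- which(toupper(a$element) %in% c("N", "O") & !a$is_hydrogen)
  hyd <- which(a$is_hydrogen)
  acc <- don
  recs <- NULL
  for (d in don) for (h in hyd) {
    if (brute_min_image(xyz[d, ], xyz[h, ], traj$box) > 1.2) next
    for (ac in acc) {
      if (ac == d || a$resid[ac] == a$resid[d]) next
      dha <- brute_min_image(xyz[h, ], xyz[ac, ], traj$box)
      dda <- brute_min_image(xyz[d, ], xyz[ac, ], traj$box)
      if (dha > crit$max_ha || dda > crit$max_da) next
      v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[ac, ] - xyz[h, ]
      ang <- acos(min(1, max(-1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= crit$min_angle)
        recs <- rbind(recs, data.frame(donor = d, hydrogen = h, acceptor = ac,
                                       dist_ha = dha, angle = ang))
    }
  }
  if (is.null(recs))
    recs <- data.frame(donor = integer(0), hydrogen = integer(0),
                       acceptor = integer(0), dist_ha = numeric(0),
                       angle = numeric(0))
  recs[order(recs$donor, recs$acceptor), , drop = FALSE]
}

# Direct double-loop nonbonded energies with explicit combining rules.
brute_energies <- function(traj, frame, params) {
  xyz <- frame_coords(traj, frame)
  N <- nrow(xyz)
  excl <- matrix(FALSE, N, N)
  if (nrow(params$exclusions)) {
    excl[params$exclusions] <- TRUE
    excl[params$exclusions[, c(2, 1), drop = FALSE]] <- TRUE
  }
  ke <- 332.0636
  ee <- ev <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    if (excl[i, j]) next
    r <- brute_min_image(xyz[i, ], xyz[j, ], traj$box)
    ee <- ee + ke * params$q[i] * params$q[j] / r
    sij <- (params$sigma[i] + params$sigma[j]) / 2
    eij <- sqrt(params$epsilon[i] * params$epsilon[j])
    ev <- ev + 4 * eij * ((sij / r)^12 - (sij / r)^6)
  }
  c(elec = ee, vdw = ev)
}

# An insulin-like two-chain backbone-only topology (21 + 30 glycines).
insulin_like_topology <- function() {
  mk <- function(chain, n) {
    do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(chain = chain, resno = i, resname = "GLY",
                 atom = c("N", "CA", "C", "O"),
                 element = c("N", "C", "C", "O"), stringsAsFactors = FALSE)))
  }
  toy_topology(rbind(mk("A", 21), mk("B", 30)))
}

# Random proper rotation matrix.
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Ideal hexagon ring residue (aromatic template) at a given center with a
# given plane normal.
hexagon_coords <- function(center = c(0, 0, 0), normal = c(0, 0, 1),
                           radius = 1.39) {
  normal <- normal / sqrt(sum(normal^2))
  p <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- p - sum(p * normal) * normal; u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  ang <- (0:5) * pi / 3
  t(vapply(ang, function(a) center + radius * (cos(a) * u + sin(a) * v),
           numeric(3)))
}

# Two-ring trajectory for pi-pi tests: rings at given COM separation along z
# and interplanar angle (degrees).
two_ring_traj <- function(dist = 5, angle = 90) {
  r1 <- hexagon_coords(c(0, 0, 0), c(0, 0, 1))
  n2 <- c(sin(angle * pi / 180), 0, cos(angle * pi / 180))
  r2 <- hexagon_coords(c(0, 0, dist), n2)
  df <- data.frame(chain = "A", resno = rep(c(1, 2), each = 6),
                   resname = "PHE",
                   atom = rep(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"), 2),
                   element = "C", stringsAsFactors = FALSE)
  md_trajectory(toy_topology(df), rbind(r1, r2))
}
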