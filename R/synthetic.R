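# Seeded synthetic trajectories with known ground truth.
#
# Residues are minimal rigid templates (N, H, CA, C, O, plus an ideal
# six-membered ring for aromatic residues) placed on a wide lattice so that
# undirected residue pairs can never touch. Directives then realize designed
# truths: contact schedules place a mobile residue near its anchor in an
# exact round(p * F) subset of frames; a hydrogen-bond directive builds
# explicit D-H...A geometry with Gaussian distance/angle jitter; a ring-pair
# directive sets ring COM separation and interplanar angle around designed
# means. Per-residue isotropic Gaussian displacement and whole-frame
# rigid-body motion are layered on top. Residues moved by a directive are
# held free of the per-residue jitter so the designed populations stay exact.

.TEMPLATE_BB <- function() {
  rbind(N = c(0.00, 0.00, 0.00),
        H = c(0.00, -1.01, 0.00),
        CA = c(1.46, 0.00, 0.00),
        C = c(2.00, 1.42, 0.00),
        O = c(3.23, 1.42, 0.00))
}

.TEMPLATE_RING <- function() {
  # ideal hexagon, radius 1.39 A, in a plane parallel to xy above CA
  ctr <- c(1.46, 0.00, 2.80)
  ang <- (0:5) * pi / 3
  m <- cbind(ctr[1] + 1.39 * cos(ang), ctr[2] + 1.39 * sin(ang),
             rep(ctr[3], 6))
  rownames(m) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  m
}

# Rotation taking unit vector a to unit vector b (Rodrigues).
.rot_from_to <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate 180 deg about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

# Rotation by `deg` degrees about unit axis (Rodrigues).
.rot_about <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

#' Specify a synthetic fixture
#'
#' @param chains named list: chain id -> character vector of residue names
#'   (author numbering is 1..n within each chain). Names in
#'   `ring_residues` get an ideal six-membered aromatic ring.
#' @param n_frames number of frames (>= 1).
#' @param seed integer random seed; fixed seed gives byte-identical output.
#' @param contacts list of contact directives, each
#'   `list(a = c(chain, resno), b = c(chain, resno), population, contact_dist
#'   = 4.2, noncontact_dist = NA)`: residue `b` is placed so one of its heavy
#'   atoms sits `contact_dist` Angstrom from `a`'s CA in exactly
#'   `round(population * n_frames)` frames (seeded shuffle) and at its remote
#'   lattice home (or at `noncontact_dist` along the same direction)
#'   otherwise.
#' @param hbonds list of hydrogen-bond directives, each
#'   `list(donor = c(chain, resno), acceptor = c(chain, resno), mean = 2.0,
#'   sd = 0.15, angle_sd = 5)`: the donor residue is placed so its backbone
#'   H sits at H...O(acceptor) distance N(mean, sd^2) with the D-H...A angle
#'   jittered off 180 degrees by |N(0, angle_sd^2)|.
#' @param rings list of ring-pair directives, each
#'   `list(a = c(chain, resno), b = c(chain, resno), mean_dist = 5.0,
#'   dist_sd = 0.3, mean_angle = 90, angle_sd = 5)`: residue `b` (aromatic)
#'   is placed so the two ring centers of mass are N(mean_dist, dist_sd^2)
#'   apart with interplanar angle N(mean_angle, angle_sd^2).
#' @param ring_residues residue names that carry the aromatic ring template
#'   (default PHE, TYR and the modified-lysine placeholder FLK).
#' @param sigma default per-residue fluctuation sigma (Angstrom per
#'   coordinate, default 0).
#' @param sigma_overrides optional data.frame (`chain`, `resno`, `sigma`)
#'   overriding sigma for specific residues.
#' @param rigid_motion list(trans_sd, rot_sd): whole-frame random translation
#'   (Angstrom per axis) and rotation (degrees about a random axis) applied
#'   to every frame.
#' @param box optional numeric(3) box lengths.
#' @return object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(chains, n_frames, seed = 1L,
                         contacts = list(), hbonds = list(), rings = list(),
                         ring_residues = c("PHE", "TYR", "FLK"),
                         sigma = 0, sigma_overrides = NULL,
                         rigid_motion = list(trans_sd = 0.5, rot_sd = 3),
                         box = NULL) {
  stopifnot(is.list(chains), length(chains) >= 1, n_frames >= 1, sigma >= 0)
  for (d in contacts) {
    if (d$population < 0 || d$population > 1)
      stop("contact population must be in [0, 1]")
  }
  spec <- structure(list(chains = chains, n_frames = as.integer(n_frames),
                         seed = as.integer(seed), contacts = contacts,
                         hbonds = hbonds, rings = rings,
                         ring_residues = ring_residues, sigma = sigma,
                         sigma_overrides = sigma_overrides,
                         rigid_motion = rigid_motion, box = box),
                    class = "fixture_spec")
  .check_directives(spec)
  spec
}

# A residue may be the mobile partner of at most one directive, and every
# directive residue must exist in the chain plan.
.check_directives <- function(spec) {
  key <- function(r) paste0(r[1], ":", r[2])
  exists_res <- function(r) {
    ch <- spec$chains[[r[1]]]
    !is.null(ch) && as.integer(r[2]) >= 1 && as.integer(r[2]) <= length(ch)
  }
  mobiles <- character(0)
  all_dir <- c(lapply(spec$contacts, function(d) list(a = d$a, m = d$b)),
               lapply(spec$hbonds, function(d) list(a = d$acceptor, m = d$donor)),
               lapply(spec$rings, function(d) list(a = d$a, m = d$b)))
  for (d in all_dir) {
    if (!exists_res(d$a) || !exists_res(d$m))
      stop("directive references a residue outside the chain plan: ",
           key(d$a), " / ", key(d$m))
    if (key(d$m) %in% mobiles)
      stop("contradictory directives: residue ", key(d$m),
           " is moved by more than one directive")
    mobiles <- c(mobiles, key(d$m))
  }
  invisible(TRUE)
}

# Build the fixture topology and the static lattice coordinates.
.fixture_topology <- function(spec) {
  atoms <- list(); residues <- list(); base <- list()
  serial <- 0L; ridx <- 0L; atom_row <- 0L
  lattice <- function(m) c(m %% 4L, (m %/% 4L) %% 4L, m %/% 16L) * 22.0
  m <- 0L
  for (ch in names(spec$chains)) {
    rn <- spec$chains[[ch]]
    for (i in seq_along(rn)) {
      ridx <- ridx + 1L
      tpl <- .TEMPLATE_BB()
      if (rn[i] %in% spec$ring_residues) tpl <- rbind(tpl, .TEMPLATE_RING())
      first <- atom_row + 1L
      for (an in rownames(tpl)) {
        serial <- serial + 1L; atom_row <- atom_row + 1L
        atoms[[atom_row]] <- data.frame(
          serial = serial, name = an,
          element = if (an == "H") "H" else substr(an, 1, 1),
          resid = ridx, is_hydrogen = an == "H",
          het = rn[i] == "FLK", stringsAsFactors = FALSE)
      }
      residues[[ridx]] <- data.frame(serial_index = ridx, name = rn[i],
                                     chain = ch, resno = i,
                                     first_atom = first, last_atom = atom_row,
                                     stringsAsFactors = FALSE)
      base[[ridx]] <- sweep(tpl, 2, -lattice(m))  # CA-relative template + origin
      m <- m + 1L
    }
  }
  top <- topology(do.call(rbind, atoms), do.call(rbind, residues))
  list(top = top, base = base)
}

# Well-separated placement directions assigned to directives in order.
.DIRECTIVE_DIRS <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1),
                         c(-1, -1, -1), c(-1, 1, 1), c(1, -1, 1), c(1, 1, -1)) / sqrt(3)

#' Generate a synthetic trajectory from a fixture spec
#'
#' Deterministic for a fixed seed. Returns the trajectory, default nonbonded
#' parameters for its topology, and a ground-truth manifest recording every
#' designed value (contact populations, hydrogen-bond and ring-pair
#' geometry, per-residue sigmas).
#'
#' @param spec a [fixture_spec()].
#' @return list with elements `trajectory` ([md_trajectory()]), `params`
#'   ([nonbonded_params()]), `manifest` (data.frame: `quantity`, `key`,
#'   `value`).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  ft <- .fixture_topology(spec)
  top <- ft$top; base <- ft$base
  R <- nrow(top$residues); Fn <- spec$n_frames
  res_of <- function(r) residue_serial(top, r[1], as.integer(r[2]))

  # per-residue sigma
  sig <- rep(spec$sigma, R)
  if (!is.null(spec$sigma_overrides)) {
    so <- spec$sigma_overrides
    for (i in seq_len(nrow(so)))
      sig[res_of(c(so$chain[i], so$resno[i]))] <- so$sigma[i]
  }
  # directive-mobile residues are exempt from positional jitter
  mobile <- c(vapply(spec$contacts, function(d) res_of(d$b), 0L),
              vapply(spec$hbonds, function(d) res_of(d$donor), 0L),
              vapply(spec$rings, function(d) res_of(d$b), 0L))
  sig[mobile] <- 0

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(spec$seed)

  manifest <- list()
  note <- function(quantity, key, value)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      quantity = quantity, key = key, value = value, stringsAsFactors = FALSE)

  # contact schedules: exact round(p * F) frame subsets
  dir_i <- 0L
  next_dir <- function() {
    dir_i <<- dir_i + 1L
    .DIRECTIVE_DIRS[(dir_i - 1L) %% nrow(.DIRECTIVE_DIRS) + 1L, ]
  }
  schedules <- lapply(spec$contacts, function(d) {
    n_on <- round(d$population * Fn)
    on <- sort(sample.int(Fn, n_on))
    note("contact_population",
         paste0(d$a[1], d$a[2], "-", d$b[1], d$b[2]), n_on / Fn)
    list(d = d, on = seq_len(Fn) %in% on, dir = next_dir(),
         anchor = res_of(d$a), mob = res_of(d$b))
  })
  hb_dirs <- lapply(spec$hbonds, function(d) {
    note("hbond_mean_ha", paste0(d$acceptor[1], d$acceptor[2], ".O-",
                                 d$donor[1], d$donor[2], ".H"), d$mean)
    list(d = d, dir = next_dir(), acc = res_of(d$acceptor),
         don = res_of(d$donor))
  })
  ring_dirs <- lapply(spec$rings, function(d) {
    note("ring_mean_dist", paste0(d$a[1], d$a[2], "-", d$b[1], d$b[2]), d$mean_dist)
    note("ring_mean_angle", paste0(d$a[1], d$a[2], "-", d$b[1], d$b[2]), d$mean_angle)
    list(d = d, dir = next_dir(), anchor = res_of(d$a), mob = res_of(d$b))
  })
  for (ri in seq_len(R))
    if (sig[ri] > 0)
      note("sigma", residue_labels(top)[ri], sig[ri])
  for (ri in mobile)
    note("mobile_residue", residue_labels(top)[ri], ri)

  N <- nrow(top$atoms)
  coords <- array(NA_real_, c(N, 3L, Fn))
  rng_of <- function(ri) top$residues$first_atom[ri]:top$residues$last_atom[ri]
  ca_of <- function(ri) {
    rng <- rng_of(ri); rng[trimws(top$atoms$name[rng]) == "CA"]
  }
  atom_of <- function(ri, nm) {
    rng <- rng_of(ri); rng[trimws(top$atoms$name[rng]) == nm]
  }
  ring_atoms_of <- function(ri) {
    rng <- rng_of(ri)
    rng[trimws(top$atoms$name[rng]) %in% c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")]
  }
  rand_unit <- function() {
    v <- stats::rnorm(3); v / sqrt(sum(v^2))
  }
  perp_unit <- function(u) {
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * u) * u; v / sqrt(sum(v^2))
  }

  for (f in seq_len(Fn)) {
    xyz <- do.call(rbind, base)
    # contact directives
    for (s in schedules) {
      anchor_ca <- xyz[ca_of(s$anchor), ]
      rng <- rng_of(s$mob)
      tpl <- base[[s$mob]]
      tpl_rel <- sweep(tpl, 2, tpl["CA", ])   # CA at origin
      Rr <- .rot_from_to(c(1, 0, 0), s$dir)
      if (s$on[f]) {
        # mobile N (on the ray, 1.46 A inside its CA) sits contact_dist from
        # the anchor CA, pointing radially outward
        dc <- if (is.null(s$d$contact_dist)) 4.2 else s$d$contact_dist
        ca_pos <- anchor_ca + s$dir * (dc + 1.46)
        xyz[rng, ] <- sweep(tpl_rel %*% t(Rr), 2, -ca_pos)
      } else if (!is.null(s$d$noncontact_dist) && !is.na(s$d$noncontact_dist)) {
        ca_pos <- anchor_ca + s$dir * (s$d$noncontact_dist + 1.46)
        xyz[rng, ] <- sweep(tpl_rel %*% t(Rr), 2, -ca_pos)
      } # else: remote lattice home (already in xyz)
    }
    # hydrogen-bond directives: donor H at N(mean, sd) from acceptor O along
    # the directive direction, D-H...A angle jittered off 180 degrees
    for (s in hb_dirs) {
      acc_o <- xyz[atom_of(s$acc, "O"), ]
      d <- s$d
      r_ha <- max(1.2, stats::rnorm(1, d$mean, if (is.null(d$sd)) 0.15 else d$sd))
      w <- s$dir
      hpos <- acc_o + r_ha * w
      asd <- if (is.null(d$angle_sd)) 5 else d$angle_sd
      alpha <- abs(stats::rnorm(1, 0, asd))
      axis <- .rot_about(w, stats::runif(1, 0, 360)) %*% perp_unit(w)
      w2 <- as.numeric(.rot_about(axis, alpha) %*% w)
      npos <- hpos + 1.01 * w2
      ridx <- s$don
      full_tpl <- base[[ridx]]
      tpl_rel <- sweep(full_tpl, 2, full_tpl["N", ])  # N at origin
      Rr <- .rot_from_to(c(0, -1, 0), -w2)            # template N->H axis onto w2
      xyz[rng_of(ridx), ] <- sweep(tpl_rel %*% t(Rr), 2, -npos)
    }
    # ring-pair directives: COM distance and interplanar angle around means
    for (s in ring_dirs) {
      ra <- ring_atoms_of(s$anchor); rb <- ring_atoms_of(s$mob)
      if (!length(ra) || !length(rb))
        stop("ring directive on a residue without a ring template")
      com_a <- colMeans(xyz[ra, , drop = FALSE])  # carbon ring: equal masses
      d <- s$d
      dist <- max(2.5, stats::rnorm(1, d$mean_dist,
                                    if (is.null(d$dist_sd)) 0.3 else d$dist_sd))
      th <- stats::rnorm(1, d$mean_angle,
                         if (is.null(d$angle_sd)) 5 else d$angle_sd)
      com_b <- com_a + dist * s$dir
      # anchor ring normal is z (templates are never rotated in place)
      n_b <- as.numeric(.rot_about(perp_unit(c(0, 0, 1)), th) %*% c(0, 0, 1))
      tplb <- base[[s$mob]]
      ring_rows <- match(rb, rng_of(s$mob))
      tpl_rel <- sweep(tplb, 2, colMeans(tplb[ring_rows, , drop = FALSE]))
      Rr <- .rot_from_to(c(0, 0, 1), n_b)
      xyz[rng_of(s$mob), ] <- sweep(tpl_rel %*% t(Rr), 2, -com_b)
    }
    # per-residue isotropic jitter
    for (ri in seq_len(R)) {
      if (sig[ri] > 0)
        xyz[rng_of(ri), ] <- sweep(xyz[rng_of(ri), , drop = FALSE], 2,
                                   -stats::rnorm(3, 0, sig[ri]))
    }
    # whole-frame rigid-body motion
    rm_ <- spec$rigid_motion
    if (!is.null(rm_) && (rm_$trans_sd > 0 || rm_$rot_sd > 0)) {
      ctr <- colMeans(xyz)
      Rf <- .rot_about(rand_unit(), stats::rnorm(1, 0, rm_$rot_sd))
      tf <- stats::rnorm(3, 0, rm_$trans_sd)
      xyz <- sweep(sweep(xyz, 2, ctr) %*% t(Rf), 2, -(ctr + tf))
    }
    coords[, , f] <- xyz
  }

  traj <- md_trajectory(top, coords, spec$box)
  list(trajectory = traj, params = fixture_params(top),
       manifest = do.call(rbind, manifest))
}

#' Default nonbonded parameters for a fixture topology
#'
#' Backbone-like partial charges (net ~0 per residue) and standard
#' Lennard-Jones well depths, assigned by atom name.
#'
#' @param top a fixture `topology`.
#' @return a [nonbonded_params()] with [default_exclusions()].
#' @export
fixture_params <- function(top) {
  tab <- list(N = c(-0.47, 3.30, 0.170), H = c(0.31, 1.07, 0.016),
              CA = c(0.07, 3.40, 0.109), C = c(0.51, 3.40, 0.086),
              O = c(-0.42, 3.00, 0.210))
  ring <- c(0.00, 3.40, 0.086)
  nm <- trimws(top$atoms$name)
  get3 <- function(j) unname(vapply(nm, function(x)
    if (!is.null(tab[[x]])) tab[[x]][j] else ring[j], 0))
  nonbonded_params(get3(1), get3(2), get3(3),
                   default_exclusions(top), nrow(top$atoms))
}

#' Insulin-like reference/variant fixture pair
#'
#' Two 51-residue (21 + 30) two-chain toy systems mimicking a native/modified
#' comparison. Both share the lattice layout and a per-residue fluctuation
#' profile; the variant's B29 residue is a nonstandard aromatic (FLK, written
#' as HETATM) engaged by designed directives: a T-shaped ring pair with A19
#' (COM ~5 A, ~90 deg), a backbone hydrogen bond from A3 (H...O ~2 A), and
#' scheduled heavy-atom contacts with A4 and A18. Terminal residues A1, A2,
#' B26, B28 and B30 fluctuate with sigma 0.6 A in the reference and 0.3 A in
#' the variant; directive residues are rigid so designed populations are
#' exact.
#'
#' @param seed integer seed (drives both systems deterministically).
#' @param n_frames frames per system (default 400).
#' @return list with `reference`, `variant` (each a [generate_fixture()]
#'   result), and `manifest` combining both systems' ground truth plus the
#'   designed contact-population differences (`delta_c` rows) and the
#'   terminal sigma ratio.
#' @export
insulin_like_pair <- function(seed = 1L, n_frames = 400L) {
  a_names <- rep("GLY", 21); b_names <- rep("GLY", 30)
  a_names[2] <- "ILE"; a_names[3] <- "VAL"; a_names[4] <- "GLU"
  a_names[18] <- "ASN"; a_names[19] <- "TYR"
  b_names[26] <- "TYR"; b_names[28] <- "PRO"; b_names[30] <- "THR"
  terminals <- data.frame(chain = c("A", "A", "B", "B", "B"),
                          resno = c(1, 2, 26, 28, 30))
  sig_ref <- cbind(terminals, sigma = 0.6)
  sig_var <- cbind(terminals, sigma = 0.3)

  ref_names <- b_names; ref_names[29] <- "LYS"
  var_names <- b_names; var_names[29] <- "FLK"

  spec_ref <- fixture_spec(chains = list(A = a_names, B = ref_names),
                           n_frames = n_frames, seed = seed,
                           sigma = 0.1, sigma_overrides = sig_ref)
  contacts <- list(
    list(a = c("B", 29), b = c("A", 4), population = 0.9),
    list(a = c("B", 29), b = c("A", 18), population = 0.7))
  hbonds <- list(
    list(donor = c("A", 3), acceptor = c("B", 29), mean = 2.0, sd = 0.15,
         angle_sd = 5))
  rings <- list(
    list(a = c("B", 29), b = c("A", 19), mean_dist = 5.0, dist_sd = 0.3,
         mean_angle = 90, angle_sd = 5))
  spec_var <- fixture_spec(chains = list(A = a_names, B = var_names),
                           n_frames = n_frames, seed = seed + 1L,
                           contacts = contacts, hbonds = hbonds, rings = rings,
                           sigma = 0.1, sigma_overrides = sig_var)
  ref <- generate_fixture(spec_ref)
  var <- generate_fixture(spec_var)

  man_ref <- cbind(system = "reference", ref$manifest)
  man_var <- cbind(system = "variant", var$manifest)
  # designed contact-population differences (reference has no directives)
  vc <- var$manifest[var$manifest$quantity == "contact_population", ]
  dc <- rbind(
    data.frame(system = "delta", quantity = "delta_c", key = vc$key,
               value = vc$value, stringsAsFactors = FALSE),
    data.frame(system = "delta", quantity = "delta_c",
               key = c("B29-A3", "B29-A19"), value = c(1.0, 1.0),
               stringsAsFactors = FALSE),
    data.frame(system = "delta", quantity = "terminal_sigma_ratio",
               key = "variant/reference", value = 0.3 / 0.6,
               stringsAsFactors = FALSE))
  list(reference = ref, variant = var,
       manifest = rbind(man_ref, man_var, dc))
}
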