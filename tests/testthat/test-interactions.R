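# Hydrogen-bond and pi-pi detection against constructed geometry and
# exhaustive brute-force oracles.

linear_hbond_traj <- function(r_ha = 2.0, angle = 180) {
  # donor N-H ... O=C, angle set by tilting the acceptor about the hydrogen
  th <- (180 - angle) * pi / 180
  h <- c(1.01, 0, 0)
  o <- h + r_ha * c(cos(th), sin(th), 0)
  df <- data.frame(chain = "A", resno = c(1, 1, 2, 2),
                   resname = c("GLY", "GLY", "GLY", "GLY"),
                   atom = c("N", "H", "O", "C"),
                   element = c("N", "H", "O", "C"), stringsAsFactors = FALSE)
  md_trajectory(toy_topology(df), rbind(c(0, 0, 0), h, o, o + c(1.23, 0, 0)))
}

test_that("a linear N-H...O geometry at 2 A is detected", {
  hb <- detect_hbonds(linear_hbond_traj(2.0, 180), 1)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$dist_ha, 2.0, tolerance = 1e-9)
  expect_equal(hb$angle, 180, tolerance = 1e-6)
})

test_that("geometry failing any one criterion is rejected", {
  expect_equal(nrow(detect_hbonds(linear_hbond_traj(2.0, 90), 1)), 0)   # angle
  expect_equal(nrow(detect_hbonds(linear_hbond_traj(2.6, 180), 1)), 0)  # H...A
  # D...A criterion: H...A fine but donor pulled away is impossible with a
  # rigid N-H, so tighten max_da instead
  expect_equal(nrow(detect_hbonds(linear_hbond_traj(2.0, 180), 1,
                                  hbond_criteria(max_da = 2.5))), 0)
})

test_that("topologies without hydrogens are rejected with advice", {
  traj <- toy_traj(rbind(c(0, 0, 0), c(3, 0, 0)), element = "N", atom = "N")
  expect_error(detect_hbonds(traj, 1), "explicit hydrogens")
})

test_that("detection matches the exhaustive triple-loop oracle", {
  pair <- insulin_like_pair(seed = 17, n_frames = 3)
  traj <- pair$variant$trajectory
  crit <- hbond_criteria()
  for (f in 1:3) {
    got <- detect_hbonds(traj, f, crit)
    want <- brute_hbonds(traj, f, crit)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$donor, want$donor)
    expect_equal(got$acceptor, want$acceptor)
    expect_equal(got$dist_ha, want$dist_ha, tolerance = 1e-9)
    expect_equal(got$angle, want$angle, tolerance = 1e-6)
  }
})

test_that("tightening any hydrogen-bond criterion never adds records", {
  pair <- insulin_like_pair(seed = 25, n_frames = 2)
  traj <- pair$variant$trajectory
  base <- nrow(detect_hbonds(traj, 1, hbond_criteria()))
  for (crit in list(hbond_criteria(max_ha = 2.0),
                    hbond_criteria(min_angle = 150),
                    hbond_criteria(max_da = 3.0))) {
    expect_lte(nrow(detect_hbonds(traj, 1, crit)), base)
  }
})

test_that("hydrogen-bond detection is invariant under rigid motion", {
  traj <- linear_hbond_traj(2.0, 170)
  set.seed(31)
  R <- random_rotation()
  xyz2 <- sweep(traj$coords[, , 1] %*% t(R), 2, -c(5, -3, 2))
  traj2 <- md_trajectory(traj$topology, xyz2)
  h1 <- detect_hbonds(traj, 1); h2 <- detect_hbonds(traj2, 1)
  expect_equal(h1$dist_ha, h2$dist_ha, tolerance = 1e-9)
  expect_equal(h1$angle, h2$angle, tolerance = 1e-6)
})

test_that("ring templates cover standard aromatics and template residues", {
  df <- function(resname, atoms) data.frame(chain = "A", resno = 1,
                                            resname = resname, atom = atoms,
                                            element = substr(atoms, 1, 1),
                                            stringsAsFactors = FALSE)
  phe <- find_aromatic_rings(toy_topology(df("PHE", c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))))
  expect_length(phe, 1)
  expect_length(phe[[1]]$atoms, 6)
  trp <- find_aromatic_rings(toy_topology(df("TRP", c("CG", "CD1", "NE1", "CE2", "CD2",
                                                      "CE3", "CZ3", "CH2", "CZ2"))))
  expect_length(trp, 2)
  his <- find_aromatic_rings(toy_topology(df("HIS", c("CG", "ND1", "CD2", "CE1", "NE2"))))
  expect_length(his, 1)
  expect_length(his[[1]]$atoms, 5)
  expect_length(find_aromatic_rings(toy_topology(df("GLY", "CA"))), 0)
  # missing ring atom: skipped with a warning, not an error
  expect_warning(r <- find_aromatic_rings(toy_topology(df("PHE", c("CG", "CD1")))),
                 "skipped")
  expect_length(r, 0)
  # configurable template for a nonstandard residue
  xyz <- find_aromatic_rings(toy_topology(df("XYZ", c("C1", "C2", "C3", "C4", "C5", "C6"))),
                             extra_templates = list(XYZ = list(c("C1", "C2", "C3", "C4", "C5", "C6"))))
  expect_length(xyz, 1)
})

test_that("pi-pi classification follows distance and angle thresholds", {
  classify <- function(d, a) {
    traj <- two_ring_traj(d, a)
    rings <- find_aromatic_rings(traj$topology)
    classify_pipi(rings[[1]], rings[[2]], traj, 1)
  }
  r <- classify(5.0, 90)
  expect_equal(r$class, "T-shaped")
  expect_equal(r$dist, 5.0, tolerance = 1e-9)
  expect_equal(r$angle, 90, tolerance = 1e-6)
  expect_equal(classify(3.8, 0)$class, "parallel")
  expect_equal(classify(5.0, 45)$class, "oblique")
  expect_null(classify(8.0, 90))
  expect_equal(classify(5.0, 60.5)$class, "T-shaped")  # just past the bound
  expect_equal(classify(5.0, 29.5)$class, "parallel")
})

test_that("pi-pi classification is symmetric in ring order", {
  traj <- two_ring_traj(4.6, 72)
  rings <- find_aromatic_rings(traj$topology)
  r1 <- classify_pipi(rings[[1]], rings[[2]], traj, 1)
  r2 <- classify_pipi(rings[[2]], rings[[1]], traj, 1)
  expect_equal(r1$dist, r2$dist)
  expect_equal(r1$angle, r2$angle)
  expect_equal(r1$class, r2$class)
})

test_that("interaction counts equal per-frame re-detection and are stable on static frames", {
  pair <- insulin_like_pair(seed = 29, n_frames = 6)
  traj <- pair$variant$trajectory
  counts <- count_interactions(traj)
  for (f in seq_len(n_frames(traj))) {
    expect_equal(counts$n_hbond[f], nrow(detect_hbonds(traj, f)))
    expect_equal(counts$n_pipi[f], nrow(detect_pipi(traj, f)))
  }
  expect_equal(attr(counts, "mean_hbond"), mean(counts$n_hbond))
  # static replicated frame: identical counts everywhere
  one <- subset_frames(traj, 1)
  rep10 <- md_trajectory(traj$topology,
                         array(one$coords[, , 1], c(n_atoms(traj), 3, 10)))
  c10 <- count_interactions(rep10)
  expect_equal(length(unique(c10$n_hbond)), 1)
  expect_equal(length(unique(c10$n_pipi)), 1)
})

test_that("the designed fixture carries one H-bond and one T-shaped pair per frame", {
  pair <- insulin_like_pair(seed = 33, n_frames = 25)
  cv <- count_interactions(pair$variant$trajectory)
  cr <- count_interactions(pair$reference$trajectory)
  expect_gte(attr(cv, "mean_hbond"), 0.9)
  expect_equal(attr(cv, "mean_pipi"), 1.0)
  expect_equal(attr(cr, "mean_hbond"), 0.0)
  expect_equal(attr(cr, "mean_pipi"), 0.0)
  pp <- detect_pipi(pair$variant$trajectory, 1)
  expect_equal(pp$class, "T-shaped")
})
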