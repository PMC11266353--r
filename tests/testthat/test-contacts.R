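# Contact detection, population maps and difference maps.

test_that("contact existence follows the heavy-atom cutoff rule", {
  # two one-atom residues at varying separation
  at <- function(d) toy_traj(rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_equal(nrow(frame_contacts(at(4.4), 1)), 1)
  expect_equal(nrow(frame_contacts(at(4.6), 1)), 0)
  expect_equal(nrow(frame_contacts(at(4.5), 1)), 1)  # boundary inclusive
})

test_that("hydrogens never create contacts", {
  # heavy atoms 6 A apart, hydrogens 1.8 A apart in between
  df <- data.frame(chain = "A", resno = c(1, 1, 2, 2),
                   resname = "GLY", atom = c("CA", "H", "CA", "H"),
                   element = c("C", "H", "C", "H"), stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 0), c(2.1, 0, 0), c(6, 0, 0), c(3.9, 0, 0))
  traj <- md_trajectory(toy_topology(df), xyz)
  expect_equal(nrow(frame_contacts(traj, 1)), 0)
})

test_that("contacts use minimum image when a box is present", {
  traj <- toy_traj(rbind(c(0.5, 5, 5), c(9.5, 5, 5)), box = c(10, 10, 10))
  expect_equal(nrow(frame_contacts(traj, 1)), 1)   # 1 A through the boundary
  traj2 <- toy_traj(rbind(c(0.5, 5, 5), c(9.5, 5, 5)))
  expect_equal(nrow(frame_contacts(traj2, 1)), 0)  # 9 A without box
})

test_that("populations equal designed contact-frame fractions exactly", {
  for (p in c(0, 0.3, 0.7, 1)) {
    spec <- fixture_spec(chains = list(A = c("GLY", "GLY"), B = "GLY"),
                         n_frames = 10, seed = 30 + round(10 * p),
                         contacts = list(list(a = c("A", 1), b = c("B", 1),
                                              population = p)),
                         rigid_motion = list(trans_sd = 0.3, rot_sd = 2))
    fx <- generate_fixture(spec)
    cm <- contact_population(fx$trajectory)
    i <- residue_serial(fx$trajectory$topology, "A", 1)
    j <- residue_serial(fx$trajectory$topology, "B", 1)
    expect_equal(unclass(cm)[i, j], p)
    expect_equal(unclass(cm)[j, i], p)
  }
})

test_that("population matrix equals the mean of brute-force per-frame contacts", {
  spec <- fixture_spec(chains = list(A = c("GLY", "GLY", "GLY"), B = "GLY"),
                       n_frames = 12, seed = 4,
                       contacts = list(list(a = c("A", 2), b = c("B", 1),
                                            population = 0.5)))
  fx <- generate_fixture(spec)
  traj <- fx$trajectory
  cm <- contact_population(traj)
  R <- n_residues(traj)
  acc <- matrix(0, R, R)
  for (f in seq_len(n_frames(traj))) {
    p <- brute_frame_contacts(traj, f, 4.5)
    if (nrow(p)) {
      acc[p] <- acc[p] + 1
      acc[p[, c(2, 1), drop = FALSE]] <- acc[p[, c(2, 1), drop = FALSE]] + 1
    }
  }
  expect_equal(unclass(cm), acc / n_frames(traj), ignore_attr = TRUE)
})

test_that("one-frame populations are binary and cutoff growth is monotone", {
  pair <- insulin_like_pair(seed = 21, n_frames = 1)
  traj <- pair$variant$trajectory
  cm <- contact_population(traj)
  expect_true(all(unclass(cm) %in% c(0, 1)))
  small <- frame_contacts(traj, 1, 4.0)
  large <- frame_contacts(traj, 1, 5.5)
  key <- function(m) paste(m[, 1], m[, 2])
  expect_true(all(key(small) %in% key(large)))
})

test_that("difference maps subtract elementwise and are antisymmetric in arguments", {
  pair <- insulin_like_pair(seed = 8, n_frames = 20)
  cv <- contact_population(pair$variant$trajectory)
  cr <- contact_population(pair$reference$trajectory)
  d1 <- diff_contact_map(cv, cr)
  d2 <- diff_contact_map(cr, cv)
  expect_equal(unclass(d1), -unclass(d2), ignore_attr = TRUE)
  expect_equal(unclass(diff_contact_map(cv, cv)),
               matrix(0, nrow(cv), ncol(cv)), ignore_attr = TRUE)
  expect_true(all(unclass(d1) >= -1 & unclass(d1) <= 1))
  # dimension mismatch is an error
  cm_small <- contact_population(toy_traj(rbind(c(0, 0, 0), c(9, 0, 0))))
  expect_error(diff_contact_map(cv, cm_small), "dimension")
})

test_that("designed population differences are recovered from the manifest", {
  pair <- insulin_like_pair(seed = 15, n_frames = 50)
  cv <- contact_population(pair$variant$trajectory)
  cr <- contact_population(pair$reference$trajectory)
  dm <- diff_contact_map(cv, cr)
  man <- pair$manifest
  dc <- man[man$quantity == "delta_c", ]
  top <- pair$variant$trajectory$topology
  for (k in seq_len(nrow(dc))) {
    ab <- strsplit(dc$key[k], "-")[[1]]
    i <- residue_serial(top, substr(ab[1], 1, 1),
                        as.integer(substring(ab[1], 2)))
    j <- residue_serial(top, substr(ab[2], 1, 1),
                        as.integer(substring(ab[2], 2)))
    expect_equal(unclass(dm)[i, j], dc$value[k])
  }
  # and no undesigned strengthened pairs appear
  up <- which(unclass(dm) > 0.05 & upper.tri(dm), arr.ind = TRUE)
  got <- apply(up, 1, function(r) paste(sort(r), collapse = "-"))
  want <- vapply(dc$key, function(k) {
    ab <- strsplit(k, "-")[[1]]
    i <- residue_serial(top, substr(ab[1], 1, 1), as.integer(substring(ab[1], 2)))
    j <- residue_serial(top, substr(ab[2], 1, 1), as.integer(substring(ab[2], 2)))
    paste(sort(c(i, j)), collapse = "-")
  }, "")
  expect_setequal(unique(got), unique(want))
})

test_that("focal-residue partner lists honour threshold and ordering", {
  pair <- insulin_like_pair(seed = 9, n_frames = 40)
  cm <- contact_population(pair$variant$trajectory)
  b29 <- residue_serial(pair$variant$trajectory$topology, "B", 29)
  part <- contacts_of_residue(cm, b29, 0.5)
  expect_true(all(diff(part$population) <= 0))
  expect_true(all(part$population >= 0.5))
  expect_setequal(part$partner,
                  c(residue_serial(pair$variant$trajectory$topology, "A", 3),
                    residue_serial(pair$variant$trajectory$topology, "A", 4),
                    residue_serial(pair$variant$trajectory$topology, "A", 18),
                    residue_serial(pair$variant$trajectory$topology, "A", 19)))
  expect_equal(nrow(contacts_of_residue(cm, b29, 1.01 - 0.01)), 2)  # only the 1.0 pairs
  expect_error(contacts_of_residue(cm, 99), "range")
  # threshold 0 returns all nonzero partners
  all_part <- contacts_of_residue(cm, b29, 0)
  expect_true(all(all_part$population > 0))
})
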