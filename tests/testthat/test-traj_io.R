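# Multi-model PDB reading/writing and residue serial numbering.

make_pdb_lines <- function(models) {
  # models: list of data.frames (atom, resname, chain, resno, x, y, z, elem)
  out <- character(0)
  for (m in seq_along(models)) {
    df <- models[[m]]
    out <- c(out, sprintf("MODEL     %4d", m),
             sprintf("ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                     seq_len(nrow(df)), df$atom, df$resname, df$chain,
                     df$resno, df$x, df$y, df$z, df$elem),
             "ENDMDL")
  }
  c(out, "END")
}

frag <- function(x0 = 0) data.frame(atom = c("N", "CA", "C"),
                                    resname = "GLY", chain = "A", resno = 1,
                                    x = x0 + c(0, 1.46, 2.0),
                                    y = c(0, 0, 1.4), z = 0, elem = c("N", "C", "C"),
                                    stringsAsFactors = FALSE)

test_that("a two-model three-atom file parses into two frames", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(make_pdb_lines(list(frag(0), frag(1))), f)
  tr <- read_multimodel_pdb(f)
  expect_equal(n_frames(tr), 2)
  expect_equal(n_atoms(tr), 3)
  expect_equal(tr$coords[1, 1, 2] - tr$coords[1, 1, 1], 1)
  expect_false(any(tr$topology$atoms$is_hydrogen))
})

test_that("an atom-count mismatch is reported with the model number", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(make_pdb_lines(list(frag(), frag()[1:2, ])), f)
  expect_error(read_multimodel_pdb(f), "model 2")
})

test_that("an unparseable coordinate field is reported with its line number", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- make_pdb_lines(list(frag()))
  lines[3] <- sub("1.460", "1.4x0", lines[3])
  writeLines(lines, f)
  expect_error(read_multimodel_pdb(f), "line 3")
})

test_that("parsing is independent of CRLF line endings", {
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  lines <- make_pdb_lines(list(frag(), frag(2)))
  writeLines(lines, f1)
  con <- file(f2, "wb"); writeLines(lines, con, sep = "\r\n"); close(con)
  t1 <- read_multimodel_pdb(f1)
  t2 <- read_multimodel_pdb(f2)
  expect_identical(t1$coords, t2$coords)
  expect_identical(t1$topology$atoms$name, t2$topology$atoms$name)
})

test_that("waters and ions are stripped by default but kept on request", {
  f <- withr::local_tempfile(fileext = ".pdb")
  df <- rbind(frag(),
              data.frame(atom = "O", resname = "HOH", chain = "W", resno = 1,
                         x = 30, y = 0, z = 0, elem = "O"))
  writeLines(make_pdb_lines(list(df)), f)
  expect_equal(n_atoms(read_multimodel_pdb(f)), 3)
  expect_equal(n_atoms(read_multimodel_pdb(f, keep_solvent = TRUE)), 4)
})

test_that("round trip preserves coordinates to PDB precision and topology exactly", {
  pair <- insulin_like_pair(seed = 11, n_frames = 4)
  tr <- pair$variant$trajectory
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(tr, f)
  t2 <- read_multimodel_pdb(f)
  expect_lt(max(abs(t2$coords - tr$coords)), 1e-3)
  expect_identical(t2$topology$residues$name, tr$topology$residues$name)
  expect_identical(t2$topology$residues$chain, tr$topology$residues$chain)
  expect_identical(trimws(t2$topology$atoms$name), trimws(tr$topology$atoms$name))
  expect_identical(t2$topology$atoms$het, tr$topology$atoms$het)
  # second round trip is exact (fixed-width quantisation is idempotent)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(t2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("written fixtures parse with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  pair <- insulin_like_pair(seed = 5, n_frames = 2)
  tr <- pair$reference$trajectory
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(tr, f)
  p <- bio3d::read.pdb(f, multi = TRUE, verbose = FALSE)
  expect_equal(nrow(p$atom), n_atoms(tr))
  expect_equal(nrow(p$xyz), n_frames(tr))
  x1 <- matrix(p$xyz[1, ], ncol = 3, byrow = TRUE)
  expect_lt(max(abs(x1 - tr$coords[, , 1])), 1e-3)
})

test_that("a CRYST1 record with right angles populates the box", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       30, 40, 50, 90, 90, 90),
               make_pdb_lines(list(frag()))), f)
  expect_equal(read_multimodel_pdb(f)$box, c(30, 40, 50))
  # non-orthorhombic box is dropped with a warning
  writeLines(c(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       30, 40, 50, 90, 90, 120),
               make_pdb_lines(list(frag()))), f)
  expect_warning(tr <- read_multimodel_pdb(f), "orthorhombic")
  expect_null(tr$box)
})

test_that("residue serial map is a chain-concatenated bijection", {
  top <- insulin_like_topology()
  m <- residue_serial_map(top)
  expect_identical(m$serial_index, 1:51)
  expect_equal(residue_serial(top, "A", 1), 1)
  expect_equal(residue_serial(top, "A", 21), 21)
  expect_equal(residue_serial(top, "B", 1), 22)
  expect_equal(residue_serial(top, "B", 30), 51)
})

test_that("gaps in author numbering do not create serial-index gaps", {
  df <- data.frame(chain = "A", resno = c(7, 8, 10),
                   resname = "GLY", atom = "CA", element = "C",
                   stringsAsFactors = FALSE)
  m <- residue_serial_map(toy_topology(df))
  expect_identical(m$serial_index, 1:3)
  expect_identical(m$resno, c(7, 8, 10))
})

test_that("duplicate chain/resnum pairs are rejected", {
  df <- data.frame(chain = "A", resno = c(1, 1), resname = c("GLY", "ALA"),
                   atom = "CA", element = "C", stringsAsFactors = FALSE)
  expect_error(residue_serial_map(toy_topology(df)), "duplicate")
})

test_that("parameter tables resolve wildcards and report missing atoms", {
  top <- toy_topology(data.frame(chain = "A", resno = c(1, 1, 2),
                                 resname = "GLY", atom = c("N", "CA", "CA"),
                                 element = c("N", "C", "C"),
                                 stringsAsFactors = FALSE))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chain\tresnum\tatom_name\tq\tsigma\tepsilon",
               "A\t1\tN\t-0.4\t3.3\t0.17",
               "*\t*\tCA\t0.1\t3.4\t0.11"), f)
  p <- read_params_table(f, top)
  expect_equal(p$q, c(-0.4, 0.1, 0.1))
  expect_equal(p$sigma, c(3.3, 3.4, 3.4))
  # missing atom is named
  writeLines(c("chain\tresnum\tatom_name\tq\tsigma\tepsilon",
               "*\t*\tCA\t0.1\t3.4\t0.11"), f)
  expect_error(read_params_table(f, top), "A1:N")
  # non-numeric field reports the row
  writeLines(c("chain\tresnum\tatom_name\tq\tsigma\tepsilon",
               "A\t1\tN\tzero\t3.3\t0.17",
               "*\t*\tCA\t0.1\t3.4\t0.11"), f)
  expect_error(read_params_table(f, top), "row 1")
})
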