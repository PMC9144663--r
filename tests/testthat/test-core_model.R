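test_that("XYZ round-trips coordinates and comment-line energies", {
  cf <- build_conformer(beta_spec(id = "rt", energy0K = 0,
                                  free_energy300K = 2.1))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(cf, path)
  back <- read_xyz(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$id, "rt")
  expect_equal(back[[1]]$free_energy300K, 2.1)
  expect_equal(back[[1]]$energy0K, 0)
  expect_equal(as.matrix(back[[1]]$atoms[, c("x", "y", "z")]),
               as.matrix(cf$atoms[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(back[[1]]$atoms$element, cf$atoms$element)
})

test_that("XYZ parser handles toy frames and reports malformed input", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "id=toy E0=0.0 G300=2.1",
               "O 0 0 0", "H 0.96 0 0", "H -0.24 0.93 0"), path)
  cfs <- read_xyz(path)
  expect_length(cfs, 1)
  expect_equal(nrow(cfs[[1]]$atoms), 3)
  expect_equal(cfs[[1]]$free_energy300K, 2.1)

  writeLines(c("x", "bad count", "O 0 0 0"), path)
  expect_error(read_xyz(path), "line 1")
  writeLines(c("2", "", "O 0 0 0", "Xx 1 0 0"), path)
  expect_error(read_xyz(path), "unknown element")
})

test_that("PDB reader accepts a single model and rejects altLocs", {
  skip_if_not_installed("bio3d")
  cf <- build_conformer(beta_spec(id = "p"))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  lines <- sprintf(
    "ATOM  %5d %-4s ALA A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(cf$atoms)), substr(cf$atoms$role, 1, 4),
    cf$atoms$x, cf$atoms$y, cf$atoms$z, toupper(cf$atoms$element))
  writeLines(c(lines, "END"), pdb)
  back <- read_pdb(pdb)
  expect_equal(nrow(back$atoms), nrow(cf$atoms))
  expect_equal(back$atoms$x, cf$atoms$x, tolerance = 1e-3)
  expect_setequal(unique(back$atoms$element), unique(cf$atoms$element))
})

test_that("bond inference reproduces the builder's declared topology", {
  cf <- build_conformer(beta_spec(id = "b"))
  inferred <- infer_bonds(conformer(cf$id, cf$atoms))
  expect_identical(inferred$bonds, cf$bonds)
  # simple distance cases
  two <- conformer("cc", data.frame(element = c("C", "C"),
                                    x = c(0, 1.53), y = 0, z = 0))
  expect_equal(nrow(suppressWarnings(infer_bonds(two))$bonds), 1)
  far <- conformer("nse", data.frame(element = c("N", "Se"),
                                     x = c(0, 3.4), y = 0, z = 0))
  expect_equal(nrow(suppressWarnings(infer_bonds(far))$bonds), 0)
})

test_that("a hydrogen with two heavy-atom bonds is rejected", {
  bad <- conformer("hh", data.frame(element = c("C", "H", "C"),
                                    x = c(0, 1.0, 2.0), y = 0, z = 0))
  expect_error(infer_bonds(bad), "hydrogen")
})

test_that("dihedral is a signed IUPAC torsion with planar limits", {
  # planar cis -> 0, trans -> 180
  at <- data.frame(element = c("C", "C", "C", "C"),
                   x = c(0, 1.5, 2.25, 3.75),
                   y = c(1.3, 0, 1.3, 0), z = 0)
  trans <- conformer("t", at, bonds = rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(dihedral(trans, 1:4), 180)
  at$x[4] <- 0.75   # p4 = p3 + (p1 - p2): eclipsed, U-shaped chain
  at$y[4] <- 2.6
  cis <- conformer("c", at, bonds = rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(dihedral(cis, 1:4), 0)
  # collinear atoms have no torsion
  lin <- data.frame(element = c("C", "C", "C", "C"),
                    x = c(0, 1.5, 3, 4), y = 0, z = 0)
  col <- conformer("l", lin, bonds = rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_error(dihedral(col, 1:4), "collinear")
})

test_that("dihedrals are invariant under rigid motion", {
  cf <- build_conformer(beta_spec(id = "rm"))
  nd0 <- named_dihedrals(cf)
  for (seed in 1:5) {
    moved <- rigid_motion(cf, seed)
    expect_equal(named_dihedrals(moved), nd0, tolerance = 1e-6)
  }
})

test_that("rotamer windows are half-open, total and 360-periodic", {
  expect_equal(classify_rotamer(60), "g+")
  expect_equal(classify_rotamer(180), "a")
  expect_equal(classify_rotamer(-420), "g-")
  # half-open boundaries: (0, 120] g+, (-120, 0] g-
  expect_equal(classify_rotamer(c(0, 120, -120, 1e-9)),
               c("g-", "g+", "a", "g+"))
  set.seed(42)
  ang <- stats::runif(200, -720, 720)
  k <- sample(-3:3, 200, replace = TRUE)
  expect_identical(classify_rotamer(ang), classify_rotamer(ang + 360 * k))
})

test_that("YAML config overrides merge and unknown keys are rejected", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("bond_scale: 1.3",
               "hbond:",
               "  min_angle: 120"), path)
  cfg <- read_config(path)
  expect_equal(cfg$bond_scale, 1.3)
  expect_equal(cfg$hbond$min_angle, 120)
  expect_equal(cfg$pi_contact$max_dist,
               default_config()$pi_contact$max_dist)
  writeLines("no_such_key: 1", path)
  expect_error(read_config(path), "no_such_key")
})
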