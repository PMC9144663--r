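beta <- label_conformer(reference_fixture(lbl("6", DELTA, "_a-", PI_S,
                                          "_g+-10")))
ext <- label_conformer(reference_fixture(lbl("5_a-7", DELTA, "/5_a-", PI_S)))
semi <- label_conformer(reference_fixture(lbl("5_a-7", DELTA, "_g+-7_L")))

test_that("canonical ring lengths hold on the capped-dipeptide template", {
  cf <- beta$conformer
  ix <- rix(cf)
  # residue-1 NH -> own carbonyl O: C5
  expect_identical(ring_size(cf, ix[["H1"]], ix[["O1"]]), 5L)
  # residue-1 NH -> own side-chain Se: 6-ring
  expect_identical(ring_size(cf, ix[["H1"]], ix[["Y1"]]), 6L)
  # residue-2 NH -> residue-1 Se: 7-ring
  expect_identical(ring_size(cf, ix[["H2"]], ix[["Y1"]]), 7L)
  # carboxamide NH -> acetyl O: C10
  expect_identical(ring_size(cf, ix[["H3t"]], ix[["O0"]]), 10L)
  # carboxamide NH -> residue-1 carbonyl O: C7 gamma-turn
  expect_identical(ring_size(cf, ix[["H3t"]], ix[["O1"]]), 7L)
})

test_that("ring counting is purely topological", {
  cf <- beta$conformer
  ix <- rix(cf)
  set.seed(11)
  jit <- cf
  jit$atoms$x <- jit$atoms$x + stats::rnorm(nrow(jit$atoms), 0, 0.05)
  jit$atoms$y <- jit$atoms$y + stats::rnorm(nrow(jit$atoms), 0, 0.05)
  jit$atoms$z <- jit$atoms$z + stats::rnorm(nrow(jit$atoms), 0, 0.05)
  expect_identical(ring_size(jit, ix[["H1"]], ix[["Y1"]]), 6L)
  expect_identical(ring_size(rigid_motion(cf, 3), ix[["H3t"]], ix[["O0"]]),
                   10L)
})

test_that("detected bonds carry the expected classes per family", {
  expect_true(any(beta$hbonds$symbol == lbl("6", DELTA) &
                    beta$hbonds$slot == 1))
  expect_true(any(beta$hbonds$ring_length == 10 & beta$hbonds$slot == 3))
  expect_true(any(ext$hbonds$symbol == lbl("7", DELTA) &
                    ext$hbonds$slot == 2))
  expect_true(any(semi$hbonds$ring_length == 7 &
                    semi$hbonds$acceptor_elem == "O" &
                    semi$hbonds$slot == 3))
  # numeric part of every backbone symbol equals the ring length
  for (lab in list(beta, ext, semi)) {
    hb <- lab$hbonds
    num <- as.integer(sub("[^0-9].*$", "", hb$symbol))
    expect_identical(num, as.integer(hb$ring_length))
  }
})

test_that("a conformer with no close contacts yields an empty bond list", {
  cfg <- default_config()
  cfg$hbond$max_dist[] <- 0.5
  cfg$pi_contact$max_dist <- 0.5
  cf <- beta$conformer
  expect_equal(nrow(detect_hbonds(cf, cfg)), 0)
  expect_identical(family_label(cf, detect_hbonds(cf, cfg),
                                detect_pi_contacts(cf, cfg)), "f-f-f")
})

test_that("side-chain acceptor positions follow the Greek ladder", {
  cf <- beta$conformer
  ix <- rix(cf)
  expect_identical(side_chain_position(cf, ix[["Y1"]]), DELTA)
  expect_identical(side_chain_position(cf, ix[["CG1"]]), "\u03b3")
  expect_identical(side_chain_position(cf, ix[["CB1"]]), "\u03b2")
  expect_true(is.na(side_chain_position(cf, ix[["O1"]])))
  expect_true(is.na(side_chain_position(cf, ix[["O0"]])))  # cap atom
})

test_that("a gamma-position thiol acceptor is labeled 5-gamma (Cys-like)", {
  # hand-built fragment with role table: N-CA-CB-S plus H on N
  atoms <- data.frame(
    element = c("N", "H", "C", "C", "S", "C", "O"),
    x = c(0, -0.6, 1.4, 1.9, 1.2, 2.0, 2.2),
    y = c(0, 0.8, 0.2, 1.6, 2.9, -0.9, -2.1),
    z = 0)
  bonds <- rbind(c(1, 2), c(1, 3), c(3, 4), c(4, 5), c(3, 6), c(6, 7))
  cf <- conformer("cys-like", atoms, bonds = bonds)
  cf <- assign_roles(cf, roles = data.frame(
    index = 1:7, role = c("N1", "H1", "CA1", "CB1", "Y1", "C1", "O1"),
    residue = 1))
  expect_identical(side_chain_position(cf, 5), "\u03b3")
  expect_identical(ring_size(cf, 2, 5), 5L)
})

test_that("gamma-turn chirality follows the enclosed psi and mirrors flip it", {
  c7 <- semi$hbonds[semi$hbonds$ring_length == 7 &
                      semi$hbonds$acceptor_elem == "O", ][1, ]
  expect_identical(gamma_turn_chirality(semi$conformer, c7), "L")
  mir <- label_conformer(mirror_conformer(semi$conformer))
  c7m <- mir$hbonds[mir$hbonds$ring_length == 7 &
                      mir$hbonds$acceptor_elem == "O", ][1, ]
  expect_identical(gamma_turn_chirality(mir$conformer, c7m), "D")
  # non-C7 bonds are rejected
  c10 <- beta$hbonds[beta$hbonds$ring_length == 10, ][1, ]
  expect_error(gamma_turn_chirality(beta$conformer, c10), "C7")
})

test_that("NH-pi detection needs an aromatic ring and the right geometry", {
  expect_true(any(beta$pi_contacts$slot == 2))   # Phe NH over the ring
  expect_true(any(ext$pi_contacts$slot == 3))    # carboxamide NH in extended
  cplx <- reference_fixture("MAA-YMe2-complex")      # no aromatic ring at all
  expect_equal(nrow(detect_pi_contacts(cplx)), 0)
})

test_that("family labels compose statuses, subscripts and duals", {
  expect_identical(beta$label, lbl("6", DELTA, "_a-", PI_S, "_g+-10"))
  expect_match(ext$label, lbl("7", DELTA, "/5"), fixed = TRUE)
  expect_identical(semi$label, lbl("5_a-7", DELTA, "_g+-7_L"))
})

test_that("interaction report writes pm distances and ring labels", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_interaction_report(beta$hbonds, path)
  rep <- utils::read.csv(path)
  expect_named(rep, c("conformer_id", "donor", "acceptor", "distance_pm",
                      "angle_deg", "ring", "label"))
  expect_true(all(rep$distance_pm > 150 & rep$distance_pm < 320))
})
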