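# Synthetic capped-dipeptide builder: assembles Ac-X-Phe-NH2 conformers
# (X = Met or its seleno analogue) from internal coordinates with a declared
# bond topology, so that every downstream operation can be tested against
# known ground truth.

#' Template internal coordinates of the builder
#'
#' Standard amide/aliphatic bond lengths (Angstrom) and valence angles
#' (degrees) used to assemble conformers.  `branch_offset` is the torsion
#' offset of C-beta relative to the carbonyl carbon about the N-CA axis;
#' -122.5 degrees yields L-residues.
#'
#' @return named list of geometry constants.
#' @export
builder_geometry <- function() {
  list(
    r_CT_C = 1.52, r_C_N = 1.335, r_N_CA = 1.455, r_CA_C = 1.522,
    r_C_O = 1.229, r_N_H = 1.01, r_CA_CB = 1.53, r_CB_CG = 1.53,
    r_CG_S = 1.81, r_CG_Se = 1.955, r_S_CE = 1.79, r_Se_CE = 1.95,
    r_CB_CAr = 1.51, r_CAr_CAr = 1.39,
    a_CT_C_N = 115.5, a_CT_C_O = 121.0, a_CA_C_N = 116.0, a_CA_C_O = 121.0,
    a_C_N_CA = 122.0, a_C_N_H = 119.5, a_N_CA_C = 110.0, a_N_CA_CB = 110.5,
    a_CA_CB_CG = 114.0, a_CB_CG_Y = 109.0, a_CG_Y_CE = 98.5,
    a_CB_CG_CAr = 120.0, a_ring = 120.0,
    branch_offset = -122.5,
    omega = 180.0
  )
}

#' Specify a capped-dipeptide conformer to build
#'
#' @param residue1 `"Sem"` (selenium side chain) or `"Met"` (sulfur).
#' @param phi1,psi1,phi2,psi2 backbone dihedrals, degrees in `(-180, 180]`.
#' @param chi1,chi2,chi3 side-chain torsions of residue 1 (N-CA-CB-CG,
#'   CA-CB-CG-Y, CB-CG-Y-CE with Y = S/Se).
#' @param chi1_phe,chi2_phe Phe side-chain torsions (ring-plane torsion
#'   `chi2_phe` defaults to 90).
#' @param id conformer identifier (autogenerated when `NULL`).
#' @param energy0K,free_energy300K optional relative energies, kJ/mol.
#' @return a `"build_spec"` list understood by [build_conformer()].
#' @export
build_spec <- function(residue1 = c("Sem", "Met"),
                       phi1, psi1, phi2, psi2,
                       chi1, chi2, chi3, chi1_phe, chi2_phe = 90,
                       id = NULL, energy0K = NA_real_,
                       free_energy300K = NA_real_) {
  residue1 <- match.arg(residue1)
  ang <- c(phi1 = phi1, psi1 = psi1, phi2 = phi2, psi2 = psi2,
           chi1 = chi1, chi2 = chi2, chi3 = chi3,
           chi1_phe = chi1_phe, chi2_phe = chi2_phe)
  stopifnot(all(is.finite(ang)))
  ang <- wrap_angle(ang)
  if (is.null(id))
    id <- paste0(residue1, "_", paste(round(ang[1:8]), collapse = "_"))
  structure(c(list(residue1 = residue1, id = id, energy0K = energy0K,
                   free_energy300K = free_energy300K), as.list(ang)),
            class = "build_spec")
}

# role -> row order of built atoms (fixed, so all built conformers align)
builder_atom_order <- c(
  "CT0", "C0", "O0", "N1", "H1", "CA1", "C1", "CB1", "O1", "N2", "H2",
  "CA2", "C2", "CB2", "O2", "N3", "H3t", "H3c", "CG1", "Y1", "CE1",
  "CG2", "CDa", "CDb", "CEa", "CEb", "CZ2")

builder_bond_roles <- rbind(
  c("CT0", "C0"), c("C0", "O0"), c("C0", "N1"), c("N1", "H1"),
  c("N1", "CA1"), c("CA1", "C1"), c("CA1", "CB1"), c("C1", "O1"),
  c("C1", "N2"), c("N2", "H2"), c("N2", "CA2"), c("CA2", "C2"),
  c("CA2", "CB2"), c("C2", "O2"), c("C2", "N3"), c("N3", "H3t"),
  c("N3", "H3c"), c("CB1", "CG1"), c("CG1", "Y1"), c("Y1", "CE1"),
  c("CB2", "CG2"), c("CG2", "CDa"), c("CG2", "CDb"), c("CDa", "CEa"),
  c("CDb", "CEb"), c("CEa", "CZ2"), c("CEb", "CZ2"))

#' Build a capped-dipeptide conformer from internal coordinates
#'
#' Atoms are placed sequentially (bond length, valence angle, torsion), so
#' every requested dihedral is reproduced exactly by construction; the
#' declared covalent topology is attached as the bond list and roles are
#' annotated directly.  A steric check rejects geometries with any
#' non-bonded pair closer than 0.8 Angstrom.
#'
#' @param spec a [build_spec()].
#' @param geom geometry template, see [builder_geometry()].
#' @return a role-annotated [conformer()] with bonds.
#' @export
build_conformer <- function(spec, geom = builder_geometry()) {
  stopifnot(inherits(spec, "build_spec"))
  g <- geom
  sel <- spec$residue1 == "Sem"
  r_CG_Y <- if (sel) g$r_CG_Se else g$r_CG_S
  r_Y_CE <- if (sel) g$r_Se_CE else g$r_S_CE

  P <- list()
  P$CT0 <- c(0, 0, 0)
  P$C0 <- c(g$r_CT_C, 0, 0)
  # O0 in the xy-plane off C0
  P$O0 <- c(g$r_CT_C - g$r_C_O * cos(g$a_CT_C_O * DEG),
            g$r_C_O * sin(g$a_CT_C_O * DEG), 0)
  pl <- function(A, B, C, r, th, phi) place_atom(P[[A]], P[[B]], P[[C]],
                                                 r, th, phi)
  P$N1 <- pl("C0", "CT0", "O0", g$r_C_N, g$a_CT_C_N, 180)
  P$H1 <- pl("N1", "C0", "CT0", g$r_N_H, g$a_C_N_H, 0)
  P$CA1 <- pl("N1", "C0", "CT0", g$r_N_CA, g$a_C_N_CA, g$omega)
  P$C1 <- pl("CA1", "N1", "C0", g$r_CA_C, g$a_N_CA_C, spec$phi1)
  P$CB1 <- pl("CA1", "N1", "C0", g$r_CA_CB, g$a_N_CA_CB,
              spec$phi1 + g$branch_offset)
  P$O1 <- pl("C1", "CA1", "N1", g$r_C_O, g$a_CA_C_O, spec$psi1 + 180)
  P$N2 <- pl("C1", "CA1", "N1", g$r_C_N, g$a_CA_C_N, spec$psi1)
  P$H2 <- pl("N2", "C1", "CA1", g$r_N_H, g$a_C_N_H, 0)
  P$CA2 <- pl("N2", "C1", "CA1", g$r_N_CA, g$a_C_N_CA, g$omega)
  P$C2 <- pl("CA2", "N2", "C1", g$r_CA_C, g$a_N_CA_C, spec$phi2)
  P$CB2 <- pl("CA2", "N2", "C1", g$r_CA_CB, g$a_N_CA_CB,
              spec$phi2 + g$branch_offset)
  P$O2 <- pl("C2", "CA2", "N2", g$r_C_O, g$a_CA_C_O, spec$psi2 + 180)
  P$N3 <- pl("C2", "CA2", "N2", g$r_C_N, g$a_CA_C_N, spec$psi2)
  P$H3t <- pl("N3", "C2", "CA2", g$r_N_H, g$a_C_N_H, 0)
  P$H3c <- pl("N3", "C2", "CA2", g$r_N_H, g$a_C_N_H, 180)
  P$CG1 <- pl("CB1", "CA1", "N1", g$r_CB_CG, g$a_CA_CB_CG, spec$chi1)
  P$Y1 <- pl("CG1", "CB1", "CA1", r_CG_Y, g$a_CB_CG_Y, spec$chi2)
  P$CE1 <- pl("Y1", "CG1", "CB1", r_Y_CE, g$a_CG_Y_CE, spec$chi3)
  P$CG2 <- pl("CB2", "CA2", "N2", g$r_CB_CAr, g$a_CA_CB_CG, spec$chi1_phe)
  P$CDa <- pl("CG2", "CB2", "CA2", g$r_CAr_CAr, g$a_CB_CG_CAr,
              spec$chi2_phe)
  P$CDb <- pl("CG2", "CB2", "CA2", g$r_CAr_CAr, g$a_CB_CG_CAr,
              spec$chi2_phe + 180)
  P$CEa <- pl("CDa", "CG2", "CB2", g$r_CAr_CAr, g$a_ring, 180)
  P$CEb <- pl("CDb", "CG2", "CB2", g$r_CAr_CAr, g$a_ring, 180)
  P$CZ2 <- pl("CEa", "CDa", "CG2", g$r_CAr_CAr, g$a_ring, 0)

  order <- builder_atom_order
  xyz <- t(vapply(order, function(nm) P[[nm]], numeric(3)))
  element_of <- c(CT0 = "C", C0 = "C", O0 = "O", N1 = "N", H1 = "H",
                  CA1 = "C", C1 = "C", CB1 = "C", O1 = "O", N2 = "N",
                  H2 = "H", CA2 = "C", C2 = "C", CB2 = "C", O2 = "O",
                  N3 = "N", H3t = "H", H3c = "H", CG1 = "C",
                  Y1 = if (sel) "Se" else "S", CE1 = "C", CG2 = "C",
                  CDa = "C", CDb = "C", CEa = "C", CEb = "C", CZ2 = "C")
  res_of <- c(CT0 = 0, C0 = 0, O0 = 0, N1 = 1, H1 = 1, CA1 = 1, C1 = 1,
              CB1 = 1, O1 = 1, N2 = 2, H2 = 2, CA2 = 2, C2 = 2, CB2 = 2,
              O2 = 2, N3 = 3, H3t = 3, H3c = 3, CG1 = 1, Y1 = 1, CE1 = 1,
              CG2 = 2, CDa = 2, CDb = 2, CEa = 2, CEb = 2, CZ2 = 2)
  atoms <- data.frame(element = unname(element_of[order]),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      role = order, residue = unname(res_of[order]))
  ridx <- stats::setNames(seq_along(order), order)
  bonds <- cbind(ridx[builder_bond_roles[, 1]], ridx[builder_bond_roles[, 2]])
  cf <- conformer(spec$id, atoms, bonds = bonds, energy0K = spec$energy0K,
                  free_energy300K = spec$free_energy300K)
  check_sterics(cf)
  cf
}

check_sterics <- function(conf, min_dist = 0.8) {
  d <- as.matrix(stats::dist(coords_matrix(conf)))
  diag(d) <- Inf
  bonded <- matrix(FALSE, nrow(d), ncol(d))
  bonded[conf$bonds] <- TRUE
  bonded <- bonded | t(bonded)
  clash <- which(d < min_dist & !bonded & upper.tri(d), arr.ind = TRUE)
  if (nrow(clash))
    stop(sprintf("steric clash: atoms %d (%s) and %d (%s) at %.2f A",
                 clash[1, 1], conf$atoms$role[clash[1, 1]],
                 clash[1, 2], conf$atoms$role[clash[1, 2]],
                 d[clash[1, 1], clash[1, 2]]))
  invisible(conf)
}

#' Mirror image of a conformer
#'
#' Reflects all coordinates through the xy-plane.  Dihedral angles change
#' sign, so rotamer classes swap `g+`/`g-` and gamma-turn chiralities swap
#' L/D while the covalent topology is untouched.
#'
#' @param conf a [conformer()].
#' @return the mirrored conformer (id suffixed `"_mirror"`).
#' @export
mirror_conformer <- function(conf) {
  conf$atoms$z <- -conf$atoms$z
  conf$id <- paste0(conf$id, "_mirror")
  conf
}
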