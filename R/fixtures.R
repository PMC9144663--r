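# Catalog of named reference conformers.  Each entry is a build_spec whose
# geometry reproduces the interactions its name announces: the two
# beta-turn forms (intra-residue 6-delta NH...Se bond, Phe NH-pi contact,
# C10 beta-turn bond), the two semi-extended forms (C5, inter-residue
# 7-delta, L gamma-turn) and the fully extended form (doubly engaged
# 7-delta/5 NH plus a carboxamide NH-pi contact).  Side-chain torsions are
# tuned so that the built H...Se distances sit close to the reported
# equilibrium values (roughly 248-259 pm depending on the form), and the
# relative energetics mirror the reported ordering (beta-turn family most
# stable; extended form at +7.6 kJ/mol free energy at 300 K).

fixture_specs <- function(residue1 = "Sem") {
  d <- "\u03b4"; p <- "\u03c0"; gm <- "g-"
  specs <- list()
  nm <- function(...) paste0(...)
  specs[[nm("6", d, "_a-", p, "_g+-10")]] <- list(
    phi1 = -60, psi1 = -30, phi2 = -90, psi2 = 0,
    chi1 = 65, chi2 = -91, chi3 = 180, chi1_phe = 40, chi2_phe = 70,
    energy0K = 0.0, free_energy300K = 0.0)
  specs[[nm("6", d, "_", gm, "-", p, "_g+-10")]] <- list(
    phi1 = -60, psi1 = -30, phi2 = -90, psi2 = 0,
    chi1 = 65, chi2 = -90, chi3 = -60, chi1_phe = 40, chi2_phe = 70,
    energy0K = 1.2, free_energy300K = 1.5)
  specs[[nm("5_a-7", d, "_g+-7_L")]] <- list(
    phi1 = -155, psi1 = 155, phi2 = -80, psi2 = 70,
    chi1 = 180, chi2 = 59, chi3 = 180, chi1_phe = 60, chi2_phe = 90,
    energy0K = 6.5, free_energy300K = 4.2)
  specs[[nm("5_a-7", d, "_", gm, "-7_L")]] <- list(
    phi1 = -155, psi1 = 155, phi2 = -80, psi2 = 70,
    chi1 = 180, chi2 = 56, chi3 = 180, chi1_phe = -60, chi2_phe = 90,
    energy0K = 7.0, free_energy300K = 4.8)
  specs[[nm("5_a-7", d, "/5_a-", p)]] <- list(
    phi1 = -160, psi1 = 160, phi2 = -160, psi2 = 160,
    chi1 = 180, chi2 = 60, chi3 = 180, chi1_phe = 170, chi2_phe = 90,
    energy0K = 11.0, free_energy300K = 7.6)
  specs
}

#' Names of the cataloged reference conformers
#'
#' @return character vector of fixture names accepted by [reference_fixture()];
#'   includes the intermolecular amide-chalcogen reference complex.
#' @export
fixture_catalog <- function() {
  c(names(fixture_specs()), "MAA-YMe2-complex")
}

#' Build a cataloged reference conformer by name
#'
#' The catalog covers the named low-energy forms of the capped dipeptide
#' (see [fixture_catalog()]) plus `"MAA-YMe2-complex"`, an intermolecular
#' trans-methylacetamide / dimethyl-chalcogenide complex used as the
#' constraint-free hydrogen-bond reference.
#'
#' @param name fixture name, one of [fixture_catalog()].
#' @param residue1 `"Sem"` (Se side chain) or `"Met"` (S).
#' @return a role-annotated [conformer()] with bonds and nominal energetics.
#' @export
reference_fixture <- function(name, residue1 = c("Sem", "Met")) {
  residue1 <- match.arg(residue1)
  if (name == "MAA-YMe2-complex") return(build_maa_complex(residue1))
  specs <- fixture_specs(residue1)
  if (!name %in% names(specs))
    stop("unknown fixture '", name, "'; catalog: ",
         paste(fixture_catalog(), collapse = ", "))
  s <- specs[[name]]
  build_conformer(build_spec(
    residue1, phi1 = s$phi1, psi1 = s$psi1, phi2 = s$phi2, psi2 = s$psi2,
    chi1 = s$chi1, chi2 = s$chi2, chi3 = s$chi3, chi1_phe = s$chi1_phe,
    chi2_phe = s$chi2_phe, id = name, energy0K = s$energy0K,
    free_energy300K = s$free_energy300K))
}

#' Build all cataloged dipeptide fixtures
#'
#' @param residue1 `"Sem"` or `"Met"`.
#' @return named list of conformers (the intermolecular complex excluded).
#' @export
fixture_set <- function(residue1 = c("Sem", "Met")) {
  residue1 <- match.arg(residue1)
  nms <- names(fixture_specs())
  stats::setNames(lapply(nms, reference_fixture, residue1 = residue1), nms)
}

# Intermolecular reference: trans-methylacetamide donating its NH to the
# chalcogen of (CH3)2Y in a linear approach at `dist` Angstrom.
build_maa_complex <- function(residue1 = "Sem", dist = 2.55) {
  g <- builder_geometry()
  sel <- residue1 == "Sem"
  P <- list()
  P$CT0 <- c(0, 0, 0)
  P$C0 <- c(g$r_CT_C, 0, 0)
  P$O0 <- c(g$r_CT_C - g$r_C_O * cos(g$a_CT_C_O * DEG),
            g$r_C_O * sin(g$a_CT_C_O * DEG), 0)
  P$N1 <- place_atom(P$C0, P$CT0, P$O0, g$r_C_N, g$a_CT_C_N, 180)
  P$H1 <- place_atom(P$N1, P$C0, P$CT0, g$r_N_H, g$a_C_N_H, 0)
  P$CM1 <- place_atom(P$N1, P$C0, P$CT0, g$r_N_CA, g$a_C_N_CA, 180)
  # near-linear N-H...Y approach (174 degrees)
  P$Y1 <- place_atom(P$H1, P$N1, P$C0, dist, 174, 0)
  r_YC <- if (sel) g$r_Se_CE else g$r_S_CE
  P$CEa <- place_atom(P$Y1, P$H1, P$N1, r_YC, 108, 90)
  P$CEb <- place_atom(P$Y1, P$H1, P$N1, r_YC, 108, -90)
  order <- c("CT0", "C0", "O0", "N1", "H1", "CM1", "Y1", "CEa", "CEb")
  xyz <- t(vapply(order, function(nm) P[[nm]], numeric(3)))
  atoms <- data.frame(
    element = c("C", "C", "O", "N", "H", "C", if (sel) "Se" else "S",
                "C", "C"),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], role = order,
    residue = c(0, 0, 0, 1, 1, 1, 9, 9, 9))
  bonds <- rbind(c(1, 2), c(2, 3), c(2, 4), c(4, 5), c(4, 6), c(7, 8),
                 c(7, 9))
  conformer("MAA-YMe2-complex", atoms, bonds = bonds)
}
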