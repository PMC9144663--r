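# Role perception for the Ac-X-Phe-NH2 template (X = Met or its seleno
# analogue), driven purely by the covalent bond graph, so that conformers
# read from XYZ/PDB files in any atom order are annotated identically to
# built ones.  Arbitrary sequences are supported only through an explicit
# role table.

#' Annotate atoms with backbone/side-chain roles
#'
#' Matches the conformer against the Ac-X-Phe-NH2 template using the bond
#' graph: acetyl cap (`CT0`, `C0`, `O0`), residue 1 backbone (`N1`, `H1`,
#' `CA1`, `C1`, `O1`) and side chain (`CB1`, `CG1`, `Y1` = S/Se, `CE1`),
#' residue 2 backbone (`N2`, `H2`, `CA2`, `C2`, `O2`) and phenyl side chain
#' (`CB2`, `CG2`, ring `CDa`/`CDb`/`CEa`/`CEb`/`CZ2`), and the carboxamide
#' cap (`N3`, `H3t`, `H3c`; `H3t` is the hydrogen *trans* to the carbonyl
#' oxygen, the one positioned to donate backbone-like hydrogen bonds).
#' Residue indices 0-3 are assigned alongside.
#'
#' @param conf a [conformer()] with bonds present (see [infer_bonds()]).
#' @param roles optional data frame with columns `index`, `role`, `residue`
#'   overriding template perception (required for non-template molecules).
#' @return the conformer with `role` and `residue` columns filled.
#' @export
assign_roles <- function(conf, roles = NULL) {
  if (!is.null(roles)) {
    stopifnot(all(c("index", "role", "residue") %in% names(roles)))
    conf$atoms$role <- NA_character_
    conf$atoms$residue <- NA_integer_
    conf$atoms$role[roles$index] <- roles$role
    conf$atoms$residue[roles$index] <- roles$residue
    return(conf)
  }
  if (is.null(conf$bonds)) stop("bond graph not present; run infer_bonds()")
  el <- conf$atoms$element
  nb <- neighbor_list(conf)

  is_carbonyl <- function(i) {
    el[i] == "C" && any(el[nb[[i]]] == "O" & lengths(nb[nb[[i]]]) == 1)
  }
  carbonyls <- Filter(is_carbonyl, seq_along(el))
  if (length(carbonyls) != 3)
    stop("template match failed: expected 3 carbonyl carbons, found ",
         length(carbonyls))
  carbonyl_O <- function(i) nb[[i]][el[nb[[i]]] == "O" &
                                      lengths(nb[nb[[i]]]) == 1][1]

  # acetyl cap: carbonyl whose remaining heavy neighbour is a terminal CH3 C
  term_methyl <- function(i) {
    cc <- nb[[i]][el[nb[[i]]] == "C"]
    cc[vapply(cc, function(j) sum(el[nb[[j]]] != "H") == 1, TRUE)]
  }
  C0 <- carbonyls[vapply(carbonyls, function(i) length(term_methyl(i)) > 0,
                         TRUE)]
  if (length(C0) != 1)
    stop("template match failed: acetyl cap not identifiable")
  CT0 <- term_methyl(C0)[1]
  O0 <- carbonyl_O(C0)

  amide_N <- function(cc) {
    n <- nb[[cc]][el[nb[[cc]]] == "N"]
    if (length(n) != 1) stop("template match failed: amide linkage broken")
    n
  }
  N1 <- amide_N(C0)
  CA1 <- setdiff(nb[[N1]][el[nb[[N1]]] == "C"], C0)
  H1 <- nb[[N1]][el[nb[[N1]]] == "H"]
  C1 <- intersect(nb[[CA1]], carbonyls)
  if (length(CA1) != 1 || length(C1) != 1 || length(H1) != 1)
    stop("template match failed at residue 1 backbone")
  O1 <- carbonyl_O(C1)
  N2 <- amide_N(C1)
  CA2 <- setdiff(nb[[N2]][el[nb[[N2]]] == "C"], C1)
  H2 <- nb[[N2]][el[nb[[N2]]] == "H"]
  C2 <- intersect(nb[[CA2]], carbonyls)
  if (length(CA2) != 1 || length(C2) != 1 || length(H2) != 1)
    stop("template match failed at residue 2 backbone")
  O2 <- carbonyl_O(C2)
  N3 <- amide_N(C2)
  H3 <- nb[[N3]][el[nb[[N3]]] == "H"]
  if (length(H3) != 2)
    stop("template match failed: carboxamide cap must carry two hydrogens")

  # chalcogen side chain: CA1-CB1-CG1-Y1-CE1
  CB1 <- setdiff(nb[[CA1]][el[nb[[CA1]]] == "C"], C1)
  CG1 <- setdiff(nb[[CB1]][el[nb[[CB1]]] == "C"], CA1)
  if (length(CB1) != 1 || length(CG1) != 1)
    stop("template match failed at residue 1 side chain")
  Y1 <- nb[[CG1]][el[nb[[CG1]]] %in% c("S", "Se")]
  if (length(Y1) != 1)
    stop("template match failed: no S/Se side-chain heteroatom")
  CE1 <- setdiff(nb[[Y1]][el[nb[[Y1]]] == "C"], CG1)

  # phenyl side chain: CA2-CB2-CG2-(6-ring)
  CB2 <- setdiff(nb[[CA2]][el[nb[[CA2]]] == "C"], C2)
  CG2 <- setdiff(nb[[CB2]][el[nb[[CB2]]] == "C"], CA2)
  if (length(CB2) != 1 || length(CG2) != 1)
    stop("template match failed at residue 2 side chain")
  CDa <- nb[[CG2]][el[nb[[CG2]]] == "C" & nb[[CG2]] != CB2][1]
  CDb <- setdiff(nb[[CG2]][el[nb[[CG2]]] == "C"], c(CB2, CDa))
  CEa <- setdiff(nb[[CDa]][el[nb[[CDa]]] == "C"], CG2)
  CEb <- setdiff(nb[[CDb]][el[nb[[CDb]]] == "C"], CG2)
  CZ2 <- intersect(nb[[CEa]], nb[[CEb]])
  if (length(CDb) != 1 || length(CEa) != 1 || length(CEb) != 1 ||
      length(CZ2) != 1)
    stop("template match failed: phenyl ring not closed")

  # carboxamide hydrogens: H3t is trans to O2 (|H-N-C-O| torsion near 180)
  xyz <- coords_matrix(conf)
  tor <- vapply(H3, function(h)
    abs(torsion4(xyz[h, ], xyz[N3, ], xyz[C2, ], xyz[O2, ])), 0)
  H3t <- H3[which.max(tor)]
  H3c <- setdiff(H3, H3t)

  idx <- c(CT0 = CT0, C0 = C0, O0 = O0,
           N1 = N1, H1 = H1, CA1 = CA1, CB1 = CB1, CG1 = CG1, Y1 = Y1,
           CE1 = CE1, C1 = C1, O1 = O1,
           N2 = N2, H2 = H2, CA2 = CA2, CB2 = CB2, CG2 = CG2,
           CDa = CDa, CDb = CDb, CEa = CEa, CEb = CEb, CZ2 = CZ2,
           C2 = C2, O2 = O2, N3 = N3, H3t = H3t, H3c = H3c)
  res <- c(CT0 = 0, C0 = 0, O0 = 0,
           N1 = 1, H1 = 1, CA1 = 1, CB1 = 1, CG1 = 1, Y1 = 1, CE1 = 1,
           C1 = 1, O1 = 1,
           N2 = 2, H2 = 2, CA2 = 2, CB2 = 2, CG2 = 2, CDa = 2, CDb = 2,
           CEa = 2, CEb = 2, CZ2 = 2, C2 = 2, O2 = 2,
           N3 = 3, H3t = 3, H3c = 3)
  conf$atoms$role <- NA_character_
  conf$atoms$residue <- NA_integer_
  conf$atoms$role[idx] <- names(idx)
  conf$atoms$residue[idx] <- res[names(idx)]
  conf
}

neighbor_list <- function(conf) {
  n <- nrow(conf$atoms)
  nb <- vector("list", n)
  for (k in seq_len(nrow(conf$bonds))) {
    i <- conf$bonds[k, 1]; j <- conf$bonds[k, 2]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}
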