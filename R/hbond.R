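# Hydrogen-bond detection and the ring-count nomenclature: a backbone NH
# engaged in an NH...O/S/Se contact is named by the atom count of the
# covalent pseudo-cycle the contact closes (C5, C7, C10 for backbone
# acceptors; 6-delta and 7-delta for the side-chain chalcogen at the Greek
# delta position), NH-pi contacts with the Phe ring are detected
# separately, and per-conformer family labels are assembled from the
# per-NH statuses.

GREEK <- c("\u03b2", "\u03b3", "\u03b4", "\u03b5")  # beta gamma delta epsilon
SYM_PI <- "\u03c0"

#' Covalent ring length closed by a putative hydrogen bond
#'
#' Counts the atoms on the shortest covalent path from the donor hydrogen to
#' the acceptor, inclusive of both endpoints.  This counting convention
#' (hydrogen included) reproduces the standard names: C5 for the
#' intra-residue NH...O=C contact, C7 for the gamma-turn, C10 for the
#' beta-turn, 6 for the intra-residue NH...Se/S contact and 7 for its
#' inter-residue counterpart.  Note that some literature counts exclude the
#' hydrogen; this package always includes it.
#'
#' The result is purely topological: it depends on the bond graph only,
#' never on coordinates.
#'
#' @param conf a [conformer()] with bonds.
#' @param donor_H,acceptor 1-based atom indices.
#' @return integer ring length (number of atoms in the pseudo-cycle).
#' @export
ring_size <- function(conf, donor_H, acceptor) {
  g <- conformer_graph(conf)
  d <- igraph::distances(g, v = donor_H, to = acceptor)[1, 1]
  if (!is.finite(d))
    stop("no covalent path between atoms ", donor_H, " and ", acceptor,
         " (disconnected; intermolecular contact?)")
  as.integer(d + 1)
}

#' Greek position of a side-chain acceptor
#'
#' Returns the Greek-letter position (beta, gamma, delta, ...) of an atom
#' relative to its residue's C-alpha, measured as the covalent graph
#' distance along the side chain.  Backbone and cap atoms return `NA`.
#'
#' @param conf a role-annotated [conformer()] with bonds.
#' @param acceptor 1-based atom index.
#' @return a single Greek letter, or `NA_character_` for backbone/cap atoms.
#' @export
side_chain_position <- function(conf, acceptor) {
  role <- conf$atoms$role[acceptor]
  res <- conf$atoms$residue[acceptor]
  if (is.na(role) || is.na(res)) return(NA_character_)
  backbone <- c("N", "H", "CA", "C", "O", "CT", "H3", "CM")
  stem <- sub("[0-9abct]*$", "", role)
  if (stem %in% backbone) return(NA_character_)
  ca <- which(conf$atoms$role == paste0("CA", res))
  if (!length(ca)) return(NA_character_)
  # walk along bonds avoiding backbone atoms other than CA itself
  keep <- which(conf$atoms$residue == res &
                  !(sub("[0-9abct]*$", "", conf$atoms$role) %in%
                      setdiff(backbone, "CA")))
  keep <- union(keep, ca)
  g <- conformer_graph(conf)
  sub <- igraph::induced_subgraph(g, keep)
  d <- igraph::distances(sub, v = match(ca, keep), to = match(acceptor, keep))
  d <- d[1, 1]
  if (!is.finite(d) || d < 1 || d > length(GREEK)) return(NA_character_)
  GREEK[d]
}

#' Detect NH...O/S/Se hydrogen bonds
#'
#' Enumerates every (N-H, acceptor) pair meeting the geometric criteria
#' (per-acceptor-element maximum H...A distance and minimum N-H...A angle,
#' see [default_config()]), computes the covalent ring length of each and
#' classifies it: backbone acceptors carry the bare ring number, side-chain
#' acceptors a Greek superscript (e.g. `"6δ"`), and acceptors with no
#' covalent path to the donor (intermolecular complexes) the symbol `"x"`.
#'
#' @param conf a role-annotated [conformer()] with bonds (see
#'   [assign_roles()]).
#' @param config configuration list.
#' @return a data frame with one row per bond: `conformer_id`, `donor_N`,
#'   `donor_H`, `acceptor`, `acceptor_elem`, `distance_HA` (Angstrom),
#'   `distance_pm`, `angle_NHA` (degrees), `ring_length`, `symbol`, `slot`;
#'   sorted by donor position along the backbone.
#' @export
detect_hbonds <- function(conf, config = default_config()) {
  if (is.null(conf$bonds)) stop("bond graph not present; run infer_bonds()")
  if (all(is.na(conf$atoms$role)))
    stop("conformer lacks backbone role annotation; run assign_roles()")
  el <- conf$atoms$element
  xyz <- coords_matrix(conf)
  nb <- neighbor_list(conf)
  crit <- config$hbond
  g <- conformer_graph(conf)
  dist_topo <- igraph::distances(g)

  donors <- which(el == "N" & vapply(nb, function(x) any(el[x] == "H"),
                                     TRUE))
  acceptors <- which(el %in% c("O", "S", "Se"))
  rows <- list()
  for (dn in donors) {
    for (dh in nb[[dn]][el[nb[[dn]]] == "H"]) {
      for (ac in acceptors) {
        if (ac == dn || ac %in% nb[[dh]]) next
        dHA <- sqrt(sum((xyz[dh, ] - xyz[ac, ])^2))
        if (dHA > crit$max_dist[[el[ac]]]) next
        ang <- angle3(xyz[dn, ], xyz[dh, ], xyz[ac, ])
        if (ang < crit$min_angle) next
        ring <- if (is.finite(dist_topo[dh, ac]))
          as.integer(dist_topo[dh, ac] + 1) else NA_integer_
        if (!is.na(ring) && ring < crit$min_ring) next
        pos <- side_chain_position(conf, ac)
        symbol <- if (is.na(ring)) "x"
          else if (is.na(pos)) as.character(ring)
          else paste0(ring, pos)
        rows[[length(rows) + 1]] <- data.frame(
          conformer_id = conf$id, donor_N = dn, donor_H = dh, acceptor = ac,
          acceptor_elem = el[ac], distance_HA = dHA,
          distance_pm = 100 * dHA, angle_NHA = ang, ring_length = ring,
          symbol = symbol, slot = donor_slot(conf, dn))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(conformer_id = character(), donor_N = integer(),
               donor_H = integer(), acceptor = integer(),
               acceptor_elem = character(), distance_HA = numeric(),
               distance_pm = numeric(), angle_NHA = numeric(),
               ring_length = integer(), symbol = character(),
               slot = integer())
  out[order(out$slot, out$donor_H, -xtfrm(out$ring_length)), ,
      drop = FALSE]
}

# Per-NH-slot interaction statuses (subscripts not yet attached): a status
# is the slash-joined symbol list of the slot, the longer ring first and
# pi last, or "f" for a free NH.
slot_statuses <- function(hbonds, pi_contacts) {
  lapply(1:3, function(s) {
    hb <- hbonds[!is.na(hbonds$slot) & hbonds$slot == s, , drop = FALSE]
    sym <- hb$symbol
    ring <- hb$ring_length
    if (any(!is.na(pi_contacts$slot) & pi_contacts$slot == s)) {
      sym <- c(sym, SYM_PI)
      ring <- c(ring, 0L)
    }
    if (!length(sym)) return(list(status = "f", hb = hb))
    o <- order(-ring)
    sym <- sym[o]
    if (length(sym) > 2)
      stop("slot ", s, " carries more than two simultaneous statuses: ",
           paste(sym, collapse = ", "))
    list(status = paste(sym, collapse = "/"), hb = hb)
  })
}

# NH slot along the backbone: 1 = residue-1 NH, 2 = residue-2 NH,
# 3 = C-terminal carboxamide NH2 (both hydrogens).
donor_slot <- function(conf, donor_N) {
  role <- conf$atoms$role[donor_N]
  if (is.na(role)) return(NA_integer_)
  switch(role, N1 = 1L, N2 = 2L, N3 = 3L, NA_integer_)
}

#' Chirality of a gamma-turn C7 hydrogen bond
#'
#' A C7 (gamma-turn) bond encloses one residue; the turn is the inverse
#' form (labelled L) when that residue's psi dihedral is positive, and the
#' direct form (D) otherwise.  Mirror-image conformers therefore swap L and
#' D.
#'
#' @param conf a role-annotated [conformer()] with bonds.
#' @param hbond one row of the [detect_hbonds()] table.
#' @return `"L"` or `"D"`.
#' @export
gamma_turn_chirality <- function(conf, hbond) {
  if (!isTRUE(hbond$ring_length == 7) || hbond$acceptor_elem != "O")
    stop("gamma-turn chirality is defined only for C7 backbone bonds")
  dn_res <- conf$atoms$residue[hbond$donor_N]
  enclosed <- dn_res - 1L
  nd <- named_dihedrals(conf)
  psi <- nd[[paste0("psi", enclosed)]]
  if (is.null(psi)) stop("cannot locate psi of enclosed residue ", enclosed)
  if (psi > 0) "L" else "D"
}

#' Detect NH-pi contacts with an aromatic ring
#'
#' A contact is recorded when the H...ring-centroid distance is at most the
#' configured cutoff and the elevation angle of the hydrogen above the ring
#' plane is at least the configured minimum.
#'
#' @param conf a role-annotated [conformer()] with bonds.
#' @param config configuration list.
#' @return data frame with `conformer_id`, `donor_N`, `donor_H`,
#'   `distance_H_centroid`, `elevation`, `slot` and a comma-separated
#'   `ring_atoms` column.
#' @export
detect_pi_contacts <- function(conf, config = default_config()) {
  rings <- aromatic_rings(conf)
  crit <- config$pi_contact
  el <- conf$atoms$element
  nb <- neighbor_list(conf)
  xyz <- coords_matrix(conf)
  rows <- list()
  for (ring in rings) {
    cent <- colMeans(xyz[ring, , drop = FALSE])
    n1 <- vhat(vcross(xyz[ring[2], ] - cent, xyz[ring[3], ] - cent))
    donors <- which(el == "N" & vapply(nb, function(x) any(el[x] == "H"),
                                       TRUE))
    for (dn in donors) {
      for (dh in nb[[dn]][el[nb[[dn]]] == "H"]) {
        v <- xyz[dh, ] - cent
        d <- vnorm(v)
        if (d > crit$max_dist) next
        elev <- abs(asin(sum(v * n1) / d)) / DEG
        if (elev < crit$min_elevation) next
        rows[[length(rows) + 1]] <- data.frame(
          conformer_id = conf$id, donor_N = dn, donor_H = dh,
          distance_H_centroid = d, elevation = elev,
          slot = donor_slot(conf, dn),
          ring_atoms = paste(ring, collapse = ","))
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(conformer_id = character(), donor_N = integer(),
               donor_H = integer(), distance_H_centroid = numeric(),
               elevation = numeric(), slot = integer(),
               ring_atoms = character())
}

# All 6-cycles of carbon atoms in the bond graph (the phenyl ring in the
# template; empty when the molecule has no aromatic ring).
aromatic_rings <- function(conf) {
  carbons <- which(conf$atoms$element == "C")
  g <- conformer_graph(conf)
  sub <- igraph::induced_subgraph(g, carbons)
  if (igraph::ecount(sub) == 0) return(list())
  gi <- igraph::girth(sub)
  if (!is.finite(gi$girth) || gi$girth != 6) return(list())
  list(carbons[as.integer(gi$circle)])
}

#' Assemble the per-NH family label of a conformer
#'
#' Builds the hyphen-joined label of the three NH slots in backbone order
#' (residue-1 NH, residue-2 NH, carboxamide NH2).  Each slot carries the
#' symbol of its interaction(s): the covalent ring number, a Greek
#' superscript for side-chain acceptors, `pi` for NH-pi contacts, and `f`
#' for a free NH.  A doubly engaged NH is written with a slash, the
#' longer-ring symbol first (e.g. `"7δ/5"`).  Subscripts: slot 1
#' carries the chi3 rotamer class of the chalcogen side chain, slot 2 the
#' Phe chi1 class, and slot 3 the L/D chirality when it donates a C7
#' gamma-turn bond; free slots are unsubscripted.
#'
#' @param conf a role-annotated [conformer()] with bonds.
#' @param hbonds,pi_contacts optional precomputed tables from
#'   [detect_hbonds()] / [detect_pi_contacts()]; computed when `NULL`.
#' @param config configuration list.
#' @return a single label string.
#' @export
family_label <- function(conf, hbonds = NULL, pi_contacts = NULL,
                         config = default_config()) {
  if (is.null(hbonds)) hbonds <- detect_hbonds(conf, config)
  if (is.null(pi_contacts)) pi_contacts <- detect_pi_contacts(conf, config)
  nd <- named_dihedrals(conf)
  slots <- slot_statuses(hbonds, pi_contacts)
  sub1 <- classify_rotamer(nd["chi3"], config$rotamer_windows)
  sub2 <- classify_rotamer(nd["chi1_phe"], config$rotamer_windows)
  lab <- character(3)
  for (s in 1:3) {
    status <- slots[[s]]$status
    if (status == "f") { lab[s] <- "f"; next }
    suffix <- ""
    if (s == 1) suffix <- paste0("_", sub1)
    if (s == 2) suffix <- paste0("_", sub2)
    if (s == 3) {
      hb <- slots[[s]]$hb
      c7 <- hb[!is.na(hb$ring_length) & hb$ring_length == 7 &
                 hb$acceptor_elem == "O", , drop = FALSE]
      if (nrow(c7))
        suffix <- paste0("_", gamma_turn_chirality(conf, c7[1, ]))
    }
    lab[s] <- paste0(status, suffix)
  }
  paste(lab, collapse = "-")
}

#' Classify, in one call, a conformer read from raw coordinates
#'
#' Convenience wrapper: infers bonds, assigns template roles, detects
#' hydrogen bonds and NH-pi contacts, and returns the label together with
#' the interaction tables.
#'
#' @param conf a [conformer()] (bonds/roles optional).
#' @param config configuration list.
#' @return list with `label`, `hbonds`, `pi_contacts`, `conformer`.
#' @export
label_conformer <- function(conf, config = default_config()) {
  if (is.null(conf$bonds)) conf <- infer_bonds(conf, config)
  if (all(is.na(conf$atoms$role))) conf <- assign_roles(conf)
  hb <- detect_hbonds(conf, config)
  pc <- detect_pi_contacts(conf, config)
  list(label = family_label(conf, hb, pc, config), hbonds = hb,
       pi_contacts = pc, conformer = conf)
}

#' Write an interaction report
#'
#' One CSV row per detected hydrogen bond: conformer id, donor and acceptor
#' (1-based indices), distance in pm, angle in degrees, ring length and
#' classification symbol.
#'
#' @param hbonds table from [detect_hbonds()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_interaction_report <- function(hbonds, path) {
  out <- hbonds[, c("conformer_id", "donor_N", "acceptor", "distance_pm",
                    "angle_NHA", "ring_length", "symbol")]
  names(out) <- c("conformer_id", "donor", "acceptor", "distance_pm",
                  "angle_deg", "ring", "label")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
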