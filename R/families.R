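# Structural families: label-based fingerprints, regrouping of conformers
# into clusters with RMSD deduplication, and Boltzmann statistics.

GAS_CONSTANT_KJ <- 8.314462618e-3  # kJ/(mol K)

#' Structural fingerprint of a conformer
#'
#' The fingerprint pairs the backbone hydrogen-bonding statuses of the three
#' NH slots (subscripts stripped, so `"6δ"`, `"π"`, `"10"`) with the
#' side-chain rotamer string (chi1, chi2, chi3, Phe chi1 classes).  Two
#' conformers with equal fingerprints belong to the same structural family.
#'
#' @param conf a [conformer()]; bonds/roles computed if absent.
#' @param hbonds,pi_contacts optional precomputed interaction tables.
#' @param config configuration list.
#' @return object of class `"family_fingerprint"`: list with
#'   `backbone_labels` (character, length 3), `rotamer_string` (named
#'   character, length 4) and a canonical `key` string.
#' @export
fingerprint <- function(conf, hbonds = NULL, pi_contacts = NULL,
                        config = default_config()) {
  if (is.null(conf$bonds)) conf <- infer_bonds(conf, config)
  if (all(is.na(conf$atoms$role))) conf <- assign_roles(conf)
  if (is.null(hbonds)) hbonds <- detect_hbonds(conf, config)
  if (is.null(pi_contacts)) pi_contacts <- detect_pi_contacts(conf, config)
  backbone <- vapply(slot_statuses(hbonds, pi_contacts), `[[`, "", "status")
  nd <- named_dihedrals(conf)
  rot <- classify_rotamer(nd[c("chi1", "chi2", "chi3", "chi1_phe")],
                          config$rotamer_windows)
  names(rot) <- c("chi1", "chi2", "chi3", "chi1_phe")
  structure(list(backbone_labels = backbone, rotamer_string = rot,
                 key = paste(c(backbone, rot), collapse = "|")),
            class = "family_fingerprint")
}

#' @export
print.family_fingerprint <- function(x, ...) {
  cat("<fingerprint>", paste(x$backbone_labels, collapse = "-"),
      " rotamers:", paste(x$rotamer_string, collapse = ""), "\n")
  invisible(x)
}

#' Regroup conformers into structural clusters
#'
#' Conformers are grouped by fingerprint equality; within a group,
#' near-duplicate geometries (heavy-atom RMSD after optimal superposition
#' below `tol`) are merged, keeping the lowest-free-energy member as the
#' cluster representative.  Clusters are sorted by representative
#' free energy at 300 K.
#'
#' @param conformers list of [conformer()] objects.
#' @param tol RMSD merge tolerance in Angstrom (0 disables merging).
#' @param config configuration list.
#' @return object of class `"conformer_clusters"`: list of clusters, each
#'   with `fingerprint`, `members` (ids), `representative` (a conformer),
#'   `n_members`.
#' @export
cluster_conformers <- function(conformers,
                               tol = default_config()$cluster$rmsd_tolerance,
                               config = default_config()) {
  stopifnot(length(conformers) >= 1)
  fps <- lapply(conformers, fingerprint, config = config)
  keys <- vapply(fps, `[[`, "", "key")
  clusters <- list()
  for (key in unique(keys)) {
    idx <- which(keys == key)
    # deduplicate near-identical geometries, keep lowest dG
    dg <- vapply(conformers[idx], function(cf)
      ifelse(is.finite(cf$free_energy300K), cf$free_energy300K, Inf), 0)
    idx <- idx[order(dg)]
    kept <- integer()
    for (i in idx) {
      dup <- tol > 0 && any(vapply(kept, function(j)
        heavy_atom_rmsd(conformers[[i]], conformers[[j]]) < tol, TRUE))
      if (!dup) kept <- c(kept, i)
    }
    rep <- conformers[[kept[1]]]
    clusters[[length(clusters) + 1]] <- list(
      fingerprint = fps[[idx[1]]],
      members = vapply(conformers[kept], `[[`, "", "id"),
      representative = rep, n_members = length(kept))
  }
  repdg <- vapply(clusters, function(cl)
    ifelse(is.finite(cl$representative$free_energy300K),
           cl$representative$free_energy300K, Inf), 0)
  structure(clusters[order(repdg)], class = "conformer_clusters")
}

#' @export
print.conformer_clusters <- function(x, ...) {
  cat("<conformer_clusters>", length(x), "cluster(s)\n")
  for (cl in x)
    cat(sprintf("  %-24s n=%d  rep=%s  dG300=%s\n",
                paste(cl$fingerprint$backbone_labels, collapse = "-"),
                cl$n_members, cl$representative$id,
                format(cl$representative$free_energy300K)))
  invisible(x)
}

#' Boltzmann populations from relative free energies
#'
#' `p_i = exp(-dG_i / RT) / sum_j exp(-dG_j / RT)` with
#' R = 8.314462618 J/(mol K).  Energies in kJ/mol.
#'
#' @param dG numeric vector of relative free energies (kJ/mol).
#' @param temperature temperature in K (> 0).
#' @return numeric vector of populations summing to 1.
#' @export
boltzmann_populations <- function(dG, temperature = 300) {
  stopifnot(all(is.finite(dG)))
  if (temperature <= 0) stop("temperature must be positive")
  w <- exp(-(dG - min(dG)) / (GAS_CONSTANT_KJ * temperature))
  w / sum(w)
}

#' Thermodynamic landscape of a conformer set
#'
#' Normalises energies to the set minimum (so `min == 0`), computes 300 K
#' Boltzmann populations and, when `clusters` is given, annotates family
#' labels.
#'
#' @param conformers list of [conformer()] objects with free energies.
#' @param temperature temperature in K for the populations.
#' @return data frame: `conformer_id`, `dE0K`, `dG300K`, `population`.
#' @export
thermo_table <- function(conformers, temperature = 300) {
  e0 <- vapply(conformers, `[[`, 0, "energy0K")
  dg <- vapply(conformers, `[[`, 0, "free_energy300K")
  if (any(!is.finite(dg)))
    stop("all conformers need a free energy for the thermodynamic table")
  e0 <- e0 - min(e0, na.rm = TRUE)
  dg <- dg - min(dg)
  data.frame(conformer_id = vapply(conformers, `[[`, "", "id"),
             dE0K = e0, dG300K = dg,
             population = boltzmann_populations(dg, temperature))
}

#' Write the conformational-landscape report
#'
#' One CSV row per cluster: family label, member count, representative
#' relative energies and 300 K population (populations computed over the
#' representatives).
#'
#' @param clusters result of [cluster_conformers()].
#' @param path output CSV path.
#' @return the report data frame, invisibly.
#' @export
write_landscape_report <- function(clusters, path) {
  reps <- lapply(clusters, `[[`, "representative")
  tab <- thermo_table(reps)
  out <- data.frame(
    family_label = vapply(clusters, function(cl)
      paste(cl$fingerprint$backbone_labels, collapse = "-"), ""),
    n_members = vapply(clusters, `[[`, 0L, "n_members"),
    dE0K = tab$dE0K, dG300K = tab$dG300K, population_300K = tab$population)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
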