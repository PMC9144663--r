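#' Default analysis configuration
#'
#' Returns the full set of tunable parameters used across the pipeline:
#' covalent radii and the bond-detection scale factor, rotamer windows,
#' hydrogen-bond and NH-pi geometric criteria, NH-stretch band regions, the
#' free-energy window and spectral tolerances used in assignment.
#'
#' Every value can be overridden through [read_config()] or by editing the
#' returned list.  Units: distances in Angstrom, angles in degrees,
#' wavenumbers in cm-1, energies in kJ/mol.
#'
#' @return a named list of parameter groups.
#' @export
default_config <- function() {
  list(
    covalent_radii = c(H = 0.31, C = 0.76, N = 0.71, O = 0.66,
                       S = 1.05, Se = 1.20),
    bond_scale = 1.20,
    # 120-degree windows centred on +60 (g+), -60 (g-) and 180 (a);
    # half-open as (lo, hi].
    rotamer_windows = list(
      "g+" = c(0, 120),
      "g-" = c(-120, 0),
      "a"  = c(120, 240)
    ),
    hbond = list(
      # maximum H...acceptor distance per acceptor element
      max_dist = c(O = 2.60, S = 3.00, Se = 3.00),
      # The C5 pseudo-cycle caps the attainable N-H...O angle near 100-105
      # degrees, so the gate sits below that; stronger bonds all exceed it.
      min_angle = 95,       # minimum N-H...A angle
      min_ring = 4          # smallest covalent pseudo-cycle reported
    ),
    pi_contact = list(
      max_dist = 3.0,       # H...ring-centroid
      min_elevation = 30    # angle of H above the ring plane, degrees
    ),
    # positions in 3400-3420 or above 3560 fall in no region and classify
    # as "unclassified"
    band_regions = list(
      "H-bonded"         = c(0, 3400),
      "weak-interaction" = c(3420, 3460),
      "free-NH"          = c(3460, 3510),
      "NH2-antisym"      = c(3510, 3560)
    ),
    assignment = list(
      energy_window = 10,   # kJ/mol at 300 K
      rms_tolerance = 20    # cm-1, flag matches above this
    ),
    cluster = list(
      rmsd_tolerance = 0.3  # heavy-atom RMSD (Angstrom) for deduplication
    )
  )
}

#' Read a YAML configuration file
#'
#' Loads a YAML file and merges it over [default_config()].  Only keys
#' present in the default schema are accepted; an unknown key raises an
#' error naming it, so typos never silently fall back to defaults.
#'
#' @param path path to a YAML file; `NULL` returns the defaults unchanged.
#' @return a configuration list as from [default_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_config(cfg, user, prefix = NULL)
}

merge_config <- function(base, user, prefix = NULL) {
  if (length(user) == 0) return(base)
  for (key in names(user)) {
    full <- paste(c(prefix, key), collapse = "$")
    if (!key %in% names(base))
      stop("unknown configuration key: ", full, call. = FALSE)
    if (is.list(base[[key]]) && is.list(user[[key]])) {
      base[[key]] <- merge_config(base[[key]], user[[key]], prefix = full)
    } else {
      val <- user[[key]]
      if (is.list(val)) val <- unlist(val)
      if (!is.null(names(base[[key]])) && !is.null(names(val)))
        base[[key]][names(val)] <- val
      else base[[key]] <- val
    }
  }
  base
}
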