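#' Construct a conformer object
#'
#' A conformer holds an ordered atom table (element, Cartesian coordinates in
#' Angstrom, optional semantic role and residue index), an undirected covalent
#' bond list, and relative energetics: the 0 K electronic energy difference
#' and the 300 K free-energy difference to the most stable conformer of the
#' set it belongs to (kJ/mol).
#'
#' Residue numbering follows the capped-dipeptide convention: 0 = acetyl cap,
#' 1 = first residue (Met or its seleno analogue), 2 = Phe, 3 = C-terminal
#' carboxamide cap.
#'
#' @param id conformer identifier string.
#' @param atoms data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `role`, `residue`.
#' @param bonds two-column integer matrix of 1-based atom indices, or `NULL`
#'   to leave bonds to [infer_bonds()].
#' @param energy0K,free_energy300K relative energies in kJ/mol (`NA` if
#'   unknown).
#' @return an object of class `"conformer"`.
#' @export
conformer <- function(id, atoms, bonds = NULL, energy0K = NA_real_,
                      free_energy300K = NA_real_) {
  stopifnot(is.data.frame(atoms),
            all(c("element", "x", "y", "z") %in% names(atoms)))
  supported <- c("H", "C", "N", "O", "S", "Se")
  bad <- setdiff(unique(atoms$element), supported)
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  if (!"role" %in% names(atoms)) atoms$role <- NA_character_
  if (!"residue" %in% names(atoms)) atoms$residue <- NA_integer_
  if (!is.null(bonds)) {
    bonds <- normalize_bonds(bonds, nrow(atoms))
  }
  structure(list(id = as.character(id), atoms = atoms, bonds = bonds,
                 energy0K = energy0K, free_energy300K = free_energy300K),
            class = "conformer")
}

normalize_bonds <- function(bonds, natoms) {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (any(bonds < 1) || any(bonds > natoms))
    stop("bond index out of range")
  swap <- bonds[, 1] > bonds[, 2]
  bonds[swap, ] <- bonds[swap, 2:1]
  bonds <- unique(bonds)
  bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
}

#' @export
print.conformer <- function(x, ...) {
  cat("<conformer>", x$id, "\n")
  cat("  atoms:", nrow(x$atoms), " bonds:",
      if (is.null(x$bonds)) "not inferred" else nrow(x$bonds), "\n")
  if (is.finite(x$energy0K) || is.finite(x$free_energy300K))
    cat(sprintf("  dE(0 K) = %s kJ/mol, dG(300 K) = %s kJ/mol\n",
                format(x$energy0K), format(x$free_energy300K)))
  invisible(x)
}

coords_matrix <- function(conf) {
  as.matrix(conf$atoms[, c("x", "y", "z")])
}

conformer_graph <- function(conf) {
  if (is.null(conf$bonds)) stop("bond graph not present; run infer_bonds()")
  g <- igraph::make_empty_graph(n = nrow(conf$atoms), directed = FALSE)
  igraph::add_edges(g, t(conf$bonds))
}

# ---- XYZ I/O ----------------------------------------------------------------

#' Read a (multi-frame) XYZ file
#'
#' Standard XYZ: atom-count line, comment line, then one `element x y z` row
#' per atom.  The comment line may carry whitespace-separated `key=value`
#' metadata; recognised keys are `id`, `E0` and `G300` (relative energies in
#' kJ/mol).
#'
#' @param path path to an XYZ file.
#' @return a list of [conformer()] objects, bonds not yet inferred.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop("malformed atom count at line ", i, ": '", lines[i], "'")
    if (i + 1L + n > length(lines))
      stop("truncated frame starting at line ", i)
    frame <- frame + 1L
    meta <- parse_xyz_comment(lines[i + 1L])
    rows <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(rows), "\\s+")
    bad <- which(vapply(tok, length, 1L) < 4L)
    if (length(bad))
      stop("malformed atom record at line ", i + 1L + bad[1])
    el <- vapply(tok, `[[`, "", 1L)
    el <- normalize_element(el, line0 = i + 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop("non-numeric coordinate in frame starting at line ", i)
    id <- if (!is.null(meta$id)) meta$id else paste0("frame", frame)
    out[[frame]] <- conformer(
      id, data.frame(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
      energy0K = if (!is.null(meta$E0)) as.numeric(meta$E0) else NA_real_,
      free_energy300K = if (!is.null(meta$G300)) as.numeric(meta$G300)
                        else NA_real_)
    i <- i + 2L + n
  }
  out
}

parse_xyz_comment <- function(line) {
  toks <- regmatches(line, gregexpr("[A-Za-z0-9_.+-]+=[^ \t]+", line))[[1]]
  if (!length(toks)) return(list())
  kv <- strsplit(toks, "=", fixed = TRUE)
  stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
}

normalize_element <- function(el, line0 = NA) {
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
  ok <- el %in% c("H", "C", "N", "O", "S", "Se")
  if (!all(ok)) {
    j <- which(!ok)[1]
    where <- if (is.na(line0)) "" else paste0(" at line ", line0 + j)
    stop("unknown element '", el[j], "'", where)
  }
  el
}

#' Write conformers to a multi-frame XYZ file
#'
#' The comment line records `id=` and, when set, `E0=` / `G300=` so that
#' [read_xyz()] round-trips energies exactly.
#'
#' @param conformers a [conformer()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(conformers, path) {
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in conformers) {
    meta <- paste0("id=", cf$id)
    if (is.finite(cf$energy0K))
      meta <- paste(meta, paste0("E0=", format(cf$energy0K, digits = 17)))
    if (is.finite(cf$free_energy300K))
      meta <- paste(meta, paste0("G300=", format(cf$free_energy300K,
                                                 digits = 17)))
    writeLines(as.character(nrow(cf$atoms)), con)
    writeLines(meta, con)
    writeLines(sprintf("%-2s %18.10f %18.10f %18.10f", cf$atoms$element,
                       cf$atoms$x, cf$atoms$y, cf$atoms$z), con)
  }
  invisible(path)
}

#' Read a single-model PDB file
#'
#' Parses ATOM/HETATM records through the bio3d reader.  Multi-model files
#' and alternate locations other than blank or "A" are rejected.
#'
#' @param path path to a PDB file.
#' @return a single [conformer()] (bonds not yet inferred).
#' @export
read_pdb <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_pdb() requires the bio3d package")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  if (!is.null(dim(pdb$xyz)) && nrow(pdb$xyz) > 1)
    stop("multi-model PDB files are not supported")
  alt <- pdb$atom$alt
  if (any(!is.na(alt) & !alt %in% c("", "A")))
    stop("alternate locations other than blank/'A' are not supported")
  el <- pdb$atom$elesy
  if (any(is.na(el) | !nzchar(el)))
    el <- substr(trimws(pdb$atom$elety), 1, 2)
  el <- sub("[0-9'].*$", "", el)
  el <- normalize_element(trimws(el))
  conformer(basename(path),
            data.frame(element = el, x = pdb$atom$x, y = pdb$atom$y,
                       z = pdb$atom$z))
}

# ---- bond inference ---------------------------------------------------------

#' Infer the covalent bond graph from interatomic distances
#'
#' Two atoms are bonded when their distance does not exceed
#' `scale * (r_cov(e1) + r_cov(e2))`, with covalent radii and scale taken
#' from the configuration.  A hydrogen bonded to two or more heavy atoms is
#' rejected as geometrically invalid; an atom with no bonds raises a warning.
#'
#' @param conf a [conformer()].
#' @param config configuration list, see [default_config()].
#' @return the conformer with its `bonds` matrix filled in.
#' @export
infer_bonds <- function(conf, config = default_config()) {
  radii <- config$covalent_radii
  scale <- config$bond_scale
  el <- conf$atoms$element
  xyz <- coords_matrix(conf)
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  rsum <- outer(radii[el], radii[el], "+") * scale
  adj <- d <= rsum & upper.tri(d)
  bonds <- which(adj, arr.ind = TRUE)
  bonds <- normalize_bonds(bonds[, c(1, 2), drop = FALSE], n)
  deg <- tabulate(c(bonds), nbins = n)
  if (any(deg == 0))
    warning("atom(s) with no covalent bond: ",
            paste(which(deg == 0), collapse = ", "))
  hv <- el[bonds[, 1]] != "H" & el[bonds[, 2]] != "H"
  hdeg <- tabulate(c(bonds[!hv, ]), nbins = n)
  over <- which(el == "H" & hdeg >= 2)
  if (length(over))
    stop("hydrogen with more than one covalent bond (invalid geometry): ",
         paste(over, collapse = ", "))
  conf$bonds <- bonds
  conf
}

# ---- dihedrals and rotamers -------------------------------------------------

#' Signed torsion angle over four atoms
#'
#' Computes the IUPAC signed torsion for a quadruple of atom indices; the
#' atoms must be distinct and consecutively bonded.
#'
#' @param conf a [conformer()] with bonds present.
#' @param quad integer vector of four 1-based atom indices.
#' @param check check that consecutive pairs are bonded (default `TRUE`).
#' @return angle in degrees, in `(-180, 180]`.
#' @export
dihedral <- function(conf, quad, check = TRUE) {
  stopifnot(length(quad) == 4)
  if (anyDuplicated(quad)) stop("dihedral atoms must be distinct")
  if (check) {
    if (is.null(conf$bonds)) stop("bond graph not present; run infer_bonds()")
    key <- paste(pmin(conf$bonds[, 1], conf$bonds[, 2]),
                 pmax(conf$bonds[, 1], conf$bonds[, 2]))
    for (k in 1:3) {
      pk <- paste(min(quad[k], quad[k + 1]), max(quad[k], quad[k + 1]))
      if (!pk %in% key)
        stop("atoms ", quad[k], " and ", quad[k + 1], " are not bonded")
    }
  }
  xyz <- coords_matrix(conf)
  torsion4(xyz[quad[1], ], xyz[quad[2], ], xyz[quad[3], ], xyz[quad[4], ])
}

#' Classify a torsion angle into a rotamer class
#'
#' Wraps the angle into `(-180, 180]` and bins it into 120-degree windows:
#' `(0, 120]` is *gauche+* (`g+`), `(-120, 0]` is *gauche-* (`g-`) and the
#' remainder (around 180) is *anti* (`a`).  Total on all finite angles and
#' periodic with period 360.
#'
#' @param angle angle(s) in degrees.
#' @param windows rotamer window list as in [default_config()].
#' @return character vector of classes among `"g+"`, `"g-"`, `"a"`.
#' @export
classify_rotamer <- function(angle, windows = default_config()$rotamer_windows) {
  stopifnot(all(is.finite(angle)))
  vapply(angle, function(a) {
    for (cls in names(windows)) {
      w <- windows[[cls]]
      # membership in (lo, hi] modulo 360
      shifted <- a - 360 * ceiling((a - w[2]) / 360)   # largest a+360k <= hi
      if (shifted > w[1] && shifted <= w[2]) return(cls)
    }
    "a"
  }, "")
}

#' Named backbone and side-chain dihedrals of a capped dipeptide
#'
#' Requires role annotation (see [assign_roles()]).  Returns phi/psi for both
#' residues, the side-chain torsions chi1 (N-CA-CB-CG), chi2 (CA-CB-CG-Y,
#' Y = S or Se), chi3 (CB-CG-Y-CE) and the Phe chi1.
#'
#' @param conf a role-annotated [conformer()] with bonds.
#' @return named numeric vector of angles in degrees.
#' @export
named_dihedrals <- function(conf) {
  ix <- role_index(conf)
  c(phi1 = dihedral(conf, c(ix["C0"], ix["N1"], ix["CA1"], ix["C1"])),
    psi1 = dihedral(conf, c(ix["N1"], ix["CA1"], ix["C1"], ix["N2"])),
    phi2 = dihedral(conf, c(ix["C1"], ix["N2"], ix["CA2"], ix["C2"])),
    psi2 = dihedral(conf, c(ix["N2"], ix["CA2"], ix["C2"], ix["N3"])),
    chi1 = dihedral(conf, c(ix["N1"], ix["CA1"], ix["CB1"], ix["CG1"])),
    chi2 = dihedral(conf, c(ix["CA1"], ix["CB1"], ix["CG1"], ix["Y1"])),
    chi3 = dihedral(conf, c(ix["CB1"], ix["CG1"], ix["Y1"], ix["CE1"])),
    chi1_phe = dihedral(conf, c(ix["N2"], ix["CA2"], ix["CB2"], ix["CG2"])))
}

role_index <- function(conf) {
  r <- conf$atoms$role
  if (all(is.na(r))) stop("conformer lacks role annotation; run assign_roles()")
  ix <- stats::setNames(seq_len(nrow(conf$atoms)), r)
  ix[!is.na(r)]
}
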