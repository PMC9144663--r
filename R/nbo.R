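# Natural bond orbital (NBO) second-order stabilization energies of
# hydrogen bonds: reading tabulated E(2) entries, summing the lone-pair
# donation channels of one bond (sum E_HB), summing every donation into
# one sigma*_NH acceptor (sum E_NH), and the semi-log distance/energy and
# shift/energy correlations.

KCAL_TO_KJ <- 4.184

#' Read an NBO second-order perturbation table (CSV schema)
#'
#' The schema stands in for quantum-chemistry program output: columns
#' `conformer_id`, `donor_orbital` (e.g. `n_Se`, `n'_Se`, `n_O`,
#' `pi_ring`), `donor_atom` (1-based index or NA), `acceptor_orbital`
#' (e.g. `sigma*_NH`), `acceptor_bond` (`N<i>-H<j>`), `E2`.  The energy
#' unit must be declared in a comment header line `# E2_unit: kJ/mol` (or
#' `kcal/mol`, converted on read: 1 kcal = 4.184 kJ).
#'
#' @param path CSV path.
#' @return data frame of entries with `E2` in kJ/mol.
#' @export
read_nbo_table <- function(path) {
  header <- readLines(path, n = 5)
  unit_line <- grep("^#\\s*E2_unit:", header, value = TRUE)
  if (!length(unit_line))
    stop("NBO table must declare its energy unit in a '# E2_unit:' header")
  unit <- trimws(sub("^#\\s*E2_unit:", "", unit_line[1]))
  if (!unit %in% c("kJ/mol", "kcal/mol"))
    stop("unknown E2 unit '", unit, "' (use kJ/mol or kcal/mol)")
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("conformer_id", "donor_orbital", "acceptor_orbital",
            "acceptor_bond", "E2")
  if (!all(need %in% names(df)))
    stop("NBO table must have columns: ", paste(need, collapse = ", "))
  bad <- which(!grepl("^(n'?_[A-Za-z]+|pi_ring|sigma)", df$donor_orbital))
  if (length(bad))
    stop("malformed donor orbital label in row ", bad[1], ": '",
         df$donor_orbital[bad[1]], "'")
  if (any(df$E2 < 0)) stop("E2 stabilization energies must be >= 0")
  if (unit == "kcal/mol") df$E2 <- df$E2 * KCAL_TO_KJ
  df
}

#' Write an NBO table with a unit header
#'
#' @param entries data frame in the NBO schema (energies in kJ/mol).
#' @param path output CSV path.
#' @param unit unit to write (`"kJ/mol"` or `"kcal/mol"`).
#' @return `path`, invisibly.
#' @export
write_nbo_table <- function(entries, path, unit = c("kJ/mol", "kcal/mol")) {
  unit <- match.arg(unit)
  out <- entries
  if (unit == "kcal/mol") out$E2 <- out$E2 / KCAL_TO_KJ
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# E2_unit: ", unit), con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Total hydrogen-bond stabilization (sum E_HB) of one bond
#'
#' Sums E(2) over the entries whose donor orbital sits on the acceptor
#' atom of the designated hydrogen bond (the chalcogen lone pairs `n_Y`
#' and `n'_Y`) and whose acceptor orbital is the sigma* of the designated
#' N-H.
#'
#' @param entries NBO entries (kJ/mol) of one conformer.
#' @param donor_N,donor_H atom indices of the N-H bond.
#' @param acceptor atom index of the hydrogen-bond acceptor.
#' @return sum E_HB in kJ/mol (0 when no entry matches).
#' @export
sum_hbond_stabilization <- function(entries, donor_N, donor_H, acceptor) {
  bond <- paste0("N", donor_N, "-H", donor_H)
  sel <- entries$acceptor_bond == bond &
    grepl("^sigma", entries$acceptor_orbital) &
    !is.na(entries$donor_atom) & entries$donor_atom == acceptor &
    grepl("^n'?_", entries$donor_orbital)
  sum(entries$E2[sel])
}

#' Total donation into one sigma*_NH acceptor (sum E_NH)
#'
#' Sums E(2) over all donor orbitals feeding the sigma* of the designated
#' N-H: beyond the hydrogen-bond lone pairs this includes accompanying C5
#' and NH-pi channels, so `sum E_NH >= sum E_HB` always.
#'
#' @param entries NBO entries (kJ/mol) of one conformer.
#' @param donor_N,donor_H atom indices of the N-H bond.
#' @return sum E_NH in kJ/mol.
#' @export
total_sigma_star_energy <- function(entries, donor_N, donor_H) {
  bond <- paste0("N", donor_N, "-H", donor_H)
  sel <- entries$acceptor_bond == bond &
    grepl("^sigma", entries$acceptor_orbital)
  sum(entries$E2[sel])
}

#' Summarise hydrogen-bond stabilizations of a conformer
#'
#' Combines a detected hydrogen-bond table with NBO entries into one row
#' per NH...S/Se bond: distance, sum E_HB and sum E_NH.
#'
#' @param hbonds table from [detect_hbonds()].
#' @param entries NBO entries (kJ/mol).
#' @return data frame `conformer_id`, `donor_N`, `donor_H`, `acceptor`,
#'   `symbol`, `distance_pm`, `sumE_HB`, `sumE_NH`.
#' @export
hbond_stabilization <- function(hbonds, entries) {
  chalc <- hbonds[hbonds$acceptor_elem %in% c("S", "Se"), , drop = FALSE]
  out <- chalc[, c("conformer_id", "donor_N", "donor_H", "acceptor",
                   "symbol", "distance_pm")]
  # atom indices repeat across conformers, so entries must be restricted
  # to the conformer each bond belongs to
  per <- function(i) entries[entries$conformer_id == chalc$conformer_id[i],
                             , drop = FALSE]
  out$sumE_HB <- vapply(seq_len(nrow(chalc)), function(i)
    sum_hbond_stabilization(per(i), chalc$donor_N[i], chalc$donor_H[i],
                            chalc$acceptor[i]), 0)
  out$sumE_NH <- vapply(seq_len(nrow(chalc)), function(i)
    total_sigma_star_energy(per(i), chalc$donor_N[i], chalc$donor_H[i]),
    0)
  out
}

#' Exponential decay fit of stabilization versus hydrogen-bond distance
#'
#' Least squares on the semi-log relation `ln(sum E) = c - d * r` with r in
#' pm.  Points with non-positive energies are excluded with a warning.
#' Per-point residuals flag bonds above the trend (enhanced) or below it
#' (frustrated).
#'
#' @param distance_pm H...acceptor distances, pm.
#' @param energy stabilization energies, kJ/mol (> 0).
#' @return object of class `"decay_fit"`: list with `c` (intercept), `d`
#'   (decay rate, 1/pm), `r_squared`, `residuals` (log scale), `flag`
#'   (`"above"`/`"below"` trend) and the fitted `lm` object.
#' @export
distance_energy_fit <- function(distance_pm, energy) {
  stopifnot(length(distance_pm) == length(energy))
  keep <- energy > 0
  if (any(!keep))
    warning(sum(!keep), " point(s) with non-positive energy excluded")
  distance_pm <- distance_pm[keep]
  energy <- energy[keep]
  if (length(energy) < 3)
    stop("need at least 3 points with positive energy")
  fit <- stats::lm(log(energy) ~ distance_pm)
  cf <- stats::coef(fit)
  res <- unname(stats::residuals(fit))
  y <- log(energy)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else 1
  structure(list(c = unname(cf[1]), d = -unname(cf[2]),
                 r_squared = r2,
                 residuals = res,
                 flag = ifelse(res > 0, "above", "below"),
                 fit = fit),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> ln(E) = %.4g - %.4g * r_pm   (R^2 = %.4f, n = %d)\n",
    x$c, x$d, x$r_squared, length(x$residuals)))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) c(c = object$c, d = object$d)

#' Per-approach-class correlation of NH-stretch shift with sum E_NH
#'
#' Fits `shift ~ sumE_NH` separately for each geometrical approach class
#' (e.g. the 7-delta, 6-delta and intermolecular families) and reports
#' whether the slopes differ beyond their combined standard errors.
#' Classes with fewer than 2 points are skipped with a warning.
#'
#' @param shift NH-stretch red shifts, cm-1.
#' @param energy total stabilizations sum E_NH, kJ/mol.
#' @param class approach-class labels (character).
#' @return object of class `"shift_correlation"`: list with `fits` (per
#'   class: slope, intercept, slope SE, n) and `slope_comparison` (data
#'   frame of pairwise differences and combined SEs).
#' @export
shift_energy_correlation <- function(shift, energy, class) {
  stopifnot(length(shift) == length(energy),
            length(shift) == length(class))
  fits <- list()
  for (cl in unique(class)) {
    i <- class == cl
    if (sum(i) < 2) {
      warning("class '", cl, "' has fewer than 2 points; skipped")
      next
    }
    fit <- stats::lm(shift[i] ~ energy[i])
    sm <- summary(fit)$coefficients
    fits[[cl]] <- list(slope = unname(sm[2, 1]),
                       intercept = unname(sm[1, 1]),
                       slope_se = unname(sm[2, 2]), n = sum(i))
  }
  comp <- NULL
  nms <- names(fits)
  if (length(nms) >= 2) {
    pairs <- utils::combn(nms, 2)
    comp <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- fits[[pairs[1, k]]]; b <- fits[[pairs[2, k]]]
      dd <- a$slope - b$slope
      se <- sqrt(a$slope_se^2 + b$slope_se^2)
      data.frame(class_a = pairs[1, k], class_b = pairs[2, k],
                 slope_diff = dd, combined_se = se,
                 distinct = is.finite(se) && abs(dd) > se)
    }))
  }
  structure(list(fits = fits, slope_comparison = comp),
            class = "shift_correlation")
}

#' @export
print.shift_correlation <- function(x, ...) {
  cat("<shift_correlation>\n")
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %-15s slope %.4g +/- %.3g cm-1 per kJ/mol (n = %d)\n",
                nm, f$slope, f$slope_se, f$n))
  }
  if (!is.null(x$slope_comparison)) {
    for (k in seq_len(nrow(x$slope_comparison))) {
      r <- x$slope_comparison[k, ]
      cat(sprintf("  %s vs %s: slopes %s beyond combined SE\n", r$class_a,
                  r$class_b, if (r$distinct) "differ" else "do not differ"))
    }
  }
  invisible(x)
}
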