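# Matching experimental band lists to candidate scaled stick spectra.
# Scoring follows the conformer-selective IR assignment practice: the
# candidate pairing minimising the sum of squared deviations is scored by
# its RMS and maximum unsigned error, and candidates are ranked jointly
# with their 300 K free energies.

#' Construct an experimental band list
#'
#' @param id spectrum identifier (e.g. `"A"`).
#' @param bands band positions in cm-1, strictly increasing.
#' @param excluded positions flagged as extraneous (e.g. a band assigned to
#'   a minor co-populated species); they are dropped before matching.
#' @param labels optional band labels.
#' @return object of class `"experimental_spectrum"`.
#' @export
experimental_spectrum <- function(id, bands, excluded = numeric(),
                                  labels = NULL) {
  stopifnot(all(is.finite(bands)))
  if (is.unsorted(bands, strictly = TRUE))
    stop("band positions must be strictly increasing")
  if (length(excluded) && !all(excluded %in% bands))
    stop("excluded positions must appear in the band list")
  structure(list(id = id, bands = bands, excluded = excluded,
                 labels = labels), class = "experimental_spectrum")
}

#' @export
print.experimental_spectrum <- function(x, ...) {
  cat("<experimental_spectrum>", x$id, ":",
      paste(format(x$bands), collapse = ", "), "cm-1\n")
  if (length(x$excluded))
    cat("  excluded:", paste(format(x$excluded), collapse = ", "), "\n")
  invisible(x)
}

included_bands <- function(exp) setdiff(exp$bands, exp$excluded)

#' Optimal pairing of experimental and theoretical bands
#'
#' Finds the pairing minimising the sum of squared deviations.  With equal
#' counts this is a bijection; with unequal counts the
#' `min(n, m)`-subset with minimal cost is selected.  Because both lists
#' are sorted and the cost is squared distance, the optimum is a monotone
#' (non-crossing) alignment, found exactly by dynamic programming; it
#' agrees with exhaustive enumeration (see the test suite).
#'
#' @param exp an [experimental_spectrum()] (exclusions honoured) or a
#'   numeric vector.
#' @param theo a `"stick_spectrum"` from [scale_spectrum()] or a numeric
#'   vector of scaled positions.
#' @param strict_carriers when `TRUE` (requires a stick spectrum),
#'   NH2-antisym modes are matched only against experimental bands in the
#'   NH2-antisym region, the remaining bands separately.
#' @param regions band regions used by the strict mode.
#' @return object of class `"band_pairing"`: data frame with
#'   `exp_position`, `theo_position`, `carrier` (when available) and
#'   `deviation` columns.
#' @export
match_bands <- function(exp, theo, strict_carriers = FALSE,
                        regions = default_config()$band_regions) {
  if (strict_carriers) {
    if (!inherits(theo, "data.frame"))
      stop("strict carrier matching needs a stick spectrum with carriers")
    ex <- if (inherits(exp, "experimental_spectrum")) included_bands(exp)
          else sort(exp)
    ex_anti <- classify_band(ex, regions) == "NH2-antisym"
    th_anti <- theo$mode_class == "NH2-antisym"
    parts <- list()
    if (any(ex_anti) && any(th_anti))
      parts$anti <- match_bands(ex[ex_anti], theo[th_anti, , drop = FALSE])
    if (any(!ex_anti) && any(!th_anti))
      parts$rest <- match_bands(ex[!ex_anti],
                                theo[!th_anti, , drop = FALSE])
    if (!length(parts)) stop("cannot match empty spectra")
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    class(out) <- c("band_pairing", "data.frame")
    return(out)
  }
  ex <- if (inherits(exp, "experimental_spectrum")) included_bands(exp)
        else sort(exp)
  carriers <- NULL
  if (inherits(theo, "data.frame")) {
    th <- theo$f_scaled
    carriers <- theo$carrier
  } else th <- theo
  o <- order(th)
  th <- th[o]
  if (!is.null(carriers)) carriers <- carriers[o]
  if (!length(ex) || !length(th))
    stop("cannot match empty spectra")
  swap <- length(ex) > length(th)
  x <- if (swap) th else ex
  y <- if (swap) ex else th
  m <- length(x); n <- length(y)
  f <- matrix(Inf, m + 1, n + 1)
  f[1, ] <- 0
  for (i in seq_len(m)) for (j in i:n)
    f[i + 1, j + 1] <- min(f[i + 1, j],
                           f[i, j] + (x[i] - y[j])^2)
  # backtrack
  pairs <- matrix(NA_integer_, m, 2)
  j <- n
  for (i in m:1) {
    while (j > i && f[i + 1, j + 1] == f[i + 1, j]) j <- j - 1
    pairs[i, ] <- c(i, j)
    j <- j - 1
  }
  ei <- if (swap) pairs[, 2] else pairs[, 1]
  ti <- if (swap) pairs[, 1] else pairs[, 2]
  out <- data.frame(exp_position = ex[ei], theo_position = th[ti],
                    carrier = if (!is.null(carriers)) carriers[ti]
                              else NA_character_)
  out$deviation <- out$theo_position - out$exp_position
  class(out) <- c("band_pairing", "data.frame")
  out
}

#' RMS and maximum unsigned error of a band pairing
#'
#' @param pairing a `"band_pairing"` from [match_bands()] (or any data
#'   frame with a `deviation` column).
#' @return named numeric vector `c(rms, max_err)`, cm-1.
#' @export
spectral_errors <- function(pairing) {
  stopifnot(nrow(pairing) >= 1)
  d <- pairing$deviation
  c(rms = sqrt(mean(d^2)), max_err = max(abs(d)))
}

#' Score and rank candidate conformers against one experimental spectrum
#'
#' Candidates are filtered to the free-energy window, scored by the optimal
#' pairing, and sorted by RMS error with ties broken by free energy and
#' then maximum error.  The full scored table is retained for audit.
#'
#' @param exp an [experimental_spectrum()].
#' @param candidates a list; each element needs `conformer_id`, `spectrum`
#'   (stick spectrum or numeric positions) and `dG300K` (kJ/mol), and may
#'   carry a `label`.
#' @param energy_window free-energy window in kJ/mol (default from
#'   configuration).
#' @param rms_tolerance matches with RMS above this (cm-1) are flagged.
#' @param strict_carriers see [match_bands()].
#' @return data frame of class `"match_table"`, best candidate first, with
#'   columns `conformer_id`, `label`, `dG300K`, `rms`, `max_err`,
#'   `n_pairs`, `flagged`, `in_window`.
#' @export
rank_candidates <- function(exp, candidates,
                            energy_window =
                              default_config()$assignment$energy_window,
                            rms_tolerance =
                              default_config()$assignment$rms_tolerance,
                            strict_carriers = FALSE) {
  stopifnot(length(candidates) >= 1)
  rows <- lapply(candidates, function(cand) {
    pr <- match_bands(exp, cand$spectrum, strict_carriers = strict_carriers)
    er <- spectral_errors(pr)
    data.frame(conformer_id = cand$conformer_id,
               label = if (!is.null(cand$label)) cand$label
                       else cand$conformer_id,
               dG300K = cand$dG300K, rms = er[["rms"]],
               max_err = er[["max_err"]], n_pairs = nrow(pr),
               flagged = er[["rms"]] > rms_tolerance,
               in_window = cand$dG300K <= energy_window)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(!tab$in_window, tab$rms, tab$dG300K, tab$max_err), ]
  rownames(tab) <- NULL
  if (!any(tab$in_window))
    warning("no candidate inside the ", energy_window,
            " kJ/mol free-energy window")
  class(tab) <- c("match_table", "data.frame")
  tab
}

#' Assign a set of experimental spectra to candidate conformers
#'
#' For each experimental spectrum the best in-window candidate is selected;
#' a spectrum whose best RMS exceeds the tolerance is reported as
#' unassigned.
#'
#' @param exp_spectra list of [experimental_spectrum()] objects.
#' @param candidates candidate list as in [rank_candidates()].
#' @param energy_window,rms_tolerance,strict_carriers see
#'   [rank_candidates()].
#' @return object of class `"assignment_report"`: list with `assignments`
#'   (data frame: `spectrum_id`, `conformer_id`, `label`, `rms`, `max_err`,
#'   `dG300K`, `assigned`), `n_distinct` and the per-spectrum `tables`.
#' @export
assign_conformers <- function(exp_spectra, candidates,
                              energy_window =
                                default_config()$assignment$energy_window,
                              rms_tolerance =
                                default_config()$assignment$rms_tolerance,
                              strict_carriers = FALSE) {
  tables <- lapply(exp_spectra, rank_candidates, candidates = candidates,
                   energy_window = energy_window,
                   rms_tolerance = rms_tolerance,
                   strict_carriers = strict_carriers)
  rows <- lapply(seq_along(exp_spectra), function(i) {
    tab <- tables[[i]]
    best <- tab[1, ]
    data.frame(spectrum_id = exp_spectra[[i]]$id,
               conformer_id = best$conformer_id, label = best$label,
               rms = best$rms, max_err = best$max_err,
               dG300K = best$dG300K,
               assigned = best$in_window && !best$flagged)
  })
  assignments <- do.call(rbind, rows)
  structure(list(assignments = assignments,
                 n_distinct = length(unique(
                   assignments$conformer_id[assignments$assigned])),
                 tables = stats::setNames(
                   tables, vapply(exp_spectra, `[[`, "", "id"))),
            class = "assignment_report")
}

#' @export
print.assignment_report <- function(x, ...) {
  cat("<assignment_report>", nrow(x$assignments), "spectra,",
      x$n_distinct, "distinct assigned conformer(s)\n")
  df <- x$assignments
  df$rms <- round(df$rms, 2)
  df$max_err <- round(df$max_err, 2)
  print.data.frame(df)
  invisible(x)
}

#' Read an experimental band-list CSV
#'
#' Expected columns: `id`, `position_cm1`, optional logical/0-1 `excluded`.
#'
#' @param path CSV path.
#' @return named list of [experimental_spectrum()] objects.
#' @export
read_exp_bands <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "position_cm1")
  if (!all(need %in% names(df)))
    stop("band list must have columns: ", paste(need, collapse = ", "))
  if (!"excluded" %in% names(df)) df$excluded <- FALSE
  out <- lapply(split(df, df$id), function(d) {
    d <- d[order(d$position_cm1), ]
    experimental_spectrum(d$id[1], d$position_cm1,
                          excluded = d$position_cm1[as.logical(d$excluded)])
  })
  out[order(names(out))]
}
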