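# Synthetic NH-stretch mode tables and NBO tables with known ground truth.
#
# The spectral generator is an explicit stand-in model, not first-principles
# physics: free NH carriers sit at fixed base positions (on the scaled,
# i.e. observable, frequency axis), hydrogen-bonded carriers are red-shifted
# by an exponential function of the H...acceptor distance with an
# approach-class-dependent amplitude (the inter-residue 7-delta approach is
# more efficient than the intra-residue 6-delta one), and weak interactions
# (C5, NH-pi) apply small fixed shifts.  Harmonic frequencies are produced
# by inverting the packaged scaling laws, so that running the scaling
# pipeline on the generated table reproduces the intended positions
# exactly at zero jitter.

#' Parameters of the synthetic NH-stretch generator
#'
#' @param base named base positions (scaled axis, cm-1) for free carriers.
#' @param S0 red-shift amplitudes (cm-1) at the reference distance, per
#'   approach class: `sidechain_7` (inter-residue NH...S/Se), `sidechain_6`
#'   (intra-residue), `backbone` (C7/C10 NH...O=C).
#' @param r0 reference H...acceptor distances (Angstrom) per element.
#' @param lambda decay lengths (Angstrom) per element.
#' @param weak fixed shifts (cm-1) for C5 and NH-pi interactions.
#' @param antisym_coupling fraction of the carboxamide shift transferred to
#'   the antisymmetric NH2 stretch.
#' @param jitter Gaussian noise sigma (cm-1) added to the intended
#'   positions.
#' @param seed optional RNG seed for the jitter.
#' @return a list of generator parameters.
#' @export
synth_spectrum_spec <- function(
    base = c("peptide-NH" = 3485, "NH2-sym" = 3435, "NH2-antisym" = 3545),
    S0 = c(sidechain_7 = 240, sidechain_6 = 140, backbone = 160),
    r0 = c(Se = 2.50, S = 2.46, O = 1.80),
    lambda = c(Se = 0.125, S = 0.125, O = 0.35),
    weak = c(C5 = 45, pi = 40),
    antisym_coupling = 0.15,
    jitter = 0, seed = NULL) {
  list(base = base, S0 = S0, r0 = r0, lambda = lambda, weak = weak,
       antisym_coupling = antisym_coupling, jitter = jitter, seed = seed)
}

# red shift of one hydrogen bond under the stand-in model
hbond_red_shift <- function(hb, spec) {
  el <- hb$acceptor_elem
  if (el %in% c("S", "Se")) {
    S0 <- if (!is.na(hb$ring_length) && hb$ring_length >= 7)
      spec$S0[["sidechain_7"]] else spec$S0[["sidechain_6"]]
  } else {
    if (!is.na(hb$ring_length) && hb$ring_length == 5)
      return(spec$weak[["C5"]])
    S0 <- spec$S0[["backbone"]]
  }
  S0 * exp(-(hb$distance_HA - spec$r0[[el]]) / spec$lambda[[el]])
}

#' Generate the synthetic NH-stretch mode table of a conformer
#'
#' Computes the intended (observable-axis) band position of each of the
#' four NH oscillators from the conformer's detected interactions, then
#' inverts the scaling laws to emit harmonic frequencies.  The strongest
#' interaction of a slot determines its shift; the carboxamide antisym
#' stretch is shifted by `antisym_coupling` times the slot-3 shift.
#'
#' @param conf a [conformer()] (bonds/roles computed when absent).
#' @param spec generator parameters, see [synth_spectrum_spec()].
#' @param laws scaling laws used for the inversion.
#' @param config configuration list for interaction detection.
#' @return list with `modes` (data frame ready for [scale_spectrum()]) and
#'   `truth` (per-carrier intended positions, shifts and interactions).
#' @export
synth_frequencies <- function(conf, spec = synth_spectrum_spec(),
                              laws = default_scaling_laws(),
                              config = default_config()) {
  lab <- label_conformer(conf, config)
  conf <- lab$conformer
  statuses <- slot_statuses(lab$hbonds, lab$pi_contacts)
  slot_shift <- vapply(1:3, function(s) {
    sh <- 0
    hb <- lab$hbonds[!is.na(lab$hbonds$slot) & lab$hbonds$slot == s, ,
                     drop = FALSE]
    if (nrow(hb))
      sh <- max(vapply(seq_len(nrow(hb)), function(i)
        hbond_red_shift(hb[i, ], spec), 0))
    if (any(!is.na(lab$pi_contacts$slot) & lab$pi_contacts$slot == s))
      sh <- max(sh, spec$weak[["pi"]])
    sh
  }, 0)
  intended <- c(
    spec$base[["peptide-NH"]] - slot_shift[1],
    spec$base[["peptide-NH"]] - slot_shift[2],
    spec$base[["NH2-sym"]] - slot_shift[3],
    spec$base[["NH2-antisym"]] - spec$antisym_coupling * slot_shift[3])
  carriers <- c("NH-1", "NH-2", "NH2-sym", "NH2-antisym")
  classes <- c("peptide-NH", "peptide-NH", "NH2-sym", "NH2-antisym")
  target <- intended
  if (spec$jitter > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    target <- target + stats::rnorm(4, 0, spec$jitter)
  }
  f_harm <- vapply(seq_along(target), function(i) {
    cf <- coef(laws[[classes[i]]])
    (target[i] - cf[["a"]]) / cf[["b"]]
  }, 0)
  modes <- data.frame(conformer_id = conf$id, carrier = carriers,
                      mode_class = classes, f_harmonic = f_harm)
  truth <- data.frame(conformer_id = conf$id, carrier = carriers,
                      slot = c(1, 2, 3, 3),
                      status = c(vapply(statuses, `[[`, "", "status")[1:3],
                                 statuses[[3]]$status),
                      shift = c(slot_shift,
                                spec$antisym_coupling * slot_shift[3]),
                      intended = intended)
  list(modes = modes, truth = truth)
}

#' Generate a synthetic NBO second-order perturbation table
#'
#' For every NH...S/Se hydrogen bond, emits the two chalcogen lone-pair
#' donation channels (`n_Y` and `n'_Y` into the sigma* orbital of the
#' donor N-H) with total stabilization following the semi-log decay
#' `ln(sum E2) = c - d * r` (r in pm), split between the channels at the
#' given ratio.  Optional extra channels emulate accompanying C5 (carbonyl
#' lone pair) and NH-pi (ring) donations into the same sigma*.
#'
#' @param hbonds table from [detect_hbonds()].
#' @param pi_contacts optional table from [detect_pi_contacts()].
#' @param c_par,d_par decay-law parameters (`c_par` dimensionless on the
#'   log-kJ/mol scale, `d_par` in 1/pm).
#' @param ratio fraction of the total in the first lone-pair channel.
#' @param extra_C5,extra_pi E2 values (kJ/mol) of the accompanying
#'   channels; 0 suppresses them.
#' @param noise relative lognormal-ish noise (multiplies each total by
#'   `1 + rnorm(0, noise)`).
#' @param seed optional RNG seed.
#' @return data frame in the NBO CSV schema: `conformer_id`,
#'   `donor_orbital`, `donor_atom`, `acceptor_orbital`, `acceptor_bond`,
#'   `E2` (kJ/mol), plus a `distance_pm` convenience column.
#' @export
synth_nbo_table <- function(hbonds, pi_contacts = NULL, c_par = 9.65,
                            d_par = 0.025, ratio = 0.7, extra_C5 = 2.0,
                            extra_pi = 1.5, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  add <- function(id, dorb, datom, abond, e2, rpm) {
    rows[[length(rows) + 1]] <<- data.frame(
      conformer_id = id, donor_orbital = dorb, donor_atom = datom,
      acceptor_orbital = "sigma*_NH", acceptor_bond = abond, E2 = e2,
      distance_pm = rpm)
  }
  nh_bond_label <- function(hb) paste0("N", hb$donor_N, "-H", hb$donor_H)
  chalc <- hbonds[hbonds$acceptor_elem %in% c("S", "Se"), , drop = FALSE]
  for (i in seq_len(nrow(chalc))) {
    hb <- chalc[i, ]
    total <- exp(c_par - d_par * hb$distance_pm)
    if (noise > 0) total <- total * max(1e-6, 1 + stats::rnorm(1, 0, noise))
    y <- hb$acceptor_elem
    add(hb$conformer_id, paste0("n_", y), hb$acceptor, nh_bond_label(hb),
        ratio * total, hb$distance_pm)
    add(hb$conformer_id, paste0("n'_", y), hb$acceptor, nh_bond_label(hb),
        (1 - ratio) * total, hb$distance_pm)
  }
  if (extra_C5 > 0) {
    c5 <- hbonds[!is.na(hbonds$ring_length) & hbonds$ring_length == 5 &
                   hbonds$acceptor_elem == "O", , drop = FALSE]
    for (i in seq_len(nrow(c5))) {
      hb <- c5[i, ]
      add(hb$conformer_id, "n_O", hb$acceptor, nh_bond_label(hb),
          extra_C5, hb$distance_pm)
    }
  }
  if (extra_pi > 0 && !is.null(pi_contacts) && nrow(pi_contacts)) {
    for (i in seq_len(nrow(pi_contacts))) {
      pc <- pi_contacts[i, ]
      add(pc$conformer_id, "pi_ring", NA_integer_,
          paste0("N", pc$donor_N, "-H", pc$donor_H), extra_pi,
          100 * pc$distance_H_centroid)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(conformer_id = character(), donor_orbital = character(),
               donor_atom = integer(), acceptor_orbital = character(),
               acceptor_bond = character(), E2 = numeric(),
               distance_pm = numeric())
}
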