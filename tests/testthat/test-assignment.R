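test_that("band pairing matches brute-force enumeration on small spectra", {
  pr <- match_bands(c(3400, 3500), c(3498, 3402))
  expect_equal(pr$exp_position, c(3400, 3500))
  expect_equal(pr$theo_position, c(3402, 3498))
  # identical lists pair identically at zero cost
  pr2 <- match_bands(c(3300, 3400, 3500), c(3300, 3400, 3500))
  expect_equal(spectral_errors(pr2), c(rms = 0, max_err = 0))
  # randomized oracle including unequal counts, up to 6 bands
  set.seed(17)
  for (k in 1:40) {
    n_ex <- sample(2:6, 1)
    n_th <- sample(2:6, 1)
    ex <- sort(stats::runif(n_ex, 3200, 3600))
    th <- sort(stats::runif(n_th, 3200, 3600))
    pr <- match_bands(ex, th)
    expect_equal(sum(pr$deviation^2),
                 brute_force_pairing(ex, th)$cost, tolerance = 1e-9)
    expect_equal(nrow(pr), min(n_ex, n_th))
    # the compared subset is matched bijectively
    expect_false(anyDuplicated(pr$exp_position) > 0)
    expect_false(anyDuplicated(pr$theo_position) > 0)
  }
  expect_error(match_bands(numeric(), c(3400)), "empty")
})

test_that("exclusions are honoured: the asterisk band is discarded", {
  ex <- experimental_spectrum("D", c(3288, 3357, 3445, 3452, 3523),
                              excluded = 3452)
  theo <- c(3290, 3355, 3444, 3525)
  pr <- match_bands(ex, theo)
  expect_equal(nrow(pr), 4)
  expect_false(3452 %in% pr$exp_position)
  expect_error(experimental_spectrum("x", c(1, 2), excluded = 3),
               "must appear")
  expect_error(experimental_spectrum("x", c(2, 1)), "increasing")
})

test_that("rms and maximum error follow their closed forms", {
  pr <- data.frame(deviation = c(10, -10))
  expect_equal(spectral_errors(pr), c(rms = 10, max_err = 10))
  pr <- data.frame(deviation = c(3, 4))
  expect_equal(spectral_errors(pr),
               c(rms = sqrt(12.5), max_err = 4), tolerance = 1e-12)
  expect_equal(spectral_errors(data.frame(deviation = c(0, 0))),
               c(rms = 0, max_err = 0))
  # rms never exceeds the maximum unsigned error
  set.seed(31)
  for (k in 1:25) {
    d <- stats::rnorm(sample(2:8, 1), 0, 10)
    er <- spectral_errors(data.frame(deviation = d))
    expect_lte(er[["rms"]], er[["max_err"]] + 1e-12)
  }
})

test_that("candidates rank by rms with energy tie-breaks and windows", {
  ex <- experimental_spectrum("A", c(3300, 3400, 3500))
  cand <- list(
    list(conformer_id = "good", spectrum = c(3302, 3401, 3499),
         dG300K = 3),
    list(conformer_id = "bad", spectrum = c(3325, 3420, 3475),
         dG300K = 0),
    list(conformer_id = "high-energy", spectrum = c(3300, 3400, 3500),
         dG300K = 25))
  tab <- rank_candidates(ex, cand)
  expect_equal(tab$conformer_id[1], "good")
  expect_false(tab$in_window[tab$conformer_id == "high-energy"])
  # equal rms: lower free energy first
  tie <- list(
    list(conformer_id = "hi", spectrum = c(3305, 3400, 3500), dG300K = 5),
    list(conformer_id = "lo", spectrum = c(3305, 3400, 3500), dG300K = 1))
  expect_equal(rank_candidates(ex, tie)$conformer_id[1], "lo")
  # nothing in the window -> warning
  expect_warning(
    rank_candidates(ex, list(list(conformer_id = "x",
                                  spectrum = c(3300, 3400, 3500),
                                  dG300K = 99))),
    "window")
})

test_that("zero-jitter self-assignment recovers every generator exactly", {
  confs <- fixture_set("Sem")
  cands <- lapply(confs, function(cf) {
    sp <- scale_spectrum(synth_frequencies(cf)$modes)
    list(conformer_id = cf$id, spectrum = sp,
         dG300K = cf$free_energy300K)
  })
  exps <- lapply(confs, function(cf) {
    tr <- synth_frequencies(cf)$truth
    experimental_spectrum(cf$id, sort(tr$intended))
  })
  rep <- assign_conformers(unname(exps), unname(cands))
  expect_identical(rep$assignments$conformer_id,
                   rep$assignments$spectrum_id)
  expect_true(all(rep$assignments$rms < 1e-9))
  expect_equal(rep$n_distinct, length(confs))
  # duplicated spectra produce identical assignments
  rep2 <- assign_conformers(unname(exps[c(1, 1)]), unname(cands))
  expect_identical(rep2$assignments$conformer_id[1],
                   rep2$assignments$conformer_id[2])
})

test_that("withholding the true family leaves the spectrum unassigned", {
  confs <- fixture_set("Sem")
  target <- confs[[lbl("5_a-7", DELTA, "_g--7_L")]]
  tr <- synth_frequencies(target)$truth
  ex <- experimental_spectrum("B", sort(tr$intended))
  others <- confs[setdiff(names(confs), target$id)]
  # drop the close sibling too so no semi-extended form remains
  others <- others[setdiff(names(others), lbl("5_a-7", DELTA, "_g+-7_L"))]
  cands <- lapply(others, function(cf)
    list(conformer_id = cf$id,
         spectrum = scale_spectrum(synth_frequencies(cf)$modes),
         dG300K = cf$free_energy300K))
  rep <- assign_conformers(list(ex), unname(cands))
  expect_false(rep$assignments$assigned)
  expect_gt(rep$assignments$rms, 20)
})

test_that("strict carrier mode pins NH2-antisym bands to their own class", {
  cf <- fixture_set("Sem")[[1]]
  sp <- scale_spectrum(synth_frequencies(cf)$modes)
  ex <- experimental_spectrum(cf$id, sort(sp$f_scaled))
  pr <- match_bands(ex, sp, strict_carriers = TRUE)
  anti <- pr$carrier == "NH2-antisym"
  expect_true(all(classify_band(pr$exp_position[anti]) == "NH2-antisym"))
  expect_equal(nrow(pr), 4)
})
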