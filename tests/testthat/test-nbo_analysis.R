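nbo_df <- function(rows) {
  do.call(rbind, lapply(rows, function(r)
    data.frame(conformer_id = r[[1]], donor_orbital = r[[2]],
               donor_atom = r[[3]], acceptor_orbital = "sigma*_NH",
               acceptor_bond = r[[4]], E2 = r[[5]],
               distance_pm = NA_real_)))
}

test_that("the NBO reader enforces the unit header and converts kcal", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "# E2_unit: kcal/mol",
    "conformer_id,donor_orbital,donor_atom,acceptor_orbital,acceptor_bond,E2",
    "c1,n_Se,20,sigma*_NH,N4-H5,1.0",
    "c1,n'_Se,20,sigma*_NH,N4-H5,0.5"), path)
  back <- read_nbo_table(path)
  expect_equal(back$E2, c(4.184, 2.092))
  # kcal -> kJ -> kcal round-trips exactly through the writer
  write_nbo_table(back, path, unit = "kcal/mol")
  expect_equal(read_nbo_table(path)$E2, back$E2, tolerance = 1e-12)
  # missing unit header
  writeLines(c("conformer_id,donor_orbital,acceptor_orbital,acceptor_bond,E2",
               "c1,n_Se,sigma*_NH,N4-H5,1"), path)
  expect_error(read_nbo_table(path), "unit")
  # malformed donor orbital label names the row
  writeLines(c("# E2_unit: kJ/mol",
               "conformer_id,donor_orbital,donor_atom,acceptor_orbital,acceptor_bond,E2",
               "c1,n_Se,20,sigma*_NH,N4-H5,1",
               "c1,???,20,sigma*_NH,N4-H5,1"), path)
  expect_error(read_nbo_table(path), "row 2")
  # an empty table parses to zero entries
  writeLines(c("# E2_unit: kJ/mol",
               "conformer_id,donor_orbital,donor_atom,acceptor_orbital,acceptor_bond,E2"),
             path)
  expect_equal(nrow(read_nbo_table(path)), 0)
})

test_that("hydrogen-bond sums select the right channels", {
  entries <- nbo_df(list(
    list("c1", "n_Se", 20L, "N4-H5", 5.0),
    list("c1", "n'_Se", 20L, "N4-H5", 3.0),
    list("c1", "n_O", 9L, "N4-H5", 2.0),       # accompanying C5 channel
    list("c1", "pi_ring", NA, "N4-H5", 1.5),   # accompanying pi channel
    list("c1", "n_Se", 20L, "N10-H11", 7.0)))  # a different NH
  expect_equal(sum_hbond_stabilization(entries, 4, 5, 20), 8.0)
  expect_equal(total_sigma_star_energy(entries, 4, 5), 11.5)
  expect_equal(sum_hbond_stabilization(entries, 2, 3, 20), 0)
  # linearity in the energies
  scaled <- entries
  scaled$E2 <- scaled$E2 * 2.5
  expect_equal(sum_hbond_stabilization(scaled, 4, 5, 20), 8.0 * 2.5)
  expect_equal(total_sigma_star_energy(scaled, 4, 5), 11.5 * 2.5)
})

test_that("sumE_NH >= sumE_HB on generated tables for every fixture", {
  for (nm in setdiff(fixture_catalog(), "MAA-YMe2-complex")) {
    lab <- label_conformer(reference_fixture(nm))
    entries <- synth_nbo_table(lab$hbonds, lab$pi_contacts)
    tab <- hbond_stabilization(lab$hbonds, entries)
    expect_true(all(tab$sumE_NH >= tab$sumE_HB - 1e-12))
    expect_true(all(tab$sumE_HB >= 0))
  }
})

test_that("the distance decay fit recovers known parameters", {
  r <- seq(230, 300, length.out = 12)
  e <- exp(9.0 - 0.024 * r)
  fit <- distance_energy_fit(r, e)
  expect_equal(fit$c, 9.0, tolerance = 1e-9)
  expect_equal(fit$d, 0.024, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # one enhanced point flags as above the trend
  e2 <- e
  e2[5] <- e2[5] * 1.6
  fit2 <- distance_energy_fit(r, e2)
  expect_identical(fit2$flag[5], "above")
  # non-positive energies excluded with a warning, too few points error
  expect_warning(distance_energy_fit(c(r, 310), c(e, 0)), "excluded")
  expect_error(distance_energy_fit(c(240, 250), c(1, 2)), "at least 3")
})

test_that("noisy decay parameters are recovered within their intervals", {
  set.seed(12)
  r <- stats::runif(50, 230, 310)
  e <- exp(9.0 - 0.024 * r) * exp(stats::rnorm(50, 0, 0.05))
  fit <- distance_energy_fit(r, e)
  se <- summary(fit$fit)$coefficients[, 2]
  expect_lt(abs(fit$c - 9.0), 3 * se[1])
  expect_lt(abs(fit$d - 0.024), 3 * se[2])
})

test_that("per-class shift/energy fits separate distinct slopes", {
  set.seed(13)
  e <- stats::runif(24, 5, 40)
  cls <- rep(c("7d", "6d"), each = 12)
  slope <- ifelse(cls == "7d", 4.5, 2.0)
  shift <- slope * e + stats::rnorm(24, 0, 2)
  res <- shift_energy_correlation(shift, e, cls)
  expect_gt(res$fits[["7d"]]$slope, res$fits[["6d"]]$slope)
  expect_true(res$slope_comparison$distinct[1])
  # identical data in both classes: slopes exactly equal, not distinct
  shift0 <- 3 * e[1:12] + stats::rnorm(12, 0, 2)
  res0 <- shift_energy_correlation(rep(shift0, 2), rep(e[1:12], 2), cls)
  expect_false(res0$slope_comparison$distinct[1])
  # one usable class only: no comparison, short class skipped with warning
  expect_warning(
    res1 <- shift_energy_correlation(c(shift[1:12], 7), c(e[1:12], 3),
                                     c(cls[1:12], "lonely")),
    "lonely")
  expect_null(res1$slope_comparison)
})

test_that("stabilization sums scale linearly through the summary table", {
  lab <- label_conformer(reference_fixture(lbl("5_a-7", DELTA, "_g+-7_L")))
  entries <- synth_nbo_table(lab$hbonds, lab$pi_contacts)
  t1 <- hbond_stabilization(lab$hbonds, entries)
  entries$E2 <- entries$E2 * 3
  t3 <- hbond_stabilization(lab$hbonds, entries)
  expect_equal(t3$sumE_HB, 3 * t1$sumE_HB, tolerance = 1e-12)
  expect_equal(t3$sumE_NH, 3 * t1$sumE_NH, tolerance = 1e-12)
})
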