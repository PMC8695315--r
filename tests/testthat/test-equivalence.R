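test_that("distance-axis peaks map through the line to the energy axis", {
  expect_equal(xm_esrc(list(slope = -1.66, intercept = 2.16), 0.82),
               0.7988, tolerance = 1e-12)
  expect_equal(round(xm_esrc(list(slope = -1.66, intercept = 2.16), 0.82), 2),
               0.80)
  expect_equal(xm_esrc(list(slope = 0, intercept = 1.9), 123), 1.9)
  expect_equal(round(xm_esrc(list(slope = -0.32, intercept = 2.71), 0.76), 2),
               2.47)
})

test_that("back-evaluation inverts the line on the unrounded vertex", {
  line <- list(slope = -0.581, intercept = 2.00)
  expect_equal(xm_rc_from_es(line, 2.00), 0)
  # unrounded energy-gap vertex reproduces the published 2-decimal value;
  # the rounded vertex would not
  xm_es <- peak_location(-21.4, 72.2)
  expect_equal(xm_es, 1.686916, tolerance = 1e-6)
  expect_equal(round(xm_rc_from_es(line, xm_es), 2), 0.54)
  expect_false(round(xm_rc_from_es(line, round(xm_es, 2)), 2) == 0.54)

  xm_es2 <- peak_location(-10.8, 42.3)
  expect_equal(xm_es2, 1.958333, tolerance = 1e-6)
  expect_equal(round(xm_rc_from_es(list(slope = -0.476, intercept = 1.99),
                                   xm_es2), 2), 0.07)
  expect_error(xm_rc_from_es(list(slope = 0, intercept = 1), 2), "zero slope")
})

test_that("mapping and back-evaluation are exact inverses", {
  set.seed(41)
  for (i in 1:50) {
    line <- list(slope = runif(1, -3, 3), intercept = runif(1, -2, 3))
    if (abs(line$slope) < 1e-3) next
    x <- runif(1, 0.3, 1.5)
    expect_equal(xm_rc_from_es(line, xm_esrc(line, x)), x,
                 tolerance = 1e-12)
  }
})

test_that("peak comparison flags the single published disagreement", {
  same <- compare_peaks(2.10, 2.10)
  expect_equal(same$abs_diff, 0)
  expect_true(same$agrees)
  exc <- compare_peaks(0.77, 0.91)
  expect_equal(exc$abs_diff, 0.14)
  expect_false(exc$agrees)
  expect_true(compare_peaks(0.77, 0.91, tol = 0.2)$agrees)
  expect_error(compare_peaks(1, 2, tol = -1), "tol")
})

test_that("per-donor report agrees across axes in the parabolic regime", {
  p <- et_params()
  lam0 <- reorganization_energy(0.72, p)
  sim <- simulate_trajectory(
    trajectory_spec(n_snapshots = 1000, rc_sd = 0.012, noise_sd_ev = 0.02,
                    neg_sfeg_mean_ev = lam0, esrc_slope_ev_per_nm = -0.5,
                    seed = 42), p)
  rep <- donor_equivalence_report(sim$snapshots, tol = 0.05)
  expect_identical(rep$exdl_class, "parabolic")
  expect_true(rep$agrees)
  expect_false(rep$extrapolated)
  expect_lt(abs(rep$xm_es - sim$true_values$segl_vertex_ev), 0.05)
})

test_that("linear-regime donors get a back-evaluated, extrapolated peak", {
  p <- et_params()
  sim <- simulate_trajectory(
    trajectory_spec(n_snapshots = 1000, rc_sd = 0.03, noise_sd_ev = 0.02,
                    neg_sfeg_mean_ev = 0.8, seed = 43), p)
  rep <- donor_equivalence_report(sim$snapshots)
  expect_identical(rep$exdl_class, "linear")
  expect_true(rep$extrapolated)
  expect_lt(rep$xm_rc, min(sim$snapshots$rc_nm))
})

test_that("peaks coincide exactly for a noiseless line at constant lambda", {
  # constant reorganization energy via a supplied lambda column, gate deep in
  # its adiabatic plateau, no scatter: both routes give the same peak
  p <- et_params(r0_nm = 2.5)
  spec <- trajectory_spec(n_snapshots = 200, rc_sd = 0.03, noise_sd_ev = 0,
                          seed = 44)
  rc <- sample_rc_series(spec)
  snaps <- tibble::tibble(
    rc_nm = rc,
    neg_sfeg_ev = 1.0 + (-0.5) * (rc - 0.72),
    lambda_ev = 1.0
  )
  snaps <- trajectory_rates(snaps, p)
  segl <- fit_segl(snaps)
  exdl <- fit_exdl(snaps)
  esrc <- fit_esrc(snaps)
  expect_identical(exdl$class, "parabolic")
  expect_equal(segl$x_peak, 1.0, tolerance = 1e-6)
  expect_equal(xm_esrc(esrc, exdl$parabola$x_peak), segl$x_peak,
               tolerance = 1e-6)
})

test_that("cross-axis disagreement shrinks with the generator noise", {
  # mean over a fixed seed ladder at three noise levels; individual runs
  # fluctuate but the average disagreement must fall as the scatter vanishes
  p <- et_params()
  lam0 <- reorganization_energy(0.72, p)
  mean_diff <- vapply(c(0.1, 0.02, 0.004), function(ns) {
    mean(vapply(45:50, function(seed) {
      sim <- simulate_trajectory(
        trajectory_spec(n_snapshots = 1000, rc_sd = 0.03, noise_sd_ev = ns,
                        neg_sfeg_mean_ev = lam0, seed = seed), p)
      donor_equivalence_report(sim$snapshots)$abs_diff
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_diff) < 0))
})

test_that("published line coefficients reproduce the printed mapped peaks", {
  t2 <- load_fixtures("T2")
  mapped <- purrr::pmap_dbl(
    list(t2$b3, t2$c3, t2$xm_rc_printed),
    function(b, c0, xm) xm_esrc(list(slope = b, intercept = c0), xm))
  ok <- !t2$known_mismatch
  expect_equal(round(mapped[ok], 2), t2$xm_esrc_printed[ok])
})

test_that("report grouping and the distance cutoff behave", {
  p <- et_params()
  s1 <- simulate_trajectory(trajectory_spec(n_snapshots = 300, seed = 46), p,
                            subunit = "A")$snapshots
  s2 <- simulate_trajectory(trajectory_spec(n_snapshots = 300, seed = 47), p,
                            subunit = "B")$snapshots
  rep <- donor_equivalence_report(dplyr::bind_rows(s1, s2))
  expect_identical(nrow(rep), 2L)
  expect_setequal(rep$subunit, c("A", "B"))

  # an upper distance cutoff restricts the fit window
  rep_cut <- donor_equivalence_report(s1, rc_max = 0.72)
  expect_identical(nrow(rep_cut), 1L)
})
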