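test_that("reorganization energy matches the closed form and its limits", {
  p <- et_params(a_donor_nm = 0.25, a_acceptor_nm = 0.25,
                 eps_optical = 2, eps_static = 5)
  # hand evaluation: C_e * (2 + 2 - 4/3) * (1/2 - 1/5)
  expect_equal(reorganization_energy(0.75, p),
               1.439964 * (4 - 4 / 3) * 0.3, tolerance = 1e-12)
  expect_equal(reorganization_energy(0.75, p), 1.1519712, tolerance = 1e-6)
  # vanishing Pekar factor in the eps_optical -> eps_static limit
  p_flat <- et_params(eps_optical = 5 - 1e-9, eps_static = 5)
  expect_lt(reorganization_energy(0.75, p_flat), 1e-8)
  # strictly increasing in distance
  rc <- seq(0.4, 2.5, by = 0.05)
  expect_true(all(diff(reorganization_energy(rc, p)) > 0))
  expect_gt(reorganization_energy(0.9, p), reorganization_energy(0.7, p))
  expect_error(reorganization_energy(-0.1, p), "rc")
  # independent scalar oracle
  expect_equal(reorganization_energy(0.68, p),
               oracle_lambda(0.68, 0.25, 0.25, 2, 5), tolerance = 1e-14)
})

test_that("rc_for_lambda inverts the continuum expression", {
  p <- et_params()
  for (lam in c(0.6, 1.0, 1.4)) {
    expect_equal(reorganization_energy(rc_for_lambda(lam, p), p), lam,
                 tolerance = 1e-12)
  }
  expect_error(rc_for_lambda(10, p), "attainable")
})

test_that("ion-pair Coulomb energy has the right magnitude and scaling", {
  expect_equal(coulomb_pair_energy(0.72, 2), 1.439964 / 1.44,
               tolerance = 1e-12)
  expect_equal(coulomb_pair_energy(0.72, 4),
               coulomb_pair_energy(0.72, 2) / 2, tolerance = 1e-12)
  expect_lt(coulomb_pair_energy(1e6, 2), 1e-5)
  expect_error(coulomb_pair_energy(0, 2), "rc")
  expect_error(coulomb_pair_energy(0.7, 0.5), "eps_da")
})

test_that("protein-charge electrostatics matches a brute-force pairwise sum", {
  donor <- c(0, 0, 0); acceptor <- c(0.72, 0, 0)
  empty <- tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          charge = numeric())
  expect_identical(net_electrostatic_energy(empty, donor, acceptor, 4), 0)
  # +1 charge equidistant from both centers cancels exactly
  mid <- tibble::tibble(x = 0.36, y = 1.0, z = 0, charge = 1)
  expect_equal(net_electrostatic_energy(mid, donor, acceptor, 4), 0,
               tolerance = 1e-12)
  # -1 charge 0.5 nm beyond the acceptor on the pair axis, eps 4
  one <- tibble::tibble(x = 0.72 + 0.5, y = 0, z = 0, charge = -1)
  expect_equal(net_electrostatic_energy(one, donor, acceptor, 4),
               1.439964 * (-1) * (-1 / (4 * 0.5) + 1 / (4 * 1.22)),
               tolerance = 1e-12)
  # randomized ensemble against the loop oracle
  set.seed(4)
  ch <- tibble::tibble(x = rnorm(20, 0.36, 1), y = rnorm(20, 0, 1),
                       z = rnorm(20, 0, 1),
                       charge = sample(c(-1, 1), 20, replace = TRUE))
  expect_equal(net_electrostatic_energy(ch, donor, acceptor, 4),
               oracle_net_energy(ch, donor, acceptor, 4), tolerance = 1e-12)
  clash <- tibble::tibble(x = 0, y = 0, z = 0, charge = 1)
  expect_error(net_electrostatic_energy(clash, donor, acceptor, 4),
               "coincides")
})

test_that("free-energy gap decomposes into gap, pair and environment terms", {
  p <- et_params(e_ip_ev = 7.0, e_ea_ev = 6.5, eps_da = 2)
  # large separation: only the electronic gap survives
  expect_equal(free_energy_gap(1e9, p), 0.5, tolerance = 1e-8)
  # hand value: 0.5 - C_e/(2 * 0.72)
  expect_equal(free_energy_gap(0.72, p), 0.5 - 1.439964 / 1.44,
               tolerance = 1e-12)
  # shifting E_EA by +0.1 eV shifts the gap by -0.1 eV
  p2 <- et_params(e_ip_ev = 7.0, e_ea_ev = 6.6, eps_da = 2)
  expect_equal(free_energy_gap(0.72, p2), free_energy_gap(0.72, p) - 0.1,
               tolerance = 1e-12)
  # explicit environment charges are added through the point-charge sum
  ch <- tibble::tibble(x = 1.5, y = 0.4, z = 0, charge = -1)
  expect_equal(
    free_energy_gap(0.72, p, charges = ch, donor_center = c(0, 0, 0),
                    acceptor_center = c(0.72, 0, 0)),
    free_energy_gap(0.72, p) +
      oracle_net_energy(ch, c(0, 0, 0), c(0.72, 0, 0), 2),
    tolerance = 1e-12)
  expect_error(free_energy_gap(0.72, p, charges = ch), "centers")
})

test_that("rate expression reproduces its gate and Franck-Condon limits", {
  # activationless transfer at the critical distance: half the prefactor
  p <- et_params(nu0_per_ps = 1000, beta_per_nm = 14, r0_nm = 0.8)
  expect_equal(et_rate(0.8, dg0 = -1.0, lam = 1.0, p), 500,
               tolerance = 1e-10)
  # hand-evaluated scalar case
  p2 <- et_params(nu0_per_ps = 1, beta_per_nm = 10, r0_nm = 0.5,
                  temperature_k = 298)
  k <- et_rate(0.5, dg0 = -0.5, lam = 1.0, p2)
  expect_equal(k, 0.5 * exp(-0.25 / (4 * 1 * KB_EV * 298)),
               tolerance = 1e-12)
  expect_equal(k, 0.04384999, tolerance = 1e-6)
  expect_error(et_rate(0.7, -0.5, lam = -1, p2), "lam")
})

test_that("deep nonadiabatic regime recovers the classical distance decay", {
  p <- et_params(beta_per_nm = 14, r0_nm = 0.6)
  # activationless, rc - r0 >= 1 nm: d ln k / d rc -> -beta
  for (rc in c(1.6, 2.0, 3.0)) {
    h <- 1e-6
    lam <- 1.0
    d <- (ln_et_rate(rc + h, -lam, lam, p) -
            ln_et_rate(rc - h, -lam, lam, p)) / (2 * h)
    expect_lt(abs(d + 14), 1e-3)
  }
})

test_that("log-rate is an exact downward parabola in the driving force", {
  p <- et_params(temperature_k = 298)
  lam <- 1.0
  rc <- p$r0_nm
  x <- c(0.3, 0.9, 1.7) # -dg0 grid; exact quadratic through 3 points
  y <- ln_et_rate(rc, -x, lam, p)
  cf <- oracle_polyfit(x, y, 2)
  expect_equal(cf[3], -1 / (4 * lam * KB_EV * 298), tolerance = 1e-9)
  expect_equal(cf[3], -9.735334, tolerance = 1e-6)
  # parabola identity: peak minus zero-driving-force value is lam/(4 kB T)
  expect_equal(ln_et_rate(rc, -lam, lam, p) - ln_et_rate(rc, 0, lam, p),
               lam / (4 * KB_EV * 298), tolerance = 1e-10)
  # vertex by dense search sits at -dg0 = lam
  grid <- seq(lam - 0.05, lam + 0.05, by = 1e-6)
  vals <- ln_et_rate(rc, -grid, lam, p)
  expect_lt(abs(grid[which.max(vals)] - lam), 2e-6)
})

test_that("exp(ln_et_rate) equals et_rate on random inputs", {
  p <- et_params()
  set.seed(9)
  rc <- runif(100, 0.4, 2); dg0 <- runif(100, -3, 1); lam <- runif(100, 0.3, 2)
  expect_equal(exp(ln_et_rate(rc, dg0, lam, p)), et_rate(rc, dg0, lam, p),
               tolerance = 1e-15)
})

test_that("trajectory_rates agrees with a per-snapshot loop and keeps order", {
  p <- et_params()
  set.seed(12)
  n <- 500L
  snaps <- tibble::tibble(
    time_ps = seq_len(n) - 1,
    rc_nm = runif(n, 0.6, 0.9),
    neg_sfeg_ev = runif(n, 0.8, 1.4)
  )
  out <- trajectory_rates(snaps, p)
  expect_identical(nrow(out), n)
  expect_identical(out$time_ps, snaps$time_ps)
  loop <- vapply(seq_len(n), function(i) {
    lam_i <- oracle_lambda(snaps$rc_nm[i], p$a_donor_nm, p$a_acceptor_nm,
                           p$eps_optical, p$eps_static)
    log(oracle_et_rate(snaps$rc_nm[i], -snaps$neg_sfeg_ev[i], lam_i,
                       p$nu0_per_ps, p$beta_per_nm, p$r0_nm,
                       p$temperature_k))
  }, numeric(1))
  expect_equal(out$ln_rate, loop, tolerance = 1e-12)
  expect_equal(mean(out$ln_rate), mean(loop), tolerance = 1e-12)

  # constant distance gives identical reorganization energies
  const <- trajectory_rates(
    tibble::tibble(rc_nm = rep(0.72, 5), neg_sfeg_ev = runif(5, 1, 1.2)), p)
  expect_equal(length(unique(const$lambda_ev)), 1L)

  # a supplied lambda column passes through untouched
  fixed <- trajectory_rates(
    tibble::tibble(rc_nm = runif(5, 0.6, 0.9), neg_sfeg_ev = rep(1, 5),
                   lambda_ev = 1.0), p)
  expect_true(all(fixed$lambda_ev == 1.0))

  # invalid snapshots abort with the offending row index
  bad <- snaps; bad$rc_nm[37] <- -1
  expect_error(trajectory_rates(bad, p), "row 37")
  expect_error(trajectory_rates(snaps[, "rc_nm"], p), "neg_sfeg_ev")
})

test_that("parameter validation and JSON config round trip", {
  expect_error(et_params(eps_optical = 6, eps_static = 5), "eps_optical")
  expect_error(et_params(nu0_per_ps = -1), "nu0_per_ps")
  expect_error(et_params(eps_da = 0.5), "eps_da")
  p <- et_params(nu0_per_ps = 850, e_ea_ev = 6.1)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  write_et_params(p, path)
  p2 <- read_et_params(path)
  expect_equal(unclass(p2), unclass(p), tolerance = 1e-12)
  jsonlite::write_json(list(nu0_per_ps = 1, bogus_key = 2), path,
                       auto_unbox = TRUE)
  expect_error(read_et_params(path), "bogus_key")
})
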