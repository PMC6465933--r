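test_that("Debye sum reproduces closed forms and conserves I(0)", {
  s <- seq(0, 0.5, by = 0.01)
  one <- bead_conformer(matrix(0, 1, 3))
  expect_equal(debye_scattering(one, s)$intensity, rep(1, length(s)))
  # two unit beads at distance d: I(s) = 2 + 2 sin(sd)/(sd)
  two <- bead_conformer(rbind(c(0, 0, 0), c(10, 0, 0)))
  closed <- 2 + 2 * ifelse(s == 0, 1, sin(s * 10) / (s * 10))
  expect_equal(debye_scattering(two, s)$intensity, closed, tolerance = 1e-12)
  # forward intensity equals (total weight)^2, also for weighted beads
  w <- c(2, 3, 0.5)
  conf <- bead_conformer(matrix(rnorm(9), 3), weights = w)
  expect_equal(debye_scattering(conf, 0)$intensity, sum(w)^2)
  # ensemble averaging preserves I(0) for equal-weight conformers
  pool <- generate_chain(30, 5, seed = 2)
  expect_equal(debye_scattering(pool, 0)$intensity, 30^2)
  expect_error(debye_scattering(list(), s),
               class = "idpbiophys_invalid_input")
})

test_that("bead-model sphere matches the analytic form factor", {
  R <- 30
  ball <- lattice_ball(R, 2000)
  n <- nrow(ball$xyz)
  s <- seq(0.005, 4 / R, length.out = 50)
  I <- debye_scattering(ball, s)$intensity
  # continuum comparison: remove the discrete self-term, normalize pairs
  pair <- (I - n) / (n * (n - 1))
  expect_lt(max(abs(pair - sphere_form_factor(s * R)) /
                sphere_form_factor(s * R)), 0.02)
})

test_that("Gaussian-chain curve has the right limits and self-consistency", {
  s <- seq(1e-3, 0.06, by = 5e-4)
  cv <- gaussian_chain_curve(50, s)
  # small-x expansion I -> 1 - x/3
  x <- (s * 50)^2
  low <- x < 0.05
  expect_equal(cv$intensity[low], (1 - x / 3)[low], tolerance = 1e-3)
  # x = 1 at s*rg = 1: I = 2/e
  cv1 <- gaussian_chain_curve(50, 0.02)
  expect_equal(cv1$intensity, 2 / exp(1), tolerance = 1e-12)
  expect_true(all(diff(cv$intensity) < 0))
  # Guinier on the oracle curve recovers the input Rg
  expect_equal(guinier_fit(cv, 0.8)$rg, 50, tolerance = 0.01)
})

test_that("Guinier and Debye-plot estimators recover coil Rg across a sweep", {
  for (rg in c(30, 50, 62, 80)) {
    s <- seq(1e-4, 3 / rg, length.out = 400)
    cv <- gaussian_chain_curve(rg, s)
    gf <- guinier_fit(cv, 1.0)
    expect_equal(gf$rg, rg, tolerance = 0.03)
    expect_lte(max(gf$s_range_used) * gf$rg, 1.0 + 1e-9)
    df <- debye_plot_rg(cv)
    expect_equal(df$rg, rg, tolerance = 0.03)
    # the Debye-plot window extends well beyond the Guinier window
    expect_gt(max(df$range_used), max(gf$s_range_used))
    expect_lt(max(df$range_used * df$rg)^2, 3 + 1e-9)
  }
})

test_that("Guinier fit of an analytic sphere returns sqrt(3/5) R", {
  R <- 30
  ball <- lattice_ball(R, 2000)
  cv <- debye_scattering(ball, seq(0.001, 0.06, by = 0.001))
  expect_equal(guinier_fit(cv, 1.3)$rg, sqrt(3 / 5) * R, tolerance = 0.01)
})

test_that("Guinier fit degenerate inputs raise fit-failure errors", {
  s <- seq(1e-3, 0.05, by = 1e-3)
  flat <- scattering_curve(s, rep(2, length(s)))
  expect_error(guinier_fit(flat), class = "idpbiophys_fit_failure")
  rising <- scattering_curve(s, exp((s * 40)^2 / 3))
  expect_error(guinier_fit(rising), class = "idpbiophys_fit_failure")
  few <- scattering_curve(s[1:3], exp(-(s[1:3] * 40)^2 / 3))
  expect_error(guinier_fit(few), class = "idpbiophys_fit_failure")
})

test_that("Debye-plot formula identity: a = 0.359 b gives Rg = 1 exactly", {
  s <- seq(0.05, 1.6, by = 0.01)      # (s*1)^2 < 3 needs s < 1.73
  b <- 2
  I <- 1 / (b + 0.359 * b * s^2.206)
  fit <- debye_plot_rg(scattering_curve(s, I))
  expect_equal(fit$rg, 1, tolerance = 1e-3)
})

test_that("Debye-plot estimator outperforms Guinier on a coil ensemble", {
  chains <- generate_chain(348, 150, seed = 21)
  true_mean <- mean(vapply(chains, conformer_rg, numeric(1)))
  cv <- debye_scattering(chains, seq(1e-3, 0.08, length.out = 60))
  g <- guinier_fit(cv, 1.3)$rg
  d <- debye_plot_rg(cv)$rg
  expect_equal(d, true_mean, tolerance = 0.05)
  expect_lt(abs(d - true_mean), abs(g - true_mean))
})

test_that("dimensionless Kratky transform shows the globule/coil contrast", {
  # Guinier-law (idealized globule) curve: peak at exactly (sqrt(3), 3/e)
  s <- seq(1e-3, 0.2, by = 2e-4)
  rg <- 30
  glaw <- scattering_curve(s, exp(-(s * rg)^2 / 3))
  k <- dimensionless_kratky(glaw, rg, 1)
  expect_equal(k$srg[which.max(k$kratky)], sqrt(3), tolerance = 1e-2)
  expect_equal(max(k$kratky), 3 / exp(1), tolerance = 1e-4)
  # Gaussian coil: monotone rise to the plateau of 2, no peak
  sc <- seq(1e-3, 0.4, by = 2e-3)
  coil <- gaussian_chain_curve(40, sc)
  kc <- dimensionless_kratky(coil, 40, 1)
  expect_true(all(diff(kc$kratky) > 0))
  expect_equal(max(kc$kratky), 2, tolerance = 0.02)
  # globule-mimic ensemble peaks near the theoretical cross
  gl <- globule_pool_confs(rep(21, 20), n_beads = 200, seed0 = 300)
  cvg <- debye_scattering(gl, seq(1e-3, 0.25, length.out = 120))
  fg <- guinier_fit(cvg, 1.3)
  kg <- dimensionless_kratky(cvg, fg$rg, fg$i0)
  pk <- which.max(kg$kratky[kg$srg < 3])
  expect_equal(kg$srg[pk], sqrt(3), tolerance = 0.1)
  expect_equal(kg$kratky[pk], 3 / exp(1), tolerance = 0.1)
  # FJC ensemble: no local maximum below s*rg = 3
  chains <- generate_chain(200, 60, seed = 44)
  cvf <- debye_scattering(chains, seq(1e-3, 0.16, length.out = 80))
  ff <- guinier_fit(cvf, 1.3)
  kf <- dimensionless_kratky(cvf, ff$rg, ff$i0)
  expect_gt(max(kf$srg), 3)
  expect_true(all(diff(kf$kratky[kf$srg < 3]) > 0))
})

test_that("pair distribution reproduces geometry and the Rg moment identity", {
  two <- bead_conformer(rbind(c(0, 0, 0), c(10, 0, 0)))
  pd <- pair_distribution(two, 1)
  expect_equal(pd$dmax, 10)
  occ <- pd$r[pd$p > 0]
  expect_length(occ, 1)
  expect_lt(abs(occ - 10), 1)          # within one bin of the true distance
  expect_true(all(pd$p >= 0))
  expect_true(all(pd$p[pd$r > pd$dmax + pd$bin_width] == 0))
  # moment identity against direct Rg, single conformers
  for (seed in 1:2) {
    cf <- generate_chain(150, 1, seed = seed)[[1]]
    pd2 <- pair_distribution(cf, 0.5)
    expect_equal(pd2$rg_from_pr, conformer_rg(cf), tolerance = 0.01)
  }
  # uniform ball: dmax near 2R, peak near 0.525 * 2R
  ball <- generate_globule(800, sqrt(3 / 5) * 30, seed = 2)
  pdb_ <- pair_distribution(ball, 0.5)
  expect_lt(pdb_$dmax, 60)
  expect_gt(pdb_$dmax, 56)
  expect_equal(pdb_$r[which.max(pdb_$p)], 0.525 * 60, tolerance = 0.08)
  expect_error(pair_distribution(two, 0), class = "idpbiophys_invalid_input")
})

test_that("scattering noise model and .dat round trip behave", {
  s <- seq(1e-3, 0.1, by = 1e-3)
  cv <- gaussian_chain_curve(40, s)
  noisy1 <- add_curve_noise(cv, 0.02, seed = 7)
  noisy2 <- add_curve_noise(cv, 0.02, seed = 7)
  expect_identical(noisy1$intensity, noisy2$intensity)
  expect_equal(noisy1$sigma, 0.02 * cv$intensity)
  f <- withr::local_tempfile(fileext = ".dat")
  write_saxs_dat(noisy1, f, comments = "seed 7")
  back <- read_saxs_dat(f)
  expect_equal(back$s, noisy1$s, tolerance = 1e-10)
  expect_equal(back$intensity, noisy1$intensity, tolerance = 1e-6)
  expect_equal(back$sigma, noisy1$sigma, tolerance = 1e-6)
  # nm^-1 reader flag converts the grid
  back_nm <- read_saxs_dat(f, s_unit = "nm^-1")
  expect_equal(back_nm$s, noisy1$s / 10, tolerance = 1e-10)
  # constructor validation
  expect_error(scattering_curve(c(0.2, 0.1), c(1, 1)),
               class = "idpbiophys_invalid_input")
  expect_error(scattering_curve(c(0.1, 0.2), c(1, 1), sigma = c(0, 1)),
               class = "idpbiophys_invalid_input")
})
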