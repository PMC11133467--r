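test_that("nuclear constant set is internally consistent", {
  nc <- nuclearConstants()
  hbar_neVns <- 6.582119569e-16 * 1e18
  expect_lt(abs(nc@naturalLinewidth_neV * nc@meanLifetime_ns - hbar_neVns) /
              hbar_neVns, 0.005)
  ER <- (14412.5)^2 / (2 * 56.9354 * 931.49410242e6) * 1e3
  expect_lt(abs(nc@recoilEnergy_meV - ER) / ER, 1e-3)
  expect_lt(abs(nc@wavenumber_invA - 14412.5 / 1973.269804) / 7.304, 1e-3)
  expect_equal(round(nc@wavenumber_invA, 3), 7.304)
  # JSON export carries the same numbers
  js <- jsonlite::fromJSON(constantsToJSON())
  expect_equal(js$recoil_energy_meV, nc@recoilEnergy_meV)
})

test_that("harmonic f_LM <-> msd conversions reproduce known values", {
  expect_equal(round(flmFromMsd(3.66e-3), 2), 0.82)
  expect_identical(flmFromMsd(0), 1)
  k <- nuclearConstants()@wavenumber_invA
  expect_equal(flmFromMsd(1 / k^2), exp(-1), tolerance = 1e-12)
  expect_equal(round(sqrt(msdFromFlm(0.78)), 3), 0.068)
  expect_equal(round(sqrt(msdFromFlm(0.17)), 2), 0.18)
  expect_identical(msdFromFlm(1), 0)
  expect_error(flmFromMsd(-1e-6), "msd")
  expect_error(msdFromFlm(0), "fLM")
  expect_error(msdFromFlm(1.01), "fLM")
})

test_that("f_LM <-> msd round trip is exact to 1e-10 on [0, 0.1]", {
  x <- seq(0, 0.1, length.out = 101)
  back <- msdFromFlm(flmFromMsd(x))
  expect_lt(max(abs(back - x) / pmax(x, 1e-15)), 1e-10)
})

test_that("Debye-model msd reproduces anchor values and limits", {
  # low-temperature anchor for theta_D = 175 K
  expect_equal(debyeMsd(4.2, 175), 3.66e-3, tolerance = 2e-3)
  expect_equal(signif(debyeMsd(4.2, 175), 3), 3.67e-3)
  # zero-point closed form
  hbar <- 1.054571817e-34; m <- 56.9354 * 1.66053906660e-27
  zp <- 3 * hbar^2 / (4 * m * 1.380649e-23 * 175) * 1e20
  expect_equal(debyeMsd(0, 175), zp, tolerance = 1e-12)
  # frozen value from an independent quadrature oracle
  expect_equal(debyeMsd(200, 175), 1.704448e-2, tolerance = 1e-5)
  # high-T law 3 hbar^2 T/(m kB thetaD^2), within 3% at 200 K
  highT <- 3 * hbar^2 * 200 / (m * 1.380649e-23 * 175^2) * 1e20
  expect_lt(abs(debyeMsd(200, 175) - highT) / highT, 0.03)
})

test_that("Debye msd is monotone in T and thetaD, and obeys the high-T law", {
  T <- seq(0, 400, by = 1)
  expect_true(all(diff(debyeMsd(T, 175)) > 0))
  th <- seq(100, 300, by = 5)
  m150 <- vapply(th, function(x) debyeMsd(150, x), numeric(1))
  expect_true(all(diff(m150) < 0))
  # for T >= 2 thetaD the classical law 3 hbar^2 T/(m kB thetaD^2) holds
  # within 1% (in the high-T expansion the zero-point 1/4 cancels against
  # the first correction of the thermal integral)
  hbar <- 1.054571817e-34; m <- 56.9354 * 1.66053906660e-27
  for (T in c(350, 400)) {
    law <- 3 * hbar^2 * T / (m * 1.380649e-23 * 175^2) * 1e20
    expect_lt(abs(debyeMsd(T, 175) - law) / law, 0.01)
  }
})

test_that("Debye-temperature fit recovers the generator", {
  T <- c(40, 110, 160, 200, 235, 295)
  fit <- fitDebyeTemperature(T, debyeMsd(T, 175))
  expect_lt(abs(fit@thetaD_K - 175), 0.5)
  expect_lt(max(abs(fit@residuals_A2)), 1e-9)
  # single-point zero-point root find (4.2 K anchor)
  fit1 <- fitDebyeTemperature(4.2, 3.66e-3)
  expect_lt(abs(fit1@thetaD_K - 175.25), 0.5)
  expect_error(fitDebyeTemperature(numeric(0), numeric(0)))
  expect_error(fitDebyeTemperature(T, debyeMsd(T, 175), weights = 0))
})

test_that("Debye fit is robust to 5% noise on msd (median over replicates)", {
  T <- c(40, 110, 160, 200, 235, 295)
  truth <- debyeMsd(T, 175)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    obs <- truth * (1 + rnorm(length(T), 0, 0.05))
    abs(fitDebyeTemperature(T, pmax(obs, 1e-5))@thetaD_K - 175)
  }, numeric(1))
  expect_lt(median(errs), 5)
})

test_that("Doppler conversion is 48.07 neV per mm/s and linear", {
  expect_equal(dopplerToEnergy(1), 48.0749, tolerance = 1e-5)
  expect_identical(dopplerToEnergy(0), 0)
  expect_equal(dopplerToEnergy(3.27), 157.205, tolerance = 1e-4)
  v <- c(0.3, 1.7, 3.27)
  expect_equal(energyToDoppler(dopplerToEnergy(v)), v, tolerance = 1e-12)
})

test_that("B-factor to RMSD uses u = sqrt(B / 8 pi^2)", {
  expect_equal(rmsdFromBfactor(8 * pi^2), 1)
  expect_equal(round(rmsdFromBfactor(3.158), 2), 0.20)
  expect_identical(rmsdFromBfactor(0), 0)
  expect_error(rmsdFromBfactor(-1))
})
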