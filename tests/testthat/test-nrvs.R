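pvDebye <- debyePVDOS(175, dE = 0.25)

test_that("excitation-probability generator obeys its sum rules", {
  nc <- nuclearConstants()
  sp <- generateExcitationProbability(pvDebye, 46)
  dE <- mean(diff(energyGrid(sp)))
  # total probability 1
  expect_equal(sum(spectrumCounts(sp)) * dE, 1, tolerance = 1e-6)
  # Lipkin first moment = recoil energy, independent of T
  for (T in c(46, 150)) {
    s <- generateExcitationProbability(pvDebye, T, gridRange = c(-60, 150))
    m1 <- sum(energyGrid(s) * spectrumCounts(s)) * dE
    expect_lt(abs(m1 - nc@recoilEnergy_meV) / nc@recoilEnergy_meV, 0.002)
  }
  # PVDOS support must fit inside the output grid
  expect_error(generateExcitationProbability(pvDebye, 46,
                                             gridRange = c(-10, 10)),
               "support")
})

test_that("noiseless generator output obeys detailed balance", {
  sp <- generateExcitationProbability(pvDebye, 100, resolution_fwhm = 0)
  E <- energyGrid(sp); y <- spectrumCounts(sp)
  i0 <- which.min(abs(E))
  j <- seq_len(100)
  dE <- mean(diff(E))
  ratio <- y[i0 - j] / (y[i0 + j] * exp(-(j * dE) / (8.617333262e-2 * 100)))
  expect_lt(max(abs(ratio - 1)), 1e-8)
  # T -> 0: anti-Stokes side empty
  s0 <- generateExcitationProbability(pvDebye, 0, resolution_fwhm = 0.8)
  expect_lt(max(spectrumCounts(s0)[energyGrid(s0) < -2]), 1e-12)
})

test_that("generator elastic fraction matches the Debye model f_LM", {
  # cross-module consistency: elastic line of the generated spectrum vs
  # flmFromMsd(debyeMsd(T)); the PVDOS quadrature converges with dE
  s <- generateExcitationProbability(pvDebye, 46)
  pr <- processNrvs(s, temperature_K = 46)
  fTh <- flmFromMsd(debyeMsd(46, 175))
  expect_lt(abs(pr$result@fLM - fTh) / fTh, 0.005)
  # at 235 K the 0.25 meV grid is too coarse; a 0.1 meV grid restores it
  pvFine <- debyePVDOS(175, dE = 0.1)
  s2 <- generateExcitationProbability(pvFine, 235, gridRange = c(-120, 280))
  pr2 <- processNrvs(s2, temperature_K = 235)
  fTh2 <- flmFromMsd(debyeMsd(235, 175))
  expect_lt(abs(pr2$result@fLM - fTh2) / fTh2, 0.005)
})

test_that("elastic-peak removal recovers an injected elastic area", {
  s <- generateExcitationProbability(pvDebye, 46)
  rem <- removeElasticPeak(s)
  pr <- normalizeAndExtract(rem$inelastic, 46, elasticArea = rem$elasticArea)
  # the two f_LM routes (sum rule vs elastic/total) agree within 1%
  expect_lt(abs(pr@fLM - pr@fLMElastic) / pr@fLM, 0.01)
  # recovered area within 1% of the spectrum's recoilless fraction
  expect_lt(abs(rem$elasticArea - pr@fLM) / pr@fLM, 0.01)
  # spectrum with no elastic component: warning, area 0, unchanged
  E <- energyGrid(s)
  dE <- mean(diff(E))
  bump <- dnorm(E, 25, 4) + dnorm(-E, 25, 4) * 0.2
  flat <- new("EnergySpectrum", energy_meV = E, counts = bump / sum(bump * dE),
              countError = rep(0, length(E)),
              metadata = list(temperature_K = 46, resolution_fwhm_meV = 0.8))
  expect_warning(r0 <- removeElasticPeak(flat), "no identifiable")
  expect_identical(r0$elasticArea, 0)
  expect_lt(sum(abs(r0$inelastic@counts - flat@counts)) * dE /
              (sum(flat@counts) * dE), 0.005)
})

test_that("detailed-balance temperature estimate is accurate", {
  s <- generateExcitationProbability(pvDebye, 100, resolution_fwhm = 0.8)
  expect_lt(abs(estimateTemperature(s) - 100), 2)
  # symmetric spectrum -> indeterminate
  E <- energyGrid(s)
  sym <- new("EnergySpectrum", energy_meV = E,
             counts = dnorm(E, 0, 20), countError = rep(0, length(E)),
             metadata = list(resolution_fwhm_meV = 0.8))
  expect_error(estimateTemperature(sym), "indeterminate")
  # Poisson noise at 1e6 counts: within 5 K of 46 K (median over seeds)
  Ts <- vapply(1:50, function(seed)
    estimateTemperature(generateExcitationProbability(
      pvDebye, 46, totalCounts = 1e6, seed = seed)), numeric(1))
  expect_lt(abs(median(Ts) - 46), 5)
  # too few anti-Stokes counts in a counted spectrum -> error
  cold <- generateExcitationProbability(pvDebye, 4.2, totalCounts = 2e3,
                                        seed = 1)
  expect_error(estimateTemperature(cold), "anti-Stokes")
})

test_that("forward -> inverse round trip recovers PVDOS, f_LM and msd", {
  dE <- 0.25
  g <- seq(dE, 90, by = dE)
  d2 <- numeric(length(g)); d2[g == 20] <- 1.2 / dE; d2[g == 45] <- 1.8 / dE
  shapes <- list(debye = pvDebye, twoMode = makePVDOS(g, d2))
  for (nm in names(shapes)) {
    pv <- shapes[[nm]]
    for (T in c(37, 100, 235)) {
      s <- generateExcitationProbability(pv, T, gridRange = c(-120, 280))
      pr <- processNrvs(s, temperature_K = T)
      pvr <- pr$result@pvdos
      idx <- match(round(pv@energy_meV / dE), round(pvr@energy_meV / dE))
      l1 <- sum(abs(pvr@density[idx] - pv@density), na.rm = TRUE) * dE / 3
      expect_lt(l1, 0.02)
      msdTh <- msdFromPVDOS(pv, T)
      expect_lt(abs(pr$result@msd_A2 - msdTh) / msdTh, 0.02)
      fTh <- flmFromMsd(msdTh)
      expect_lt(abs(pr$result@fLM - fTh) / fTh, 0.005)
    }
  }
})

test_that("NRVS pipeline reproduces the published low-temperature msd", {
  # 4.2 K: Debye anchor 3.66e-3 A^2
  s <- generateExcitationProbability(pvDebye, 4.2)
  pr <- processNrvs(s, temperature_K = 4.2)
  expect_equal(pr$result@msd_A2, 3.66e-3, tolerance = 0.015)
  # 37 K: ~4.7e-3 A^2, within 10% of the published 4.9e-3 measurement
  s37 <- generateExcitationProbability(pvDebye, 37)
  pr37 <- processNrvs(s37, temperature_K = 37)
  expect_lt(abs(pr37$result@msd_A2 - debyeMsd(37, 175)) / debyeMsd(37, 175),
            0.02)
  expect_lt(abs(pr37$result@msd_A2 - 4.9e-3) / 4.9e-3, 0.10)
})

test_that("a zero-temperature Einstein mode gives the one-oscillator msd", {
  dE <- 0.25
  g <- seq(dE, 90, by = dE)
  d <- numeric(length(g)); d[g == 30] <- 3 / dE
  pvE <- makePVDOS(g, d)
  s <- generateExcitationProbability(pvE, 0, gridRange = c(-30, 120))
  pr <- processNrvs(s, temperature_K = 0)
  hbar <- 1.054571817e-34; m <- 56.9354 * 1.66053906660e-27
  msdTh <- hbar^2 / (2 * m * 30 * 1.602176634e-22) * 1e20
  expect_equal(pr$result@msd_A2, msdTh, tolerance = 1e-3)
})

test_that("normalization fails loudly on pathological input", {
  E <- seq(-30, 90, by = 0.25)
  # all intensity on the anti-Stokes side: negative first moment
  bad <- new("EnergySpectrum", energy_meV = E,
             counts = dnorm(E, -15, 3), countError = rep(0, length(E)),
             metadata = list(temperature_K = 100,
                             resolution_fwhm_meV = 0.8))
  expect_error(normalizeAndExtract(bad, 100), "normalization failed")
})
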