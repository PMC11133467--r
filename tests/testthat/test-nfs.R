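test_that("beat model has the right period, thin limit and t->0 limit", {
  dOm <- 0.2389
  t <- seq(0.1, 660, by = 0.05)
  I <- nfsIntensity(t, chi = 5, deltaOmega = dOm)
  # cos^2 minima spaced by 2 pi / dOmega
  dips <- t[which(diff(sign(diff(I))) > 0) + 1]
  gaps <- diff(dips)
  gaps <- gaps[gaps > 5]   # ignore numerical doubles at the Bessel zeros
  expect_equal(median(gaps), 2 * pi / dOm, tolerance = 0.01)
  # thin limit: intensity scales as chi^2
  r <- nfsIntensity(100, 0.02, dOm) / nfsIntensity(100, 0.01, dOm)
  expect_equal(r, 4, tolerance = 0.005)
  # finite t -> 0 limit: chi^2/8 envelope
  I0 <- nfsIntensity(1e-9, 5, 0)
  expect_equal(I0, 25 / 8, tolerance = 1e-6)
})

test_that("quantum-beat constant is 86 ns from first principles", {
  expect_equal(round(nfsBeatConstant()), 86)
  expect_equal(beatPeriodToDeltaEQ(86), 1, tolerance = 1e-3)
  expect_equal(round(beatPeriodToDeltaEQ(26.3), 2), 3.27)
  expect_equal(deltaEQToBeatPeriod(beatPeriodToDeltaEQ(26.3)), 26.3,
               tolerance = 1e-12)
  expect_error(beatPeriodToDeltaEQ(0))
  # a published fit pair: dOmega = 0.240 rad/ns has ~26 ns beat spacing
  expect_equal(2 * pi / 0.240, 26.2, tolerance = 0.005)
})

test_that("NFS fit recovers noiseless parameters and defeats aliasing", {
  sp <- simulateNfsSpectrum(5, 3.27, totalCounts = 1e6)
  fit <- fitNfs(sp)
  expect_lt(abs(fit@chi - 5) / 5, 1e-3)
  expect_lt(abs(fit@deltaEQ_mm_s - 3.27) / 3.27, 1e-3)
  # starting from a doubled beat frequency still finds the true one
  dOmTrue <- fit@deltaOmega_rad_ns
  fit2 <- fitNfs(sp, initDeltaOmega = 2 * dOmTrue)
  expect_lt(abs(fit2@deltaOmega_rad_ns - dOmTrue) / dOmTrue, 1e-3)
  # too few counts -> error
  expect_error(fitNfs(simulateNfsSpectrum(5, 3.27, totalCounts = 500,
                                          seed = 1)),
               "insufficient")
})

test_that("windowed model intensity increases with effective thickness", {
  t <- seq(18, 600, by = 0.4675)
  I <- vapply(seq(0.5, 10, by = 0.5), function(chi)
    sum(nfsIntensity(t, chi, 0.2389)), numeric(1))
  expect_true(all(diff(I) > 0))
})

test_that("fitted splitting agrees with the measured beat spacing", {
  sp <- simulateNfsSpectrum(5, 3.27, totalCounts = 1e6)
  fit <- fitNfs(sp)
  t <- timeBins(sp); y <- spectrumCounts(sp)
  win <- t >= 18 & t <= 600
  tw <- t[win]; yw <- y[win]
  dips <- tw[which(diff(sign(diff(yw))) > 0) + 1]
  gaps <- diff(dips); gaps <- gaps[gaps > 10 & gaps < 40]
  dEQbeat <- beatPeriodToDeltaEQ(median(gaps))
  expect_lt(abs(dEQbeat - fit@deltaEQ_mm_s) / fit@deltaEQ_mm_s, 0.01)
})

test_that("Poisson parameter recovery is accurate and calibrated", {
  reps <- 100
  est <- vapply(seq_len(reps), function(s) {
    f <- fitNfs(simulateNfsSpectrum(5, 3.27, totalCounts = 1e5,
                                    seed = 9000 + s), nStarts = 1)
    c(f@deltaEQ_mm_s, unname(f@stderr["deltaEQ_mm_s"]))
  }, numeric(2))
  err <- abs(est[1, ] - 3.27) / 3.27
  expect_lt(median(err), 0.01)
  cover <- mean(abs(est[1, ] - 3.27) < est[2, ])
  expect_gte(cover, 0.55)
  expect_lte(cover, 0.80)
})

test_that("count-rate series convert to f_LM in both regimes", {
  pts <- flmFromCountRates(c(4.2, 40), c(0.82e6, 0.77e6), regime = "thick",
                           anchorFlm = 0.82)
  expect_equal(pts$f_LM, c(0.82, 0.77), tolerance = 1e-6)
  expect_identical(pts$f_LM[1], 0.82)
  # thin regime: sqrt law
  thin <- flmFromCountRates(c(4.2, 100), c(1e6, 0.25e6), regime = "thin",
                            anchorFlm = 0.82)
  expect_equal(thin$f_LM[2] / thin$f_LM[1], 0.5, tolerance = 1e-6)
  # regime inference from chi, and the ambiguous band
  thick <- flmFromCountRates(c(4.2, 40), c(1e6, 9e5), chiAnchor = 5)
  expect_equal(thick$f_LM[2], 0.9 * 0.82, tolerance = 1e-6)
  expect_error(flmFromCountRates(c(4.2, 40), c(1e6, 9e5), chiAnchor = 1),
               "ambiguous")
  expect_error(flmFromCountRates(c(40, 90), c(1e6, 9e5), regime = "thick"),
               "anchor")
})
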