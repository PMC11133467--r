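test_that("simulated doublet has dips at delta +/- dEQ/2 and linear area", {
  sp <- simulateDoublet(0.67, 3.28, 0.28, fLM = 0.82, scale = 8000,
                        baseline = 5e4)
  v <- velocityGrid(sp); y <- spectrumCounts(sp)
  # the two local minima sit at -0.97 and +2.31 mm/s
  lows <- v[order(y)[1:8]]
  expect_lt(min(abs(lows - (-0.97))), mean(diff(v)))
  expect_lt(min(abs(lows - 2.31)), mean(diff(v)))
  # dEQ = 0 collapses to a single line at delta with doubled depth
  s1 <- simulateDoublet(0.67, 0, 0.28, fLM = 0.82, scale = 8000,
                        baseline = 5e4)
  expect_lt(abs(v[which.min(spectrumCounts(s1))] - 0.67), mean(diff(v)))
  expect_gt(max(5e4 - spectrumCounts(s1)), 1.9 * max(5e4 - y))
  # thin-absorber linearity: doubling f_LM doubles the fitted area
  a1 <- fitDoublet(simulateDoublet(0.67, 3.28, 0.28, fLM = 0.4,
                                   scale = 8000, baseline = 5e4))@totalArea
  a2 <- fitDoublet(simulateDoublet(0.67, 3.28, 0.28, fLM = 0.8,
                                   scale = 8000, baseline = 5e4))@totalArea
  expect_equal(a2 / a1, 2, tolerance = 1e-6)
  # grid must cover the lines
  expect_error(simulateDoublet(0.67, 3.28, 0.28, fLM = 0.8, scale = 8000,
                               baseline = 5e4, grid = seq(-1, 1, 0.01)),
               "grid")
})

test_that("doublet fit recovers noiseless parameters near-exactly", {
  sp <- simulateDoublet(0.67, 3.31, 0.28, fLM = 0.82, scale = 8000,
                        baseline = 5e4)
  fit <- fitDoublet(sp)
  expect_equal(fit@isomerShift_mm_s, 0.67, tolerance = 1e-6)
  expect_equal(fit@quadrupoleSplitting_mm_s, 3.31, tolerance = 1e-6)
  expect_equal(fit@linewidth_mm_s, 0.28, tolerance = 1e-6)
  expect_equal(fit@totalArea, 0.82 * 8000, tolerance = 1e-6)
  expect_equal(fit@baseline, 5e4, tolerance = 1e-6)
})

test_that("doublet fit is consistent under Poisson noise", {
  fits <- lapply(c(11, 12), function(s)
    fitDoublet(simulateDoublet(0.67, 3.31, 0.28, fLM = 0.82, scale = 8000,
                               baseline = 5e4, seed = s)))
  for (f in fits) {
    expect_lt(abs(f@isomerShift_mm_s - 0.67),
              3 * f@stderr["isomerShift_mm_s"])
    expect_lt(abs(f@quadrupoleSplitting_mm_s - 3.31),
              3 * f@stderr["quadrupoleSplitting_mm_s"])
    expect_lt(abs(f@totalArea - 0.82 * 8000), 3 * f@stderr["totalArea"])
  }
  # two seeds agree within 3x the reported stderr
  d <- abs(fits[[1]]@quadrupoleSplitting_mm_s -
           fits[[2]]@quadrupoleSplitting_mm_s)
  expect_lt(d, 3 * sqrt(fits[[1]]@stderr["quadrupoleSplitting_mm_s"]^2 +
                        fits[[2]]@stderr["quadrupoleSplitting_mm_s"]^2))
})

test_that("a flat spectrum raises 'no doublet found'", {
  flat <- new("VelocitySpectrum",
              velocity_mm_s = seq(-6, 6, length.out = 256),
              counts = rpois(256, 5e4) * 0 + 5e4,
              metadata = list())
  expect_error(fitDoublet(flat), "no doublet")
})

test_that("fitted splitting is invariant under velocity reflection", {
  sp <- simulateDoublet(0.67, 3.31, 0.28, fLM = 0.82, scale = 8000,
                        baseline = 5e4, seed = 5)
  fit <- fitDoublet(sp)
  refl <- new("VelocitySpectrum", velocity_mm_s = sp@velocity_mm_s,
              counts = rev(sp@counts), metadata = sp@metadata)
  fitR <- fitDoublet(refl)
  expect_equal(fitR@quadrupoleSplitting_mm_s, fit@quadrupoleSplitting_mm_s,
               tolerance = 1e-6)
  expect_equal(fitR@isomerShift_mm_s, -fit@isomerShift_mm_s,
               tolerance = 1e-4)
})

test_that("area, not depth, carries f_LM (linewidth invariance)", {
  areas <- vapply(c(0.24, 0.28, 0.34), function(g)
    fitDoublet(simulateDoublet(0.67, 3.28, g, fLM = 0.6, scale = 8000,
                               baseline = 5e4))@totalArea, numeric(1))
  expect_lt((max(areas) - min(areas)) / mean(areas), 0.005)
})

test_that("area series anchored at 4.2 K gives absolute f_LM", {
  # published-style ratio: area ratio 0.78/0.82 at 40 K -> f_LM = 0.78
  pts <- flmSeriesFromAreas(c(4.2, 40), areas = c(0.82, 0.78),
                            anchorFlm = 0.82, protein = "Pf")
  expect_equal(pts$f_LM, c(0.82, 0.78), tolerance = 1e-12)
  expect_equal(pts$rmsd_A[2], 0.068, tolerance = 0.005)
  # anchor point maps to the anchor value exactly
  expect_identical(pts$f_LM[1], 0.82)
  # missing anchor -> error
  expect_error(flmSeriesFromAreas(c(40, 90), areas = c(1, 0.9)),
               "anchor")
})
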