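test_that("effective msd separates fast and slow probes", {
  p <- proteinModel("X")
  T <- c(4.2, 40, 100, 200, 220, 235, 250)
  # a 4 ps probe sees the pure Debye curve at all temperatures
  expect_equal(effectiveMsd(p, T, 4e-3), debyeMsd(T, 175), tolerance = 1e-12)
  # a 100 ns probe sees the slow term: f_LM <= 0.05 at 250 K
  expect_lte(flmFromMsd(effectiveMsd(p, 250, 100)), 0.05)
  # at 40 K the logistic tail is negligible: within 1% of Debye
  expect_lt(abs(effectiveMsd(p, 40, 100) - debyeMsd(40, 175)) /
              debyeMsd(40, 175), 0.01)
})

test_that("effective msd is non-decreasing in T and probe time", {
  p <- proteinModel("X")
  T <- seq(0, 300, by = 2)
  expect_true(all(diff(effectiveMsd(p, T, 100)) > 0))
  expect_true(all(diff(effectiveMsd(p, T, 4e-3)) > 0))
  expect_true(all(effectiveMsd(p, T, 100) >= effectiveMsd(p, T, 4e-3)))
})

test_that("study generation is deterministic for a fixed master seed", {
  cfg <- studyConfig(masterSeed = 7, temperatures_K = c(4.2, 100, 235),
                     nrvsCounts = 2e5, nfsCountsAnchor = 2e5)
  d1 <- file.path(tempdir(), "ff-det-1")
  d2 <- file.path(tempdir(), "ff-det-2")
  unlink(c(d1, d2), recursive = TRUE)
  generateStudy(cfg, d1)
  generateStudy(cfg, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("with the slow term off, all three techniques agree", {
  cfg <- studyConfig(
    proteins = list(proteinModel("A", slowMsdAmplitude_A2 = 0),
                    proteinModel("B", slowMsdAmplitude_A2 = 0)),
    temperatures_K = c(4.2, 40, 120, 200, 235), noise = FALSE)
  dir <- file.path(tempdir(), "ff-harmonic")
  unlink(dir, recursive = TRUE)
  man <- generateStudy(cfg, dir)
  tab <- processStudy(dir)
  truth <- studyTruth(man)
  # noiseless NRVS recovery within 2% of the manifest ground truth
  nr <- merge(tab[tab$technique == "NRVS", ], truth)
  expect_lt(max(abs(nr$f_LM - nr$f_nrvs) / nr$f_nrvs), 0.02)
  # three techniques agree within 2% at every temperature
  for (p in c("A", "B")) for (T in cfg$temperatures_K) {
    f3 <- tab$f_LM[tab$protein == p & tab$temperature_K == T]
    expect_equal(length(f3), 3)
    expect_lt((max(f3) - min(f3)) / mean(f3), 0.02)
  }
})

test_that("noisy pipelines recover manifest truth within Poisson errors", {
  st <- defaultStudy()
  truth <- studyTruth(st$manifest)
  for (tech in c("MOSSBAUER", "NFS")) {
    m <- merge(st$table[st$table$technique == tech, ], truth)
    z <- (m$f_LM - m$f_moss) / m$f_LM_sigma
    # calibrated recovery: most points within 1 sigma, all within 3 sigma
    expect_gte(mean(abs(z) <= 1), 0.5)
    expect_lt(max(abs(z)), 3)
  }
  # NRVS-derived f_LM decreases monotonically with temperature
  for (p in unique(st$table$protein)) {
    s <- st$table[st$table$technique == "NRVS" & st$table$protein == p, ]
    s <- s[order(s$temperature_K), ]
    expect_true(all(diff(s$f_LM) < 0))
  }
})
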