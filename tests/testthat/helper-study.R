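# Shared fixtures, generated in code and cached across test files.

.ffTestCache <- new.env(parent = emptyenv())

# default two-protein noisy study (the stated world), generated once
defaultStudy <- function() {
  if (is.null(.ffTestCache$study)) {
    dir <- file.path(tempdir(), "ferroflex-default-study")
    cfg <- studyConfig(masterSeed = 1)
    man <- generateStudy(cfg, dir)
    tab <- processStudy(dir)
    .ffTestCache$study <- list(dir = dir, config = cfg, manifest = man,
                               table = tab)
  }
  .ffTestCache$study
}

# manifest ground truth as a data.frame
studyTruth <- function(manifest) {
  do.call(rbind, lapply(manifest$records, function(r)
    data.frame(protein = r$protein, temperature_K = r$temperature_K,
               f_nrvs = r$truth$f_LM_nrvs, f_moss = r$truth$f_LM_moss,
               msd_nrvs = r$truth$msd_nrvs_A2, msd_moss = r$truth$msd_moss_A2)))
}

# discrete-grid msd oracle for an arbitrary PVDOS: rectangle rule over the
# positive grid plus the finite E = 0 quasi-elastic bin (integrand limit
# 2 k_B T D''(0), of which one rectangle of half that value belongs to the
# double-sided zero bin), matching the stated quadrature convention
msdFromPVDOS <- function(pv, T_K) {
  hbar <- 1.054571817e-34
  m <- 56.9354 * 1.66053906660e-27
  kB <- 8.617333262e-2
  dE <- mean(diff(pv@energy_meV))
  coth <- 1 / tanh(pv@energy_meV / (2 * kB * max(T_K, 1e-12)))
  if (T_K == 0) coth <- rep(1, length(pv@energy_meV))
  s <- sum(pv@density * coth / pv@energy_meV) * dE
  if (T_K > 0)
    s <- s + pv@density[1] / pv@energy_meV[1]^2 * kB * T_K * dE
  hbar^2 / (6 * m) * s / 1.602176634e-22 * 1e20
}

# published temperature series (printed tables), shipped as extdata
publishedRmsd <- function() {
  read.csv(system.file("extdata", "rubredoxin_rmsd_published.csv",
                       package = "ferroflex"))
}
publishedFlm <- function() {
  read.csv(system.file("extdata", "rubredoxin_flm_published.csv",
                       package = "ferroflex"))
}
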