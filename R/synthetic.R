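# Synthetic two-protein, three-technique, multi-temperature study.  The
# stated world: Debye-like harmonic Fe dynamics (theta_D = 175 K) common to
# all probes, plus a slow (tens of ns) logistic-activated displacement term
# that only probes with a timescale longer than the slow motion can see --
# Moessbauer and NFS (~100 ns excited-state lifetime) but not NRVS (~4 ps).
# Poisson counting noise is the sole noise source, with per-file seeds
# derived deterministically from the master seed.

#' Protein model for the synthetic study
#'
#' Harmonic dynamics are a Debye solid with temperature \code{thetaD}.  The
#' slow anharmonic term is an additive msd
#' \eqn{a\,\sigma((T - T_0)/w)} (logistic activation) visible only to probes
#' with \code{probe_time > slowTimescale_ns}.  The defaults were calibrated
#' once against the published Moessbauer/NFS f_LM sequence between 220 and
#' 250 K (collapse by more than half between 220 and 235 K, f_LM <= 0.05 at
#' 250 K) and are not tuning knobs.
#'
#' @param label protein label (e.g. "Pf-like", "Pg-like")
#' @param thetaD Debye temperature (K, default 175)
#' @param slowMsdAmplitude_A2 amplitude a of the slow term (Angstrom^2)
#' @param slowOnsetT_K activation midpoint T_0 (K)
#' @param slowOnsetWidth_K activation width w (K)
#' @param slowTimescale_ns timescale of the slow motion (ns); probes faster
#'   than this see only the harmonic term
#' @return a list of class "proteinModel"
#' @export
proteinModel <- function(label, thetaD = 175, slowMsdAmplitude_A2 = 0.040,
                         slowOnsetT_K = 232, slowOnsetWidth_K = 8,
                         slowTimescale_ns = 10) {
  stopifnot(thetaD > 0, slowMsdAmplitude_A2 >= 0, slowOnsetT_K > 0,
            slowOnsetWidth_K > 0, slowTimescale_ns > 0)
  structure(list(label = label, thetaD = thetaD,
                 slowMsdAmplitude_A2 = slowMsdAmplitude_A2,
                 slowOnsetT_K = slowOnsetT_K,
                 slowOnsetWidth_K = slowOnsetWidth_K,
                 slowTimescale_ns = slowTimescale_ns),
            class = "proteinModel")
}

#' Probe-time-dependent mean-square displacement
#'
#' \deqn{\langle u^2 \rangle_{eff}(T) = \langle u^2 \rangle_{Debye}(T) +
#'   a\,\sigma\!\left(\frac{T - T_0}{w}\right)
#'   \mathbf{1}[t_{probe} > t_{slow}],}
#' continuous and non-decreasing in both T and probe time.  NRVS (4 ps) sees
#' the pure Debye curve; Moessbauer/NFS (100 ns) see the slow term too.
#'
#' @param protein a [proteinModel()]
#' @param temperature_K temperature (K, >= 0); vectorized
#' @param probeTime_ns probe timescale (ns): 4e-3 for NRVS, 100 for
#'   Moessbauer/NFS
#' @return msd (Angstrom^2)
#' @export
effectiveMsd <- function(protein, temperature_K, probeTime_ns) {
  base <- debyeMsd(temperature_K, protein$thetaD)
  slow <- if (probeTime_ns > protein$slowTimescale_ns)
    protein$slowMsdAmplitude_A2 *
      plogis((temperature_K - protein$slowOnsetT_K) /
               protein$slowOnsetWidth_K)
  else 0
  base + slow
}

#' Configuration of the synthetic measurement campaign
#'
#' @param proteins list of [proteinModel()] objects (default: an equal
#'   "Pf-like"/"Pg-like" pair at theta_D = 175 K)
#' @param temperatures_K measurement temperatures; must include the 4.2 K
#'   anchor
#' @param masterSeed integer master seed; per-file seeds are
#'   \code{masterSeed * 10000 + iProtein * 1000 + iTemperature * 10 +
#'   iTechnique} (technique 1 = NRVS, 2 = Moessbauer, 3 = NFS), so any file
#'   is regenerable in isolation
#' @param noise apply Poisson noise (FALSE gives the noiseless campaign)
#' @param nrvsCounts expected counts per NRVS scan
#' @param nrvsResolution_fwhm_meV monochromator resolution (meV)
#' @param nrvsGridRange NRVS energy range (meV)
#' @param nrvsGrid_dE NRVS grid spacing (meV)
#' @param mossBaseline counts per Moessbauer channel off resonance
#' @param mossScale resonant-area scale (counts * mm/s at f_LM = 1)
#' @param mossChannels number of velocity channels over +/- 6 mm/s
#' @param nfsCountsAnchor expected windowed NFS counts at the anchor
#'   temperature (rates at other temperatures scale with f_LM)
#' @param chiAnchor effective thickness at the anchor (thick regime)
#' @param probeTimeNrvs_ns,probeTimeMoss_ns probe timescales (ns)
#' @return a list of class "studyConfig"
#' @export
studyConfig <- function(proteins = list(proteinModel("Pf-like"),
                                        proteinModel("Pg-like")),
                        temperatures_K = c(4.2, 18, 40, 90, 100, 120, 150,
                                           180, 200, 220, 235, 250),
                        masterSeed = 1, noise = TRUE,
                        nrvsCounts = 2e6, nrvsResolution_fwhm_meV = 0.8,
                        nrvsGridRange = c(-40, 120), nrvsGrid_dE = 0.25,
                        mossBaseline = 5e4, mossScale = 8000,
                        mossChannels = 256,
                        nfsCountsAnchor = 2e6, chiAnchor = 5,
                        probeTimeNrvs_ns = 4e-3, probeTimeMoss_ns = 100) {
  if (!any(abs(temperatures_K - 4.2) < 1e-9))
    stop("temperature list must include the 4.2 K anchor")
  structure(as.list(environment()), class = "studyConfig")
}

.fileSeed <- function(masterSeed, iProt, iTemp, iTech)
  masterSeed * 10000 + iProt * 1000 + iTemp * 10 + iTech

#' Generate the full synthetic dataset on disk
#'
#' For each protein and temperature, writes one NRVS energy spectrum (from
#' the protein's Debye PVDOS), one Moessbauer velocity spectrum and one NFS
#' time spectrum (both with the slow-motion-suppressed f_LM at the 100 ns
#' probe time), plus a per-protein NFS count-rate table, and a
#' \code{manifest.json} recording ground truth, seeds and the configuration.
#' The same master seed reproduces the dataset byte for byte.
#'
#' @param config a [studyConfig()]
#' @param outDir output directory (created if needed)
#' @param constants a [NuclearConstants-class] object
#' @return the manifest, invisibly
#' @export
generateStudy <- function(config, outDir,
                          constants = nuclearConstants()) {
  stopifnot(inherits(config, "studyConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  temps <- config$temperatures_K
  anchorIdx <- which(abs(temps - 4.2) < 1e-9)[1]
  records <- list()
  mossGrid <- seq(-6, 6, length.out = config$mossChannels)

  for (ip in seq_along(config$proteins)) {
    p <- config$proteins[[ip]]
    pdir <- file.path(outDir, p$label)
    dir.create(pdir, showWarnings = FALSE)
    pv <- debyePVDOS(p$thetaD, dE = config$nrvsGrid_dE)
    fAnchorMoss <- flmFromMsd(effectiveMsd(p, temps[anchorIdx],
                                           config$probeTimeMoss_ns),
                              constants)
    rateTab <- data.frame(temperature_K = numeric(0), counts = numeric(0))

    for (it in seq_along(temps)) {
      T <- temps[it]
      msdN <- effectiveMsd(p, T, config$probeTimeNrvs_ns)
      msdM <- effectiveMsd(p, T, config$probeTimeMoss_ns)
      fN <- flmFromMsd(msdN, constants)
      fM <- flmFromMsd(msdM, constants)

      sN <- .fileSeed(config$masterSeed, ip, it, 1)
      nr <- generateExcitationProbability(
        pv, T, resolution_fwhm = config$nrvsResolution_fwhm_meV,
        constants = constants, gridRange = config$nrvsGridRange,
        totalCounts = config$nrvsCounts,
        seed = if (config$noise) sN else NULL, protein = p$label)
      fN_nrvs <- file.path(pdir, sprintf("nrvs_%07.2fK.tsv", T))
      writeSpectrumTSV(nr, fN_nrvs)

      sM <- .fileSeed(config$masterSeed, ip, it, 2)
      dEQ <- if (ip == 1) 3.28 else 3.31
      ms <- simulateDoublet(0.67, dEQ, 0.28, fLM = fM,
                            scale = config$mossScale,
                            baseline = config$mossBaseline, grid = mossGrid,
                            seed = if (config$noise) sM else NULL,
                            temperature_K = T, protein = p$label)
      fM_file <- file.path(pdir, sprintf("moss_%07.2fK.tsv", T))
      writeSpectrumTSV(ms, fM_file)

      sF <- .fileSeed(config$masterSeed, ip, it, 3)
      dEQnfs <- if (ip == 1) 3.24 else 3.27
      chi <- config$chiAnchor * fM / fAnchorMoss
      nfsCounts <- config$nfsCountsAnchor * fM / fAnchorMoss
      nf <- simulateNfsSpectrum(chi, dEQnfs, totalCounts = nfsCounts,
                                seed = if (config$noise) sF else NULL,
                                temperature_K = T, protein = p$label,
                                constants = constants)
      fF_file <- file.path(pdir, sprintf("nfs_%07.2fK.tsv", T))
      writeSpectrumTSV(nf, fF_file)
      winCounts <- sum(nf@counts[nf@time_ns >= nf@window[1] &
                                 nf@time_ns <= nf@window[2]])
      rateTab <- rbind(rateTab,
                       data.frame(temperature_K = T, counts = winCounts))

      records[[length(records) + 1]] <- list(
        protein = p$label, temperature_K = T,
        files = list(nrvs = basename(fN_nrvs), moss = basename(fM_file),
                     nfs = basename(fF_file)),
        seeds = list(nrvs = sN, moss = sM, nfs = sF),
        truth = list(msd_nrvs_A2 = msdN, msd_moss_A2 = msdM,
                     f_LM_nrvs = fN, f_LM_moss = fM, chi = chi,
                     deltaEQ_moss = dEQ, deltaEQ_nfs = dEQnfs))
    }
    write.table(rateTab, file.path(pdir, "nfs_count_rates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cfgEcho <- config
  cfgEcho$proteins <- lapply(config$proteins, unclass)
  manifest <- list(seed_scheme = "masterSeed*10000 + iProtein*1000 + iTemperature*10 + iTechnique(1=NRVS,2=MOSS,3=NFS)",
                   config = unclass(cfgEcho), records = records)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Process a synthetic (or equally formatted) study back to a flexibility table
#'
#' Runs the three technique pipelines over every file recorded in the
#' manifest: NRVS spectra through [processNrvs()]; Moessbauer spectra through
#' [fitDoublet()] and [flmSeriesFromAreas()] (anchored at the Debye 4.2 K
#' value); NFS count-rate tables through [flmFromCountRates()] (thick
#' regime).  Returns the merged flexibility table.
#'
#' @param dir directory written by [generateStudy()]
#' @param anchorFlm absolute anchor f_LM; the default is the unrounded
#'   Debye-model value at 4.2 K for theta_D = 175 K (0.8224, printed as 0.82)
#' @param constants a [NuclearConstants-class] object
#' @return a flexibility table data.frame (see [makeFlexibilityPoints()])
#' @export
processStudy <- function(dir,
                         anchorFlm = flmFromMsd(debyeMsd(4.2, 175),
                                                constants),
                         constants = nuclearConstants()) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  recs <- manifest$records
  prots <- unique(vapply(recs, function(r) r$protein, ""))
  out <- list()
  for (p in prots) {
    rp <- Filter(function(r) r$protein == p, recs)
    temps <- vapply(rp, function(r) r$temperature_K, numeric(1))

    nrvsRows <- lapply(rp, function(r) {
      sp <- readSpectrumTSV(file.path(dir, p, r$files$nrvs))
      pr <- processNrvs(sp, constants)
      c(f = pr$result@fLM, sig = pr$fLM_sigma)
    })
    fN <- vapply(nrvsRows, `[[`, numeric(1), "f")
    sN <- vapply(nrvsRows, `[[`, numeric(1), "sig")
    out[[length(out) + 1]] <-
      makeFlexibilityPoints(temps, pmin(fN, 1), sN, "NRVS", p,
                            constants = constants)

    # spectra with no measurable doublet (f_LM ~ 0 above the collapse) are
    # dropped, like the missing high-temperature entries of a real campaign
    fits <- lapply(rp, function(r) tryCatch(
      fitDoublet(readSpectrumTSV(file.path(dir, p, r$files$moss))),
      error = function(e) NULL))
    ok <- !vapply(fits, is.null, logical(1))
    out[[length(out) + 1]] <-
      flmSeriesFromAreas(temps[ok], fits[ok], anchorFlm = anchorFlm,
                         protein = p, constants = constants)

    rates <- read.table(file.path(dir, p, "nfs_count_rates.tsv"),
                        header = TRUE, sep = "\t")
    out[[length(out) + 1]] <-
      flmFromCountRates(rates$temperature_K, rates$counts, regime = "thick",
                        anchorFlm = anchorFlm, protein = p,
                        constants = constants)
  }
  do.call(rbind, out)
}
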