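# Accessors and show() methods.

#' @rdname accessors
#' @param object a spectrum, PVDOS or fit object
#' @export
setGeneric("energyGrid", function(object) standardGeneric("energyGrid"))
#' @rdname accessors
#' @export
setGeneric("spectrumCounts", function(object) standardGeneric("spectrumCounts"))
#' @rdname accessors
#' @export
setGeneric("spectrumMeta", function(object) standardGeneric("spectrumMeta"))
#' @rdname accessors
#' @export
setGeneric("temperatureK", function(object) standardGeneric("temperatureK"))

#' Accessors for ferroflex objects
#'
#' \code{energyGrid} returns the energy grid in meV, \code{spectrumCounts}
#' the counts vector, \code{spectrumMeta} the metadata list and
#' \code{temperatureK} the temperature recorded in the metadata.
#'
#' @name accessors
#' @return numeric vector, list, or scalar as appropriate
NULL

#' @rdname accessors
#' @export
setMethod("energyGrid", "EnergySpectrum", function(object) object@energy_meV)
#' @rdname accessors
#' @export
setMethod("energyGrid", "PVDOS", function(object) object@energy_meV)
#' @rdname accessors
#' @export
setMethod("spectrumCounts", "EnergySpectrum", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("spectrumCounts", "VelocitySpectrum", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("spectrumCounts", "TimeSpectrum", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("spectrumMeta", "EnergySpectrum", function(object) object@metadata)
#' @rdname accessors
#' @export
setMethod("spectrumMeta", "VelocitySpectrum", function(object) object@metadata)
#' @rdname accessors
#' @export
setMethod("spectrumMeta", "TimeSpectrum", function(object) object@metadata)

.metaT <- function(object) {
  T <- object@metadata$temperature_K
  if (is.null(T)) NA_real_ else as.numeric(T)
}
#' @rdname accessors
#' @export
setMethod("temperatureK", "EnergySpectrum", .metaT)
#' @rdname accessors
#' @export
setMethod("temperatureK", "VelocitySpectrum", .metaT)
#' @rdname accessors
#' @export
setMethod("temperatureK", "TimeSpectrum", .metaT)

#' @rdname accessors
#' @export
setGeneric("velocityGrid", function(object) standardGeneric("velocityGrid"))
#' @rdname accessors
#' @export
setMethod("velocityGrid", "VelocitySpectrum",
          function(object) object@velocity_mm_s)

#' @rdname accessors
#' @export
setGeneric("timeBins", function(object) standardGeneric("timeBins"))
#' @rdname accessors
#' @export
setMethod("timeBins", "TimeSpectrum", function(object) object@time_ns)

#' @rdname accessors
#' @export
setGeneric("dosDensity", function(object) standardGeneric("dosDensity"))
#' @rdname accessors
#' @export
setMethod("dosDensity", "PVDOS", function(object) object@density)

setMethod("show", "NuclearConstants", function(object) {
  cat("57Fe nuclear constants (14.4125 keV transition)\n")
  cat(sprintf("  E0        %10.4f keV\n", object@resonanceEnergy_keV))
  cat(sprintf("  k         %10.4f 1/A\n", object@wavenumber_invA))
  cat(sprintf("  tau0      %10.1f ns\n", object@meanLifetime_ns))
  cat(sprintf("  Gamma0    %10.2f neV\n", object@naturalLinewidth_neV))
  cat(sprintf("  sigma0    %10.3e cm^2\n", object@maxCrossSection_cm2))
  cat(sprintf("  m(57Fe)   %10.4f u\n", object@fe57Mass_u))
  cat(sprintf("  E_R       %10.4f meV\n", object@recoilEnergy_meV))
  cat(sprintf("  E(1 mm/s) %10.3f neV\n", object@dopplerPerMmS_neV))
})

.showSpec <- function(kind, n, rng, unit, meta) {
  cat(sprintf("%s: %d points, %s %.4g .. %.4g\n", kind, n, unit,
              rng[1], rng[2]))
  if (length(meta)) {
    keys <- vapply(meta, function(x) paste(format(x), collapse = ","), "")
    cat("  metadata:", paste(names(meta), keys, sep = "=", collapse = "  "),
        "\n")
  }
}

setMethod("show", "EnergySpectrum", function(object)
  .showSpec("EnergySpectrum", length(object@energy_meV),
            range(object@energy_meV), "meV", object@metadata))
setMethod("show", "VelocitySpectrum", function(object)
  .showSpec("VelocitySpectrum", length(object@velocity_mm_s),
            range(object@velocity_mm_s), "mm/s", object@metadata))
setMethod("show", "TimeSpectrum", function(object) {
  .showSpec("TimeSpectrum", length(object@time_ns), range(object@time_ns),
            "ns", object@metadata)
  cat(sprintf("  window %.1f-%.1f ns, bunch period %.1f ns\n",
              object@window[1], object@window[2], object@bunchPeriod_ns))
})
setMethod("show", "PVDOS", function(object) {
  dE <- mean(diff(object@energy_meV))
  cat(sprintf("PVDOS: %d points, 0 < E <= %.3g meV, integral %.6f\n",
              length(object@energy_meV), max(object@energy_meV),
              sum(object@density) * dE))
})
setMethod("show", "DebyeFit", function(object) {
  cat(sprintf("Debye fit: theta_D = %.2f K (se %.2f K), %d points, rms resid %.3g A^2\n",
              object@thetaD_K, object@stderr_K, nrow(object@data),
              sqrt(mean(object@residuals_A2^2))))
})
setMethod("show", "DoubletFit", function(object) {
  cat(sprintf(
    "Quadrupole doublet: delta = %.3f, dEQ = %.3f, Gamma = %.3f mm/s, area = %.4g\n",
    object@isomerShift_mm_s, object@quadrupoleSplitting_mm_s,
    object@linewidth_mm_s, object@totalArea))
})
setMethod("show", "NFSFit", function(object) {
  cat(sprintf(
    "NFS fit: chi = %.3f, dOmega = %.4f rad/ns (dEQ = %.3f mm/s), deviance = %.1f\n",
    object@chi, object@deltaOmega_rad_ns, object@deltaEQ_mm_s,
    object@deviance))
})
setMethod("show", "NRVSResult", function(object) {
  cat(sprintf(
    "NRVS result: fLM = %.4f (elastic-ratio %.4f), msd = %.4g A^2, M1 = %.4f meV\n",
    object@fLM, object@fLMElastic, object@msd_A2, object@firstMoment_meV))
})
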