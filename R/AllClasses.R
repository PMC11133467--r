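# S4 containers for the three observables, the PVDOS, and fit results.
# Grids carry physical units in their slot names; metadata is a named list
# with at least the keys each pipeline stage needs (temperature_K, protein,
# resolution_fwhm_meV for NRVS).

.checkUniform <- function(x, tol = 1e-8) {
  if (length(x) < 2) return(TRUE)
  d <- diff(x)
  all(d > 0) && (max(d) - min(d)) < tol * max(abs(d))
}

#' NuclearConstants: the 57Fe constants every equation uses
#'
#' All nuclear constants for the 14.4125 keV Moessbauer transition of 57Fe,
#' with derived quantities (wavenumber, recoil energy, Doppler conversion)
#' computed from CODATA-2018 fundamental constants at construction time.
#' Validity enforces the internal consistency of the set:
#' \eqn{\Gamma_0 \tau_0 = \hbar} (0.5%), \eqn{E_R = E_0^2/(2 m c^2)} (0.1%)
#' and \eqn{k = E_0/(\hbar c)} (0.1%).
#'
#' @slot resonanceEnergy_keV nuclear transition energy (14.4125 keV)
#' @slot wavenumber_invA photon wavenumber \eqn{k = 2\pi/\lambda} (1/Angstrom)
#' @slot meanLifetime_ns mean lifetime of the excited state \eqn{\tau_0} (ns)
#' @slot naturalLinewidth_neV natural linewidth \eqn{\Gamma_0} (neV)
#' @slot maxCrossSection_cm2 maximum resonance cross section \eqn{\sigma_0}
#' @slot fe57Mass_u 57Fe atomic mass (u)
#' @slot recoilEnergy_meV free-nucleus recoil energy \eqn{E_R} (meV)
#' @slot dopplerPerMmS_neV Doppler energy per 1 mm/s source velocity (neV)
#' @exportClass NuclearConstants
setClass("NuclearConstants",
  representation(
    resonanceEnergy_keV  = "numeric",
    wavenumber_invA      = "numeric",
    meanLifetime_ns      = "numeric",
    naturalLinewidth_neV = "numeric",
    maxCrossSection_cm2  = "numeric",
    fe57Mass_u           = "numeric",
    recoilEnergy_meV     = "numeric",
    dopplerPerMmS_neV    = "numeric"
  )
)

setValidity("NuclearConstants", function(object) {
  msgs <- character()
  E0_eV <- object@resonanceEnergy_keV * 1e3
  hbar_neVns <- .pc$hbar_eVs * 1e18
  if (abs(object@naturalLinewidth_neV * object@meanLifetime_ns - hbar_neVns) >
      5e-3 * hbar_neVns)
    msgs <- c(msgs, "Gamma0 * tau0 deviates from hbar by more than 0.5%")
  ER <- E0_eV^2 / (2 * object@fe57Mass_u * .pc$amu_eV) * 1e3
  if (abs(object@recoilEnergy_meV - ER) > 1e-3 * ER)
    msgs <- c(msgs, "recoil energy inconsistent with E0^2/(2 m c^2)")
  k <- E0_eV / .pc$hbarc_eVA
  if (abs(object@wavenumber_invA - k) > 1e-3 * k)
    msgs <- c(msgs, "wavenumber inconsistent with E0/(hbar c)")
  if (length(msgs)) msgs else TRUE
})

#' EnergySpectrum: an NRVS scan on a uniform energy grid
#'
#' Counts (per meV) on a strictly increasing uniform grid of energies in meV
#' relative to the nuclear resonance; positive energy = phonon creation
#' (Stokes side).  The grid must contain 0 meV.
#'
#' @slot energy_meV energy grid (meV, uniform, contains 0)
#' @slot counts counts per meV per point (non-negative)
#' @slot countError 1-sigma counting error per point (same units as counts)
#' @slot metadata named list: temperature_K, protein, resolution_fwhm_meV
#' @exportClass EnergySpectrum
setClass("EnergySpectrum",
  representation(energy_meV = "numeric", counts = "numeric",
                 countError = "numeric", metadata = "list"))

setValidity("EnergySpectrum", function(object) {
  msgs <- character()
  if (!.checkUniform(object@energy_meV))
    msgs <- c(msgs, "energy grid must be strictly increasing and uniform")
  if (length(object@counts) != length(object@energy_meV))
    msgs <- c(msgs, "counts length != grid length")
  if (any(object@counts < 0)) msgs <- c(msgs, "counts must be >= 0")
  if (min(abs(object@energy_meV)) > 1e-6 * mean(diff(object@energy_meV)))
    msgs <- c(msgs, "grid must contain 0 meV")
  if (length(msgs)) msgs else TRUE
})

#' PVDOS: 57Fe partial vibrational density of states
#'
#' One-phonon partial density of vibrational states on a positive energy
#' grid, normalized so that the integral equals 3 (three Cartesian degrees of
#' freedom of the Fe nucleus).
#'
#' @slot energy_meV energy grid (meV, > 0, uniform)
#' @slot density states per meV (non-negative)
#' @exportClass PVDOS
setClass("PVDOS",
  representation(energy_meV = "numeric", density = "numeric"))

setValidity("PVDOS", function(object) {
  msgs <- character()
  if (any(object@energy_meV <= 0)) msgs <- c(msgs, "grid must be > 0")
  if (!.checkUniform(object@energy_meV))
    msgs <- c(msgs, "grid must be strictly increasing and uniform")
  if (any(object@density < -1e-12)) msgs <- c(msgs, "density must be >= 0")
  dE <- mean(diff(object@energy_meV))
  tot <- sum(object@density) * dE
  if (abs(tot - 3) > 1e-6)
    msgs <- c(msgs, sprintf("density must integrate to 3 (got %.8f)", tot))
  if (length(msgs)) msgs else TRUE
})

#' VelocitySpectrum: a transmission Moessbauer spectrum
#'
#' Transmission counts per channel on a uniform velocity grid (mm/s),
#' symmetric about zero.  Absorption appears as dips below the baseline.
#'
#' @slot velocity_mm_s velocity grid (mm/s, uniform)
#' @slot counts transmission counts per channel (> 0)
#' @slot metadata named list: temperature_K, protein
#' @exportClass VelocitySpectrum
setClass("VelocitySpectrum",
  representation(velocity_mm_s = "numeric", counts = "numeric",
                 metadata = "list"))

setValidity("VelocitySpectrum", function(object) {
  msgs <- character()
  if (!.checkUniform(object@velocity_mm_s))
    msgs <- c(msgs, "velocity grid must be uniform and increasing")
  if (length(object@counts) != length(object@velocity_mm_s))
    msgs <- c(msgs, "counts length != grid length")
  if (any(object@counts <= 0))
    msgs <- c(msgs, "transmission counts must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' TimeSpectrum: a nuclear-forward-scattering time spectrum
#'
#' Delayed counts in uniform time bins after the excitation pulse.  Bins must
#' lie inside one synchrotron bunch period; fitting uses only the analysis
#' window (default 18--600 ns, which excises the prompt pulse).
#'
#' @slot time_ns bin centres (ns, uniform)
#' @slot counts counts per bin (non-negative)
#' @slot window analysis window c(t_min, t_max) in ns
#' @slot bunchPeriod_ns synchrotron bunch period (ns)
#' @slot metadata named list: temperature_K, protein
#' @exportClass TimeSpectrum
setClass("TimeSpectrum",
  representation(time_ns = "numeric", counts = "numeric", window = "numeric",
                 bunchPeriod_ns = "numeric", metadata = "list"))

setValidity("TimeSpectrum", function(object) {
  msgs <- character()
  if (!.checkUniform(object@time_ns))
    msgs <- c(msgs, "time bins must be uniform and increasing")
  if (any(object@time_ns <= 0) ||
      any(object@time_ns >= object@bunchPeriod_ns))
    msgs <- c(msgs, "bins must lie within (0, bunch period)")
  if (any(object@counts < 0)) msgs <- c(msgs, "counts must be >= 0")
  if (length(object@window) != 2 || object@window[1] >= object@window[2])
    msgs <- c(msgs, "window must be c(t_min, t_max) with t_min < t_max")
  if (object@window[1] < min(object@time_ns) - mean(diff(object@time_ns)) ||
      object@window[2] > max(object@time_ns) + mean(diff(object@time_ns)))
    msgs <- c(msgs, "window must lie within the binned range")
  if (length(msgs)) msgs else TRUE
})

#' DebyeFit: a fitted Debye temperature
#'
#' @slot thetaD_K fitted Debye temperature (K)
#' @slot stderr_K 1-sigma uncertainty (K; NA for a single point)
#' @slot residuals_A2 residuals msd_obs - msd_model (Angstrom^2)
#' @slot fitted_A2 fitted msd values (Angstrom^2)
#' @slot data data.frame with temperature_K, msd_A2, weight
#' @exportClass DebyeFit
setClass("DebyeFit",
  representation(thetaD_K = "numeric", stderr_K = "numeric",
                 residuals_A2 = "numeric", fitted_A2 = "numeric",
                 data = "data.frame"))

#' DoubletFit: a fitted quadrupole doublet
#'
#' Thin-absorber Lorentzian doublet parameters with 1-sigma uncertainties
#' (slot \code{stderr}, named numeric).  \code{totalArea} is the summed dip
#' area in counts * mm/s; in the thin-absorber regime it is proportional to
#' \eqn{f_{LM}} times the resonant thickness scale.
#'
#' @slot isomerShift_mm_s centroid shift (mm/s)
#' @slot quadrupoleSplitting_mm_s line separation Delta E_Q (mm/s, >= 0)
#' @slot linewidth_mm_s FWHM per line (mm/s, >= 2 Gamma_0 in Doppler units)
#' @slot totalArea summed dip area (counts * mm/s)
#' @slot baseline off-resonance transmission level (counts)
#' @slot stderr named 1-sigma uncertainties
#' @slot converged logical
#' @exportClass DoubletFit
setClass("DoubletFit",
  representation(isomerShift_mm_s = "numeric",
                 quadrupoleSplitting_mm_s = "numeric",
                 linewidth_mm_s = "numeric", totalArea = "numeric",
                 baseline = "numeric", stderr = "numeric",
                 converged = "logical"))

setValidity("DoubletFit", function(object) {
  msgs <- character()
  if (object@quadrupoleSplitting_mm_s < 0)
    msgs <- c(msgs, "quadrupole splitting must be >= 0")
  if (object@linewidth_mm_s < 0.19)
    msgs <- c(msgs, "linewidth below doubled natural linewidth (~0.194 mm/s)")
  if (length(msgs)) msgs else TRUE
})

#' NFSFit: fitted parameters of the quantum/dynamical-beat model
#'
#' @slot chi effective resonant thickness (dimensionless, > 0)
#' @slot deltaOmega_rad_ns quantum-beat angular frequency (rad/ns)
#' @slot deltaEQ_mm_s quadrupole splitting implied by deltaOmega (mm/s)
#' @slot amplitude counts scale
#' @slot tOffset_ns time-zero offset (ns)
#' @slot stderr named 1-sigma uncertainties
#' @slot deviance Poisson deviance at the optimum
#' @exportClass NFSFit
setClass("NFSFit",
  representation(chi = "numeric", deltaOmega_rad_ns = "numeric",
                 deltaEQ_mm_s = "numeric", amplitude = "numeric",
                 tOffset_ns = "numeric", stderr = "numeric",
                 deviance = "numeric"))

#' NRVSResult: what the NRVS inversion pipeline returns
#'
#' @slot fLM Lamb-Moessbauer factor from the sum-rule normalization
#'   (1 - integral of the normalized inelastic spectrum)
#' @slot fLMElastic Lamb-Moessbauer factor from the elastic/total ratio
#'   (NA when no elastic area was supplied)
#' @slot msd_A2 mean-square displacement along the beam (Angstrom^2)
#' @slot detailedBalanceT_K temperature from detailed balance (NA if not
#'   estimated)
#' @slot pvdos recovered [PVDOS-class] object
#' @slot firstMoment_meV first moment of the normalized spectrum (= E_R)
#' @exportClass NRVSResult
setClass("NRVSResult",
  representation(fLM = "numeric", fLMElastic = "numeric", msd_A2 = "numeric",
                 detailedBalanceT_K = "numeric", pvdos = "PVDOS",
                 firstMoment_meV = "numeric"))
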