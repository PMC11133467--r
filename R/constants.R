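# CODATA-2018 fundamental constants used throughout.  Internal.
.pc <- list(
  hbar_Js   = 1.054571817e-34,   # J s
  hbar_eVs  = 6.582119569e-16,   # eV s
  h_eVs     = 4.135667696e-15,   # eV s
  c_mps     = 2.99792458e8,      # m/s
  kB_JK     = 1.380649e-23,      # J/K
  kB_meVK   = 8.617333262e-2,    # meV/K
  u_kg      = 1.66053906660e-27, # kg
  amu_eV    = 931.49410242e6,    # eV per u (mass-energy)
  eV_J      = 1.602176634e-19,   # J per eV
  hbarc_eVA = 1973.269804        # eV Angstrom
)

#' 57Fe nuclear constants
#'
#' Build the [NuclearConstants-class] set for the 14.4125 keV transition.
#' Measured nuclear properties (lifetime, linewidth, cross section, mass) are
#' pinned; wavenumber, recoil energy and the Doppler conversion are derived
#' from CODATA-2018 fundamental constants, so the validity invariants hold by
#' construction.  Note the derived recoil energy is 1.9583 meV (the often
#' quoted 1.956 meV uses A = 57 rather than the atomic mass 56.9354 u).
#'
#' @return a validated [NuclearConstants-class] object
#' @examples
#' nc <- nuclearConstants()
#' nc@wavenumber_invA          # ~7.304 1/Angstrom
#' @export
nuclearConstants <- function() {
  E0_keV <- 14.4125
  E0_eV <- E0_keV * 1e3
  m_u <- 56.9354
  new("NuclearConstants",
      resonanceEnergy_keV  = E0_keV,
      wavenumber_invA      = E0_eV / .pc$hbarc_eVA,
      meanLifetime_ns      = 141.1,
      naturalLinewidth_neV = 4.66,
      maxCrossSection_cm2  = 2.56e-18,
      fe57Mass_u           = m_u,
      recoilEnergy_meV     = E0_eV^2 / (2 * m_u * .pc$amu_eV) * 1e3,
      dopplerPerMmS_neV    = E0_eV * (1e-3 / .pc$c_mps) * 1e9)
}

#' Lamb-Moessbauer factor from mean-square displacement (and back)
#'
#' For harmonic motion the recoilless fraction is
#' \eqn{f_{LM} = \exp(-k^2 \langle u^2 \rangle)} with \eqn{k = 2\pi/\lambda}
#' the photon wavenumber and \eqn{\langle u^2 \rangle} the mean-square
#' displacement of the 57Fe nucleus projected along the beam.
#'
#' @param msd mean-square displacement (Angstrom^2, >= 0); vectorized
#' @param constants a [NuclearConstants-class] object
#' @return \code{flmFromMsd}: recoilless fraction in (0, 1];
#'   \code{msdFromFlm}: msd in Angstrom^2
#' @examples
#' flmFromMsd(3.66e-3)   # ~0.82
#' msdFromFlm(0.78)      # ~4.66e-3 (rmsd 0.068 Angstrom)
#' @export
flmFromMsd <- function(msd, constants = nuclearConstants()) {
  if (any(!is.finite(msd)) || any(msd < 0))
    stop("msd must be finite and >= 0")
  exp(-constants@wavenumber_invA^2 * msd)
}

#' @rdname flmFromMsd
#' @param fLM recoilless fraction in (0, 1]; vectorized
#' @export
msdFromFlm <- function(fLM, constants = nuclearConstants()) {
  if (any(!is.finite(fLM)) || any(fLM <= 0) || any(fLM > 1))
    stop("fLM must lie in (0, 1]")
  -log(fLM) / constants@wavenumber_invA^2
}

#' Doppler velocity-energy conversion
#'
#' First-order Doppler shift of the 14.4125 keV line: \eqn{E = E_0 v / c},
#' i.e. 48.07 neV per mm/s.
#'
#' @param v_mm_s source velocity (mm/s); vectorized
#' @param E_neV energy (neV); vectorized
#' @param constants a [NuclearConstants-class] object
#' @return energy in neV (\code{dopplerToEnergy}) or velocity in mm/s
#' @examples
#' dopplerToEnergy(1)      # 48.07 neV
#' energyToDoppler(157.2)  # ~3.27 mm/s
#' @export
dopplerToEnergy <- function(v_mm_s, constants = nuclearConstants()) {
  v_mm_s * constants@dopplerPerMmS_neV
}

#' @rdname dopplerToEnergy
#' @export
energyToDoppler <- function(E_neV, constants = nuclearConstants()) {
  E_neV / constants@dopplerPerMmS_neV
}

#' RMS displacement from a crystallographic B-factor
#'
#' Standard isotropic Debye-Waller relation \eqn{u = \sqrt{B / 8\pi^2}},
#' used to place diffraction B-values on the same RMSD scale as the nuclear
#' techniques.
#'
#' @param B isotropic B-factor (Angstrom^2, >= 0); vectorized
#' @return rms displacement (Angstrom)
#' @examples
#' rmsdFromBfactor(3.158)  # ~0.20 Angstrom
#' @export
rmsdFromBfactor <- function(B) {
  if (any(!is.finite(B)) || any(B < 0)) stop("B must be finite and >= 0")
  sqrt(B / (8 * pi^2))
}

#' Export the constant set as JSON
#'
#' Serializes the constant set for provenance: energies in meV (plus the keV
#' transition energy), velocities in mm/s, times in ns, lengths in Angstrom.
#'
#' @param path file to write; if NULL, the JSON string is returned
#' @param constants a [NuclearConstants-class] object
#' @return the JSON string, invisibly when written to a file
#' @export
constantsToJSON <- function(path = NULL, constants = nuclearConstants()) {
  x <- list(
    resonance_energy_keV   = constants@resonanceEnergy_keV,
    resonance_energy_meV   = constants@resonanceEnergy_keV * 1e9 / 1e3,
    wavenumber_invA        = constants@wavenumber_invA,
    mean_lifetime_ns       = constants@meanLifetime_ns,
    natural_linewidth_meV  = constants@naturalLinewidth_neV * 1e-6,
    max_cross_section_cm2  = constants@maxCrossSection_cm2,
    fe57_mass_u            = constants@fe57Mass_u,
    recoil_energy_meV      = constants@recoilEnergy_meV,
    doppler_per_mm_s_meV   = constants@dopplerPerMmS_neV * 1e-6)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
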