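# Debye model of the Fe-site mean-square displacement and the theta_D fit.

#' Debye-model mean-square displacement
#'
#' Mean-square displacement of a nucleus of mass \code{mass_u} in a Debye
#' solid with Debye temperature \code{thetaD},
#' \deqn{\langle u^2 \rangle(T) = \frac{3\hbar^2}{m k_B \theta_D}
#'   \left[\frac14 + \left(\frac{T}{\theta_D}\right)^2
#'   \int_0^{\theta_D/T} \frac{x}{e^x - 1}\,dx \right],}
#' evaluated by adaptive quadrature (absolute tolerance 1e-12).  At T = 0 the
#' bracket is exactly 1/4 (zero-point motion); the function is strictly
#' increasing in T and strictly decreasing in thetaD.
#'
#' @param temperature_K temperature (K, >= 0); vectorized
#' @param thetaD Debye temperature (K, > 0)
#' @param mass_u oscillator mass (u); default the 57Fe atomic mass
#' @return mean-square displacement (Angstrom^2)
#' @examples
#' debyeMsd(4.2, 175)   # 3.665e-3 Angstrom^2, hence f_LM = 0.82
#' @export
debyeMsd <- function(temperature_K, thetaD,
                     mass_u = nuclearConstants()@fe57Mass_u) {
  if (!is.finite(thetaD) || thetaD <= 0) stop("thetaD must be > 0")
  if (!is.finite(mass_u) || mass_u <= 0) stop("mass_u must be > 0")
  if (any(!is.finite(temperature_K)) || any(temperature_K < 0))
    stop("temperature must be >= 0")
  pref <- 3 * .pc$hbar_Js^2 / (mass_u * .pc$u_kg * .pc$kB_JK * thetaD) * 1e20
  vapply(temperature_K, function(T) {
    br <- if (T == 0) 0.25 else
      0.25 + (T / thetaD)^2 *
        integrate(function(x) ifelse(x == 0, 1, x / expm1(x)),
                  0, thetaD / T, rel.tol = 1e-10, abs.tol = 1e-12)$value
    pref * br
  }, numeric(1))
}

#' Fit a Debye temperature to a mean-square-displacement series
#'
#' Weighted least squares of [debyeMsd()] against observed
#' \eqn{\langle u^2 \rangle (T)} over thetaD alone (1-D bounded minimization
#' on [20, 1000] K).  Weights default to uniform; pass \code{weights = 1 /
#' sigma^2} when per-point uncertainties are known.  The standard error is
#' the linearized WLS value \eqn{\sqrt{\hat\sigma^2 / \sum w g'(\theta)^2}}
#' with the residual variance estimated from the fit (NA for n < 2 or a
#' perfect fit).
#'
#' @param temperature_K temperatures (K, > 0)
#' @param msd_A2 observed mean-square displacements (Angstrom^2, > 0)
#' @param weights optional non-negative weights (recycled)
#' @param mass_u oscillator mass (u)
#' @param bounds search interval for thetaD (K)
#' @return a [DebyeFit-class] object
#' @examples
#' T <- c(40, 110, 160, 200, 235, 295)
#' fit <- fitDebyeTemperature(T, debyeMsd(T, 175))
#' fit@thetaD_K   # 175 to < 0.5 K
#' @export
fitDebyeTemperature <- function(temperature_K, msd_A2, weights = NULL,
                                mass_u = nuclearConstants()@fe57Mass_u,
                                bounds = c(20, 1000)) {
  n <- length(temperature_K)
  if (n == 0 || length(msd_A2) != n)
    stop("need matching, non-empty temperature and msd vectors")
  if (any(temperature_K <= 0) || any(msd_A2 <= 0))
    stop("temperatures and msd must be positive")
  w <- if (is.null(weights)) rep(1, n) else rep_len(as.numeric(weights), n)
  if (any(w < 0) || all(w == 0)) stop("weights must be >= 0 and not all zero")
  obj <- function(th) {
    m <- debyeMsd(temperature_K, th, mass_u)
    sum(w * (m - msd_A2)^2)
  }
  opt <- optimize(obj, interval = bounds, tol = 1e-6)
  th <- opt$minimum
  fitted <- debyeMsd(temperature_K, th, mass_u)
  res <- msd_A2 - fitted
  se <- NA_real_
  if (n >= 2) {
    dth <- max(1e-3, th * 1e-4)
    g <- (debyeMsd(temperature_K, th + dth, mass_u) -
          debyeMsd(temperature_K, th - dth, mass_u)) / (2 * dth)
    s2 <- sum(w * res^2) / (n - 1)
    denom <- sum(w * g^2)
    if (denom > 0 && s2 > 0) se <- sqrt(s2 / denom)
  }
  new("DebyeFit", thetaD_K = th, stderr_K = se, residuals_A2 = res,
      fitted_A2 = fitted,
      data = data.frame(temperature_K = temperature_K, msd_A2 = msd_A2,
                        weight = w))
}

#' Debye partial vibrational density of states
#'
#' The Debye PVDOS \eqn{D(E) = 9E^2/E_D^3} for \eqn{0 < E \le E_D} with
#' \eqn{E_D = k_B \theta_D}, discretized on a uniform grid and renormalized
#' so the discrete integral equals exactly 3 (which makes the discretized
#' zero-point msd reproduce \eqn{3\hbar^2/(4 m k_B \theta_D)}).
#'
#' @param thetaD Debye temperature (K)
#' @param dE grid spacing (meV)
#' @param eMax_meV upper edge of the grid (meV); defaults to just above the
#'   Debye cutoff
#' @return a [PVDOS-class] object
#' @export
debyePVDOS <- function(thetaD, dE = 0.25, eMax_meV = NULL) {
  ED <- .pc$kB_meVK * thetaD
  if (is.null(eMax_meV)) eMax_meV <- ED * 1.2
  grid <- seq(dE, eMax_meV, by = dE)
  dens <- ifelse(grid <= ED, 9 * grid^2 / ED^3, 0)
  dens <- dens * 3 / (sum(dens) * dE)
  new("PVDOS", energy_meV = grid, density = dens)
}

#' Construct a PVDOS from arbitrary density values
#'
#' Renormalizes the supplied density to integrate to exactly 3.
#'
#' @param energy_meV uniform positive energy grid (meV)
#' @param density non-negative density values
#' @return a [PVDOS-class] object
#' @export
makePVDOS <- function(energy_meV, density) {
  if (all(density <= 0)) stop("density must have positive mass")
  density <- pmax(density, 0)
  dE <- mean(diff(energy_meV))
  new("PVDOS", energy_meV = energy_meV,
      density = density * 3 / (sum(density) * dE))
}
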