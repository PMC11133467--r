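# Velocity-domain Moessbauer: thin-absorber quadrupole-doublet simulation and
# least-squares fitting, plus conversion of absorption-area temperature
# series to absolute f_LM via the low-temperature Debye anchor.

# unit-area Lorentzian with FWHM gamma
.lorentz <- function(v, centre, gamma) {
  (gamma / (2 * pi)) / ((v - centre)^2 + (gamma / 2)^2)
}

.doubletModel <- function(v, baseline, area, shift, splitting, gamma) {
  baseline - (area / 2) * (.lorentz(v, shift - splitting / 2, gamma) +
                           .lorentz(v, shift + splitting / 2, gamma))
}

#' Simulate a thin-absorber quadrupole doublet
#'
#' Transmission spectrum with two equal-area Lorentzian absorption dips at
#' \eqn{\delta \pm \Delta E_Q / 2}; the total dip area is
#' \eqn{f_{LM} \times scale} (thin-absorber linearity: area, not depth,
#' carries the recoilless fraction).  Optional Poisson counting noise.
#'
#' @param isomerShift centroid shift delta (mm/s)
#' @param quadrupoleSplitting Delta E_Q (mm/s, >= 0)
#' @param linewidth Lorentzian FWHM per line (mm/s, >= 0.194)
#' @param fLM recoilless fraction in (0, 1]
#' @param scale resonant-area scale (counts * mm/s at f_LM = 1)
#' @param baseline off-resonance counts per channel
#' @param grid velocity grid (mm/s); must cover both lines +/- 3 linewidths
#' @param seed integer seed for Poisson noise (NULL = noiseless)
#' @param temperature_K,protein metadata labels
#' @return a [VelocitySpectrum-class] object
#' @examples
#' sp <- simulateDoublet(0.67, 3.28, 0.28, fLM = 0.82, scale = 8000,
#'                       baseline = 5e4)
#' @export
simulateDoublet <- function(isomerShift, quadrupoleSplitting, linewidth,
                            fLM, scale, baseline,
                            grid = seq(-6, 6, length.out = 256),
                            seed = NULL, temperature_K = NA_real_,
                            protein = NULL) {
  if (quadrupoleSplitting < 0) stop("quadrupole splitting must be >= 0")
  if (fLM <= 0 || fLM > 1) stop("fLM must lie in (0, 1]")
  lines <- isomerShift + c(-1, 1) * quadrupoleSplitting / 2
  if (min(lines) - 3 * linewidth < min(grid) ||
      max(lines) + 3 * linewidth > max(grid))
    stop("grid does not cover both lines +/- 3 linewidths")
  mu <- .doubletModel(grid, baseline, fLM * scale, isomerShift,
                      quadrupoleSplitting, linewidth)
  if (any(mu <= 0)) stop("model transmission non-positive; reduce scale")
  cnt <- if (!is.null(seed)) .withSeed(seed, rpois(length(mu), mu)) else mu
  cnt <- pmax(cnt, 1)  # transmission counts must stay positive
  new("VelocitySpectrum", velocity_mm_s = grid, counts = cnt,
      metadata = list(temperature_K = temperature_K, protein = protein))
}

#' Fit a quadrupole doublet to a transmission spectrum
#'
#' Weighted least squares (Poisson weights 1/counts) of the thin-absorber
#' doublet model over baseline, total area, isomer shift, splitting and
#' common linewidth.  Starting values come from the two deepest local dips.
#' Parameter uncertainties are the linearized values from the weighted
#' normal equations (absolute Poisson errors, no chi-square rescaling).
#'
#' @param spec a [VelocitySpectrum-class] object
#' @param minSNR minimum dip depth over Poisson noise to attempt a fit
#' @return a [DoubletFit-class] object
#' @export
fitDoublet <- function(spec, minSNR = 3) {
  stopifnot(is(spec, "VelocitySpectrum"))
  v <- spec@velocity_mm_s
  y <- spec@counts
  b0 <- median(y[c(seq_len(10), length(y) - 0:9)])
  depth <- b0 - min(y)
  if (depth < minSNR * sqrt(max(b0, 1)))
    stop("no doublet found: dip depth below ", minSNR, " sigma")

  # locate the two deepest separated minima for starting values
  dips <- order(y)[seq_len(max(10, length(y) %/% 8))]
  c1 <- v[dips[1]]
  far <- dips[abs(v[dips] - c1) > 0.5]
  c2 <- if (length(far)) v[far[1]] else c1 + 1
  g0 <- 0.3

  # variable projection: (baseline, area) are linear given (shift, splitting,
  # linewidth) and are solved exactly by weighted least squares
  w <- 1 / pmax(y, 1)
  linSolve <- function(d, q, g) {
    shape <- (.lorentz(v, d - q / 2, g) + .lorentz(v, d + q / 2, g)) / 2
    X <- cbind(1, -shape)
    XtW <- t(X * w)
    solve(XtW %*% X, XtW %*% y)  # c(baseline, area)
  }
  objNL <- function(th) {
    d <- th[1]; q <- abs(th[2]); g <- max(th[3], 0.194)
    ba <- tryCatch(linSolve(d, q, g), error = function(e) c(b0, 0))
    m <- .doubletModel(v, ba[1], ba[2], d, q, g)
    sum(w * (y - m)^2)
  }
  th0 <- c((c1 + c2) / 2, max(abs(c2 - c1), 0.2), g0)
  fit <- optim(th0, objNL, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  fit2 <- optim(fit$par, objNL, method = "Nelder-Mead",
                control = list(reltol = 1e-13, maxit = 2000))
  # a zero-residual (noiseless) fit can exhaust iterations without meeting
  # the relative tolerance; accept when the restart no longer improves
  conv <- fit2$convergence == 0 ||
    (fit$value - fit2$value) <= 1e-12 * sum(w * y^2)
  th <- fit2$par
  if (!conv)
    stop("doublet fit did not converge (last iterate: ",
         paste(sprintf("%.4g", th), collapse = ", "), ")")
  d <- th[1]; q <- abs(th[2]); g <- max(th[3], 0.194)
  ba <- linSolve(d, q, g)
  p <- c(ba[1], ba[2], d, q, g)

  # linearized covariance from the weighted Jacobian
  J <- matrix(0, length(v), 5)
  eps <- pmax(abs(p) * 1e-6, 1e-8)
  for (k in seq_len(5)) {
    pp <- p; pp[k] <- pp[k] + eps[k]
    pm <- p; pm[k] <- pm[k] - eps[k]
    J[, k] <- (.doubletModel(v, pp[1], pp[2], pp[3], abs(pp[4]), pp[5]) -
               .doubletModel(v, pm[1], pm[2], pm[3], abs(pm[4]), pm[5])) /
      (2 * eps[k])
  }
  cov <- tryCatch(solve(t(J) %*% (w * J)),
                  error = function(e) matrix(NA_real_, 5, 5))
  se <- sqrt(pmax(diag(cov), 0))
  names(se) <- c("baseline", "totalArea", "isomerShift_mm_s",
                 "quadrupoleSplitting_mm_s", "linewidth_mm_s")
  new("DoubletFit", isomerShift_mm_s = p[[3]],
      quadrupoleSplitting_mm_s = abs(p[[4]]), linewidth_mm_s = p[[5]],
      totalArea = p[[2]], baseline = p[[1]], stderr = se, converged = conv)
}

#' Absolute f_LM series from doublet areas and a low-temperature anchor
#'
#' Conventional Moessbauer measures only relative recoilless fractions; the
#' series is made absolute by anchoring the area at (or within 1 K of)
#' \code{anchorT} to \code{anchorFlm} -- the Debye-model low-temperature
#' limit (0.82 at 4.2 K for theta_D = 175 K).  Area uncertainties are
#' propagated in quadrature.
#'
#' @param temperature_K temperatures of the fitted spectra (K)
#' @param fits list of [DoubletFit-class] objects (same order), or NULL if
#'   \code{areas} is given
#' @param areas,areaSigma optional numeric vectors instead of \code{fits}
#' @param anchorFlm absolute f_LM at the anchor (default 0.82)
#' @param anchorT anchor temperature (K, default 4.2)
#' @param protein label for the output rows
#' @param constants a [NuclearConstants-class] object
#' @return a data.frame of flexibility points: temperature_K, protein,
#'   technique, f_LM, f_LM_sigma, msd_A2, rmsd_A
#' @export
flmSeriesFromAreas <- function(temperature_K, fits = NULL, areas = NULL,
                               areaSigma = NULL, anchorFlm = 0.82,
                               anchorT = 4.2, protein = NA_character_,
                               constants = nuclearConstants()) {
  if (is.null(areas)) {
    areas <- vapply(fits, function(f) f@totalArea, numeric(1))
    areaSigma <- vapply(fits, function(f)
      unname(f@stderr["totalArea"]), numeric(1))
  }
  if (is.null(areaSigma)) areaSigma <- rep(0, length(areas))
  ia <- which(abs(temperature_K - anchorT) <= 1)
  if (!length(ia))
    stop("missing anchor temperature: no point within 1 K of ", anchorT)
  ia <- ia[which.min(abs(temperature_K[ia] - anchorT))]
  f <- areas / areas[ia] * anchorFlm
  relv <- (areaSigma / areas)^2 + (areaSigma[ia] / areas[ia])^2
  relv[ia] <- (areaSigma[ia] / areas[ia])^2
  sig <- f * sqrt(relv)
  makeFlexibilityPoints(temperature_K, f, sig, technique = "MOSSBAUER",
                        protein = protein, constants = constants)
}

#' Assemble flexibility points from an f_LM series
#'
#' Converts recoilless fractions to msd and rmsd via the harmonic relation
#' and returns the pipeline's central per-temperature record.
#'
#' @param temperature_K temperatures (K)
#' @param fLM recoilless fractions in (0, 1]
#' @param fLM_sigma 1-sigma uncertainties on f_LM (0 or NA if unknown)
#' @param technique one of "NRVS", "MOSSBAUER", "NFS", "DIFFRACTION",
#'   "MD_EXTERNAL"
#' @param protein label
#' @param interpolated logical flag per row (default FALSE)
#' @param constants a [NuclearConstants-class] object
#' @return a data.frame with columns temperature_K, protein, technique,
#'   f_LM, f_LM_sigma, msd_A2, rmsd_A, interpolated
#' @export
makeFlexibilityPoints <- function(temperature_K, fLM, fLM_sigma = NA_real_,
                                  technique, protein = NA_character_,
                                  interpolated = FALSE,
                                  constants = nuclearConstants()) {
  technique <- match.arg(technique, c("NRVS", "MOSSBAUER", "NFS",
                                      "DIFFRACTION", "MD_EXTERNAL"))
  msd <- msdFromFlm(fLM, constants)
  data.frame(temperature_K = temperature_K,
             protein = rep_len(protein, length(fLM)),
             technique = technique,
             f_LM = fLM,
             f_LM_sigma = rep_len(fLM_sigma, length(fLM)),
             msd_A2 = msd, rmsd_A = sqrt(msd),
             interpolated = rep_len(interpolated, length(fLM)),
             stringsAsFactors = FALSE)
}
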