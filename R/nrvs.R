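# NRVS: forward generation of the nuclear excitation probability from a model
# PVDOS (one-phonon kernel + multiphonon self-convolutions), and the inverse
# pipeline (elastic-peak removal, Lipkin first-moment normalization,
# Fourier-log deconvolution back to the one-phonon term and PVDOS).
#
# Conventions: energy in meV relative to the resonance, positive = phonon
# creation (Stokes).  "counts" are densities per meV; the mass in a bin is
# counts * dE.

# linear convolution of two mass arrays on the same uniform grid whose zero
# offset sits at index i0; result restricted back to that grid
.convSame <- function(x, y, i0) {
  n <- length(x)
  cv <- convolve(x, rev(y), type = "open")
  cv[i0:(i0 + n - 1)]
}

# convolve mass array (any grid) with a short centered kernel, same length out
.convKernel <- function(x, kern) {
  h <- (length(kern) - 1L) / 2L
  cv <- convolve(x, rev(kern), type = "open")
  cv[(h + 1L):(h + length(x))]
}

.gaussKernel <- function(fwhm, dE) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(5 * sigma / dE))
  x <- (-half:half) * dE
  w <- dnorm(x, 0, sigma)
  w / sum(w)
}

.bose <- function(E_meV, T_K) {
  if (T_K <= 0) return(rep(0, length(E_meV)))
  1 / expm1(E_meV / (.pc$kB_meVK * T_K))
}

# evaluate expr under a local RNG seed without disturbing the global stream
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Forward-generate an NRVS excitation-probability spectrum
#'
#' Builds the harmonic nuclear excitation probability from a one-phonon
#' PVDOS: the Stokes/anti-Stokes one-phonon term
#' \deqn{S_1(E) = \frac{E_R D(|E|)}{3|E|} \times \{n(|E|,T)+1 \ (E>0);\
#'   n(|E|,T) \ (E<0)\},}
#' the multiphonon series \eqn{S = f_{LM}[\delta(E) + \sum_n S_1^{*n}/n!]}
#' with \eqn{f_{LM} = \exp(-\int S_1 dE)} (series truncated when a term's
#' integral drops below 1e-6), and a Gaussian resolution convolution of the
#' stated FWHM.  The noiseless output integrates to 1, satisfies the Lipkin
#' first-moment sum rule \eqn{\int E S(E) dE = E_R}, and (before resolution
#' broadening) obeys detailed balance \eqn{S(-E) = S(E) e^{-E/k_BT}}.
#'
#' @param pvdos a normalized [PVDOS-class] object
#' @param temperature_K sample temperature (K, >= 0)
#' @param resolution_fwhm monochromator resolution FWHM (meV); 0 skips the
#'   resolution convolution
#' @param constants a [NuclearConstants-class] object
#' @param gridRange output energy range c(min, max) in meV; the PVDOS support
#'   must not exceed \code{gridRange[2]} (aliasing guard).  Internally the
#'   grid is padded so the multiphonon series never wraps.
#' @param totalCounts if non-NULL, scale to this many expected counts and
#'   (with \code{seed}) apply Poisson noise
#' @param seed integer seed for the Poisson draw (NULL = no noise)
#' @param protein optional label stored in the metadata
#' @return an [EnergySpectrum-class] object (counts per meV)
#' @export
generateExcitationProbability <- function(pvdos, temperature_K,
                                          resolution_fwhm = 0.8,
                                          constants = nuclearConstants(),
                                          gridRange = c(-30, 90),
                                          totalCounts = NULL, seed = NULL,
                                          protein = NULL) {
  stopifnot(is(pvdos, "PVDOS"))
  if (temperature_K < 0) stop("temperature must be >= 0")
  dE <- mean(diff(pvdos@energy_meV))
  ER <- constants@recoilEnergy_meV
  eMaxD <- max(pvdos@energy_meV[pvdos@density > 0])
  if (eMaxD > gridRange[2] + 1e-9)
    stop("PVDOS support exceeds grid range (would alias in convolution)")
  # index form of the PVDOS (j * dE)
  jD <- as.integer(round(pvdos@energy_meV / dE))
  if (max(abs(pvdos@energy_meV - jD * dE)) > 1e-6 * dE)
    stop("PVDOS grid must be a multiple of its spacing")
  dens <- setNames(pvdos@density, jD)

  imin <- as.integer(round(gridRange[1] / dE))
  imax <- as.integer(round(gridRange[2] / dE))

  # one-phonon masses on a trial grid to size the series
  s1mass <- function(j) {
    E <- j * dE
    D <- ifelse(abs(j) <= max(jD) & abs(j) >= min(jD),
                dens[as.character(abs(j))], 0)
    D[is.na(D)] <- 0
    out <- numeric(length(j))
    pos <- E > 0
    nb <- .bose(abs(E), temperature_K)
    out[pos] <- ER * D[pos] / (3 * E[pos]) * (nb[pos] + 1) * dE
    out[!pos & j != 0] <- ER * D[!pos & j != 0] / (3 * abs(E[!pos & j != 0])) *
      nb[!pos & j != 0] * dE
    # E = 0 bin: finite quasi-elastic limit (E_R/3) D''(0) k_B T with
    # D(E) ~ D'' E^2 near zero, estimated from the first PVDOS point
    if (any(j == 0) && temperature_K > 0) {
      E1 <- min(jD) * dE
      D1 <- unname(dens[as.character(min(jD))])
      out[j == 0] <- ER / 3 * (D1 / E1^2) * .pc$kB_meVK * temperature_K * dE
    }
    out
  }
  jProbe <- seq(-max(jD), max(jD))
  M0 <- sum(s1mass(jProbe))
  nmax <- 1L
  while (nmax < 60L && M0^(nmax + 1) / factorial(nmax + 1) >= 1e-6)
    nmax <- nmax + 1L

  kern <- if (resolution_fwhm > 0) .gaussKernel(resolution_fwhm, dE) else NULL
  halfK <- if (is.null(kern)) 0L else (length(kern) - 1L) / 2L
  K <- max(abs(imin), imax, nmax * max(jD)) + halfK + 2L
  jj <- seq(-K, K)
  i0 <- K + 1L
  S1 <- s1mass(jj)
  fLM <- exp(-sum(S1))

  total <- S1
  term <- S1
  n <- 1L
  while (n < nmax) {
    n <- n + 1L
    term <- .convSame(term, S1, i0) / n
    total <- total + term
    if (sum(term) < 1e-6) break
  }
  p <- fLM * total
  p[i0] <- p[i0] + fLM
  if (!is.null(kern)) p <- .convKernel(p, kern)
  p <- pmax(p, 0)

  sel <- (i0 + imin):(i0 + imax)
  grid <- jj[sel] * dE
  pOut <- p[sel]
  if (is.null(totalCounts)) {
    counts <- pOut / dE
    err <- rep(0, length(counts))
  } else {
    mu <- pOut * totalCounts
    cnt <- if (!is.null(seed)) .withSeed(seed, rpois(length(mu), mu)) else mu
    counts <- cnt / dE
    err <- sqrt(pmax(cnt, 1)) / dE
    err[cnt == 0] <- 1 / dE
  }
  new("EnergySpectrum", energy_meV = grid, counts = counts, countError = err,
      metadata = list(temperature_K = temperature_K, protein = protein,
                      resolution_fwhm_meV = resolution_fwhm))
}

#' Estimate and remove the elastic (recoilless) line
#'
#' Fits a resolution-shaped Gaussian centred at 0 meV (width free within
#' +/-30% of the nominal resolution) plus a constant pedestal over the window
#' |E| <= 2 FWHM, then subtracts the Gaussian component across the whole grid
#' (clipping at zero).  The pedestal absorbs the locally flat one-phonon
#' background and is not subtracted.  With a delta-resolution spectrum
#' (FWHM = 0) the elastic line is the single bin at E = 0 and is excised by
#' local interpolation.
#'
#' @param spec an [EnergySpectrum-class] with \code{resolution_fwhm_meV}
#'   metadata
#' @return a list with elements \code{inelastic} (the subtracted
#'   [EnergySpectrum-class]), \code{elasticArea} (counts, i.e. density *
#'   meV) and \code{fit} (named vector: amplitude, sigma, pedestal)
#' @export
removeElasticPeak <- function(spec) {
  stopifnot(is(spec, "EnergySpectrum"))
  fwhm <- spec@metadata$resolution_fwhm_meV
  if (is.null(fwhm) || is.na(fwhm))
    stop("resolution_fwhm_meV metadata is required")
  E <- spec@energy_meV
  y <- spec@counts
  dE <- mean(diff(E))
  i0 <- which.min(abs(E))

  if (fwhm <= 0) {
    bg <- mean(y[c(i0 - 1, i0 + 1)])
    area <- max(y[i0] - bg, 0) * dE
    y2 <- y
    y2[i0] <- bg
    out <- spec
    out@counts <- y2
    return(list(inelastic = out, elasticArea = area,
                fit = c(amplitude = max(y[i0] - bg, 0), sigma = 0,
                        pedestal = bg)))
  }

  sigma0 <- fwhm / (2 * sqrt(2 * log(2)))
  win <- abs(E) <= 2 * fwhm
  outer <- abs(E) > 2 * fwhm & abs(E) <= 4 * fwhm
  b0 <- if (any(outer)) median(y[outer]) else min(y[win])
  a0 <- max(y[win]) - b0
  # pedestal is linear in E: the one-phonon term under the peak is locally
  # a + bE (quasi-elastic Bose tail), and a flat pedestal biases f_LM high
  obj <- function(p) {
    a <- p[1]; s <- p[2]; b <- p[3]; cc <- p[4]
    sum((y[win] - (a * exp(-E[win]^2 / (2 * s^2)) + b + cc * E[win]))^2)
  }
  fit <- optim(c(max(a0, 0), sigma0, max(b0, 0), 0), obj,
               method = "L-BFGS-B",
               lower = c(0, 0.7 * sigma0, 0, -Inf),
               upper = c(Inf, 1.3 * sigma0, Inf, Inf))
  a <- fit$par[1]; s <- fit$par[2]; b <- fit$par[3]
  if (a <= 0 || a * s * sqrt(2 * pi) < 1e-12 * sum(y) * dE) {
    warning("no identifiable elastic peak at 0 meV; elastic area set to 0")
    return(list(inelastic = spec, elasticArea = 0,
                fit = c(amplitude = 0, sigma = s, pedestal = b)))
  }
  y2 <- pmax(y - a * exp(-E^2 / (2 * s^2)), 0)
  out <- spec
  out@counts <- y2
  list(inelastic = out, elasticArea = a * s * sqrt(2 * pi),
       fit = c(amplitude = a, sigma = s, pedestal = b))
}

#' Estimate the sample temperature from detailed balance
#'
#' Weighted straight-line fit (through the origin) of
#' \eqn{\ln[S(E)/S(-E)] = E / k_B T} over \eqn{|E|} between the resolution
#' FWHM and \code{eMax_meV}.  Requires usable intensity on both energy signs;
#' a symmetric spectrum (infinite apparent temperature) and insufficient
#' anti-Stokes statistics both raise errors.
#'
#' @param spec an [EnergySpectrum-class] object
#' @param eMax_meV upper end of the fit range (meV)
#' @param minAntiStokesCounts minimum integrated anti-Stokes counts for a
#'   counted (noisy) spectrum
#' @return estimated temperature (K)
#' @export
estimateTemperature <- function(spec, eMax_meV = 40,
                                minAntiStokesCounts = 100) {
  stopifnot(is(spec, "EnergySpectrum"))
  E <- spec@energy_meV
  y <- spec@counts
  err <- spec@countError
  dE <- mean(diff(E))
  fwhm <- spec@metadata$resolution_fwhm_meV
  if (is.null(fwhm) || is.na(fwhm)) fwhm <- 0
  eMin <- max(fwhm, dE)

  anti <- E < -eMin & E >= -eMax_meV
  if (any(err > 0)) {
    if (sum(y[anti] * dE) < minAntiStokesCounts)
      stop("temperature indeterminate: insufficient anti-Stokes counts")
  } else if (sum(y[anti]) * dE < 1e-12)
    stop("temperature indeterminate: no anti-Stokes intensity")

  i0 <- which.min(abs(E))
  jmax <- min(i0 - 1, length(E) - i0, floor(eMax_meV / dE))
  j <- seq(ceiling(eMin / dE), jmax)
  Sp <- y[i0 + j]; Sm <- y[i0 - j]
  ep <- err[i0 + j]; em <- err[i0 - j]
  ok <- Sp > 0 & Sm > 0
  if (sum(ok) < 2) stop("temperature indeterminate: too few usable pairs")
  x <- (j * dE)[ok]
  yy <- log(Sp[ok] / Sm[ok])
  w <- if (any(err > 0)) {
    v <- (ep[ok] / Sp[ok])^2 + (em[ok] / Sm[ok])^2
    1 / pmax(v, 1e-12)
  } else rep(1, length(x))
  slope <- sum(w * x * yy) / sum(w * x^2)
  if (!is.finite(slope) || slope <= 0)
    stop("temperature indeterminate: spectrum symmetric within noise")
  T <- 1 / (.pc$kB_meVK * slope)
  if (T > 1e4) stop("temperature indeterminate: apparent T > 1e4 K")
  T
}

#' Normalize an inelastic NRVS spectrum and extract PVDOS, f_LM and msd
#'
#' Implements the moment-normalization + Fourier-log pipeline.  The inelastic
#' spectrum (elastic line already removed) is scaled so its first moment
#' equals the recoil energy (Lipkin sum rule; the elastic line carries no
#' first moment, so the scale is independent of \eqn{f_{LM}}).  Then
#' \eqn{f_{LM} = 1 - \int S_{inel} dE}; the full spectrum including the
#' \eqn{f_{LM}\delta(E)} term is Fourier transformed, the complex logarithm
#' taken, \eqn{\ln f_{LM}} subtracted and (optionally) the resolution
#' response divided out, and the inverse transform yields the one-phonon term
#' \eqn{S_1}, which the one-phonon kernel inverts to the PVDOS.  Finally
#' \deqn{\langle u^2 \rangle = \frac{\hbar^2}{6 m}\int
#'   \frac{D(E)}{E}\coth\frac{E}{2 k_B T}\,dE.}
#'
#' @param inelastic an [EnergySpectrum-class] with the elastic line removed
#' @param temperature_K sample temperature used for the Bose factors (K)
#' @param constants a [NuclearConstants-class] object
#' @param elasticArea optional elastic area (same count units as
#'   \code{inelastic}) from [removeElasticPeak()]; enables the elastic/total
#'   estimate of \eqn{f_{LM}}
#' @param deconvolveResolution divide out the Gaussian resolution response
#'   recorded in the metadata (default TRUE)
#' @param pvdosMax_meV truncate the recovered PVDOS above this energy
#'   (default: the positive end of the grid)
#' @return an [NRVSResult-class] object
#' @export
normalizeAndExtract <- function(inelastic, temperature_K,
                                constants = nuclearConstants(),
                                elasticArea = NULL,
                                deconvolveResolution = TRUE,
                                pvdosMax_meV = NULL) {
  stopifnot(is(inelastic, "EnergySpectrum"))
  E <- inelastic@energy_meV
  dE <- mean(diff(E))
  N <- length(E)
  i0 <- which.min(abs(E))
  ER <- constants@recoilEnergy_meV
  s <- inelastic@counts * dE              # masses

  M1raw <- sum(E * s)
  if (!is.finite(M1raw) || M1raw <= 0)
    stop("normalization failed: non-positive first moment")
  scale <- ER / M1raw
  s <- s * scale
  inelInt <- sum(s)
  fLM <- 1 - inelInt
  if (fLM <= 0)
    stop("normalization failed: inelastic area >= 1 after normalization")

  fE <- NA_real_
  if (!is.null(elasticArea) && is.finite(elasticArea) && elasticArea > 0)
    fE <- elasticArea / (elasticArea + sum(inelastic@counts) * dE)

  # Fourier-log deconvolution
  ord <- c(i0:N, seq_len(i0 - 1))
  FT <- fft(s[ord])              # inelastic part only
  fwhm <- inelastic@metadata$resolution_fwhm_meV
  if (isTRUE(deconvolveResolution) && !is.null(fwhm) && !is.na(fwhm) &&
      fwhm > 0) {
    # the elastic delta was subtracted before this point, so only the
    # inelastic part carries the resolution response
    kern <- .gaussKernel(fwhm, dE)
    h <- (length(kern) - 1L) / 2L
    kfull <- numeric(N)
    kfull[i0 + (-h:h)] <- kern
    G <- Re(fft(kfull[ord]))
    FT <- FT / pmax(G, 1e-8)
  }
  L <- log(fLM + FT) - log(fLM)
  s1 <- Re(fft(L, inverse = TRUE)) / N
  s1full <- numeric(N)
  s1full[ord] <- s1

  if (is.null(pvdosMax_meV)) pvdosMax_meV <- max(E)
  pos <- E > dE / 2 & E <= pvdosMax_meV
  Ep <- E[pos]
  nb <- .bose(Ep, temperature_K)
  Dp <- 3 * Ep * (s1full[pos] / dE) / (ER * (nb + 1))
  Dp <- pmax(Dp, 0)
  if (sum(Dp) * dE <= 0) stop("normalization failed: empty PVDOS")
  pv <- makePVDOS(Ep, Dp)

  coth <- 1 + 2 * .bose(pv@energy_meV, temperature_K)
  m_kg <- constants@fe57Mass_u * .pc$u_kg
  integ <- sum(pv@density * coth / pv@energy_meV) * dE   # 1/meV
  msd <- .pc$hbar_Js^2 / (6 * m_kg) * integ / (.pc$eV_J * 1e-3) * 1e20

  new("NRVSResult", fLM = fLM, fLMElastic = fE, msd_A2 = msd,
      detailedBalanceT_K = NA_real_, pvdos = pv,
      firstMoment_meV = sum(E * s))
}

#' One-call NRVS processing: elastic removal, normalization, extraction
#'
#' Convenience wrapper chaining [removeElasticPeak()], (optionally)
#' [estimateTemperature()] and [normalizeAndExtract()].  A rough 1-sigma
#' uncertainty on \eqn{f_{LM}} is propagated from the per-point counting
#' errors through the inelastic integral and the first-moment scale.
#'
#' @param spec a raw [EnergySpectrum-class]
#' @param constants a [NuclearConstants-class] object
#' @param temperature_K sample temperature; default from metadata
#' @param ... passed to [normalizeAndExtract()]
#' @return list with \code{result} ([NRVSResult-class]), \code{fLM_sigma},
#'   \code{elasticArea}, \code{detailedBalanceT_K} (NA when not estimable)
#' @export
processNrvs <- function(spec, constants = nuclearConstants(),
                        temperature_K = NULL, ...) {
  if (is.null(temperature_K)) temperature_K <- temperatureK(spec)
  if (is.na(temperature_K)) stop("temperature_K required (metadata empty)")
  rem <- removeElasticPeak(spec)
  Tdb <- tryCatch(estimateTemperature(spec), error = function(e) NA_real_)
  res <- normalizeAndExtract(rem$inelastic, temperature_K, constants,
                             elasticArea = rem$elasticArea, ...)
  res@detailedBalanceT_K <- Tdb
  # crude Poisson propagation of sigma(fLM)
  dE <- mean(diff(spec@energy_meV))
  err <- rem$inelastic@countError * dE
  M1 <- sum(spec@energy_meV * rem$inelastic@counts * dE)
  sig <- NA_real_
  if (any(err > 0) && M1 > 0) {
    scale <- constants@recoilEnergy_meV / M1
    sInt <- scale * sqrt(sum(err^2))
    sM1 <- sqrt(sum((spec@energy_meV * err)^2))
    inelInt <- 1 - res@fLM
    sig <- sqrt(sInt^2 + (inelInt * sM1 / M1)^2)
  }
  list(result = res, fLM_sigma = sig, elasticArea = rem$elasticArea,
       detailedBalanceT_K = Tdb)
}
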