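# Nuclear forward scattering: the quantum-beat / dynamical-beat time-spectrum
# model, Poisson-deviance fitting, the beat-period <-> quadrupole-splitting
# conversion, and f_LM extraction from count-rate temperature series.

.hbar_neVns <- function() .pc$hbar_eVs * 1e18  # 658.212 neV ns

#' Time-dependent forward-scattered intensity of a quadrupole doublet
#'
#' Transmitted delayed intensity for an effective resonant thickness
#' \eqn{\chi} and quantum-beat angular frequency \eqn{\Delta\omega}:
#' \deqn{I(t) = A\, e^{-\tau}\, \frac{\chi}{\tau}\,
#'   J_1^2\!\left(\sqrt{0.5\,\chi\tau}\right)
#'   \cos^2\!\left(\frac{\Delta\omega}{2} t +
#'   \frac{\chi \Gamma_0}{8\,\Delta E}\right),}
#' with \eqn{\tau = t/\tau_0}, \eqn{J_1} the order-1 Bessel function of the
#' first kind and \eqn{\Delta E = \hbar\Delta\omega} the splitting in energy
#' units.  The Bessel factor encodes the thickness (dynamical) beats; the
#' \eqn{t \to 0^+} limit is finite (\eqn{\chi/\tau \cdot J_1^2 \to \chi^2/8})
#' and in the thin limit \eqn{I \propto \chi^2}.  For \eqn{\Delta\omega = 0}
#' there is no splitting and the phase term is dropped.
#'
#' @param t_ns time after the excitation pulse (ns, > 0); vectorized
#' @param chi effective thickness (> 0)
#' @param deltaOmega beat angular frequency (rad/ns, >= 0)
#' @param amplitude intensity scale
#' @param tOffset_ns time-zero offset (ns)
#' @param constants a [NuclearConstants-class] object
#' @return intensity (arbitrary units)
#' @export
nfsIntensity <- function(t_ns, chi, deltaOmega, amplitude = 1,
                         tOffset_ns = 0, constants = nuclearConstants()) {
  if (chi <= 0) stop("chi must be > 0")
  if (deltaOmega < 0) stop("deltaOmega must be >= 0")
  tau <- pmax((t_ns - tOffset_ns) / constants@meanLifetime_ns, 0)
  x2 <- 0.5 * chi * tau
  # chi/tau * J1(sqrt(x2))^2, with the tau -> 0 series limit chi^2/8
  env <- (chi / pmax(tau, 1e-300)) * besselJ(sqrt(x2), 1)^2
  small <- x2 < 1e-8
  if (any(small)) env[small] <- chi^2 / 8 * (1 - x2[small] / 4)
  phase <- if (deltaOmega > 0) {
    dE_neV <- .hbar_neVns() * deltaOmega
    deltaOmega / 2 * (t_ns - tOffset_ns) +
      chi * constants@naturalLinewidth_neV / (8 * dE_neV)
  } else 0
  amplitude * exp(-tau) * env * cos(phase)^2
}

#' Quantum-beat period to quadrupole splitting (and back)
#'
#' The two scattered frequencies of a quadrupole doublet beat with period
#' \eqn{T_{qb} = 2\pi/\Delta\omega}.  Expressed in Doppler units the
#' conversion constant is \eqn{h / (E_0/c \cdot 1\,\mathrm{mm/s})}, which
#' evaluates to 86.0 ns, so \eqn{\Delta E_Q[\mathrm{mm/s}] = 86\,\mathrm{ns}
#' / T_{qb}}.
#'
#' @param Tqb_ns beat period (ns, > 0); vectorized
#' @param deltaEQ quadrupole splitting (mm/s, > 0); vectorized
#' @param constants a [NuclearConstants-class] object
#' @return splitting in mm/s, or beat period in ns
#' @examples
#' beatPeriodToDeltaEQ(86)    # 1 mm/s
#' beatPeriodToDeltaEQ(26.3)  # ~3.27 mm/s
#' @export
beatPeriodToDeltaEQ <- function(Tqb_ns, constants = nuclearConstants()) {
  if (any(Tqb_ns <= 0)) stop("beat period must be > 0")
  nfsBeatConstant(constants) / Tqb_ns
}

#' @rdname beatPeriodToDeltaEQ
#' @export
deltaEQToBeatPeriod <- function(deltaEQ, constants = nuclearConstants()) {
  if (any(deltaEQ <= 0)) stop("splitting must be > 0")
  nfsBeatConstant(constants) / deltaEQ
}

#' @rdname beatPeriodToDeltaEQ
#' @export
nfsBeatConstant <- function(constants = nuclearConstants()) {
  2 * pi * .hbar_neVns() / constants@dopplerPerMmS_neV
}

.deltaOmegaToEQ <- function(dOmega, constants)
  .hbar_neVns() * dOmega / constants@dopplerPerMmS_neV
.eqToDeltaOmega <- function(dEQ, constants)
  dEQ * constants@dopplerPerMmS_neV / .hbar_neVns()

#' Simulate an NFS time spectrum
#'
#' Integrates [nfsIntensity()] over uniform detector bins (midpoint rule at
#' 10x oversampling), scales so the expected counts inside the analysis
#' window equal \code{totalCounts}, and optionally applies Poisson noise.
#'
#' @param chi effective thickness
#' @param deltaEQ quadrupole splitting (mm/s); converted internally to the
#'   beat frequency
#' @param totalCounts expected counts in the window
#' @param binWidth_ns detector bin width (ns, default 0.4675)
#' @param window analysis window (ns, default c(18, 600))
#' @param bunchPeriod_ns synchrotron bunch period (ns, default 684.3)
#' @param tOffset_ns time-zero offset (ns)
#' @param seed integer seed for Poisson noise (NULL = noiseless)
#' @param temperature_K,protein metadata labels
#' @param constants a [NuclearConstants-class] object
#' @return a [TimeSpectrum-class] object
#' @export
simulateNfsSpectrum <- function(chi, deltaEQ, totalCounts = 1e6,
                                binWidth_ns = 0.4675, window = c(18, 600),
                                bunchPeriod_ns = 684.3, tOffset_ns = 0,
                                seed = NULL, temperature_K = NA_real_,
                                protein = NULL,
                                constants = nuclearConstants()) {
  dOmega <- .eqToDeltaOmega(deltaEQ, constants)
  nb <- floor((bunchPeriod_ns - binWidth_ns / 2) / binWidth_ns)
  centres <- (seq_len(nb) - 0.5) * binWidth_ns
  mu <- .binnedNfsModel(centres, binWidth_ns, chi, dOmega, tOffset_ns,
                        constants)
  inWin <- centres >= window[1] & centres <= window[2]
  mu <- mu * totalCounts / sum(mu[inWin])
  cnt <- if (!is.null(seed)) .withSeed(seed, rpois(length(mu), mu)) else mu
  new("TimeSpectrum", time_ns = centres, counts = cnt, window = window,
      bunchPeriod_ns = bunchPeriod_ns,
      metadata = list(temperature_K = temperature_K, protein = protein))
}

# model intensity integrated over bins: midpoint rule at 10x oversampling,
# fully vectorized (one nfsIntensity call over all sub-samples)
.binnedNfsModel <- function(centres, bw, chi, dOmega, tOffset_ns, constants) {
  over <- 10L
  sub <- ((seq_len(over) - 0.5) / over - 0.5) * bw
  tt <- rep(centres, each = over) + rep(sub, times = length(centres))
  I <- nfsIntensity(tt, chi, dOmega, 1, tOffset_ns, constants)
  colMeans(matrix(I, nrow = over))
}

.nfsDeviance <- function(n, mu) {
  mu <- pmax(mu, 1e-12)
  2 * sum(mu - n + ifelse(n > 0, n * log(n / mu), 0))
}

#' Fit the beat model to an NFS time spectrum
#'
#' Minimizes the Poisson deviance of the [nfsIntensity()] model (amplitude,
#' chi, deltaOmega; time offset fixed unless freed) over the analysis
#' window.  To avoid beat-aliasing local minima the optimisation is
#' multi-started from 5 deterministic initial beat frequencies
#' (\code{init} times 0.5, 0.75, 1, 1.5, 2, clipped to the bounds); the
#' lowest-deviance solution wins.  Uncertainties come from the inverse
#' Hessian of half the deviance at the optimum.
#'
#' @param spec a [TimeSpectrum-class] object
#' @param initDeltaOmega starting beat frequency (rad/ns); default from the
#'   periodogram of the windowed counts
#' @param initChi starting effective thickness
#' @param nStarts number of deterministic multi-start frequencies (1 or 5)
#' @param bounds list with elements \code{chi} (c(lo, hi), default (0, 50])
#'   and \code{deltaOmega} (default [0.01, 2] rad/ns)
#' @param constants a [NuclearConstants-class] object
#' @return an [NFSFit-class] object
#' @export
fitNfs <- function(spec, initDeltaOmega = NULL, initChi = 2, nStarts = 5,
                   bounds = list(chi = c(1e-3, 50), deltaOmega = c(0.01, 2)),
                   constants = nuclearConstants()) {
  stopifnot(is(spec, "TimeSpectrum"))
  t <- spec@time_ns
  inWin <- t >= spec@window[1] & t <= spec@window[2]
  n <- spec@counts[inWin]
  tw <- t[inWin]
  if (sum(n) < 1e3)
    stop("insufficient statistics: fewer than 1000 counts in the window")
  bw <- mean(diff(t))
  modelMu <- function(logA, logChi, dOmega)
    exp(logA) * .binnedNfsModel(tw, bw, exp(logChi), dOmega, 0, constants)
  obj <- function(p) .nfsDeviance(n, modelMu(p[1], p[2], p[3]))
  # amplitude profiled out analytically (Poisson ML: A = sum(n)/sum(mu))
  sumN <- sum(n)
  obj2 <- function(p2) {
    m <- .binnedNfsModel(tw, bw, exp(p2[1]), p2[2], 0, constants)
    .nfsDeviance(n, m * (sumN / sum(m)))
  }

  if (is.null(initDeltaOmega)) {
    # dominant beat frequency from the periodogram of the envelope-corrected
    # counts; beats appear at deltaOmega (cos^2 doubles the frequency)
    y <- n / pmax(exp(-tw / constants@meanLifetime_ns), 1e-12)
    y <- y - mean(y)
    np <- nextn(length(y))
    sp <- Mod(fft(c(y, rep(0, np - length(y)))))^2
    freq <- 2 * pi * (seq_len(np) - 1) / (np * bw)
    keep <- freq > 0.02 & freq < 4
    initDeltaOmega <- freq[keep][which.max(sp[keep])]
  }
  starts <- if (nStarts >= 5) c(1, 0.5, 0.75, 1.5, 2) else 1
  starts <- unique(pmin(pmax(initDeltaOmega * starts,
                             bounds$deltaOmega[1]), bounds$deltaOmega[2]))

  lo <- c(log(bounds$chi[1]), bounds$deltaOmega[1])
  hi <- c(log(bounds$chi[2]), bounds$deltaOmega[2])
  best <- NULL
  for (s in starts) {  # coarse multi-start, then one fine polish below
    f <- tryCatch(
      optim(c(log(initChi), s), obj2, method = "L-BFGS-B",
            lower = lo, upper = hi,
            control = list(factr = 1e10, maxit = 40)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  if (is.null(best)) stop("NFS fit failed to converge from all starts")
  best <- optim(best$par, obj2, method = "L-BFGS-B", lower = lo, upper = hi,
                control = list(factr = 1e5, maxit = 500))
  m <- .binnedNfsModel(tw, bw, exp(best$par[1]), best$par[2], 0, constants)
  p <- c(log(sumN / sum(m)), best$par)

  # covariance = inverse Hessian of deviance/2, central second differences
  H <- matrix(0, 3, 3)
  eps <- c(1e-4, 1e-4, 1e-5)
  for (i in 1:3) for (j in i:3) {
    pp <- function(si, sj) {
      q <- p; q[i] <- q[i] + si * eps[i]; q[j] <- q[j] + sj * eps[j]
      obj(q) / 2
    }
    H[i, j] <- H[j, i] <- if (i == j)
      (pp(1, 0) - 2 * best$value / 2 + pp(-1, 0)) / eps[i]^2
    else (pp(1, 1) - pp(1, -1) - pp(-1, 1) + pp(-1, -1)) /
      (4 * eps[i] * eps[j])
  }
  cov <- tryCatch(solve((H + t(H)) / 2), error = function(e)
    matrix(NA_real_, 3, 3))
  seP <- sqrt(pmax(diag(cov), 0))
  chi <- exp(p[2])
  dOmega <- p[3]
  dEQ <- .deltaOmegaToEQ(dOmega, constants)
  se <- c(amplitude = exp(p[1]) * seP[1], chi = chi * seP[2],
          deltaOmega_rad_ns = seP[3],
          deltaEQ_mm_s = .deltaOmegaToEQ(seP[3], constants))
  new("NFSFit", chi = chi, deltaOmega_rad_ns = dOmega, deltaEQ_mm_s = dEQ,
      amplitude = exp(p[1]), tOffset_ns = 0, stderr = se,
      deviance = best$value)
}

#' f_LM series from NFS count rates
#'
#' For concentrated ("thick", chi >> 1) samples the delayed count rate
#' integrated over the analysis window is approximately proportional to
#' \eqn{f_{LM}}; for thin samples (chi <= 1) it is proportional to
#' \eqn{\chi^2} and hence to \eqn{f_{LM}^2}.  The series is anchored the
#' same way as the Moessbauer areas.  Poisson errors on the integrated
#' counts are propagated.
#'
#' @param temperature_K temperatures (K)
#' @param counts integrated delayed counts in the window per temperature
#' @param regime "thick" or "thin"; if NULL it is inferred from
#'   \code{chiAnchor} (> 3 thick, < 0.5 thin, otherwise an error)
#' @param anchorFlm,anchorT anchor as in [flmSeriesFromAreas()]
#' @param chiAnchor effective thickness at the anchor temperature (used only
#'   to infer the regime)
#' @param protein label for the output rows
#' @param constants a [NuclearConstants-class] object
#' @return a data.frame of flexibility points (see [makeFlexibilityPoints()])
#' @export
flmFromCountRates <- function(temperature_K, counts, regime = NULL,
                              anchorFlm = 0.82, anchorT = 4.2,
                              chiAnchor = NULL, protein = NA_character_,
                              constants = nuclearConstants()) {
  if (is.null(regime)) {
    if (is.null(chiAnchor))
      stop("regime ambiguous: give regime or chiAnchor")
    regime <- if (chiAnchor > 3) "thick" else if (chiAnchor < 0.5) "thin"
      else stop("regime ambiguous: 0.5 < chi < 3; specify regime explicitly")
  }
  regime <- match.arg(regime, c("thick", "thin"))
  ia <- which(abs(temperature_K - anchorT) <= 1)
  if (!length(ia))
    stop("missing anchor temperature: no point within 1 K of ", anchorT)
  ia <- ia[which.min(abs(temperature_K[ia] - anchorT))]
  ratio <- counts / counts[ia]
  relv <- 1 / counts + 1 / counts[ia]
  relv[ia] <- 1 / counts[ia]
  if (regime == "thick") {
    f <- ratio * anchorFlm
    sig <- f * sqrt(relv)
  } else {
    f <- sqrt(ratio) * anchorFlm
    sig <- f * sqrt(relv) / 2
  }
  makeFlexibilityPoints(temperature_K, pmin(f, 1), sig, technique = "NFS",
                        protein = protein, constants = constants)
}
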