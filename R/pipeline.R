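# Cross-technique flexibility table, the two-protein comparison report, and
# the consensus RMSD summary.

.ffCols <- c("temperature_K", "protein", "technique", "f_LM", "f_LM_sigma",
             "msd_A2", "rmsd_A", "interpolated")

#' Build the cross-technique flexibility table
#'
#' Merges per-technique flexibility series (data.frames from
#' [makeFlexibilityPoints()] and friends) into one table keyed by (protein,
#' temperature, technique); optionally adds rows linearly interpolated in T
#' (on msd, not f_LM), flagged in the \code{interpolated} column.
#' Conflicting duplicate keys raise an error listing the offenders.
#'
#' @param ... flexibility data.frames (or one list of them)
#' @param interpolateAt optional temperatures (K) at which every
#'   (protein, technique) series is augmented by linear interpolation
#' @param constants a [NuclearConstants-class] object
#' @return a data.frame with the standard flexibility columns
#' @export
buildFlexibilityTable <- function(..., interpolateAt = NULL,
                                  constants = nuclearConstants()) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !is.data.frame(parts[[1]])) parts <- parts[[1]]
  parts <- Filter(Negate(is.null), parts)
  if (!length(parts)) stop("no technique series supplied")
  tab <- do.call(rbind, lapply(parts, function(d) d[, .ffCols]))
  key <- paste(tab$protein, tab$temperature_K, tab$technique)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    bad <- dup[vapply(dup, function(k) {
      r <- tab[key == k, ]
      any(abs(r$f_LM - r$f_LM[1]) > 1e-9)
    }, logical(1))]
    if (length(bad))
      stop("conflicting duplicate rows for: ", paste(bad, collapse = "; "))
    tab <- tab[!duplicated(key), ]
  }
  if (!is.null(interpolateAt)) {
    add <- list()
    for (p in unique(tab$protein)) for (tech in unique(tab$technique)) {
      s <- tab[tab$protein == p & tab$technique == tech, ]
      if (nrow(s) < 2) next
      want <- setdiff(interpolateAt, s$temperature_K)
      want <- want[want >= min(s$temperature_K) &
                   want <= max(s$temperature_K)]
      if (!length(want)) next
      m <- approx(s$temperature_K, s$msd_A2, xout = want)$y
      sg <- if (sum(!is.na(s$f_LM_sigma)) >= 2)
        approx(s$temperature_K, s$f_LM_sigma, xout = want)$y
      else rep(NA_real_, length(want))
      add[[length(add) + 1]] <-
        makeFlexibilityPoints(want, flmFromMsd(m, constants), sg, tech, p,
                              interpolated = TRUE, constants = constants)
    }
    if (length(add)) tab <- rbind(tab, do.call(rbind, add))
  }
  tab <- tab[order(tab$protein, tab$technique, tab$temperature_K), ]
  rownames(tab) <- NULL
  tab
}

#' Compare the Fe-site flexibility of two proteins
#'
#' Per (temperature, technique) z-score of the msd difference,
#' \eqn{z = \Delta\langle u^2\rangle / \sigma_\Delta}.  The denominator
#' combines the statistical uncertainties propagated from the two f_LM
#' errors with a cross-technique systematic term: the half-range of msd
#' across techniques at that temperature within each protein, floored at
#' \code{sysFloorFrac} of the mean msd.  Counting statistics alone
#' understate the reproducibility of recoilless-fraction measurements
#' (elastic-peak estimation, thickness and normalization systematics), and
#' with dozens of comparisons the max of purely statistical z-scores would
#' routinely exceed 2 even for identical proteins.  The verdict is
#' "equivalent" iff \eqn{\max|z| < z_{crit}}.  The report also carries a
#' fitted Debye temperature per protein and technique.
#'
#' @param table a flexibility table from [buildFlexibilityTable()]
#' @param proteinA,proteinB labels present in the table
#' @param zCrit verdict threshold (default 2)
#' @param sysFloorFrac systematic floor as a fraction of msd (default 0.05,
#'   the low end of the published cross-technique dispersion)
#' @param minCommon minimum common temperatures per technique (default 3)
#' @param constants a [NuclearConstants-class] object
#' @return a list of class "comparisonReport": \code{rows} (per-point
#'   data.frame with z), \code{verdict}, \code{maxAbsZ}, \code{zCrit},
#'   \code{thetaD} (per protein x technique fits)
#' @export
compareProteins <- function(table, proteinA, proteinB, zCrit = 2,
                            sysFloorFrac = 0.05, minCommon = 3,
                            constants = nuclearConstants()) {
  A <- table[table$protein == proteinA, ]
  B <- table[table$protein == proteinB, ]
  if (!nrow(A) || !nrow(B)) stop("protein label(s) not found in table")
  k2 <- constants@wavenumber_invA^2

  rows <- list()
  for (tech in intersect(unique(A$technique), unique(B$technique))) {
    a <- A[A$technique == tech, ]
    b <- B[B$technique == tech, ]
    common <- intersect(a$temperature_K, b$temperature_K)
    if (length(common) < minCommon) next
    for (T in sort(common)) {
      ra <- a[a$temperature_K == T, ][1, ]
      rb <- b[b$temperature_K == T, ][1, ]
      sA <- .msdSigma(ra, k2)
      sB <- .msdSigma(rb, k2)
      sysA <- .techSpread(A, T)
      sysB <- .techSpread(B, T)
      sys <- max(sysA, sysB,
                 sysFloorFrac * mean(c(ra$msd_A2, rb$msd_A2)))
      d <- ra$msd_A2 - rb$msd_A2
      rows[[length(rows) + 1]] <- data.frame(
        temperature_K = T, technique = tech, dmsd_A2 = d,
        sigma_stat_A2 = sqrt(sA^2 + sB^2), sigma_sys_A2 = sys,
        z = d / sqrt(sA^2 + sB^2 + sys^2))
    }
  }
  if (!length(rows))
    stop("insufficient overlap: fewer than ", minCommon,
         " common temperatures in every technique")
  rows <- do.call(rbind, rows)

  thetaD <- do.call(rbind, lapply(c(proteinA, proteinB), function(p) {
    s <- table[table$protein == p, ]
    do.call(rbind, lapply(unique(s$technique), function(tech) {
      ss <- s[s$technique == tech & s$temperature_K > 0, ]
      fit <- tryCatch(fitDebyeTemperature(ss$temperature_K, ss$msd_A2),
                      error = function(e) NULL)
      data.frame(protein = p, technique = tech,
                 thetaD_K = if (is.null(fit)) NA_real_ else fit@thetaD_K,
                 thetaD_se_K = if (is.null(fit)) NA_real_ else fit@stderr_K)
    }))
  }))

  maxZ <- max(abs(rows$z))
  structure(list(proteinA = proteinA, proteinB = proteinB, rows = rows,
                 maxAbsZ = maxZ, zCrit = zCrit,
                 verdict = if (maxZ < zCrit) "equivalent" else "different",
                 thetaD = thetaD),
            class = "comparisonReport")
}

.msdSigma <- function(row, k2) {
  s <- row$f_LM_sigma
  if (is.na(s) || s <= 0) return(0)
  s / (row$f_LM * k2)
}

# half-range of msd across techniques at temperature T within one protein
.techSpread <- function(sub, T) {
  m <- sub$msd_A2[sub$temperature_K == T]
  if (length(m) < 2) return(0)
  (max(m) - min(m)) / 2
}

#' @export
print.comparisonReport <- function(x, ...) {
  cat(sprintf("Fe-site flexibility comparison: %s vs %s\n", x$proteinA,
              x$proteinB))
  cat(sprintf("  %d comparisons, max |z| = %.2f (z_crit = %g)\n",
              nrow(x$rows), x$maxAbsZ, x$zCrit))
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' @param report a comparisonReport from [compareProteins()]
#' @param path output file; if NULL the JSON string is returned
#' @return JSON string, invisibly when written
#' @export
reportToJSON <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Consensus RMS displacement across techniques
#'
#' Arithmetic mean and half-range of the selected techniques' rmsd at one
#' temperature (the "0.16 +/- 0.01 A" style of cross-technique summary).
#'
#' @param table a flexibility table
#' @param temperature_K temperature (K)
#' @param techniques techniques to include (>= 2 must be present)
#' @param protein optional protein filter
#' @return list(mean_rmsd_A, half_range_A, n)
#' @export
consensusRmsd <- function(table, temperature_K,
                          techniques = c("NRVS", "MOSSBAUER", "MD_EXTERNAL"),
                          protein = NULL) {
  s <- table[table$temperature_K == temperature_K &
             table$technique %in% techniques, ]
  if (!is.null(protein)) s <- s[s$protein == protein, ]
  if (nrow(s) < 2)
    stop("need at least 2 techniques at T = ", temperature_K, " K")
  r <- s$rmsd_A
  list(mean_rmsd_A = mean(r), half_range_A = (max(r) - min(r)) / 2,
       n = length(r))
}

#' Ingest external (diffraction / molecular-dynamics) RMSD values
#'
#' Diffraction and MD columns are display-only context: they are read as
#' numbers from a CSV with columns temperature_K, rmsd_A (or bfactor_A2 for
#' diffraction, converted via [rmsdFromBfactor()]) and never computed here.
#'
#' @param path CSV file
#' @param technique "DIFFRACTION" or "MD_EXTERNAL"
#' @param protein label
#' @param constants a [NuclearConstants-class] object
#' @return a flexibility data.frame
#' @export
readExternalRmsd <- function(path, technique = c("MD_EXTERNAL",
                                                 "DIFFRACTION"),
                             protein = NA_character_,
                             constants = nuclearConstants()) {
  technique <- match.arg(technique)
  d <- read.csv(path)
  rmsd <- if ("rmsd_A" %in% names(d)) d$rmsd_A else
    rmsdFromBfactor(d$bfactor_A2)
  makeFlexibilityPoints(d$temperature_K, flmFromMsd(rmsd^2, constants),
                        NA_real_, technique, protein, constants = constants)
}

#' Write / read a flexibility table as CSV
#'
#' Plain CSV with the standard columns; numbers are printed with 15
#' significant digits so write -> read -> write is idempotent.
#'
#' @param table a flexibility table
#' @param path CSV file
#' @return \code{path} (write) or the table (read)
#' @export
writeFlexibilityTable <- function(table, path) {
  out <- table
  for (k in c("temperature_K", "f_LM", "f_LM_sigma", "msd_A2", "rmsd_A"))
    out[[k]] <- formatC(table[[k]], digits = 15, format = "g")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFlexibilityTable
#' @export
readFlexibilityTable <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$interpolated <- as.logical(d$interpolated)
  d[, .ffCols]
}
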