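# Plain-text TSV serialization of the spectrum containers.  Format: comment
# header lines "# key: value" followed by a tab-separated column block.

.writeTSV <- function(path, header, df) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header))
    if (!is.null(header[[k]]) && !all(is.na(header[[k]])))
      writeLines(sprintf("# %s: %s", k,
                         paste(format(header[[k]], trim = TRUE),
                               collapse = " ")), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  write.table(format(df, trim = TRUE, digits = 12, scientific = NA),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.readTSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  keys <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) keys[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  df <- read.table(text = paste(body, collapse = "\n"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  list(keys = keys, data = df)
}

.numKey <- function(keys, name) {
  if (is.null(keys[[name]])) return(NA_real_)
  as.numeric(strsplit(keys[[name]], "\\s+")[[1]])
}

#' Write a spectrum or PVDOS to a TSV file
#'
#' Writes comment header lines (\code{# key: value}; technique,
#' temperature_K, protein and technique-specific keys) followed by the data
#' columns.  [readSpectrumTSV()] restores the object; a write-read-write
#' round trip is byte-identical.
#'
#' @param object an [EnergySpectrum-class], [VelocitySpectrum-class],
#'   [TimeSpectrum-class] or [PVDOS-class] object
#' @param path output file
#' @return \code{path}, invisibly
#' @export
setGeneric("writeSpectrumTSV",
           function(object, path) standardGeneric("writeSpectrumTSV"))

#' @rdname writeSpectrumTSV
#' @export
setMethod("writeSpectrumTSV", "EnergySpectrum", function(object, path) {
  md <- object@metadata
  .writeTSV(path,
            list(technique = "NRVS",
                 temperature_K = md$temperature_K, protein = md$protein,
                 resolution_fwhm_meV = md$resolution_fwhm_meV),
            data.frame(energy_meV = object@energy_meV,
                       counts = object@counts, error = object@countError))
})

#' @rdname writeSpectrumTSV
#' @export
setMethod("writeSpectrumTSV", "PVDOS", function(object, path) {
  .writeTSV(path, list(technique = "PVDOS"),
            data.frame(energy_meV = object@energy_meV,
                       dos_per_meV = object@density))
})

#' @rdname writeSpectrumTSV
#' @export
setMethod("writeSpectrumTSV", "VelocitySpectrum", function(object, path) {
  md <- object@metadata
  .writeTSV(path,
            list(technique = "MOSSBAUER",
                 temperature_K = md$temperature_K, protein = md$protein),
            data.frame(velocity_mm_s = object@velocity_mm_s,
                       counts = object@counts))
})

#' @rdname writeSpectrumTSV
#' @export
setMethod("writeSpectrumTSV", "TimeSpectrum", function(object, path) {
  md <- object@metadata
  .writeTSV(path,
            list(technique = "NFS",
                 temperature_K = md$temperature_K, protein = md$protein,
                 bunch_period_ns = object@bunchPeriod_ns,
                 bin_width_ns = mean(diff(object@time_ns)),
                 window = object@window),
            data.frame(time_ns = object@time_ns, counts = object@counts))
})

#' Read a spectrum or PVDOS from a TSV file
#'
#' Dispatches on the \code{# technique:} header key written by
#' [writeSpectrumTSV()].
#'
#' @param path file written by [writeSpectrumTSV()]
#' @return an object of the class recorded in the file
#' @export
readSpectrumTSV <- function(path) {
  x <- .readTSV(path)
  tech <- x$keys$technique
  if (is.null(tech)) stop("file has no '# technique:' header: ", path)
  md <- list()
  if (!is.na(.numKey(x$keys, "temperature_K")[1]))
    md$temperature_K <- .numKey(x$keys, "temperature_K")
  if (!is.null(x$keys$protein)) md$protein <- x$keys$protein
  switch(tech,
    NRVS = {
      md$resolution_fwhm_meV <- .numKey(x$keys, "resolution_fwhm_meV")
      err <- if ("error" %in% names(x$data)) x$data$error else
        sqrt(pmax(x$data$counts, 0))
      new("EnergySpectrum", energy_meV = x$data$energy_meV,
          counts = x$data$counts, countError = err, metadata = md)
    },
    PVDOS = new("PVDOS", energy_meV = x$data$energy_meV,
                density = x$data$dos_per_meV),
    MOSSBAUER = new("VelocitySpectrum", velocity_mm_s = x$data$velocity_mm_s,
                    counts = x$data$counts, metadata = md),
    NFS = new("TimeSpectrum", time_ns = x$data$time_ns,
              counts = x$data$counts,
              window = .numKey(x$keys, "window"),
              bunchPeriod_ns = .numKey(x$keys, "bunch_period_ns"),
              metadata = md),
    stop("unknown technique in header: ", tech))
}
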