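# On-disk exchange of variable-temperature series: one two-column CSV per
# temperature plus a YAML manifest mapping temperature -> file.

#' Write / read a VT series as CSV spectra plus a YAML manifest
#'
#' `write_vt_series()` writes one `frequency_hz,intensity` CSV per
#' temperature into `dir` and a `manifest.yaml` listing
#' `temperature_K: path` pairs (plus the generating truth when present).
#' `read_vt_series()` reads such a manifest back into a [vt_series()].
#'
#' @param series a [vt_series()].
#' @param dir output directory (created if missing).
#' @return `write_vt_series()`: the manifest path, invisibly.
#' @export
write_vt_series <- function(series, dir) {
  stopifnot(inherits(series, "vt_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("spectrum_%07.2fK.csv", series$temperatures)
  for (i in seq_along(series$temperatures)) {
    utils::write.csv(data.frame(frequency_hz = series$frequency,
                                intensity = series$intensities[i, ]),
                     file.path(dir, files[i]), row.names = FALSE)
  }
  manifest <- list(spectra = stats::setNames(as.list(files),
                                             sprintf("%g", series$temperatures)))
  if (!is.null(series$true_params)) {
    tp <- series$true_params
    manifest$true_params <- list(dG = tp$dG,
                                 nuA = tp$sys$nuA, nuB = tp$sys$nuB,
                                 pA = tp$sys$pA, T2 = tp$sys$T2)
  }
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @param manifest path to a `manifest.yaml` written by `write_vt_series()`.
#' @return `read_vt_series()`: a [vt_series()].
#' @rdname write_vt_series
#' @export
read_vt_series <- function(manifest) {
  m <- yaml::read_yaml(manifest)
  if (is.null(m$spectra) || !length(m$spectra))
    stop("manifest lists no spectra")
  dir <- dirname(manifest)
  temps <- as.numeric(names(m$spectra))
  o <- order(temps)
  temps <- temps[o]
  files <- unlist(m$spectra)[o]
  spectra <- lapply(files, function(f) utils::read.csv(file.path(dir, f)))
  freq <- spectra[[1]][[1]]
  for (sp in spectra)
    if (length(sp[[1]]) != length(freq) || max(abs(sp[[1]] - freq)) > 1e-9)
      stop("spectra do not share a common frequency grid")
  ints <- t(vapply(spectra, function(sp) as.numeric(sp[[2]]),
                   numeric(length(freq))))
  tp <- NULL
  if (!is.null(m$true_params)) {
    p <- m$true_params
    tp <- list(dG = p$dG,
               sys = exchange_system(p$nuA, p$nuB, pA = p$pA, T2 = p$T2))
  }
  vt_series(temps, freq, ints, true_params = tp)
}
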