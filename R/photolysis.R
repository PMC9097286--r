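#' Read an actinic-flux table
#'
#' Two-column text (wavelength in nm, flux in quanta s^-1 cm^-2 nm^-1),
#' whitespace- or comma-delimited, `#` comment lines allowed — the format
#' exported by quick TUV-style calculators.
#'
#' @param path path to the flux file.
#' @param metadata free-text provenance (altitude, zenith angle, ...).
#' @return an `actinic_flux`: list with `wavelength_nm` (strictly
#'   increasing), `flux` (non-negative) and `metadata`.
#' @export
read_actinic_flux <- function(path, metadata = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[,[:space:]]+")
  vals <- suppressWarnings(
    t(vapply(parts, function(p) as.numeric(p[1:2]), numeric(2))))
  if (any(is.na(vals)))
    stop("could not parse flux file (need two numeric columns)",
         call. = FALSE)
  actinic_flux(vals[, 1], vals[, 2], metadata)
}

#' @rdname read_actinic_flux
#' @param wavelength_nm wavelengths in nm, strictly increasing.
#' @param flux actinic flux values, non-negative.
#' @export
actinic_flux <- function(wavelength_nm, flux, metadata = "") {
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength axis must be strictly increasing", call. = FALSE)
  if (any(flux < 0)) stop("flux must be non-negative", call. = FALSE)
  structure(list(wavelength_nm = wavelength_nm, flux = flux,
                 metadata = metadata),
            class = "actinic_flux")
}

#' Re-express a spectrum on a wavelength axis
#'
#' Pointwise relabeling `lambda_nm = 1239.841984 / E_eV` (no Jacobian: the
#' cross section is a pointwise function of photon energy), with the axis
#' reversed so wavelength increases.
#'
#' @param spec a `band_spectrum` or `full_spectrum` on an energy grid.
#' @return a `wavelength_spectrum`: list with `wavelength_nm`, `sigma`,
#'   and the inherited `prefactor_mode`.
#' @export
spectrum_to_wavelength <- function(spec) {
  cur <- .as_curve(spec)
  lambda <- .EV_NM / cur$grid
  ord <- order(lambda)
  structure(list(wavelength_nm = lambda[ord], sigma = cur$sigma[ord],
                 prefactor_mode = spec$prefactor_mode),
            class = "wavelength_spectrum")
}

#' Photolysis rate from spectrum, quantum yield, and actinic flux
#'
#' `J = integral phi(lambda) sigma(lambda) F(lambda) dlambda` by the
#' trapezoid rule over the overlap of the spectrum and flux supports, with
#' the flux linearly interpolated onto the spectrum grid. Requires a
#' physical-mode spectrum (cm^2) so that J comes out in s^-1.
#'
#' @param spec a `wavelength_spectrum` (see [spectrum_to_wavelength()]),
#'   built in `prefactor_mode = "physical"`.
#' @param flux an [actinic_flux()].
#' @param yield quantum yield as a function of wavelength (nm); default the
#'   constant 1.
#' @return J in s^-1, with attribute `coverage`: the fraction of the
#'   spectrum's absorption area inside the overlap window.
#' @export
photolysis_rate <- function(spec, flux, yield = function(lambda) 1) {
  stopifnot(inherits(spec, "wavelength_spectrum"),
            inherits(flux, "actinic_flux"))
  if (!identical(spec$prefactor_mode, "physical"))
    stop("photolysis rates need a spectrum in physical units (cm^2); ",
         "rebuild with nea_constants(\"physical\")", call. = FALSE)
  lo <- max(min(spec$wavelength_nm), min(flux$wavelength_nm))
  hi <- min(max(spec$wavelength_nm), max(flux$wavelength_nm))
  if (lo >= hi)
    stop("no wavelength overlap between spectrum [",
         round(min(spec$wavelength_nm), 1), ", ",
         round(max(spec$wavelength_nm), 1), "] nm and flux [",
         round(min(flux$wavelength_nm), 1), ", ",
         round(max(flux$wavelength_nm), 1), "] nm", call. = FALSE)
  keep <- spec$wavelength_nm >= lo & spec$wavelength_nm <= hi
  lam <- spec$wavelength_nm[keep]
  sig <- spec$sigma[keep]
  Fl <- stats::approx(flux$wavelength_nm, flux$flux, xout = lam)$y
  phi <- yield(lam)
  if (any(phi < 0)) stop("quantum yield must be non-negative", call. = FALSE)
  J <- trapz(lam, phi * sig * Fl)
  tot <- trapz(spec$wavelength_nm, spec$sigma)
  structure(J, coverage = if (tot > 0) trapz(lam, sig) / tot else 0)
}
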