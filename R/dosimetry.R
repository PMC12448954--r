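#' CIE reference erythema action spectrum
#'
#' Relative erythemal effectiveness of monochromatic UV radiation,
#' per the CIE-1998 standard piecewise definition:
#' \deqn{\epsilon(\lambda) = 1 \quad (250 \le \lambda \le 298)}
#' \deqn{\epsilon(\lambda) = 10^{0.094 (298 - \lambda)} \quad (298 < \lambda \le 328)}
#' \deqn{\epsilon(\lambda) = 10^{0.015 (139 - \lambda)} \quad (328 < \lambda \le 400)}
#' The function is continuous at the segment boundaries and non-increasing
#' above 298 nm. This is the weighting underlying the standard erythema
#' dose (SED), defined as 100 J m^-2 of erythemally weighted exposure.
#'
#' @param wavelength wavelength(s) in nm, within \[250, 400\].
#' @return Dimensionless weight(s) in (0, 1].
#' @examples
#' erythema_weight(c(280, 298, 311, 330))
#' @export
erythema_weight <- function(wavelength) {
  if (!is.numeric(wavelength) || any(!is.finite(wavelength))) {
    abort("wavelength must be finite numeric", class = "uvb_domain_error")
  }
  if (any(wavelength < 250 | wavelength > 400)) {
    abort("wavelength outside the erythemal domain [250, 400] nm",
          class = "uvb_domain_error")
  }
  ifelse(wavelength <= 298, 1,
    ifelse(wavelength <= 328,
           10^(0.094 * (298 - wavelength)),
           10^(0.015 * (139 - wavelength))))
}

#' Construct or read a lamp emission spectrum
#'
#' A spectrum is a tibble with columns `wavelength` (nm, strictly
#' increasing, within \[250, 400\]) and `relative_power` (non-negative,
#' arbitrary units, total > 0). `read_spectrum()` reads two-column
#' whitespace- or comma-delimited text; lines starting with `#` are
#' comments.
#'
#' @param wavelength,relative_power numeric vectors of equal length.
#' @return A tibble of class `uvb_spectrum`.
#' @export
spectrum <- function(wavelength, relative_power) {
  if (length(wavelength) != length(relative_power) || length(wavelength) < 1) {
    abort("wavelength and relative_power must be equal-length, non-empty",
          class = "uvb_domain_error")
  }
  if (is.unsorted(wavelength, strictly = TRUE)) {
    abort("wavelength grid must be strictly increasing", class = "uvb_domain_error")
  }
  if (any(wavelength < 250 | wavelength > 400)) {
    abort("spectrum wavelengths must lie in [250, 400] nm",
          class = "uvb_domain_error")
  }
  if (any(relative_power < 0) || sum(relative_power) <= 0) {
    abort("relative_power must be non-negative with positive total",
          class = "uvb_degenerate_spectrum_error")
  }
  structure(tibble::tibble(wavelength = as.numeric(wavelength),
                           relative_power = as.numeric(relative_power)),
            class = c("uvb_spectrum", class(tibble::tibble())))
}

#' @rdname spectrum
#' @param path path to a two-column spectrum file.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("spectrum file does not exist: %s", path), class = "uvb_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "[[:space:],]+")
  mat <- vapply(parts, function(p) as.numeric(p[1:2]), numeric(2))
  spectrum(mat[1, ], mat[2, ])
}

#' Synthetic narrowband-UVB lamp spectrum
#'
#' A constructed (synthetic, not measured) spectral power distribution
#' emulating a TL-01-type fluorescent NB-UVB lamp: a narrow asymmetric band
#' peaking near 311 nm with minor mercury emission lines at 305.4 and
#' 313.2 nm. Its erythemal conversion factor under [sed_per_jcm2()] is
#' about 5.8 SED per J cm^-2, close to the 5.7 conventionally adopted for
#' NB-UVB dosimetry.
#'
#' @return A `uvb_spectrum` tibble.
#' @export
tl01_spectrum <- function() {
  wl <- seq(304, 318, by = 0.25)
  main <- exp(-0.5 * ((wl - 311.1) / ifelse(wl < 311.1, 0.85, 1.1))^2)
  p <- main +
    0.012 * exp(-0.5 * ((wl - 305.4) / 0.3)^2) +
    0.040 * exp(-0.5 * ((wl - 313.2) / 0.3)^2)
  spectrum(wl, p)
}

#' Erythemal conversion factor of a lamp spectrum
#'
#' Computes the SED per J cm^-2 delivered by a lamp with spectral power
#' distribution `E(lambda)`:
#' \deqn{100 \int E(\lambda)\,\epsilon(\lambda)\, d\lambda \big/ \int E(\lambda)\, d\lambda}
#' i.e. 100 times the erythemally weighted fraction of the emitted power.
#' Integration is by the trapezoidal rule on the supplied grid; a
#' single-line spectrum is treated as a delta function, giving
#' `100 * erythema_weight(lambda)`. The factor is invariant under rescaling
#' of `relative_power` and lies in (0, 100], reaching 100 only for spectra
#' confined to the unit plateau below 298 nm.
#'
#' @param spec a spectrum as returned by [spectrum()] or [read_spectrum()].
#' @return SED per J cm^-2 (scalar).
#' @examples
#' sed_per_jcm2(spectrum(311, 1))        # monochromatic 311 nm
#' sed_per_jcm2(tl01_spectrum())         # ~5.8
#' @export
sed_per_jcm2 <- function(spec) {
  stopifnot(is.data.frame(spec),
            all(c("wavelength", "relative_power") %in% names(spec)))
  wl <- spec$wavelength
  p <- spec$relative_power
  if (sum(p) <= 0) {
    abort("degenerate spectrum: total power is zero",
          class = "uvb_degenerate_spectrum_error")
  }
  if (length(wl) == 1) {
    return(100 * erythema_weight(wl))
  }
  trapz <- function(y) sum(diff(wl) * (head(y, -1) + tail(y, -1)) / 2)
  total <- trapz(p)
  if (total <= 0) {
    abort("degenerate spectrum: zero integrated power",
          class = "uvb_degenerate_spectrum_error")
  }
  100 * trapz(p * erythema_weight(wl)) / total
}

#' Convert NB-UVB radiant exposure to erythemally effective dose
#'
#' Multiplies a dose in J cm^-2 by the lamp's erythemal conversion factor.
#' The default factor 5.7 SED per J cm^-2 is the conventional value for
#' NB-UVB lamps; pass the output of [sed_per_jcm2()] to use a measured (or
#' synthetic) spectrum instead. The conversion is linear and exact;
#' rounding belongs to the presentation layer.
#'
#' @param dose_jcm2 radiant exposure(s) in J cm^-2, >= 0.
#' @param factor SED per J cm^-2 (default 5.7).
#' @return Dose(s) in SED.
#' @examples
#' jcm2_to_sed(0.5)  # 2.85, printed as 2.9
#' @export
jcm2_to_sed <- function(dose_jcm2, factor = 5.7) {
  if (any(dose_jcm2 < 0)) {
    abort("dose must be >= 0", class = "uvb_domain_error")
  }
  dose_jcm2 * factor
}

#' @rdname jcm2_to_sed
#' @param dose_sed dose(s) in SED, >= 0.
#' @export
sed_to_jcm2 <- function(dose_sed, factor = 5.7) {
  if (any(dose_sed < 0)) {
    abort("dose must be >= 0", class = "uvb_domain_error")
  }
  dose_sed / factor
}
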