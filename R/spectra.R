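#' Construct an emission spectrum
#'
#' An emission spectrum is a tibble with columns `wavelength` (nm, strictly
#' increasing) and `intensity` (arbitrary fluorescence units). All spectrum
#' operations in the package accept any data frame with these two columns.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param intensity Numeric vector of intensities, same length.
#' @return A tibble with columns `wavelength` and `intensity`.
#' @examples
#' emission_spectrum(c(1000, 1100, 1200), c(0, 1, 0))
#' @export
emission_spectrum <- function(wavelength, intensity) {
  spec <- tibble(wavelength = as.numeric(wavelength),
                 intensity = as.numeric(intensity))
  validate_spectrum(spec)
  spec
}

validate_spectrum <- function(spec, what = "spectrum") {
  check_columns(spec, c("wavelength", "intensity"), what)
  if (nrow(spec) < 2) abort(sprintf("`%s` needs at least 2 points", what))
  if (!all(is.finite(spec$wavelength)) || !all(is.finite(spec$intensity))) {
    abort(sprintf("`%s` contains non-finite values", what))
  }
  if (any(diff(spec$wavelength) <= 0)) {
    abort(sprintf("`%s` wavelengths must be strictly increasing", what))
  }
  invisible(spec)
}

#' Integrate an emission spectrum
#'
#' Trapezoidal integral of intensity over wavelength, optionally restricted
#' to a wavelength window. Integrated intensities are the basis of every
#' \eqn{\Delta F/F} value in the screening pipeline.
#'
#' @param spectrum Data frame with columns `wavelength`, `intensity`.
#' @param window Optional length-2 numeric, `c(lo, hi)` in nm. The integral
#'   is computed over the intersection of the window with the grid; the
#'   window must overlap the wavelength range.
#' @return Integrated intensity (a.u. times nm) as a single number.
#' @examples
#' s <- emission_spectrum(seq(1000, 1200, by = 10), rep(1, 21))
#' integrate_spectrum(s)            # 200
#' integrate_spectrum(s, c(1000, 1100))  # 100
#' @export
integrate_spectrum <- function(spectrum, window = NULL) {
  validate_spectrum(spectrum)
  wl <- spectrum$wavelength
  it <- spectrum$intensity
  if (!is.null(window)) {
    if (length(window) != 2 || !all(is.finite(window))) {
      abort("`window` must be a finite length-2 numeric vector")
    }
    window <- sort(window)
    keep <- wl >= window[1] & wl <= window[2]
    if (sum(keep) < 2) {
      abort(sprintf(
        "window [%g, %g] nm does not overlap the spectrum grid (%g-%g nm)",
        window[1], window[2], min(wl), max(wl)))
    }
    wl <- wl[keep]
    it <- it[keep]
  }
  sum(diff(wl) * (utils::head(it, -1) + utils::tail(it, -1)) / 2)
}

#' Subtract a blank spectrum
#'
#' Pointwise subtraction of a blank well read from a sample read. Both
#' spectra must be on an identical wavelength grid. Negative intensities in
#' the result are kept: clipping them would bias the integrals used for
#' \eqn{\Delta F/F}.
#'
#' @param sample,blank Data frames with columns `wavelength`, `intensity`,
#'   on identical grids.
#' @return The blank-subtracted spectrum as a tibble.
#' @export
subtract_blank <- function(sample, blank) {
  validate_spectrum(sample, "sample")
  validate_spectrum(blank, "blank")
  if (nrow(sample) != nrow(blank) ||
      any(sample$wavelength != blank$wavelength)) {
    bad <- if (nrow(sample) != nrow(blank)) {
      "grids differ in length"
    } else {
      i <- which(sample$wavelength != blank$wavelength)[1]
      sprintf("first differing wavelength: sample %g vs blank %g nm",
              sample$wavelength[i], blank$wavelength[i])
    }
    abort(paste0("sample and blank wavelength grids do not match (", bad, ")"))
  }
  tibble(wavelength = sample$wavelength,
         intensity = sample$intensity - blank$intensity)
}

#' Relative fluorescence change
#'
#' \eqn{\Delta F/F = (F - F_0)/F_0}, the intensiometric sensor response,
#' from integrated baseline (`F0`) and post-addition (`F`) intensities.
#'
#' @param F0 Baseline integrated intensity, must be positive.
#' @param F Post-analyte integrated intensity.
#' @return Dimensionless \eqn{\Delta F/F}; vectorized.
#' @examples
#' compute_dff(200, 250)  # 0.25
#' @export
compute_dff <- function(F0, F) {
  if (any(!is.finite(F0)) || any(!is.finite(F))) {
    abort("F0 and F must be finite")
  }
  if (any(F0 <= 0)) {
    abort("F0 must be positive (degenerate baseline)")
  }
  (F - F0) / F0
}

#' Chirality-window response
#'
#' \eqn{\Delta F/F} restricted to one nanotube chirality: both spectra are
#' integrated over the given wavelength window (e.g. around the (9,4)
#' emission peak) before forming \eqn{(F - F_0)/F_0}.
#'
#' @param F0_spec,F_spec Baseline and post-analyte spectra on a shared grid
#'   covering the window.
#' @param chirality_window Length-2 numeric wavelength interval in nm.
#' @return Dimensionless window-restricted \eqn{\Delta F/F}.
#' @export
extract_peak_response <- function(F0_spec, F_spec, chirality_window) {
  f0 <- integrate_spectrum(F0_spec, chirality_window)
  f <- integrate_spectrum(F_spec, chirality_window)
  compute_dff(f0, f)
}
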