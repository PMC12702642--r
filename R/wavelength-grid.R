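#' Construct a wavelength grid
#'
#' A wavelength grid is a strictly increasing vector of wavelengths in
#' nanometres on which spectra are tabulated. All spectra entering a joint
#' analysis (library components, measurements, reconstructions) must share
#' one grid.
#'
#' @param values Numeric vector of wavelengths in nm, strictly increasing,
#'   finite, and within the 100--3000 nm sanity range.
#'
#' @return A numeric vector of class `"wavelength_grid"`.
#' @examples
#' g <- wavelength_grid(c(400, 500, 600))
#' @export
wavelength_grid <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("wavelength grid must contain at least one wavelength", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("wavelength grid contains non-finite values", call. = FALSE)
  }
  if (length(values) > 1L && any(diff(values) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(values < 100 | values > 3000)) {
    stop("wavelengths outside the 100-3000 nm sanity range", call. = FALSE)
  }
  structure(values, class = "wavelength_grid")
}

#' Default analysis grid: 200--1000 nm
#'
#' The canonical analysis range for deep-UV to near-infrared tissue
#' spectroscopy, sampled at spectrometer-class resolution (1 nm by default,
#' 801 points).
#'
#' @param step_nm Grid spacing in nm.
#' @return A [wavelength_grid()].
#' @export
default_grid <- function(step_nm = 1) {
  wavelength_grid(seq(200, 1000, by = step_nm))
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %d points, %.6g-%.6g nm\n",
    length(x), min(x), max(x)
  ))
  invisible(x)
}

# shared-grid check used across modules
same_grid <- function(a, b) {
  length(a) == length(b) && all(as.numeric(a) == as.numeric(b))
}

as_grid <- function(x) {
  if (inherits(x, "wavelength_grid")) x else wavelength_grid(x)
}
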