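#' Construct a chromophore component spectrum
#'
#' One chromophore's absorption curve on a wavelength grid. Values are
#' either absolute absorption coefficients (1/cm) or dimensionless after
#' 0--1 normalization, tracked by the `normalized` flag.
#'
#' @param name Chromophore identifier (e.g. `"water"`, `"melanin"`,
#'   `"lipofuscin"`, `"DNA"`, `"HbO2"`, `"Hb"`, `"proteins"`, `"lipids"`,
#'   or user-defined).
#' @param grid A [wavelength_grid()] (or numeric vector coerced to one).
#' @param values Non-negative finite absorption values, one per wavelength.
#' @param normalized Logical; `TRUE` asserts `min(values) == 0` and
#'   `max(values) == 1` (checked to 1e-12).
#' @param provenance Free-text note on where the curve came from.
#'
#' @return An object of class `"component_spectrum"`.
#' @export
component_spectrum <- function(name, grid, values, normalized = FALSE,
                               provenance = "") {
  grid <- as_grid(grid)
  values <- as.numeric(values)
  if (length(values) != length(grid)) {
    stop(sprintf(
      "component '%s': %d values for %d wavelengths",
      name, length(values), length(grid)
    ), call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop(sprintf("component '%s': non-finite absorption values", name),
      call. = FALSE
    )
  }
  if (any(values < 0)) {
    stop(sprintf("component '%s': negative absorption values", name),
      call. = FALSE
    )
  }
  if (isTRUE(normalized)) {
    if (abs(min(values)) > 1e-12 || abs(max(values) - 1) > 1e-12) {
      stop(sprintf(
        "component '%s': normalized flag set but range is [%g, %g]",
        name, min(values), max(values)
      ), call. = FALSE)
    }
  }
  structure(
    list(
      name = as.character(name), grid = grid, values = values,
      normalized = isTRUE(normalized), provenance = as.character(provenance)
    ),
    class = "component_spectrum"
  )
}

#' @export
print.component_spectrum <- function(x, ...) {
  cat(sprintf(
    "<component_spectrum> %s: %d points, %.6g-%.6g nm, range [%.4g, %.4g]%s\n",
    x$name, length(x$grid), min(x$grid), max(x$grid),
    min(x$values), max(x$values),
    if (x$normalized) ", normalized 0-1" else ""
  ))
  invisible(x)
}

#' Rescale a component spectrum to the unit range
#'
#' Applies the affine map `(v - min) / (max - min)` so the spectrum spans
#' exactly `[0, 1]`. Library spectra are brought to a common scale this way
#' before entering the design matrix, which makes the fitted weights
#' mutually comparable.
#'
#' @param spectrum A [component_spectrum()] with at least 2 points and a
#'   non-constant curve.
#' @return The normalized [component_spectrum()] (`normalized` flag set).
#'   Idempotent and rank-order preserving.
#' @export
normalize_unit_range <- function(spectrum) {
  stopifnot(inherits(spectrum, "component_spectrum"))
  if (length(spectrum$values) < 2L) {
    stop(sprintf(
      "component '%s': need at least 2 points to normalize", spectrum$name
    ), call. = FALSE)
  }
  lo <- min(spectrum$values)
  hi <- max(spectrum$values)
  if (hi == lo) {
    stop(sprintf(
      "degenerate spectrum: component '%s' is constant (min == max == %g)",
      spectrum$name, lo
    ), call. = FALSE)
  }
  spectrum$values <- (spectrum$values - lo) / (hi - lo)
  spectrum$normalized <- TRUE
  spectrum
}

#' Resample a component spectrum onto a target grid
#'
#' Piecewise-linear interpolation at the target wavelengths. Wavelengths
#' outside the source support are filled with zero and recorded in the
#' `"extrapolated_nm"` attribute of the result; linear interpolation keeps
#' non-negative inputs non-negative and reproduces source values exactly at
#' source wavelengths contained in the target grid.
#'
#' @param spectrum A [component_spectrum()] with at least 2 points.
#' @param target A [wavelength_grid()] to resample onto.
#' @return A [component_spectrum()] on `target`. The `normalized` flag is
#'   dropped (interpolation need not preserve the exact 0--1 range).
#' @export
resample_to_grid <- function(spectrum, target) {
  stopifnot(inherits(spectrum, "component_spectrum"))
  target <- as_grid(target)
  if (length(spectrum$grid) < 2L) {
    stop(sprintf(
      "component '%s': need at least 2 points to resample", spectrum$name
    ), call. = FALSE)
  }
  x <- as.numeric(spectrum$grid)
  out <- stats::approx(x, spectrum$values,
    xout = as.numeric(target),
    method = "linear", yleft = 0, yright = 0, ties = "ordered"
  )$y
  outside <- as.numeric(target) < min(x) | as.numeric(target) > max(x)
  res <- component_spectrum(spectrum$name, target, out,
    normalized = FALSE, provenance = spectrum$provenance
  )
  attr(res, "extrapolated_nm") <- as.numeric(target)[outside]
  res
}

#' Zero a component spectrum below a cutoff wavelength
#'
#' Encodes conventions of the form "this chromophore has negligible (taken
#' as zero) absorption below some wavelength", e.g. lipids below 620 nm,
#' where literature short-wavelength data are absent and visible absorption
#' is orders of magnitude below the hemoglobin bands.
#'
#' @param spectrum A [component_spectrum()].
#' @param cutoff_nm Values at wavelengths strictly below this are set to 0.
#'   A cutoff at or below the grid start is a no-op.
#' @return The modified [component_spectrum()]; never increases any value
#'   and leaves the grid untouched.
#' @export
apply_zero_convention <- function(spectrum, cutoff_nm) {
  stopifnot(inherits(spectrum, "component_spectrum"), is.numeric(cutoff_nm))
  mask <- as.numeric(spectrum$grid) < cutoff_nm
  spectrum$values[mask] <- 0
  if (spectrum$normalized &&
    (abs(min(spectrum$values)) > 1e-12 ||
      abs(max(spectrum$values) - 1) > 1e-12)) {
    spectrum$normalized <- FALSE
  }
  spectrum
}

#' Assemble a spectral library
#'
#' An ordered set of component spectra on one shared wavelength grid; its
#' column-wise arrangement is the design matrix of the unmixing fit. The
#' canonical order for the kidney analysis is water, melanin, lipofuscin,
#' DNA, HbO2, Hb, proteins, lipids.
#'
#' @param components List of [component_spectrum()] objects with unique
#'   names and identical grids.
#' @return An object of class `"spectral_library"`.
#' @export
spectral_library <- function(components) {
  if (length(components) < 1L) {
    stop("spectral library needs at least one component", call. = FALSE)
  }
  ok <- vapply(components, inherits, logical(1), "component_spectrum")
  if (!all(ok)) {
    stop("all library entries must be component_spectrum objects",
      call. = FALSE
    )
  }
  nms <- vapply(components, function(s) s$name, character(1))
  if (anyDuplicated(nms)) {
    stop(sprintf(
      "duplicate component names: %s",
      paste(unique(nms[duplicated(nms)]), collapse = ", ")
    ), call. = FALSE)
  }
  ref <- components[[1]]$grid
  bad <- nms[!vapply(
    components, function(s) same_grid(s$grid, ref), logical(1)
  )]
  if (length(bad)) {
    stop(sprintf(
      "components not on the shared grid: %s", paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  names(components) <- nms
  structure(
    list(components = components, grid = ref),
    class = "spectral_library"
  )
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf(
    "<spectral_library> %d components on %d wavelengths (%.6g-%.6g nm)\n",
    length(x$components), length(x$grid), min(x$grid), max(x$grid)
  ))
  cat("  ", paste(names(x$components), collapse = ", "), "\n", sep = "")
  invisible(x)
}

component_names <- function(library) names(library$components)

#' Build the design matrix of a spectral library
#'
#' One column per component (library order), one row per wavelength. The
#' matrix carries its grid, the component order, and a condition-number
#' diagnostic as attributes. Numerically collinear columns (condition
#' number above `warn_condition`) trigger a warning but never a refusal:
#' overlapping UV bands make tissue chromophore libraries intrinsically
#' ill-conditioned, and the caller decides how to proceed.
#'
#' @param library A [spectral_library()].
#' @param warn_condition Condition-number threshold for the collinearity
#'   warning (default 1e8).
#' @return Numeric matrix `n_wavelengths x n_components` with attributes
#'   `grid`, `condition_number`, `rank`, and `collinearity_warning`.
#' @export
build_design_matrix <- function(library, warn_condition = 1e8) {
  stopifnot(inherits(library, "spectral_library"))
  X <- vapply(
    library$components, function(s) s$values,
    numeric(length(library$grid))
  )
  X <- matrix(X,
    nrow = length(library$grid),
    dimnames = list(NULL, component_names(library))
  )
  d <- svd(X, nu = 0, nv = 0)$d
  kappa <- if (min(d) > 0) max(d) / min(d) else Inf
  rank <- sum(d > max(d) * max(dim(X)) * .Machine$double.eps)
  collinear <- !is.finite(kappa) || kappa > warn_condition
  if (collinear) {
    warning(sprintf(
      "design matrix is numerically collinear (condition number %.3g)",
      kappa
    ), call. = FALSE)
  }
  attr(X, "grid") <- library$grid
  attr(X, "condition_number") <- kappa
  attr(X, "rank") <- rank
  attr(X, "collinearity_warning") <- collinear
  X
}
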