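#' Construct a slab measurement
#'
#' One sample's total transmittance and total reflectance spectra plus the
#' slab thickness, as measured with an integrating sphere. Both spectra are
#' dimensionless fractions of the incident light.
#'
#' @param sample_id Sample identifier.
#' @param condition Cohort label, e.g. `"healthy"` or `"crcc"`.
#' @param grid A [wavelength_grid()].
#' @param Tt Total transmittance per wavelength, in `[0, 1]`.
#' @param Rt Total reflectance per wavelength, in `[0, 1]`.
#' @param thickness_cm Slab thickness in cm (> 0); 0.5 mm slabs are
#'   `thickness_cm = 0.05`.
#'
#' @return An object of class `"sample_measurement"`.
#' @export
sample_measurement <- function(sample_id, condition, grid, Tt, Rt,
                               thickness_cm) {
  grid <- as_grid(grid)
  Tt <- as.numeric(Tt)
  Rt <- as.numeric(Rt)
  if (length(Tt) != length(grid) || length(Rt) != length(grid)) {
    stop("Tt, Rt and grid must have equal length", call. = FALSE)
  }
  for (nm in c("Tt", "Rt")) {
    v <- get(nm)
    if (any(!is.finite(v))) {
      stop(sprintf(
        "%s is not finite at %g nm (sample '%s')",
        nm, as.numeric(grid)[which(!is.finite(v))[1]], sample_id
      ), call. = FALSE)
    }
    if (any(v < 0 | v > 1)) {
      stop(sprintf(
        "%s outside [0, 1] at %g nm (sample '%s')",
        nm, as.numeric(grid)[which(v < 0 | v > 1)[1]], sample_id
      ), call. = FALSE)
    }
  }
  if (!is.numeric(thickness_cm) || length(thickness_cm) != 1L ||
    !is.finite(thickness_cm) || thickness_cm <= 0) {
    stop("thickness_cm must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      sample_id = as.character(sample_id),
      condition = as.character(condition),
      grid = grid, Tt = Tt, Rt = Rt, thickness_cm = thickness_cm
    ),
    class = "sample_measurement"
  )
}

#' Construct an absorption spectrum
#'
#' @param grid A [wavelength_grid()].
#' @param mua Absorption coefficient per wavelength, 1/cm, finite and >= 0.
#' @param clipped_points Wavelengths (nm) where a raw negative value was
#'   clipped to zero.
#' @return An object of class `"absorption_spectrum"`.
#' @export
absorption_spectrum <- function(grid, mua, clipped_points = numeric(0)) {
  grid <- as_grid(grid)
  mua <- as.numeric(mua)
  if (length(mua) != length(grid)) {
    stop("mua and grid must have equal length", call. = FALSE)
  }
  if (any(!is.finite(mua)) || any(mua < 0)) {
    stop("mua must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(grid = grid, mua = mua, clipped_points = as.numeric(clipped_points)),
    class = "absorption_spectrum"
  )
}

#' @export
print.absorption_spectrum <- function(x, ...) {
  cat(sprintf(
    "<absorption_spectrum> %d points, mua %.4g-%.4g 1/cm%s\n",
    length(x$grid), min(x$mua), max(x$mua),
    if (length(x$clipped_points)) {
      sprintf(" (%d wavelengths clipped to 0)", length(x$clipped_points))
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Absorption coefficient of a slab from total transmittance and reflectance
#'
#' Treats all light not transmitted or reflected as absorbed over the slab
#' path length: `mua(lambda) = (1 - (Tt + Rt)) / d` in 1/cm. Noise can push
#' `Tt + Rt` slightly above 1 where true absorption is near zero; the
#' resulting negative raw values are clipped to 0 and the affected
#' wavelengths recorded in `clipped_points`.
#'
#' @param measurement A [sample_measurement()].
#' @return An [absorption_spectrum()] in 1/cm.
#' @examples
#' m <- sample_measurement("s1", "healthy", c(500, 600),
#'   Tt = c(0.4, 0.5), Rt = c(0.3, 0.5), thickness_cm = 0.05
#' )
#' compute_mua(m)$mua # 6.0, 0.0
#' @export
compute_mua <- function(measurement) {
  stopifnot(inherits(measurement, "sample_measurement"))
  raw <- (1 - (measurement$Tt + measurement$Rt)) / measurement$thickness_cm
  clipped <- as.numeric(measurement$grid)[raw < 0]
  absorption_spectrum(measurement$grid, pmax(raw, 0), clipped)
}

#' Mean and standard deviation of a set of absorption spectra
#'
#' Aggregates per-sample absorption spectra of one tissue condition into a
#' per-wavelength arithmetic mean and sample standard deviation (divisor
#' `n - 1`). The mean spectrum is the target of the unmixing fit and the SD
#' defines the fit-quality envelope.
#'
#' @param members List of [absorption_spectrum()] objects on one grid.
#' @param condition Cohort label.
#' @return An object of class `"absorption_ensemble"` with fields
#'   `condition`, `members`, `mean` (an [absorption_spectrum()]), `sd`
#'   (numeric, 1/cm), and `n`. For a single member the SD is reported as
#'   all-zero and `single_member` is set.
#' @export
ensemble_stats <- function(members, condition = "unspecified") {
  if (length(members) < 1L) {
    stop("ensemble needs at least one member spectrum", call. = FALSE)
  }
  ok <- vapply(members, inherits, logical(1), "absorption_spectrum")
  if (!all(ok)) {
    stop("all members must be absorption_spectrum objects", call. = FALSE)
  }
  ref <- members[[1]]$grid
  if (!all(vapply(members, function(s) same_grid(s$grid, ref), logical(1)))) {
    stop("ensemble members are on different wavelength grids", call. = FALSE)
  }
  M <- vapply(members, function(s) s$mua, numeric(length(ref)))
  M <- matrix(M, nrow = length(ref))
  mu <- rowMeans(M)
  n <- ncol(M)
  sdv <- if (n >= 2L) apply(M, 1L, stats::sd) else rep(0, length(ref))
  structure(
    list(
      condition = as.character(condition), members = members,
      mean = absorption_spectrum(ref, mu), sd = sdv, n = n,
      single_member = n == 1L
    ),
    class = "absorption_ensemble"
  )
}

#' @export
print.absorption_ensemble <- function(x, ...) {
  cat(sprintf(
    "<absorption_ensemble> '%s': n = %d, %d wavelengths, mean mua %.4g-%.4g 1/cm\n",
    x$condition, x$n, length(x$mean$grid), min(x$mean$mua), max(x$mean$mua)
  ))
  invisible(x)
}

#' Forward slab model: transmittance/reflectance from an absorption spectrum
#'
#' Exact algebraic inverse of [compute_mua()], used by the synthetic-data
#' generator: `Tt + Rt = 1 - mua * d` per wavelength, split as
#' `Rt = reflectance_fraction * (1 - mua * d)`. Only the sum `Tt + Rt`
#' enters the absorption calculation, so the split fraction cannot affect
#' downstream results.
#'
#' @param mua An [absorption_spectrum()].
#' @param thickness_cm Slab thickness in cm.
#' @param reflectance_fraction Share of the unabsorbed light assigned to
#'   reflectance, in `[0, 1]`.
#' @param sample_id,condition Labels for the generated measurement.
#' @return A [sample_measurement()] satisfying
#'   `compute_mua(forward_ttrt(s)) == s` on physical inputs
#'   (`mua * d <= 1`).
#' @export
forward_ttrt <- function(mua, thickness_cm, reflectance_fraction = 0.4,
                         sample_id = "synthetic", condition = "synthetic") {
  stopifnot(inherits(mua, "absorption_spectrum"))
  if (!is.numeric(reflectance_fraction) || length(reflectance_fraction) != 1L ||
    reflectance_fraction < 0 || reflectance_fraction > 1) {
    stop("reflectance_fraction must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(thickness_cm) || thickness_cm <= 0) {
    stop("thickness_cm must be positive", call. = FALSE)
  }
  ad <- mua$mua * thickness_cm
  if (any(ad > 1)) {
    stop(sprintf(
      "mua * d > 1 at %g nm: non-physical for this slab model",
      as.numeric(mua$grid)[which(ad > 1)[1]]
    ), call. = FALSE)
  }
  s <- 1 - ad
  Rt <- reflectance_fraction * s
  Tt <- s - Rt
  sample_measurement(sample_id, condition, mua$grid, Tt, Rt, thickness_cm)
}
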