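#' Parametric absorption band model
#'
#' Building block for synthetic chromophore spectra: either a Gaussian band
#' `amplitude * exp(-(lambda - center)^2 / (2 width^2))` or an exponential
#' UV-anchored decay `amplitude * exp(-k (lambda - 200))`, the latter
#' emulating the wavelength-decreasing broadband baseline of pigments such
#' as melanin and lipofuscin.
#'
#' @param kind `"gaussian"` or `"exponential-decay"`.
#' @param center_nm Band center in nm (gaussian).
#' @param width_nm Gaussian width (sigma) in nm, > 0.
#' @param decay_per_nm Decay constant k in 1/nm, > 0 (exponential).
#' @param amplitude Peak amplitude, >= 0.
#' @return An object of class `"band_model"`.
#' @export
band_model <- function(kind = c("gaussian", "exponential-decay"),
                       center_nm = NULL, width_nm = NULL,
                       decay_per_nm = NULL, amplitude = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(amplitude) || amplitude < 0) {
    stop("amplitude must be >= 0", call. = FALSE)
  }
  if (kind == "gaussian") {
    if (is.null(center_nm) || is.null(width_nm) || width_nm <= 0) {
      stop("gaussian band needs center_nm and width_nm > 0", call. = FALSE)
    }
  } else {
    if (is.null(decay_per_nm) || decay_per_nm <= 0) {
      stop("exponential-decay band needs decay_per_nm > 0", call. = FALSE)
    }
  }
  structure(
    list(
      kind = kind, center_nm = center_nm, width_nm = width_nm,
      decay_per_nm = decay_per_nm, amplitude = amplitude
    ),
    class = "band_model"
  )
}

#' Evaluate a band model on a wavelength grid
#'
#' @param model A [band_model()].
#' @param grid A [wavelength_grid()].
#' @return Numeric vector of band values, one per wavelength. Spectra built
#'   from several bands are sums of such evaluations.
#' @export
evaluate_band <- function(model, grid) {
  stopifnot(inherits(model, "band_model"))
  lambda <- as.numeric(as_grid(grid))
  if (model$kind == "gaussian") {
    model$amplitude *
      exp(-(lambda - model$center_nm)^2 / (2 * model$width_nm^2))
  } else {
    model$amplitude * exp(-model$decay_per_nm * (lambda - 200))
  }
}

sum_bands <- function(bands, grid) {
  Reduce(`+`, lapply(bands, evaluate_band, grid = grid))
}

#' Default synthetic chromophore library
#'
#' Eight components in the canonical order (water, melanin, lipofuscin,
#' DNA, HbO2, Hb, proteins, lipids) with band positions at the landmarks of
#' real tissue spectra: protein band near 230 nm, DNA near 260 nm, the
#' hemoglobin Soret band at 415 nm with Q-bands at 540/570 nm (HbO2) or a
#' single visible band near 555 nm (Hb), the water band at 980 nm, a lipid
#' band near 930 nm with the zero-below-620 nm convention applied, and
#' exponentially decaying pigment baselines (melanin steeper than
#' lipofuscin), all normalized to the 0--1 range. Band widths and decay
#' constants are package defaults chosen for qualitative resemblance to
#' published curves, not quantitative fidelity.
#'
#' @param grid A [wavelength_grid()] spanning at least 200--980 nm so every
#'   band center is covered.
#' @return A [spectral_library()] whose design matrix has full rank 8 on
#'   the default grid.
#' @export
make_default_library <- function(grid = default_grid()) {
  grid <- as_grid(grid)
  if (min(grid) > 200 || max(grid) < 980) {
    stop("grid must cover 200-980 nm to contain all default band centers",
      call. = FALSE
    )
  }
  g <- function(center, width, amp = 1) {
    band_model("gaussian", center_nm = center, width_nm = width, amplitude = amp)
  }
  e <- function(k) band_model("exponential-decay", decay_per_nm = k)
  specs <- list(
    water = list(g(980, 45)),
    melanin = list(e(0.011)),
    lipofuscin = list(e(0.0055)),
    DNA = list(g(260, 14)),
    HbO2 = list(g(415, 14), g(540, 14, 0.18), g(570, 12, 0.18)),
    Hb = list(g(415, 16), g(555, 16, 0.2)),
    proteins = list(g(230, 12)),
    lipids = list(g(930, 30))
  )
  comps <- lapply(names(specs), function(nm) {
    s <- component_spectrum(nm, grid, sum_bands(specs[[nm]], grid),
      provenance = "synthetic parametric band model"
    )
    if (nm == "lipids") s <- apply_zero_convention(s, 620)
    normalize_unit_range(s)
  })
  spectral_library(comps)
}

#' Define a synthetic measurement scenario
#'
#' Parameters of a forward-generated cohort: the true chromophore weights,
#' cohort size, slab thickness, and the additive Gaussian noise applied to
#' the transmittance and reflectance channels (noise enters measurement
#' space, where it arises in a real integrating-sphere acquisition, not the
#' derived absorption spectra). Defaults mirror a realistic acquisition:
#' 10 samples per condition of 0.5 mm slabs on the 200--1000 nm grid.
#'
#' @param seed Integer seed controlling all randomness of the cohort.
#' @param n_samples Samples per condition, >= 1.
#' @param true_weights Named weight vector in library order, or `NULL` to
#'   use the healthy-kidney reference weights scaled to the physical range
#'   (see [scale_weights_to_physical()]).
#' @param thickness_cm Slab thickness in cm.
#' @param noise_sd SD of the additive Gaussian noise on Tt and Rt
#'   (independent per channel, sample, and wavelength), >= 0.
#' @param reflectance_fraction Split of the unabsorbed light into Rt.
#' @param grid Wavelength grid of the measurements.
#' @param condition Cohort label.
#' @return An object of class `"synthetic_scenario"`.
#' @export
synthetic_scenario <- function(seed, n_samples = 10, true_weights = NULL,
                               thickness_cm = 0.05, noise_sd = 1e-3,
                               reflectance_fraction = 0.4,
                               grid = default_grid(),
                               condition = "synthetic") {
  stopifnot(
    is.numeric(seed), length(seed) == 1L,
    n_samples >= 1, noise_sd >= 0, thickness_cm > 0,
    reflectance_fraction >= 0, reflectance_fraction <= 1
  )
  structure(
    list(
      seed = as.integer(seed), n_samples = as.integer(n_samples),
      true_weights = true_weights, thickness_cm = thickness_cm,
      noise_sd = noise_sd, reflectance_fraction = reflectance_fraction,
      grid = as_grid(grid), condition = as.character(condition)
    ),
    class = "synthetic_scenario"
  )
}

#' Scale a weight vector into the physical range of the slab model
#'
#' The slab relation `Tt + Rt = 1 - mua * d` is only physical while
#' `mua * d <= 1`; a raw reference weight vector applied to a 0--1
#' normalized library can exceed that. This rescales all weights by one
#' common factor so that `max(mua) * d` equals `target` (common rescaling
#' leaves the concentration conversion unchanged).
#'
#' @param weights Named weight vector in library order.
#' @param library A [spectral_library()].
#' @param thickness_cm Slab thickness in cm.
#' @param target Desired `max(mua * d)`, in (0, 1].
#' @return The rescaled named weight vector.
#' @export
scale_weights_to_physical <- function(weights, library, thickness_cm = 0.05,
                                      target = 0.9) {
  stopifnot(target > 0, target <= 1)
  X <- suppressWarnings(build_design_matrix(library))
  peak <- max(as.numeric(X %*% as.numeric(weights))) * thickness_cm
  if (peak <= 0) stop("weights produce a non-positive spectrum", call. = FALSE)
  weights * (target / peak)
}

#' Generate a synthetic measurement cohort with known ground truth
#'
#' Forward-generates `n_samples` slab measurements: the true absorption
#' spectrum is the library reconstruction `X %*% true_weights`, each
#' sample's Tt/Rt are the exact slab inverse ([forward_ttrt()]) plus
#' independent Gaussian noise, clipped into `[0, 1]` (clipping events are
#' counted). Fully deterministic under the scenario seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @param library A [spectral_library()] on the scenario grid.
#' @return List with `measurements` (list of [sample_measurement()]) and
#'   `truth` (true weights, true [absorption_spectrum()], clip count, and
#'   the scenario).
#' @export
generate_cohort <- function(scenario, library) {
  stopifnot(
    inherits(scenario, "synthetic_scenario"),
    inherits(library, "spectral_library")
  )
  if (!same_grid(scenario$grid, library$grid)) {
    stop("scenario and library are on different grids", call. = FALSE)
  }
  w <- scenario$true_weights
  if (is.null(w)) {
    w <- scale_weights_to_physical(
      reference_weights("healthy"), library, scenario$thickness_cm
    )
  }
  X <- suppressWarnings(build_design_matrix(library))
  mua_true <- as.numeric(X %*% as.numeric(w))
  ad <- mua_true * scenario$thickness_cm
  if (any(ad > 1)) {
    stop(sprintf(
      "true mua * d > 1 at %g nm: rescale the weights (see scale_weights_to_physical)",
      as.numeric(scenario$grid)[which(ad > 1)[1]]
    ), call. = FALSE)
  }
  truth_spec <- absorption_spectrum(scenario$grid, mua_true)
  base <- forward_ttrt(truth_spec, scenario$thickness_cm,
    scenario$reflectance_fraction,
    condition = scenario$condition
  )
  set.seed(scenario$seed)
  n_clipped <- 0L
  measurements <- lapply(seq_len(scenario$n_samples), function(i) {
    Tt <- base$Tt + stats::rnorm(length(base$Tt), 0, scenario$noise_sd)
    Rt <- base$Rt + stats::rnorm(length(base$Rt), 0, scenario$noise_sd)
    n_clipped <<- n_clipped +
      sum(Tt < 0 | Tt > 1) + sum(Rt < 0 | Rt > 1)
    sample_measurement(
      sprintf("%s_%03d", scenario$condition, i), scenario$condition,
      scenario$grid, pmin(pmax(Tt, 0), 1), pmin(pmax(Rt, 0), 1),
      scenario$thickness_cm
    )
  })
  list(
    measurements = measurements,
    truth = list(
      weights = w, mua = truth_spec,
      n_clipped = n_clipped, scenario = scenario
    )
  )
}
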