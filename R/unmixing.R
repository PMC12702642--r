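#' Least-squares chromophore weights
#'
#' Solves `min_b || y - X b ||^2` for the component weights, the linear
#' spectral-unmixing step. The solution is computed with a QR factorization
#' (numerically stable for the strongly overlapping UV bands of tissue
#' libraries); the textbook normal-equations form `(X'X)^-1 X'y` is
#' algebraically identical and is reserved for cross-checks. Rank-deficient
#' designs yield the minimum-norm solution (via the singular value
#' decomposition) with an explicit warning rather than a failure.
#'
#' Plain least squares can return negative weights when components are
#' nearly collinear or absent; these are flagged with a warning pointing to
#' the non-negativity-constrained variant (`nonneg = TRUE`, solved with the
#' Lawson--Hanson active-set algorithm).
#'
#' @param X Design matrix (wavelengths x components), e.g. from
#'   [build_design_matrix()].
#' @param y Observed (mean) absorption spectrum, one value per row of `X`.
#' @param nonneg Constrain all weights to be >= 0.
#' @return A named numeric vector of class `"weight_vector"`, one weight
#'   per column of `X`, with attribute `rank_deficient`.
#' @export
solve_weights <- function(X, y, nonneg = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) {
    stop(sprintf(
      "dimension mismatch: %d design rows vs %d observations",
      nrow(X), length(y)
    ), call. = FALSE)
  }
  if (ncol(X) < 1L) {
    stop("design matrix needs at least one column", call. = FALSE)
  }
  rank_deficient <- FALSE
  if (nonneg) {
    w <- pracma::lsqnonneg(X, y)$x
  } else {
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) {
      rank_deficient <- TRUE
      warning(sprintf(
        "design matrix is rank deficient (rank %d of %d columns); returning the minimum-norm solution",
        qrx$rank, ncol(X)
      ), call. = FALSE)
      sv <- svd(X)
      tol <- max(sv$d) * max(dim(X)) * .Machine$double.eps
      dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
      w <- sv$v %*% (dinv * crossprod(sv$u, y))
      w <- as.numeric(w)
    } else {
      w <- as.numeric(qr.coef(qrx, y))
    }
  }
  names(w) <- colnames(X)
  if (!nonneg && any(w < 0)) {
    warning(sprintf(
      "negative weights for: %s; consider the non-negativity constrained fit (nonneg = TRUE)",
      paste(names(w)[w < 0], collapse = ", ")
    ), call. = FALSE)
  }
  structure(w, class = "weight_vector", rank_deficient = rank_deficient)
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector>\n")
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Reconstruct an absorption spectrum from library weights
#'
#' The weighted sum `sum_i w_i * mua_i(lambda)` over the library
#' components. Negative sums (possible with negative weights) are clipped
#' to 0 in the returned absorption spectrum, with the raw unclipped values
#' kept in the `"raw"` attribute for residual diagnostics.
#'
#' @param library A [spectral_library()].
#' @param weights A named weight vector matching the library components in
#'   name and order.
#' @return An [absorption_spectrum()] on the library grid.
#' @export
reconstruct <- function(library, weights) {
  stopifnot(inherits(library, "spectral_library"))
  w <- as.numeric(weights)
  nms <- names(weights)
  if (length(w) != length(library$components)) {
    stop(sprintf(
      "%d weights for %d library components",
      length(w), length(library$components)
    ), call. = FALSE)
  }
  if (!is.null(nms) && !identical(nms, component_names(library))) {
    stop(sprintf(
      "weight names/order do not match the library (%s vs %s)",
      paste(nms, collapse = ","), paste(component_names(library), collapse = ",")
    ), call. = FALSE)
  }
  X <- build_design_matrix(library)
  raw <- as.numeric(X %*% w)
  clipped <- as.numeric(library$grid)[raw < 0]
  out <- absorption_spectrum(library$grid, pmax(raw, 0), clipped)
  attr(out, "raw") <- raw
  out
}

#' Fraction of wavelengths where a reconstruction stays within the SD envelope
#'
#' The fit-quality criterion for the reconstruction: at each wavelength the
#' reconstructed value must lie within one sample standard deviation of the
#' ensemble mean. Where the SD is exactly zero the reconstruction must
#' match the mean to `tol_zero_sd`.
#'
#' @param observed An [ensemble_stats()] result with at least 2 members.
#' @param reconstruction An [absorption_spectrum()] on the same grid.
#' @param tol_zero_sd Equality tolerance at zero-SD wavelengths.
#' @return List with `fraction` (in `[0, 1]`) and the logical per-wavelength
#'   `mask`.
#' @export
check_within_sd <- function(observed, reconstruction, tol_zero_sd = 1e-9) {
  stopifnot(
    inherits(observed, "absorption_ensemble"),
    inherits(reconstruction, "absorption_spectrum")
  )
  if (observed$n < 2L) {
    stop("SD envelope undefined for an ensemble with fewer than 2 members",
      call. = FALSE
    )
  }
  if (!same_grid(observed$mean$grid, reconstruction$grid)) {
    stop("ensemble and reconstruction are on different grids", call. = FALSE)
  }
  dev <- abs(observed$mean$mua - reconstruction$mua)
  mask <- ifelse(observed$sd > 0, dev <= observed$sd, dev <= tol_zero_sd)
  list(fraction = mean(mask), mask = mask)
}

#' Full unmixing fit for one tissue condition
#'
#' Composes the pipeline for one cohort of slab measurements: per-sample
#' absorption via [compute_mua()], ensemble mean and SD via
#' [ensemble_stats()], weights on the ensemble mean via [solve_weights()],
#' reconstruction via [reconstruct()], SD-envelope check via
#' [check_within_sd()] (skipped for a single-member cohort), and the
#' water-anchored concentration conversion via
#' [weights_to_concentrations()].
#'
#' If plain least squares returns a negative weight the concentration
#' conversion is not meaningful; the result then carries `concentrations =
#' NULL` with a warning (rerun with `nonneg = TRUE` for a volume-valid
#' fit), while the weights and residual diagnostics remain available.
#'
#' @param condition_measurements List of [sample_measurement()] objects of
#'   one condition.
#' @param library A [spectral_library()].
#' @param water_fraction_pct Water volume anchor in percent (default 77).
#' @param nonneg Use the non-negativity constrained solver.
#' @return Object of class `"unmixing_result"`: `condition`, `ensemble`,
#'   `weights`, `reconstruction`, `residuals` (observed minus raw
#'   reconstruction), `rmse`, `within_sd_fraction` (`NA` for n = 1),
#'   `within_sd_mask`, `condition_number`, `concentrations`.
#' @export
fit_condition <- function(condition_measurements, library,
                          water_fraction_pct = 77, nonneg = FALSE) {
  if (length(condition_measurements) < 1L) {
    stop("fit_condition: no measurements supplied", call. = FALSE)
  }
  stopifnot(inherits(library, "spectral_library"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  condition <- condition_measurements[[1]]$condition
  members <- stage(
    "compute_mua",
    lapply(condition_measurements, compute_mua)
  )
  ens <- stage("ensemble_stats", ensemble_stats(members, condition))
  X <- stage("build_design_matrix", build_design_matrix(library))
  if (!same_grid(attr(X, "grid"), ens$mean$grid)) {
    stop("[solve_weights] library and measurements are on different grids",
      call. = FALSE
    )
  }
  w <- stage("solve_weights", solve_weights(X, ens$mean$mua, nonneg = nonneg))
  recon <- stage("reconstruct", reconstruct(library, w))
  residuals <- ens$mean$mua - attr(recon, "raw")
  wsd <- if (ens$n >= 2L) {
    stage("check_within_sd", check_within_sd(ens, recon))
  } else {
    list(fraction = NA_real_, mask = NULL)
  }
  conc <- if (any(as.numeric(w)[tolower(names(w)) != "water"] < 0)) {
    warning(
      "negative non-water weights: concentration table not computed; rerun with nonneg = TRUE",
      call. = FALSE
    )
    NULL
  } else {
    stage(
      "weights_to_concentrations",
      weights_to_concentrations(w,
        water_fraction_pct = water_fraction_pct,
        condition = condition
      )
    )
  }
  structure(
    list(
      condition = condition,
      ensemble = ens,
      weights = w,
      reconstruction = recon,
      residuals = residuals,
      rmse = sqrt(mean(residuals^2)),
      within_sd_fraction = wsd$fraction,
      within_sd_mask = wsd$mask,
      condition_number = attr(X, "condition_number"),
      concentrations = conc
    ),
    class = "unmixing_result"
  )
}

#' @export
print.unmixing_result <- function(x, ...) {
  cat(sprintf(
    "<unmixing_result> '%s': n = %d samples, rmse %.4g 1/cm, within-SD fraction %s, cond(X) %.3g\n",
    x$condition, x$ensemble$n, x$rmse,
    ifelse(is.na(x$within_sd_fraction), "NA (single member)",
      sprintf("%.3f", x$within_sd_fraction)
    ),
    x$condition_number
  ))
  cat("weights:\n")
  print(stats::setNames(as.numeric(x$weights), names(x$weights)))
  if (!is.null(x$concentrations)) {
    cat("concentrations (% tissue volume):\n")
    print(x$concentrations)
  }
  invisible(x)
}
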