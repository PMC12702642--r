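#' Convert chromophore weights to volume concentrations
#'
#' Tissue water content is anchored at a fixed volume fraction (77% for
#' kidney, the value reported for rat kidney and adopted for human tissue
#' in the absence of a measured figure); the remaining volume is shared
#' among the non-water chromophores in proportion to their fitted weights:
#' `c_i = w_i / sum_j(w_j) * (100 - water_fraction_pct)` over non-water
#' components `j`. The water weight itself does not enter the denominator
#' - water is anchored, not allocated. Concentrations always sum to
#' exactly 100% before rounding and are invariant to a common rescaling of
#' the non-water weights.
#'
#' @param weights Named numeric weight vector (e.g. from [solve_weights()])
#'   containing a component named `water` (case-insensitive). All non-water
#'   weights must be >= 0: volumes cannot be negative, so a negative
#'   least-squares weight must first be addressed (see the `nonneg` flag of
#'   [solve_weights()]).
#' @param water_fraction_pct Water anchor in percent, strictly between 0
#'   and 100, or exactly 100 (all non-water concentrations then 0).
#' @param condition Optional cohort label stored with the table.
#' @param decimals Reporting precision (2 decimals by convention);
#'   comparisons and the stored values are unrounded.
#' @return A `data.frame` of class `"concentration_table"` with columns
#'   `component`, `weight`, `concentration_pct`, and attributes
#'   `condition`, `water_fraction_pct`, `decimals`.
#' @examples
#' w <- reference_weights("healthy")
#' weights_to_concentrations(w) # water fixed at 77%, DNA 1.32%, HbO2 17.53%, ...
#' @export
weights_to_concentrations <- function(weights, water_fraction_pct = 77,
                                      condition = NULL, decimals = 2) {
  w <- as.numeric(weights)
  nms <- names(weights)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("weights must be a fully named vector", call. = FALSE)
  }
  if (!is.numeric(water_fraction_pct) || length(water_fraction_pct) != 1L ||
    water_fraction_pct <= 0 || water_fraction_pct > 100) {
    stop("water_fraction_pct must be in (0, 100]", call. = FALSE)
  }
  iw <- which(tolower(nms) == "water")
  if (length(iw) != 1L) {
    stop("weights must contain exactly one component named 'water'",
      call. = FALSE
    )
  }
  other <- w[-iw]
  if (any(other < 0)) {
    stop(sprintf(
      "negative non-water weights (%s): volume concentrations require non-negative weights; refit with nonneg = TRUE",
      paste(nms[-iw][other < 0], collapse = ", ")
    ), call. = FALSE)
  }
  tot <- sum(other)
  if (tot == 0 && water_fraction_pct < 100) {
    stop("non-water weights sum to zero: cannot allocate the non-water volume",
      call. = FALSE
    )
  }
  conc <- numeric(length(w))
  conc[iw] <- water_fraction_pct
  if (water_fraction_pct < 100) {
    conc[-iw] <- other / tot * (100 - water_fraction_pct)
  }
  out <- data.frame(
    component = nms,
    weight = w,
    concentration_pct = conc,
    stringsAsFactors = FALSE
  )
  structure(out,
    class = c("concentration_table", "data.frame"),
    condition = if (is.null(condition)) NA_character_ else as.character(condition),
    water_fraction_pct = water_fraction_pct,
    decimals = decimals
  )
}

#' @export
print.concentration_table <- function(x, ...) {
  dec <- attr(x, "decimals")
  cond <- attr(x, "condition")
  if (!is.na(cond)) cat(sprintf("condition: %s\n", cond))
  shown <- data.frame(
    component = x$component,
    weight = x$weight,
    concentration_pct = round(x$concentration_pct, dec)
  )
  print.data.frame(shown, row.names = FALSE, ...)
  cat(sprintf("total: %g%%\n", round(sum(x$concentration_pct), dec)))
  invisible(x)
}

#' Compare chromophore concentrations between two conditions
#'
#' Signed concentration differences (second condition minus first) with a
#' direction label assigned at reporting precision, e.g. to contrast a
#' healthy with a carcinoma cohort.
#'
#' @param a,b [weights_to_concentrations()] tables with identical component
#'   sets.
#' @param decimals Precision at which `increased`/`decreased`/`unchanged`
#'   is decided (differences themselves are returned unrounded).
#' @return A `data.frame` with columns `component`, `conc_a`, `conc_b`,
#'   `difference`, `direction`.
#' @export
compare_conditions <- function(a, b, decimals = 2) {
  stopifnot(
    inherits(a, "concentration_table"),
    inherits(b, "concentration_table")
  )
  if (!setequal(a$component, b$component) ||
    nrow(a) != nrow(b)) {
    stop("concentration tables have mismatched component sets", call. = FALSE)
  }
  bb <- b[match(a$component, b$component), ]
  diff_raw <- bb$concentration_pct - a$concentration_pct
  diff_rep <- round(bb$concentration_pct, decimals) -
    round(a$concentration_pct, decimals)
  direction <- ifelse(diff_rep > 0, "increased",
    ifelse(diff_rep < 0, "decreased", "unchanged")
  )
  data.frame(
    component = a$component,
    conc_a = a$concentration_pct,
    conc_b = bb$concentration_pct,
    difference = diff_raw,
    direction = direction,
    stringsAsFactors = FALSE
  )
}

#' Published chromophore weight sets for human kidney
#'
#' The least-squares chromophore weights reported for mean absorption
#' spectra of healthy and chromophobe renal cell carcinoma (CRCC) human
#' kidney tissue (0.5 mm slabs, 200--1000 nm), in the canonical component
#' order. Useful as a realistic reference composition for the
#' concentration conversion and for the synthetic-data generator.
#'
#' @param condition `"healthy"` or `"crcc"`.
#' @return Named numeric vector of 8 weights (water, melanin, lipofuscin,
#'   DNA, HbO2, Hb, proteins, lipids).
#' @export
reference_weights <- function(condition = c("healthy", "crcc")) {
  condition <- match.arg(tolower(condition), c("healthy", "crcc"))
  nms <- c(
    "water", "melanin", "lipofuscin", "DNA", "HbO2", "Hb",
    "proteins", "lipids"
  )
  w <- switch(condition,
    healthy = c(14.47, 1.00, 5.65, 14.55, 193.21, 37.28, 1.71, 0.07),
    crcc = c(18.46, 0.1, 8.97, 30.91, 254.04, 11.05, 5.22, 0.43)
  )
  stats::setNames(w, nms)
}
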