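#' Read a two-column spectrum CSV
#'
#' Expects header `wavelength_nm,value` (comment lines starting with `#`
#' are skipped). Rows are sorted by wavelength; duplicate wavelengths and
#' non-numeric rows are rejected with the offending wavelength or line.
#'
#' @param path Path to the CSV file.
#' @return List with `grid` (a [wavelength_grid()]) and `values`.
#' @export
read_spectrum_csv <- function(path) {
  parsed <- read_numeric_csv(path, c("wavelength_nm", "value"))
  ord <- order(parsed$wavelength_nm)
  wl <- parsed$wavelength_nm[ord]
  if (anyDuplicated(wl)) {
    stop(sprintf(
      "%s: duplicated wavelength %g nm", path, wl[duplicated(wl)][1]
    ), call. = FALSE)
  }
  list(grid = wavelength_grid(wl), values = parsed$value[ord])
}

#' Write a two-column spectrum CSV
#'
#' @param grid A [wavelength_grid()].
#' @param values Numeric values, one per wavelength.
#' @param path Output path.
#' @param meta Named character vector written as `# key: value` header
#'   comments.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(grid, values, path, meta = character(0)) {
  write_csv_stable(
    data.frame(wavelength_nm = as.numeric(grid), value = values),
    path,
    meta = meta
  )
}

#' Read a per-sample measurement CSV
#'
#' Expects header `wavelength_nm,Tt,Rt`; thickness and condition are not
#' part of the file and are supplied by the caller (typically from a run
#' configuration, with `thickness_mm` converted to cm).
#'
#' @param path Path to the CSV file.
#' @param thickness_cm Slab thickness in cm.
#' @param condition Cohort label.
#' @param sample_id Sample identifier; defaults to the file name.
#' @return A [sample_measurement()].
#' @export
read_measurement_csv <- function(path, thickness_cm, condition,
                                 sample_id = NULL) {
  parsed <- read_numeric_csv(path, c("wavelength_nm", "Tt", "Rt"))
  ord <- order(parsed$wavelength_nm)
  wl <- parsed$wavelength_nm[ord]
  if (anyDuplicated(wl)) {
    stop(sprintf(
      "%s: duplicated wavelength %g nm", path, wl[duplicated(wl)][1]
    ), call. = FALSE)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.csv$", "", basename(path), ignore.case = TRUE)
  }
  sample_measurement(
    sample_id, condition, wavelength_grid(wl),
    parsed$Tt[ord], parsed$Rt[ord], thickness_cm
  )
}

#' Read a spectral library from a manifest CSV
#'
#' The manifest has columns `component,path,normalize,zero_below_nm`, one
#' row per chromophore in the desired library order. Relative spectrum
#' paths are resolved against the manifest's directory. Each spectrum is
#' resampled to `grid`, the zero-below convention applied where
#' `zero_below_nm > 0`, and 0--1 normalization applied where `normalize`
#' is true.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param grid Target [wavelength_grid()].
#' @return A [spectral_library()].
#' @export
read_library_manifest <- function(manifest_path, grid = default_grid()) {
  man <- utils::read.csv(manifest_path,
    comment.char = "#",
    stringsAsFactors = FALSE
  )
  need <- c("component", "path", "normalize", "zero_below_nm")
  if (!all(need %in% names(man))) {
    stop(sprintf(
      "%s: manifest must have columns %s",
      manifest_path, paste(need, collapse = ", ")
    ), call. = FALSE)
  }
  comps <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(dirname(manifest_path), man$path[i])
    sp <- read_spectrum_csv(p)
    s <- component_spectrum(man$component[i], sp$grid, sp$values,
      provenance = p
    )
    s <- resample_to_grid(s, grid)
    if (is.finite(man$zero_below_nm[i]) && man$zero_below_nm[i] > 0) {
      s <- apply_zero_convention(s, man$zero_below_nm[i])
    }
    if (isTRUE(as.logical(man$normalize[i]))) s <- normalize_unit_range(s)
    s
  })
  spectral_library(comps)
}

#' Write a spectral library as per-component CSVs plus a manifest
#'
#' @param library A [spectral_library()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_library_dir <- function(library, dir) {
  stopifnot(inherits(library, "spectral_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(library$components, function(s) {
    f <- paste0(s$name, ".csv")
    write_spectrum_csv(s$grid, s$values, file.path(dir, f))
    data.frame(
      component = s$name, path = f,
      normalize = FALSE, zero_below_nm = 0,
      stringsAsFactors = FALSE
    )
  })
  manifest <- file.path(dir, "library_manifest.csv")
  write_csv_stable(do.call(rbind, rows), manifest)
  invisible(manifest)
}

#' Assemble and validate a run configuration
#'
#' Defaults encode the kidney-slab study conditions: 0.5 mm slabs, 77%
#' water anchor, 200--1000 nm at 1 nm.
#'
#' @param measurements_dir Directory with one subdirectory per condition,
#'   each holding `wavelength_nm,Tt,Rt` CSVs.
#' @param output_dir Directory for result artifacts (created if missing).
#' @param library_manifest Manifest CSV path, or `NULL` for the default
#'   synthetic library ([make_default_library()]).
#' @param thickness_mm Slab thickness in mm (> 0; stored internally in cm).
#' @param water_fraction_pct Water anchor, in (0, 100).
#' @param grid_min_nm,grid_max_nm,grid_step_nm Analysis grid specification.
#' @param nonneg Use the non-negativity constrained solver.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(measurements_dir, output_dir,
                       library_manifest = NULL, thickness_mm = 0.5,
                       water_fraction_pct = 77, grid_min_nm = 200,
                       grid_max_nm = 1000, grid_step_nm = 1,
                       nonneg = FALSE) {
  if (thickness_mm <= 0) stop("thickness_mm must be > 0", call. = FALSE)
  if (water_fraction_pct <= 0 || water_fraction_pct >= 100) {
    stop("water_fraction_pct must be in (0, 100)", call. = FALSE)
  }
  if (grid_min_nm >= grid_max_nm) {
    stop("grid min must be below grid max", call. = FALSE)
  }
  structure(
    list(
      measurements_dir = measurements_dir, output_dir = output_dir,
      library_manifest = library_manifest, thickness_mm = thickness_mm,
      water_fraction_pct = water_fraction_pct, grid_min_nm = grid_min_nm,
      grid_max_nm = grid_max_nm, grid_step_nm = grid_step_nm,
      nonneg = isTRUE(nonneg)
    ),
    class = "run_config"
  )
}

#' Run the full unmixing analysis over a measurement directory
#'
#' For each condition subdirectory: reads the sample CSVs, runs
#' [fit_condition()], and writes four artifacts (`ensemble.csv`,
#' `weights.csv`, `reconstruction.csv`, `concentrations.csv`) plus a
#' `run_summary.txt` with the library order, normalization convention,
#' condition number, rmse, and within-SD fraction. With exactly two
#' conditions a `comparison.csv` of signed concentration differences is
#' written. Output files are byte-stable across reruns and carry a
#' config-hash/version header comment.
#'
#' @param config A [run_config()].
#' @return Named list of [fit_condition()] results, invisibly.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  conds <- list.dirs(config$measurements_dir,
    recursive = FALSE,
    full.names = TRUE
  )
  if (length(conds) == 0L) {
    stop(sprintf(
      "no samples: '%s' contains no condition subdirectories",
      config$measurements_dir
    ), call. = FALSE)
  }
  grid <- wavelength_grid(seq(config$grid_min_nm, config$grid_max_nm,
    by = config$grid_step_nm
  ))
  library <- if (is.null(config$library_manifest)) {
    make_default_library(grid)
  } else {
    read_library_manifest(config$library_manifest, grid)
  }
  meta <- c(
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("chromounmix"))
  )
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  for (cond_dir in conds) {
    cond <- basename(cond_dir)
    files <- sort(list.files(cond_dir, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0L) {
      stop(sprintf("no samples: condition '%s' has no CSV files", cond),
        call. = FALSE
      )
    }
    measurements <- lapply(
      files, read_measurement_csv,
      thickness_cm = config$thickness_mm / 10, condition = cond
    )
    measurements <- lapply(measurements, function(m) {
      if (!same_grid(m$grid, grid)) {
        stop(sprintf(
          "sample '%s' is not on the configured analysis grid", m$sample_id
        ), call. = FALSE)
      }
      m
    })
    res <- fit_condition(measurements, library,
      water_fraction_pct = config$water_fraction_pct,
      nonneg = config$nonneg
    )
    out <- file.path(config$output_dir, cond)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_csv_stable(
      data.frame(
        wavelength_nm = as.numeric(grid),
        mean_mua_percm = res$ensemble$mean$mua,
        sd_mua_percm = res$ensemble$sd
      ),
      file.path(out, "ensemble.csv"), meta
    )
    write_csv_stable(
      data.frame(
        component = names(res$weights),
        weight = as.numeric(res$weights)
      ),
      file.path(out, "weights.csv"), meta
    )
    write_csv_stable(
      data.frame(
        wavelength_nm = as.numeric(grid),
        reconstructed_mua_percm = res$reconstruction$mua,
        residual_percm = res$residuals
      ),
      file.path(out, "reconstruction.csv"), meta
    )
    if (!is.null(res$concentrations)) {
      write_csv_stable(
        data.frame(
          component = res$concentrations$component,
          weight = res$concentrations$weight,
          concentration_pct = res$concentrations$concentration_pct
        ),
        file.path(out, "concentrations.csv"), meta
      )
    }
    writeLines(
      c(
        paste0("# config_hash: ", meta[["config_hash"]]),
        paste0("# package_version: ", meta[["package_version"]]),
        paste0("condition: ", cond),
        paste0("n_samples: ", res$ensemble$n),
        paste0("library_order: ", paste(names(res$weights), collapse = ",")),
        "library_scale: normalized_0_1",
        paste0("condition_number: ", fmt_num(res$condition_number)),
        paste0("rmse_percm: ", fmt_num(res$rmse)),
        paste0("within_sd_fraction: ", fmt_num(res$within_sd_fraction)),
        paste0("water_fraction_pct: ", fmt_num(config$water_fraction_pct)),
        paste0("nonneg: ", config$nonneg)
      ),
      file.path(out, "run_summary.txt")
    )
    results[[cond]] <- res
  }
  if (length(results) == 2L &&
    !is.null(results[[1]]$concentrations) &&
    !is.null(results[[2]]$concentrations)) {
    cmp <- compare_conditions(
      results[[1]]$concentrations, results[[2]]$concentrations
    )
    write_csv_stable(
      cmp, file.path(config$output_dir, "comparison.csv"),
      c(meta,
        condition_a = names(results)[1], condition_b = names(results)[2]
      )
    )
  }
  invisible(results)
}

#' Write a synthetic cohort, its library, and the ground truth to disk
#'
#' Produces the on-disk layout [run_full_analysis()] consumes: one
#' subdirectory per condition with sample CSVs, a library directory with a
#' manifest, and a `ground_truth.csv` of the generating weights.
#'
#' @param scenario A [synthetic_scenario()].
#' @param library A [spectral_library()].
#' @param dir Output directory.
#' @return List of paths (`measurements`, `library_manifest`,
#'   `ground_truth`), invisibly.
#' @export
simulate_to_dir <- function(scenario, library, dir) {
  cohort <- generate_cohort(scenario, library)
  meas_dir <- file.path(dir, "measurements", scenario$condition)
  dir.create(meas_dir, recursive = TRUE, showWarnings = FALSE)
  for (m in cohort$measurements) {
    write_csv_stable(
      data.frame(
        wavelength_nm = as.numeric(m$grid), Tt = m$Tt, Rt = m$Rt
      ),
      file.path(meas_dir, paste0(m$sample_id, ".csv"))
    )
  }
  manifest <- write_library_dir(library, file.path(dir, "library"))
  truth_path <- file.path(dir, "ground_truth.csv")
  write_csv_stable(
    data.frame(
      component = names(cohort$truth$weights),
      true_weight = as.numeric(cohort$truth$weights)
    ),
    truth_path,
    meta = c(
      seed = as.character(scenario$seed),
      n_samples = as.character(scenario$n_samples),
      thickness_cm = fmt_num(scenario$thickness_cm),
      noise_sd = fmt_num(scenario$noise_sd),
      reflectance_fraction = fmt_num(scenario$reflectance_fraction),
      n_clipped = as.character(cohort$truth$n_clipped)
    )
  )
  invisible(list(
    measurements = file.path(dir, "measurements"),
    library_manifest = manifest,
    ground_truth = truth_path
  ))
}

# ---- internal helpers -------------------------------------------------------

# strict numeric CSV reader shared by the spectrum/measurement readers;
# reports malformed rows with their (1-based, post-comment) line numbers
read_numeric_csv <- function(path, columns) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path,
    comment.char = "#", stringsAsFactors = FALSE,
    colClasses = "character"
  )
  if (!all(columns %in% names(df))) {
    stop(sprintf(
      "%s: expected columns %s, found %s",
      path, paste(columns, collapse = ","), paste(names(df), collapse = ",")
    ), call. = FALSE)
  }
  if (nrow(df) == 0L) stop(sprintf("%s: no data rows", path), call. = FALSE)
  out <- list()
  for (cn in columns) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf(
        "%s: malformed value '%s' in column %s, data row %d",
        path, df[[cn]][bad[1]], cn, bad[1]
      ), call. = FALSE)
    }
    out[[cn]] <- v
  }
  out
}

fmt_num <- function(x) formatC(x, digits = 6, format = "g")

# full-precision, locale-independent, byte-stable CSV writer
write_csv_stable <- function(df, path, meta = character(0)) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    sub("^\\s+", "", formatC(x, digits = 15, format = "g"))
  })
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(sprintf("# %s: %s", names(meta), meta), con)
  }
  utils::write.table(df, con,
    sep = ",", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

# djb2-style rolling hash of the deparsed configuration (reproducibility stamp)
config_hash <- function(config) {
  fields <- unclass(config)
  bytes <- utf8ToInt(paste(
    deparse(fields[order(names(fields))]),
    collapse = "\n"
  ))
  h <- 5381
  for (b in bytes) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", h)
}
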