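test_that("wavelength grids enforce monotonicity and the sanity range", {
  expect_s3_class(wavelength_grid(c(200, 300, 400)), "wavelength_grid")
  expect_error(wavelength_grid(c(300, 200)), "strictly increasing")
  expect_error(wavelength_grid(c(200, 200)), "strictly increasing")
  expect_error(wavelength_grid(c(50, 200)), "sanity range")
  expect_error(wavelength_grid(c(200, NA)), "non-finite")
  g <- default_grid()
  expect_length(g, 801)
  expect_equal(range(as.numeric(g)), c(200, 1000))
})

test_that("normalize_unit_range maps endpoints exactly and is idempotent", {
  g <- wavelength_grid(c(400, 500, 600))
  s <- component_spectrum("x", g, c(2, 4, 6))
  n1 <- normalize_unit_range(s)
  expect_equal(n1$values, c(0, 0.5, 1))
  expect_true(n1$normalized)
  # idempotence: a spectrum already spanning [0, 1] is unchanged
  expect_equal(normalize_unit_range(n1)$values, n1$values)
})

test_that("normalize_unit_range matches an element-wise oracle on random input", {
  set.seed(1)
  g <- default_grid()
  v <- runif(801, 5, 9)
  out <- normalize_unit_range(component_spectrum("r", g, v))
  expect_identical(min(out$values), 0)
  expect_identical(max(out$values), 1)
  expect_equal(out$values, (v - min(v)) / (max(v) - min(v)))
  expect_identical(order(out$values), order(v)) # rank order preserved
})

test_that("normalization rejects constant spectra, naming the component", {
  g <- wavelength_grid(c(400, 500))
  expect_error(
    normalize_unit_range(component_spectrum("flatline", g, c(3, 3))),
    "degenerate spectrum.*flatline"
  )
})

test_that("resample_to_grid interpolates linearly and zero-fills outside support", {
  src <- component_spectrum("k", wavelength_grid(c(400, 402)), c(0, 1))
  out <- resample_to_grid(src, wavelength_grid(c(350, 401)))
  expect_equal(out$values, c(0, 0.5))
  expect_equal(attr(out, "extrapolated_nm"), 350)
  expect_error(resample_to_grid(src, wavelength_grid(numeric(0))))
})

test_that("resample round-trip recovers original knot values", {
  set.seed(7)
  knots <- sort(runif(20, 300, 900))
  vals <- runif(20, 0, 5)
  src <- component_spectrum("rt", wavelength_grid(knots), vals)
  fine_x <- sort(unique(c(knots, seq(min(knots), max(knots), length.out = 96))))
  fine <- resample_to_grid(src, wavelength_grid(fine_x))
  back <- resample_to_grid(fine, wavelength_grid(knots))
  expect_equal(back$values, vals, tolerance = 1e-12)
  expect_true(all(fine$values >= 0))
})

test_that("apply_zero_convention zeroes exactly the wavelengths below the cutoff", {
  g <- default_grid()
  set.seed(3)
  s <- component_spectrum("lipids", g, runif(801, 0.1, 1))
  z <- apply_zero_convention(s, 620)
  expect_identical(sum(z$values == 0), 420L) # [200, 620) at 1 nm
  expect_equal(
    z$values[as.numeric(g) >= 620],
    s$values[as.numeric(g) >= 620]
  )
  expect_true(all(z$values <= s$values))
  expect_identical(as.numeric(z$grid), as.numeric(g))
  # cutoff at or below the grid start is a no-op
  expect_equal(apply_zero_convention(s, 200)$values, s$values)
})

test_that("spectral_library validates names and shared grids", {
  lib <- toy_library()
  expect_named(lib$components, c("alpha", "beta"))
  g <- tiny_grid()
  a <- component_spectrum("a", g, 1:5)
  expect_error(spectral_library(list()), "at least one")
  expect_error(spectral_library(list(a, a)), "duplicate")
  b <- component_spectrum("b", tiny_grid(from = 401), 1:5)
  expect_error(spectral_library(list(a, b)), "shared grid.*b")
})

test_that("build_design_matrix lays out components as columns in order", {
  g <- wavelength_grid(c(400, 500, 600))
  one <- spectral_library(list(component_spectrum("only", g, c(1, 2, 3))))
  X1 <- build_design_matrix(one)
  expect_equal(dim(X1), c(3L, 1L))
  expect_equal(as.numeric(X1), c(1, 2, 3))

  lib <- make_default_library()
  X <- build_design_matrix(lib)
  expect_equal(dim(X), c(801L, 8L))
  expect_equal(colnames(X), names(lib$components))
  # per-column oracle: column means equal each component's mean value
  expect_equal(
    colMeans(X),
    vapply(lib$components, function(s) mean(s$values), numeric(1))
  )
})

test_that("permuting library components permutes design-matrix columns identically", {
  lib <- make_default_library()
  perm <- c(5, 1, 8, 2, 7, 3, 6, 4)
  plib <- spectral_library(lib$components[perm])
  bare <- function(m) matrix(as.numeric(m), nrow = nrow(m))
  expect_equal(
    bare(build_design_matrix(plib)),
    bare(build_design_matrix(lib)[, perm])
  )
})

test_that("duplicate columns trigger a collinearity warning but still build", {
  g <- tiny_grid()
  a <- component_spectrum("a", g, c(1, 2, 3, 4, 5))
  b <- component_spectrum("b", g, c(1, 2, 3, 4, 5))
  expect_warning(X <- build_design_matrix(spectral_library(list(a, b))),
    "collinear"
  )
  expect_equal(dim(X), c(5L, 2L))
  expect_true(attr(X, "collinearity_warning"))
  expect_lt(attr(X, "rank"), 2L)
})
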