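test_that("solve_weights recovers exact solutions in trivial geometries", {
  x <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "only"))
  w <- solve_weights(x, 3.7 * x[, 1])
  expect_equal(as.numeric(w), 3.7)
  expect_named(w, "only")

  u <- c(1, 0, 0, 1)
  v <- c(0, 1, -1, 0) # orthogonal to u
  X <- cbind(u = u, v = v)
  w2 <- suppressWarnings(solve_weights(X, 2 * u + 5 * v))
  expect_equal(as.numeric(w2), c(2, 5))
})

test_that("solve_weights matches pseudoinverse and normal-equations oracles", {
  set.seed(23)
  X <- matrix(runif(801 * 8), 801, 8)
  w_star <- runif(8, 0, 10)
  y <- X %*% w_star
  w <- solve_weights(X, y)
  expect_equal(as.numeric(w), w_star, tolerance = 1e-8)
  expect_equal(as.numeric(w), pinv_solve(X, y), tolerance = 1e-10)
  yn <- y + rnorm(801, 0, 0.1)
  wn <- suppressWarnings(solve_weights(X, yn))
  expect_equal(as.numeric(wn), normal_equations_solve(X, yn),
    tolerance = 1e-8
  )
  # residual orthogonality at the solution
  r <- yn - X %*% as.numeric(wn)
  expect_lt(
    max(abs(t(X) %*% r)) / max(abs(t(X) %*% yn)), 1e-8
  )
})

test_that("solve_weights flags rank deficiency and returns the minimum-norm solution", {
  set.seed(29)
  x1 <- runif(50)
  X <- cbind(a = x1, b = 2 * x1) # exactly collinear
  y <- 3 * x1
  expect_warning(w <- solve_weights(X, y), "rank deficient")
  expect_true(attr(w, "rank_deficient"))
  expect_equal(as.numeric(w), pinv_solve(X, y), tolerance = 1e-10)
  expect_error(solve_weights(X, y[-1]), "dimension mismatch")
})

test_that("negative OLS weights warn and point to the constrained fit", {
  set.seed(31)
  X <- matrix(runif(100 * 2), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- X %*% c(1, -0.5)
  expect_warning(solve_weights(X, y), "nonneg = TRUE")
  wc <- pracma::lsqnonneg(X, as.numeric(y))$x
  expect_equal(as.numeric(solve_weights(X, y, nonneg = TRUE)), wc)
  expect_true(all(as.numeric(solve_weights(X, y, nonneg = TRUE)) >= 0))
})

test_that("column scaling equivariance: weight scales inversely, reconstruction unchanged", {
  set.seed(37)
  lib <- toy_library()
  X <- build_design_matrix(lib)
  y <- as.numeric(X %*% c(2, 3)) + rnorm(nrow(X), 0, 0.01)
  w <- solve_weights(X, y)
  X2 <- X
  X2[, 2] <- X2[, 2] * 10
  w2 <- solve_weights(X2, y)
  expect_equal(as.numeric(w2), as.numeric(w) / c(1, 10), tolerance = 1e-8)
  expect_equal(as.numeric(X2 %*% as.numeric(w2)),
    as.numeric(X %*% as.numeric(w)),
    tolerance = 1e-8
  )
})

test_that("reconstruct returns basis components and closes with solve_weights", {
  lib <- toy_library()
  g <- lib$grid
  zero <- reconstruct(lib, c(alpha = 0, beta = 0))
  expect_equal(zero$mua, rep(0, length(g)))
  basis <- reconstruct(lib, c(alpha = 1, beta = 0))
  expect_equal(basis$mua, lib$components$alpha$values)

  X <- build_design_matrix(lib)
  w_star <- c(1.5, 4.2)
  y <- as.numeric(X %*% w_star)
  w <- solve_weights(X, y)
  expect_equal(reconstruct(lib, w)$mua, y, tolerance = 1e-8)
})

test_that("reconstruct validates names/order and annotates negative clipping", {
  lib <- toy_library()
  expect_error(reconstruct(lib, c(beta = 1, alpha = 1)), "names/order")
  expect_error(reconstruct(lib, c(alpha = 1)), "2 library components")
  neg <- suppressWarnings(reconstruct(lib, c(alpha = -1, beta = 0)))
  expect_true(all(neg$mua >= 0))
  expect_gt(length(neg$clipped_points), 0)
  expect_true(any(attr(neg, "raw") < 0))
})

test_that("check_within_sd computes the envelope fraction against brute force", {
  set.seed(41)
  g <- default_grid(step_nm = 10)
  members <- lapply(1:6, function(i) {
    absorption_spectrum(g, 5 + runif(length(g), 0, 2))
  })
  ens <- ensemble_stats(members, "h")
  expect_equal(check_within_sd(ens, ens$mean)$fraction, 1)
  above <- absorption_spectrum(g, ens$mean$mua + 2 * ens$sd)
  expect_equal(check_within_sd(ens, above)$fraction, 0)

  recon <- absorption_spectrum(g, ens$mean$mua + runif(length(g), -1, 1))
  got <- check_within_sd(ens, recon)
  brute <- vapply(seq_along(g), function(i) {
    d <- abs(ens$mean$mua[i] - recon$mua[i])
    if (ens$sd[i] > 0) d <= ens$sd[i] else d <= 1e-9
  }, logical(1))
  expect_equal(got$mask, brute)
  expect_equal(got$fraction, mean(brute))
  expect_error(
    check_within_sd(ensemble_stats(members[1], "h"), recon),
    "fewer than 2"
  )
})

test_that("fit_condition recovers ground truth on a noiseless synthetic cohort", {
  lib <- make_default_library()
  sc <- synthetic_scenario(101, n_samples = 3, noise_sd = 0)
  coh <- generate_cohort(sc, lib)
  res <- fit_condition(coh$measurements, lib)
  expect_s3_class(res, "unmixing_result")
  expect_equal(as.numeric(res$weights), as.numeric(coh$truth$weights),
    tolerance = 1e-6
  )
  expect_lt(res$rmse, 1e-10)
  expect_equal(res$condition, "synthetic")
  expect_s3_class(res$concentrations, "concentration_table")
  expect_equal(sum(res$concentrations$concentration_pct), 100, tolerance = 1e-9)
})

test_that("fit_condition handles a single-sample cohort with SD check skipped", {
  lib <- make_default_library()
  sc <- synthetic_scenario(7, n_samples = 1, noise_sd = 0)
  coh <- generate_cohort(sc, lib)
  res <- fit_condition(coh$measurements, lib)
  expect_true(res$ensemble$single_member)
  expect_true(is.na(res$within_sd_fraction))
  expect_error(fit_condition(list(), lib), "no measurements")
})

test_that("fit_condition reproduces the published concentration table from printed weights", {
  # inject the published healthy weights through the pipeline's conversion stage
  lib <- make_default_library()
  w <- reference_weights("healthy")
  ct <- weights_to_concentrations(w, 77, condition = "healthy")
  expect_equal(
    round(ct$concentration_pct, 2),
    c(77.00, 0.09, 0.51, 1.32, 17.53, 3.38, 0.16, 0.01)
  )
})

test_that("weight recovery error decreases as noise goes to zero", {
  lib <- make_default_library()
  w_true <- scale_weights_to_physical(reference_weights("healthy"), lib)
  mae <- vapply(c(1e-1, 1e-2, 1e-3), function(ns) {
    errs <- vapply(1:3, function(seed) {
      coh <- generate_cohort(
        synthetic_scenario(seed, n_samples = 5, noise_sd = ns), lib
      )
      res <- suppressWarnings(fit_condition(coh$measurements, lib))
      mean(abs(as.numeric(res$weights) - as.numeric(w_true)))
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(mae) < 0)) # monotone decreasing over sigma 1e-1..1e-3
})
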