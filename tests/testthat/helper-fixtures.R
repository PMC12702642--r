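# small in-code fixtures shared across the suite

tiny_grid <- function(n = 5, from = 400, to = 500) {
  wavelength_grid(seq(from, to, length.out = n))
}

# two-component toy library with non-overlapping bands on a coarse grid
toy_library <- function(n = 11) {
  g <- wavelength_grid(seq(400, 600, length.out = n))
  a <- component_spectrum("alpha", g, exp(-((as.numeric(g) - 420)^2) / 800))
  b <- component_spectrum("beta", g, exp(-((as.numeric(g) - 580)^2) / 800))
  spectral_library(list(normalize_unit_range(a), normalize_unit_range(b)))
}

# independent pseudoinverse oracle (SVD-based), coded apart from solve_weights
pinv_solve <- function(X, y) {
  sv <- svd(X)
  tol <- max(sv$d) * max(dim(X)) * .Machine$double.eps
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  as.numeric(sv$v %*% (dinv * crossprod(sv$u, y)))
}

# literal normal-equations formula, the textbook form of the estimator
normal_equations_solve <- function(X, y) {
  as.numeric(solve(t(X) %*% X) %*% t(X) %*% y)
}

random_measurement <- function(grid, thickness_cm = 0.05, id = "s1",
                               condition = "synthetic") {
  n <- length(grid)
  Tt <- runif(n, 0.2, 0.5)
  Rt <- runif(n, 0.1, 0.4)
  sample_measurement(id, condition, grid, Tt, Rt, thickness_cm)
}
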