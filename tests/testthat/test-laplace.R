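test_that("constant Dirichlet data gives a constant harmonic solution", {
  f <- matrix(0.3, 11, 11)
  f[4:8, 4:8] <- 0.9  # values inside the mask are irrelevant
  m <- matrix(FALSE, 11, 11); m[4:8, 4:8] <- TRUE
  T_img <- solve_tissue(f, m)
  expect_equal(T_img[m], rep(0.3, sum(m)), tolerance = 1e-12)
  expect_identical(T_img[!m], f[!m])  # untouched outside
})

test_that("a single unknown equals the mean of its four neighbors", {
  f <- matrix(0, 3, 3)
  f[1, 2] <- 0.2; f[2, 1] <- 0.4; f[2, 3] <- 0.6; f[3, 2] <- 0.8
  m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE
  expect_equal(solve_tissue(f, m)[2, 2], 0.5, tolerance = 1e-12)
})

test_that("affine fields are reproduced exactly on a disk mask", {
  n <- 21
  rows <- matrix(rep(seq_len(n), times = n), n, n)
  cols <- matrix(rep(seq_len(n), each = n), n, n)
  f <- 0.1 + 0.02 * (cols - 1) + 0.03 * (rows - 1)
  f <- f / max(f)  # keep in [0,1]; still affine
  m <- disk_mask(n, 7)
  T_img <- solve_tissue(f, m)
  expect_lt(max(abs(T_img - f)), 1e-9)  # affine => discrete-harmonic
})

test_that("exact solutions match a 1e-12 Gauss-Seidel oracle", {
  set.seed(7)
  shapes <- list(
    disk_mask(15, 5),
    {m <- matrix(FALSE, 18, 18); m[2:6, 2:6] <- TRUE; m[10:16, 8:15] <- TRUE; m},
    {m <- matrix(FALSE, 12, 20); m[1:5, 1:6] <- TRUE; m},          # touches border
    matrix(runif(20 * 20) < 0.4, 20, 20))
  for (m in shapes) {
    f <- matrix(runif(length(m), 0.05, 0.95), nrow(m), ncol(m))
    T_pkg <- solve_tissue(f, m)
    T_gs <- gs_oracle(f, m, tol = 1e-12)
    expect_lt(max(abs(T_pkg - T_gs)), 1e-8)
  }
})

test_that("solutions respect the maximum principle on every component", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(runif(24 * 24) < 0.35, 24, 24)
    if (!any(m)) next
    f <- matrix(runif(24 * 24), 24, 24)
    T_img <- solve_tissue(f, m)
    expect_no_interior_extremum(T_img, m, f)
  }
})

test_that("the solve commutes with 90-degree rotation of the problem", {
  set.seed(3)
  f <- matrix(runif(15 * 19, 0.1, 0.9), 15, 19)
  m <- matrix(FALSE, 15, 19); m[4:11, 5:15] <- TRUE; m[13, 2] <- TRUE
  rot <- function(x) t(x)[ncol(x):1, , drop = FALSE]
  T1 <- rot(solve_tissue(f, m))
  T2 <- solve_tissue(rot(f), rot(m) > 0)
  expect_equal(T1, T2, tolerance = 1e-12)
})

test_that("the solve is linear in the boundary data (pre-clamp)", {
  set.seed(9)
  m <- disk_mask(17, 6)
  f1 <- matrix(runif(17 * 17, 0, 0.4), 17, 17)
  f2 <- matrix(runif(17 * 17, 0, 0.4), 17, 17)
  a <- 0.6; b <- 0.3  # combination stays in [0,1], clamp inactive
  Tc <- solve_tissue(a * f1 + b * f2, m)
  expect_equal(Tc, a * solve_tissue(f1, m) + b * solve_tissue(f2, m),
               tolerance = 1e-9)
})

test_that("residual_report isolates a single perturbed pixel", {
  n <- 9
  m <- matrix(FALSE, n, n); m[3:7, 3:7] <- TRUE
  f <- matrix(0.5, n, n)
  T_img <- solve_tissue(f, m)       # constant, residual 0
  expect_equal(max(residual_report(T_img, m)), 0, tolerance = 1e-12)
  delta <- 0.01
  T_img[5, 5] <- T_img[5, 5] + delta
  expect_equal(max(residual_report(T_img, m)), 4 * delta, tolerance = 1e-12)
  # empty interior: a 1-pixel component reports residual 0
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  expect_equal(residual_report(matrix(0.2, 5, 5), m1), 0)
})

test_that("multiple components are solved independently", {
  f <- matrix(0.2, 12, 12)
  f[, 7:12] <- 0.8
  m <- matrix(FALSE, 12, 12)
  m[3:5, 2:4] <- TRUE    # inside the 0.2 half
  m[8:10, 8:10] <- TRUE  # inside the 0.8 half
  T_img <- solve_tissue(f, m)
  expect_equal(T_img[4, 3], 0.2, tolerance = 1e-10)
  expect_equal(T_img[9, 9], 0.8, tolerance = 1e-10)
})

test_that("the tissue ceiling clamp engages near saturated boundaries", {
  f <- matrix(1, 7, 7)   # all-bright image
  m <- matrix(FALSE, 7, 7); m[3:5, 3:5] <- TRUE
  cfg <- solver_config(epsilon = 1e-4)
  T_img <- solve_tissue(f, m, cfg)
  expect_lte(max(T_img[m]), 1 - 1e-4)
})

test_that("fast mode approximates the exact solution and reports residuals", {
  ph <- generate_phantom(phantom_spec(height = 96, width = 96,
                                      tissue_kind = "harmonic_in_mask",
                                      n_bones = 2, seed = 31))
  T_exact <- solve_tissue(ph$f, ph$M_true)
  T_fast <- solve_tissue(ph$f, ph$M_true, solver_config(mode = "fast"))
  # approximate path: bounded error, no exactness claim
  expect_lt(max(abs(T_fast - T_exact)), 0.1)
  expect_true(all(is.finite(residual_report(T_fast, ph$M_true))))
  expect_identical(T_fast[!ph$M_true], ph$f[!ph$M_true])
})
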