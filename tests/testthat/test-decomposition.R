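test_that("compute_alpha follows the reciprocal-maximum-ratio definition", {
  T_img <- matrix(0.5, 5, 5)
  f <- T_img
  f[2, 2] <- 1        # ratio (1 - 0.5)/(1 - 0.5) = 1
  expect_equal(compute_alpha(f, T_img), 1)
  f[2, 2] <- 0.75     # ratio 0.25/0.5 = 0.5
  expect_equal(compute_alpha(f, T_img), 2)
  expect_error(compute_alpha(T_img, T_img),
               class = "btd_error_no_bone_signal")
})

test_that("alpha is at least 1 for any valid input pair", {
  set.seed(101)
  for (i in 1:50) {
    T_img <- matrix(runif(36, 0, 0.9), 6, 6)
    f <- pmin(T_img + matrix(runif(36, 0, 1), 6, 6) * (1 - T_img), 1)
    if (max((f - T_img) / (1 - T_img)) < 1e-6) next
    expect_gte(compute_alpha(f, T_img), 1)
  }
})

test_that("compute_bone applies the closed form and normalizes to max 1", {
  f <- matrix(0.8, 4, 4); T_img <- matrix(0.6, 4, 4)
  expect_equal(compute_bone(f, T_img, 1.5)[1, 1], 0.75)  # 1.5 * 0.2/0.4
  expect_equal(compute_bone(T_img, T_img, 2), matrix(0, 4, 4))  # f = T => B = 0
  set.seed(55)
  T_img <- matrix(runif(64, 0, 0.8), 8, 8)
  f <- pmin(T_img + matrix(runif(64, 0.05, 0.3), 8, 8), 1)
  a <- compute_alpha(f, T_img)
  expect_equal(max(compute_bone(f, T_img, a)), 1, tolerance = 1e-12)
})

test_that("recompose inverts the bone formula and honors the degenerate limits", {
  T_img <- matrix(runif(49, 0, 0.8), 7, 7)
  expect_equal(recompose(matrix(0, 7, 7), T_img, 2), T_img)      # pure tissue
  B <- matrix(runif(49), 7, 7)
  expect_equal(recompose(B, matrix(0, 7, 7), 2.5), B / 2.5)      # pure bone
  f <- pmin(T_img + matrix(runif(49, 0, 0.2), 7, 7), 1)          # f >= T
  a <- compute_alpha(f, T_img)
  expect_equal(recompose(compute_bone(f, T_img, a), T_img, a), f,
               tolerance = 1e-12)
})

test_that("nonlinear tissue estimation dominates the linear baseline", {
  f <- matrix(0.8, 3, 3); B <- matrix(0.75, 3, 3)
  expect_equal(tissue_from_bone(f, B, 1.5)[1, 1], 0.6)  # (0.8-0.5)/(1-0.5)
  expect_equal(tissue_from_bone(f, matrix(0, 3, 3), 2), f)  # B = 0 identity
  expect_error(tissue_from_bone(f, matrix(1, 3, 3), 1),
               class = "btd_error_bad_input")  # B/alpha at the pole
  # dominance on the open strip 0 < b < 1, f <= 1
  g <- expand.grid(f = seq(0.01, 0.99, length.out = 45),
                   b = seq(0.01, 0.95, length.out = 45))
  fm <- matrix(g$f, 45, 45); bm <- matrix(g$b, 45, 45)
  expect_true(all(tissue_from_bone(fm, bm, 1) >= linear_tissue(fm, bm)))
})

test_that("linear_tissue is a clipped pixelwise difference", {
  f <- matrix(c(0.8, 0.2, 1, 0.5), 2, 2)
  fb <- matrix(c(0.3, 0.5, 0, 0.5), 2, 2)
  expect_equal(linear_tissue(f, fb),
               matrix(c(0.5, 0, 1, 0), 2, 2))
  expect_equal(linear_tissue(f, matrix(0, 2, 2)), f)
  expect_equal(linear_tissue(f, f), matrix(0, 2, 2))
})

test_that("contrast report captures the scaling and tie conventions", {
  # T = 0: B = alpha * f, gradients scale by alpha >= 1
  set.seed(77)
  f <- matrix(runif(100, 0.1, 0.45), 10, 10)
  a <- 2
  rep1 <- contrast_report(f, a * f, matrix(0, 10, 10),
                          matrix(TRUE, 10, 10))
  expect_equal(rep1$fraction_enhanced, 1.0)
  # constant image: all gradients zero, ties count as enhanced
  fc <- matrix(0.4, 8, 8)
  rep2 <- contrast_report(fc, fc, fc, matrix(TRUE, 8, 8))
  expect_equal(rep2$fraction_enhanced, 1.0)
  # nothing passes an impossible flatness filter: NA, not an error
  rep3 <- contrast_report(f, a * f, f, matrix(TRUE, 10, 10),
                          flat_threshold = -1)
  expect_true(is.na(rep3$fraction_enhanced))
  expect_equal(rep3$n_evaluated, 0L)
})

test_that("decompose recovers harmonic phantoms and keeps its invariants", {
  ph <- generate_phantom(phantom_spec(height = 72, width = 72,
                                      tissue_kind = "harmonic_in_mask",
                                      alpha_true = 2.3, n_bones = 2,
                                      seed = 17))
  dec <- decompose(ph$f, ph$M_true)
  rec <- evaluate_recovery(ph, dec)
  expect_lte(rec$max_err_T, 1e-6)
  expect_lte(rec$alpha_rel_error, 1e-6)
  expect_lte(rec$max_err_B, 1e-5)
  expect_gte(dec$alpha, 1)
  expect_equal(max(dec$bone), 1, tolerance = 1e-9)
  expect_true(all(dec$bone[!ph$M_true] == 0))   # B = 0 where T = f
  expect_lte(max(abs(recompose(dec$bone, dec$tissue, dec$alpha) - ph$f)),
             1e-10)
})

test_that("a bone-free image raises the no-bone-signal error", {
  # an affine field is discrete-harmonic, so the solve reproduces it
  # inside any mask: f = T everywhere means no bones
  n <- 48
  rows <- matrix(rep(seq_len(n), times = n), n, n)
  cols <- matrix(rep(seq_len(n), each = n), n, n)
  f <- (0.1 + 0.004 * rows + 0.006 * cols)
  m <- matrix(FALSE, n, n); m[10:20, 10:20] <- TRUE
  expect_error(decompose(f, m), class = "btd_error_no_bone_signal")
})

test_that("the T <= f clamp guarantees nonnegative bone on smooth phantoms", {
  ph <- generate_phantom(phantom_spec(height = 64, width = 64,
                                      tissue_kind = "smooth", alpha_true = 1.5,
                                      n_bones = 2, seed = 23))
  dec <- decompose(ph$f, ph$M_true)
  expect_true(all(dec$tissue <= ph$f + 1e-15))
  expect_true(all(dec$bone >= 0))
  expect_true(is.finite(dec$diagnostics$clamped_pixels))
})
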