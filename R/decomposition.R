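#' Compute the global contrast parameter alpha
#'
#' With the bone maximum normalized to one, alpha is the reciprocal of the
#' largest bone ratio:
#' \deqn{\alpha = 1 / \max_p \frac{\max(0, f(p) - T(p))}{1 - T(p)}.}
#' Because `f <= 1`, the ratio never exceeds 1 and therefore `alpha >= 1`
#' always; alpha linearly rescales the bone term while preserving the
#' linear intensity-dose relationship.
#'
#' @param f radiograph matrix.
#' @param T_img tissue matrix with `T <= 1 - epsilon` everywhere.
#' @param eps_alpha if the largest ratio is below this, the image carries
#'   no bone signal (`f` is tissue everywhere) and an error of class
#'   `btd_error_no_bone_signal` is raised.
#' @return scalar alpha, guaranteed `>= 1`.
#' @export
compute_alpha <- function(f, T_img, eps_alpha = 1e-6) {
  stopifnot(identical(dim(f), dim(T_img)))
  r_max <- max(bone_ratio(f, T_img))
  if (r_max < eps_alpha)
    btd_stop("btd_error_no_bone_signal",
             "no bone signal: f and T agree everywhere (max ratio %.3g)", r_max)
  1 / r_max
}

#' Compute the bone image
#'
#' `B(p) = alpha * max(0, f(p) - T(p)) / (1 - T(p))`. When `alpha` comes
#' from [compute_alpha()] on the same pair, `max(B) = 1` and
#' `0 <= B <= 1`; `B = 0` wherever `f = T` (in particular everywhere
#' outside the mask, where `T` equals `f` by construction).
#'
#' @param f radiograph matrix.
#' @param T_img tissue matrix, `T <= 1 - epsilon`.
#' @param alpha scalar `>= 1`.
#' @return bone image matrix.
#' @export
compute_bone <- function(f, T_img, alpha) {
  stopifnot(identical(dim(f), dim(T_img)), alpha >= 1)
  alpha * bone_ratio(f, T_img)
}

# (f - T)/(1 - T) with negative numerators clamped to 0 and the 0/0 case
# at saturated pixels (f = T = 1, possible outside the mask where T is
# not epsilon-clamped) defined as 0: no tissue-free residual, no bone.
bone_ratio <- function(f, T_img) {
  num <- pmax(0, f - T_img)
  r <- matrix(0, nrow(f), ncol(f))
  pos <- num > 0
  r[pos] <- num[pos] / (1 - T_img[pos])
  r
}

#' Recompose a radiograph from its components
#'
#' The forward composition model:
#' `f(p) = (1/alpha) * B(p) * (1 - T(p)) + T(p)`. With `B = 0` the
#' observation is pure tissue; with `T = 0` it is `B / alpha`, pure bone.
#' Values are snapped into `[0, 1]` only when they fall outside by less
#' than `1e-12` (floating-point dust), never clipped otherwise.
#'
#' @param B bone image matrix.
#' @param T_img tissue matrix.
#' @param alpha scalar `> 0`.
#' @return radiograph matrix.
#' @export
recompose <- function(B, T_img, alpha) {
  stopifnot(identical(dim(B), dim(T_img)), alpha > 0)
  f <- B * (1 - T_img) / alpha + T_img
  f[f < 0 & f > -1e-12] <- 0
  f[f > 1 & f < 1 + 1e-12] <- 1
  f
}

#' Tissue from a known bone image (nonlinear suppression)
#'
#' Inverts the composition model for `T` given `f` and `B`:
#' `T = (f - B/alpha) / (1 - B/alpha)`, clipped to `[0, 1 - eps]`. This is
#' the nonlinear counterpart of the linear subtraction [linear_tissue()];
#' wherever `0 < B/alpha < 1` and `f <= 1` it suppresses bone at least as
#' strongly in the sense `tissue_from_bone >= linear_tissue`.
#'
#' @param f radiograph matrix.
#' @param B bone image matrix.
#' @param alpha scalar `>= 1`.
#' @param eps denominator guard; pixels with `B/alpha >= 1 - eps` are
#'   degenerate and raise an error listing their positions.
#' @return tissue matrix.
#' @export
tissue_from_bone <- function(f, B, alpha, eps = 1e-6) {
  stopifnot(identical(dim(f), dim(B)), alpha > 0)
  b <- B / alpha
  bad <- which(b >= 1 - eps)
  if (length(bad)) {
    pos <- arrayInd(head(bad, 5L), dim(f))
    btd_stop("btd_error_bad_input",
             "%d degenerate pixels with B/alpha >= 1 - eps (first at row %d, col %d)",
             length(bad), pos[1, 1], pos[1, 2])
  }
  pmin(pmax((f - b) / (1 - b), 0), 1 - eps)
}

#' Linear bone-suppression baseline
#'
#' The classical additive model `f = f_tissue + f_bone`, inverted as a
#' pixelwise difference `f - f_bone`, clipped to `[0, 1]`.
#'
#' @param f radiograph matrix.
#' @param f_bone bone layer on the same scale as `f` (for comparison with
#'   the nonlinear model, pass `B / alpha`).
#' @return tissue matrix.
#' @export
linear_tissue <- function(f, f_bone) {
  stopifnot(identical(dim(f), dim(f_bone)))
  pmin(pmax(f - f_bone, 0), 1)
}

# Forward-difference gradient magnitude; differences at the last row /
# column are zero-padded so no fictitious edge is created there.
grad_mag <- function(x) {
  h <- nrow(x); w <- ncol(x)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, -w] <- x[, -1] - x[, -w]
  gy[-h, ] <- x[-1, ] - x[-h, ]
  sqrt(gx^2 + gy^2)
}

#' Contrast-enhancement report
#'
#' Quantifies the guarantee that the bone image has at least the input's
#' contrast wherever the tissue is locally flat: since
#' `grad B = alpha * [grad f / (1-T) - (1-f) grad T / (1-T)^2]` and
#' `alpha / (1-T) >= 1`, pixels with `grad T ~ 0` satisfy
#' `|grad B| >= |grad f|`. Gradients are forward differences
#' (zero-padded at the far edges); evaluation is restricted to mask
#' pixels with `|grad T| <= flat_threshold`, and ties count as enhanced.
#'
#' @param f,B,T_img decomposition inputs/outputs, same shape.
#' @param mask logical matrix.
#' @param flat_threshold gradient-magnitude cutoff (intensity per pixel)
#'   defining "locally flat tissue". Default `1e-3`.
#' @return list of class `btd_contrast_report`: `fraction_enhanced`
#'   (NA when no pixel passes the flatness filter), `n_evaluated`,
#'   `flat_tissue_threshold`, and the three gradient-magnitude matrices.
#' @export
contrast_report <- function(f, B, T_img, mask, flat_threshold = 1e-3) {
  stopifnot(identical(dim(f), dim(B)), identical(dim(f), dim(T_img)),
            identical(dim(f), dim(mask)))
  gf <- grad_mag(f); gb <- grad_mag(B); gt <- grad_mag(T_img)
  eval_set <- mask & gt <= flat_threshold
  n <- sum(eval_set)
  frac <- if (n == 0L) NA_real_ else mean(gb[eval_set] >= gf[eval_set])
  structure(list(fraction_enhanced = frac,
                 n_evaluated = n,
                 flat_tissue_threshold = flat_threshold,
                 grad_f = gf, grad_B = gb, grad_T = gt),
            class = "btd_contrast_report")
}

#' @export
print.btd_contrast_report <- function(x, ...) {
  cat(sprintf(
    "Contrast report: %s of %d flat-tissue pixels (|grad T| <= %g) have |grad B| >= |grad f|\n",
    ifelse(is.na(x$fraction_enhanced), "NA",
           sprintf("%.1f%%", 100 * x$fraction_enhanced)),
    x$n_evaluated, x$flat_tissue_threshold))
  invisible(x)
}

#' Bone and tissue decomposition of a radiograph
#'
#' The full pipeline: solve the Laplace-Dirichlet problem for the tissue
#' image inside the mask, clamp `T <= f` pixelwise (the harmonic
#' interpolant can overshoot `f` at isolated pixels; the clamp guarantees
#' `B >= 0` and an exact recomposition), then compute `alpha` and the
#' bone image in closed form.
#'
#' @param f radiograph matrix (values in `[0, 1]`, bones bright).
#' @param mask logical matrix covering the bones (from [estimate_mask()],
#'   [validate_user_mask()] or a phantom's ground truth).
#' @param cfg a [solver_config()].
#' @param flat_threshold passed to [contrast_report()].
#' @param eps_alpha passed to [compute_alpha()].
#' @return object of class `btd_decomposition`: list with `tissue`,
#'   `bone`, `alpha`, `mask`, and `diagnostics` (`max_residual` of the
#'   pre-clamp solution, `clamped_pixels`, `contrast` report).
#' @export
decompose <- function(f, mask, cfg = solver_config(),
                      flat_threshold = 1e-3, eps_alpha = 1e-6) {
  f <- as_radiograph(f)
  if (!any(mask))
    btd_stop("btd_error_empty_mask", "mask is empty")
  T_img <- solve_tissue(f, mask, cfg)
  res <- residual_report(T_img, mask)
  clamped <- sum(T_img > f)
  T_img <- pmin(T_img, f)           # assumption T <= f
  alpha <- compute_alpha(f, T_img, eps_alpha)
  B <- compute_bone(f, T_img, alpha)
  ctr <- contrast_report(f, B, T_img, mask, flat_threshold)
  structure(list(
    tissue = T_img, bone = B, alpha = alpha, mask = mask,
    diagnostics = list(max_residual = if (length(res)) max(res) else 0,
                       residual_per_component = res,
                       clamped_pixels = clamped,
                       contrast = ctr)),
    class = "btd_decomposition")
}

#' @export
print.btd_decomposition <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("Bone-tissue decomposition (%d x %d)\n",
              nrow(x$tissue), ncol(x$tissue)))
  cat(sprintf("  alpha            : %.6g\n", x$alpha))
  cat(sprintf("  max(B)           : %.9g\n", max(x$bone)))
  cat(sprintf("  mask pixels      : %d\n", sum(x$mask)))
  cat(sprintf("  max residual     : %.3g\n", d$max_residual))
  cat(sprintf("  clamped pixels   : %d\n", d$clamped_pixels))
  cat(sprintf("  fraction enhanced: %s\n",
              ifelse(is.na(d$contrast$fraction_enhanced), "NA",
                     sprintf("%.4f", d$contrast$fraction_enhanced))))
  invisible(x)
}
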