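#' Phantom specification
#'
#' Parameters of the synthetic radiograph generator. The phantom runs the
#' composition model forward: a smooth tissue field, a compactly
#' supported bone field with maximum exactly 1, a known `alpha_true >= 1`,
#' and `f = (1/alpha) B (1 - T) + T` plus optional sensor noise. All four
#' model assumptions (`T <= f`, `T < 1`, smooth `T`, `max(B) = 1`) hold
#' by construction at `noise_sigma = 0` and are machine-checked at
#' generation time.
#'
#' @param height,width raster size in pixels.
#' @param alpha_true ground-truth contrast parameter, `>= 1`.
#' @param tissue_kind `"smooth"` (low-frequency cosine field),
#'   `"harmonic_in_mask"` (the field is replaced inside the mask by the
#'   discrete harmonic interpolant of its own boundary values, making
#'   recovery by the pipeline exact up to solver tolerance), or
#'   `"constant_in_mask"` (replaced by the boundary mean on the mask and
#'   its boundary ring, giving `grad T = 0` exactly at every mask pixel).
#' @param tissue_max peak tissue intensity, in `[0, 1)`; soft tissue is
#'   dimmer than bone in the bones-bright convention. Default 0.55.
#' @param n_bones number of elliptical bone blobs (0 gives a bone-free
#'   image on which [decompose()] raises `no bone signal`).
#' @param bone_texture_amp relative amplitude of the cosine ripple added
#'   to bone interiors so gradient-based contrast checks are
#'   non-degenerate. Default 0.2.
#' @param noise_sigma additive Gaussian sensor noise on `f` only (ground
#'   truth stays noiseless). Default 0.
#' @param seed integer seed; all randomness flows from it.
#' @return list of class `btd_phantom_spec`.
#' @export
phantom_spec <- function(height = 128, width = 128, alpha_true = 2,
                         tissue_kind = c("smooth", "harmonic_in_mask",
                                         "constant_in_mask"),
                         tissue_max = 0.55, n_bones = 2,
                         bone_texture_amp = 0.2, noise_sigma = 0,
                         seed = 1) {
  tissue_kind <- match.arg(tissue_kind)
  stopifnot(height >= 16, width >= 16, alpha_true >= 1,
            tissue_max >= 0, tissue_max < 1, n_bones >= 0,
            bone_texture_amp >= 0, bone_texture_amp <= 1, noise_sigma >= 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 alpha_true = alpha_true, tissue_kind = tissue_kind,
                 tissue_max = tissue_max, n_bones = as.integer(n_bones),
                 bone_texture_amp = bone_texture_amp,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "btd_phantom_spec")
}

#' Generate a synthetic radiograph with known ground truth
#'
#' Builds `T_true` as a sum of four low-frequency cosine modes (random
#' orientations, frequencies of 0.25-1 cycles across the field of view,
#' random phases) rescaled to `[0, tissue_max]` -- soft tissue varies on
#' the scale of the whole anatomy, so sub-cycle frequencies are the
#' realistic regime. `B_true` is a union of random ellipses with a smooth
#' `1 - rho^2` interior profile modulated by a cosine ripple of relative
#' amplitude `bone_texture_amp` (wavelength 4-12 px), rescaled so its
#' global maximum is exactly 1. `M_true` is the bone support dilated by
#' 3 px, so the Dirichlet ring `f = T_true` is bone-free. The observed
#' image is the forward composition plus optional noise, clipped to
#' `[0, 1]`.
#'
#' Ellipses are placed with a margin keeping `M_true` and its boundary
#' inside the raster; a raster too small for the sampled axes raises an
#' error. Samples are fully determined by `spec$seed`; the caller's RNG
#' state is left untouched.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `btd_phantom`: `f`, `T_true`, `B_true`,
#'   `alpha_true`, `M_true`, `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "btd_phantom_spec"))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(spec$seed, kind = "Mersenne-Twister")

  h <- spec$height; w <- spec$width
  X <- matrix(rep(seq_len(w) - 1L, each = h), h, w) / w
  Y <- matrix(rep(seq_len(h) - 1L, times = w), h, w) / h

  # smooth tissue field: 4 cosine modes
  T_true <- matrix(0, h, w)
  for (k in 1:4) {
    fr <- runif(1, 0.25, 1.0)
    th <- runif(1, 0, 2 * pi)
    ph <- runif(1, 0, 2 * pi)
    a <- runif(1, 0.3, 1)
    T_true <- T_true + a * cos(2 * pi * fr * (cos(th) * X + sin(th) * Y) + ph)
  }
  rng <- range(T_true)
  T_true <- if (spec$tissue_max > 0 && rng[2] > rng[1]) {
    (T_true - rng[1]) / (rng[2] - rng[1]) * spec$tissue_max
  } else {
    matrix(0, h, w)
  }

  # elliptical bone blobs with interior texture
  B_true <- matrix(0, h, w)
  if (spec$n_bones > 0) {
    rows <- matrix(rep(seq_len(h), times = w), h, w)
    cols <- matrix(rep(seq_len(w), each = h), h, w)
    for (k in seq_len(spec$n_bones)) {
      ax_a <- runif(1, 0.08, 0.18) * min(h, w)
      ax_b <- runif(1, 0.08, 0.18) * min(h, w)
      margin <- ceiling(max(ax_a, ax_b)) + 5L
      if (2L * margin >= min(h, w))
        btd_stop("btd_error_phantom",
                 "raster %d x %d too small for a bone of extent %d px",
                 h, w, margin)
      cy <- runif(1, margin + 1, h - margin)
      cx <- runif(1, margin + 1, w - margin)
      th <- runif(1, 0, pi)
      dy <- rows - cy; dx <- cols - cx
      u <- (dx * cos(th) + dy * sin(th)) / ax_a
      v <- (-dx * sin(th) + dy * cos(th)) / ax_b
      base <- pmax(0, 1 - (u^2 + v^2))
      lam <- runif(1, 4, 12)
      tht <- runif(1, 0, pi)
      pht <- runif(1, 0, 2 * pi)
      ripple <- 1 + spec$bone_texture_amp *
        cos(2 * pi * (dx * cos(tht) + dy * sin(tht)) / lam + pht)
      B_true <- pmax(B_true, base * ripple)
    }
    B_true <- B_true / max(B_true)   # global maximum exactly 1
  }

  M_true <- if (any(B_true > 0)) {
    EBImage::dilate((B_true > 0) * 1, disk_kernel(3)) > 0
  } else {
    matrix(FALSE, h, w)
  }

  if (spec$tissue_kind != "smooth" && any(M_true)) {
    if (spec$tissue_kind == "harmonic_in_mask") {
      T_true <- solve_tissue(T_true, M_true, solver_config(mode = "exact"))
    } else {
      bnd <- extract_boundary(M_true, T_true)
      cst <- mean(bnd$value)
      T_true[M_true] <- cst
      real <- !bnd$synthetic
      T_true[cbind(bnd$row[real], bnd$col[real])] <- cst
    }
  }

  f <- B_true * (1 - T_true) / spec$alpha_true + T_true
  f <- pmin(pmax(f, 0), 1)   # forward model stays in range; snaps fp dust
  if (spec$noise_sigma > 0) {
    f <- f + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
    f <- pmin(pmax(f, 0), 1)
  } else {
    # machine-check the four model assumptions on the noiseless sample
    stopifnot(all(T_true <= f + 1e-12), max(T_true) < 1,
              spec$n_bones == 0 || abs(max(B_true) - 1) == 0,
              all(B_true >= 0))
  }

  structure(list(f = f, T_true = T_true, B_true = B_true,
                 alpha_true = spec$alpha_true, M_true = M_true,
                 spec = spec),
            class = "btd_phantom")
}

#' Quantify recovery of a phantom's ground truth
#'
#' @param sample a [generate_phantom()] result.
#' @param result a [decompose()] result on `sample$f`.
#' @return list: `rmse_T`, `rmse_B` (root-mean-square errors over the
#'   whole raster), `max_err_T`, `max_err_B` (max absolute errors),
#'   `alpha_rel_error`, and `fraction_enhanced` from the decomposition's
#'   contrast report.
#' @export
evaluate_recovery <- function(sample, result) {
  stopifnot(inherits(sample, "btd_phantom"),
            inherits(result, "btd_decomposition"),
            identical(dim(sample$f), dim(result$tissue)))
  dT <- result$tissue - sample$T_true
  dB <- result$bone - sample$B_true
  list(rmse_T = sqrt(mean(dT^2)),
       rmse_B = sqrt(mean(dB^2)),
       max_err_T = max(abs(dT)),
       max_err_B = max(abs(dB)),
       alpha_rel_error = abs(result$alpha - sample$alpha_true) /
         sample$alpha_true,
       fraction_enhanced = result$diagnostics$contrast$fraction_enhanced)
}
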