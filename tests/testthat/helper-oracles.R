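# Independent brute-force oracles used to cross-check the package's
# vectorized / sparse implementations. Deliberately slow and literal.

# Gauss-Seidel relaxation of the 5-point Laplace problem, plain loops,
# iterated until the residual max-norm drops below `tol`. Off-grid
# neighbors take the edge-replicated Dirichlet value f(p), matching the
# problem definition.
gs_oracle <- function(f, mask, tol = 1e-12, max_iter = 200000L) {
  T_img <- f
  h <- nrow(f); w <- ncol(f)
  px <- which(mask, arr.ind = TRUE)
  n <- nrow(px)
  nbval <- function(r, c, p_r, p_c) {
    if (r < 1 || r > h || c < 1 || c > w) return(f[p_r, p_c])
    T_img[r, c]
  }
  for (it in seq_len(max_iter)) {
    worst <- 0
    for (k in seq_len(n)) {
      r <- px[k, 1]; c <- px[k, 2]
      s <- nbval(r - 1, c, r, c) + nbval(r + 1, c, r, c) +
        nbval(r, c - 1, r, c) + nbval(r, c + 1, r, c)
      worst <- max(worst, abs(4 * T_img[r, c] - s))
      T_img[r, c] <- s / 4
    }
    if (worst < tol) break
  }
  T_img
}

# Brute-force binary dilation by a Euclidean disk of radius r: a pixel is
# set iff some mask pixel lies within distance r.
brute_dilate <- function(mask, r) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  src <- which(mask, arr.ind = TRUE)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    d2 <- (src[, 1] - i)^2 + (src[, 2] - j)^2
    out[i, j] <- any(d2 <= r^2)
  }
  out
}

# Snap doubles to the nearest IEEE single-precision value (the float
# TIFF sample format), via a 4-byte round trip.
single_precision <- function(x) {
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4), "numeric",
               n = length(x), size = 4)
  if (is.matrix(x)) matrix(y, nrow(x), ncol(x)) else y
}

# A disk-shaped mask centered in an n x n image.
disk_mask <- function(n, radius, center = (n + 1) / 2) {
  rows <- matrix(rep(seq_len(n), times = n), n, n)
  cols <- matrix(rep(seq_len(n), each = n), n, n)
  (rows - center)^2 + (cols - center)^2 <= radius^2
}

expect_no_interior_extremum <- function(T_img, mask, f) {
  # maximum principle per 4-connected component: solution values lie
  # within the range of that component's Dirichlet data
  lab <- btd::label_components(mask)
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    bnd <- btd::extract_boundary(comp, f)
    expect_gte(min(T_img[comp]), min(bnd$value) - 1e-9)
    expect_lte(max(T_img[comp]), max(bnd$value) + 1e-9)
  }
}
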