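#' Solver configuration
#'
#' @param mode `"exact"` (sparse direct solve of the 5-point system; the
#'   reference path) or `"fast"` (coarse-to-fine pyramid with red-black
#'   Gauss-Seidel smoothing; approximate, accuracy reported not
#'   guaranteed).
#' @param tol residual tolerance: the exact solve is verified against it,
#'   and fast-mode smoothing stops early once the interior residual drops
#'   below it.
#' @param max_iter cap on fast-mode smoothing sweeps per pyramid level.
#' @param epsilon denominator guard: tissue values are clamped to
#'   `<= 1 - epsilon` so the bone formula `(f - T)/(1 - T)` never divides
#'   by zero. Must lie in `(0, 0.5)`.
#' @return list of class `btd_solver_config`.
#' @export
solver_config <- function(mode = c("exact", "fast"), tol = 1e-8,
                          max_iter = 100L, epsilon = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(tol > 0, epsilon > 0, epsilon < 0.5, max_iter >= 1)
  structure(list(mode = mode, tol = tol, max_iter = as.integer(max_iter),
                 epsilon = epsilon),
            class = "btd_solver_config")
}

#' Solve for the soft-tissue image
#'
#' Computes the tissue image `T`: equal to `f` outside the mask, and the
#' discrete harmonic interpolant of the boundary values inside it. Each
#' interior pixel satisfies the 5-point Laplace stencil
#' `4 T(p) = sum of the 4 neighbors`, with Dirichlet data `T = f` on the
#' mask boundary; mask pixels on the image border take edge-replicated
#' Dirichlet values (see [extract_boundary()]). Connected components of
#' the mask are solved as independent systems in deterministic order.
#'
#' Inside the mask the result is clamped to `<= 1 - epsilon` so the
#' downstream bone formula has a strictly positive denominator; outside
#' the mask `T = f` exactly.
#'
#' @param f radiograph matrix.
#' @param mask logical matrix, non-empty, same shape as `f`.
#' @param cfg a [solver_config()].
#' @return numeric matrix `T`, same shape as `f`.
#' @export
solve_tissue <- function(f, mask, cfg = solver_config()) {
  f <- as_radiograph(f)
  if (!identical(dim(mask), dim(f)))
    btd_stop("btd_error_bad_input", "mask shape does not match image")
  if (!any(mask))
    btd_stop("btd_error_empty_mask", "mask is empty")
  T_img <- if (cfg$mode == "exact") {
    solve_exact(f, mask, cfg)
  } else {
    solve_pyramid(f, mask, cfg)
  }
  # denominator guard applies inside the mask only: outside, T = f exactly
  T_img[mask] <- pmin(T_img[mask], 1 - cfg$epsilon)
  T_img
}

# Exact path: per-component sparse SPD solve (Cholesky via Matrix).
solve_exact <- function(f, mask, cfg) {
  h <- nrow(f); w <- ncol(f)
  T_img <- f
  lab <- label_components(mask)
  for (k in seq_len(max(lab))) {
    lin <- which(lab == k)
    T_img[lin] <- solve_component(f, mask, lin, h, w)
  }
  res <- residual_report(T_img, mask)
  if (length(res) && max(res) > cfg$tol)
    btd_stop("btd_error_solver",
             "direct solve residual %.3g exceeds tol %.3g", max(res), cfg$tol)
  T_img
}

solve_component <- function(f, mask, lin, h, w) {
  n <- length(lin)
  map <- integer(h * w)
  map[lin] <- seq_len(n)
  r <- ((lin - 1L) %% h) + 1L
  cc <- ((lin - 1L) %/% h) + 1L
  b <- numeric(n)
  ii <- integer(0); jj <- integer(0)
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nr <- r + d[1]; nc <- cc + d[2]
    inside <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    # off-grid neighbor: edge-replicated Dirichlet value f(p)
    contrib <- numeric(n)
    contrib[!inside] <- f[lin[!inside]]
    qlin <- (nc[inside] - 1L) * h + nr[inside]
    q_id <- map[qlin]
    unk <- q_id > 0L
    p_in <- which(inside)
    ii <- c(ii, p_in[unk]); jj <- c(jj, q_id[unk])
    # in-grid neighbor outside the mask: Dirichlet value f(q)
    contrib[p_in[!unk]] <- f[qlin[!unk]]
    b <- b + contrib
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(n), ii), j = c(seq_len(n), jj),
                            x = c(rep(4, n), rep(-1, length(ii))),
                            dims = c(n, n))
  A <- methods::as(A, "symmetricMatrix")
  as.numeric(Matrix::solve(A, b))
}

# Fast path: restrict the problem to a half-resolution grid, solve there
# (recursively, bottoming out in the exact solver), prolong bilinearly,
# then smooth with red-black Gauss-Seidel sweeps.
solve_pyramid <- function(f, mask, cfg) {
  h <- nrow(f); w <- ncol(f)
  if (sum(mask) <= 512L || min(h, w) <= 8L)
    return(solve_exact(f, mask, cfg))
  h2 <- ceiling(h / 2); w2 <- ceiling(w / 2)
  ri <- pmin(((seq_len(h) + 1L) %/% 2L), h2)
  ci <- pmin(((seq_len(w) + 1L) %/% 2L), w2)
  # block means / block any for restriction
  f2 <- rowsum(t(rowsum(f, ri)), ci)
  cnt <- rowsum(t(rowsum(matrix(1, h, w), ri)), ci)
  f2 <- t(f2 / cnt)
  m2 <- t(rowsum(t(rowsum(mask * 1, ri)), ci)) > 0
  T2 <- solve_pyramid(pmin(pmax(f2, 0), 1), m2, cfg)
  # bilinear prolongation of the coarse solution at mask pixels
  T_img <- f
  lin <- which(mask)
  r <- ((lin - 1L) %% h) + 1L
  cc <- ((lin - 1L) %/% h) + 1L
  pr <- pmin(pmax((r + 0.5) / 2, 1), h2)
  pc <- pmin(pmax((cc + 0.5) / 2, 1), w2)
  r0 <- pmin(floor(pr), h2 - 1L); c0 <- pmin(floor(pc), w2 - 1L)
  wr <- pr - r0; wc <- pc - c0
  at <- function(i, j) T2[(j - 1L) * h2 + i]
  T_img[lin] <- (1 - wr) * (1 - wc) * at(r0, c0) +
    (1 - wr) * wc * at(r0, c0 + 1L) +
    wr * (1 - wc) * at(r0 + 1L, c0) +
    wr * wc * at(r0 + 1L, c0 + 1L)
  gauss_seidel_smooth(T_img, f, mask, cfg$max_iter, cfg$tol)
}

# Vectorized red-black Gauss-Seidel on the mask pixels. Off-grid
# neighbors carry the edge-replicated Dirichlet value f(p), frozen.
gauss_seidel_smooth <- function(T_img, f, mask, sweeps, tol) {
  h <- nrow(f); w <- ncol(f)
  lin <- which(mask)
  r <- ((lin - 1L) %% h) + 1L
  cc <- ((lin - 1L) %/% h) + 1L
  nb <- lapply(list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L)),
               function(d) {
                 nr <- r + d[1]; nc <- cc + d[2]
                 inside <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
                 q <- ifelse(inside, (pmax(nc, 1L) - 1L) * h + pmax(nr, 1L), NA_integer_)
                 list(q = q, inside = inside)
               })
  fixed <- numeric(length(lin))  # replicated contributions per pixel
  for (d in nb) fixed <- fixed + ifelse(d$inside, 0, f[lin])
  colr <- (r + cc) %% 2L
  for (s in seq_len(sweeps)) {
    for (color in c(0L, 1L)) {
      sel <- colr == color
      acc <- fixed[sel]
      for (d in nb) {
        q <- d$q[sel]
        acc <- acc + ifelse(is.na(q), 0, T_img[ifelse(is.na(q), 1L, q)])
      }
      T_img[lin[sel]] <- acc / 4
    }
    if (s %% 10L == 0L) {
      res <- residual_report(T_img, mask)
      if (!length(res) || max(res) <= tol) break
    }
  }
  T_img
}

#' Per-component residual of the 5-point Laplace stencil
#'
#' Computes, for each connected component of the mask, the maximum of
#' `|4 T(p) - sum of 4 neighbors|` over the component's interior pixels
#' (mask pixels whose four neighbors all lie inside the raster and inside
#' the mask). A component with no interior pixels reports residual 0.
#'
#' @param T_img tissue image matrix.
#' @param mask logical matrix, same shape.
#' @return numeric vector, one maximum residual per component (in
#'   [label_components()] order); length 0 when the mask is empty.
#' @export
residual_report <- function(T_img, mask) {
  stopifnot(identical(dim(T_img), dim(mask)))
  h <- nrow(mask); w <- ncol(mask)
  lab <- label_components(mask)
  ncomp <- max(lab)
  if (ncomp == 0L) return(numeric(0))
  lin <- which(mask)
  r <- ((lin - 1L) %% h) + 1L
  cc <- ((lin - 1L) %/% h) + 1L
  interior <- r > 1L & r < h & cc > 1L & cc < w
  interior[interior] <- mask[lin[interior] - 1L] & mask[lin[interior] + 1L] &
    mask[lin[interior] - h] & mask[lin[interior] + h]
  out <- numeric(ncomp)
  if (any(interior)) {
    p <- lin[interior]
    res <- abs(4 * T_img[p] - T_img[p - 1L] - T_img[p + 1L] -
                 T_img[p - h] - T_img[p + h])
    mx <- tapply(res, lab[p], max)
    out[as.integer(names(mx))] <- as.numeric(mx)
  }
  out
}
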