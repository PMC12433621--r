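#' Disk structuring element
#'
#' Binary disk of radius `r` under the Euclidean metric: offsets `(dy, dx)`
#' with `dy^2 + dx^2 <= r^2`. Radius 0 gives the 1x1 identity element.
#'
#' @param r non-negative integer radius in pixels.
#' @return numeric 0/1 matrix of size `(2r+1) x (2r+1)`.
#' @export
disk_kernel <- function(r) {
  r <- as.integer(r)
  stopifnot(r >= 0L)
  d <- seq(-r, r)
  outer(d, d, function(dy, dx) as.numeric(dy^2 + dx^2 <= r^2))
}

#' 4-connected component labels of a binary mask
#'
#' Labels are positive integers in deterministic (first pixel in R's
#' column-major order) numbering; 0 outside the mask. The Laplace systems
#' of distinct components decouple exactly, so this ordering fixes the
#' order in which [solve_tissue()] and [residual_report()] treat them.
#'
#' @param mask logical matrix.
#' @return integer matrix of labels.
#' @export
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lin <- which(mask)
  n <- length(lin)
  if (n == 0L) return(lab)
  map <- integer(h * w)
  map[lin] <- seq_len(n)
  r <- ((lin - 1L) %% h) + 1L
  cc <- ((lin - 1L) %/% h) + 1L
  right_ok <- cc < w & mask[pmin(lin + h, h * w)]
  down_ok <- r < h & mask[pmin(lin + 1L, h * w)]
  ea <- c(map[lin[right_ok]], map[lin[down_ok]])
  eb <- c(map[lin[right_ok] + h], map[lin[down_ok] + 1L])
  g <- igraph::make_graph(rbind(ea, eb), n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber by first appearance in pixel order for determinism
  u <- unique(memb)
  relabel <- integer(max(memb))
  relabel[u] <- seq_along(u)
  lab[lin] <- relabel[memb]
  lab
}

#' Estimate a bone-covering mask by thresholding and morphology
#'
#' Produces the flexible mask `M` that the decomposition solves inside.
#' The mask only needs to cover the bones; it need not align with bone
#' boundaries, which is why a generous dilation step is applied last. The
#' recipe is: binarize at the threshold, morphological closing (disk of
#' `close_radius`), optional hole filling, removal of connected components
#' smaller than `min_area`, then dilation by a disk of `dilate_radius`.
#'
#' Defaults (Otsu threshold, closing 3, fill holes, min_area 64,
#' dilation 5) are deliberately generous: decomposition quality is
#' insensitive to the exact mask shape as long as bones are covered.
#'
#' @param f radiograph matrix (values in `[0, 1]`, bones bright).
#' @param threshold `"otsu"` for Otsu's method, or a fixed numeric cutoff;
#'   pixels with `f >= threshold` seed the mask.
#' @param close_radius disk radius for morphological closing (0 = skip).
#' @param dilate_radius disk radius for the final dilation (0 = skip).
#' @param min_area discard connected components (4-connectivity) smaller
#'   than this many pixels before dilating.
#' @param fill_holes fill enclosed holes after closing.
#' @return logical matrix, `TRUE` inside the mask.
#' @export
estimate_mask <- function(f, threshold = "otsu", close_radius = 3,
                          dilate_radius = 5, min_area = 64,
                          fill_holes = TRUE) {
  f <- as_radiograph(f)
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(f, range = c(0, 1))
  } else {
    as.numeric(threshold)
  }
  m <- f >= thr
  if (close_radius > 0 && any(m))
    m <- EBImage::closing(m * 1, disk_kernel(close_radius)) > 0
  if (isTRUE(fill_holes) && any(m))
    m <- EBImage::fillHull(m * 1) > 0
  if (min_area > 1 && any(m)) {
    lab <- label_components(m)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_area)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  if (dilate_radius > 0 && any(m))
    m <- EBImage::dilate(m * 1, disk_kernel(dilate_radius)) > 0
  if (!any(m))
    btd_stop("btd_error_empty_mask",
             "no bone-like region found (mask empty after filtering)")
  m
}

#' Validate a user-supplied bone mask
#'
#' Accepts interactively drawn or externally computed masks: checks the
#' shape against the companion image, binarizes (nonzero = inside), and
#' warns when the mask touches the image border (handled downstream by
#' edge replication of the Dirichlet data).
#'
#' @param mask numeric or logical matrix; nonzero means inside.
#' @param f companion radiograph matrix (shape reference).
#' @return logical matrix.
#' @export
validate_user_mask <- function(mask, f) {
  if (!is.matrix(mask))
    btd_stop("btd_error_bad_input", "mask must be a matrix")
  if (!identical(dim(mask), dim(f)))
    btd_stop("btd_error_bad_input",
             "mask shape (%d x %d) does not match image (%d x %d)",
             nrow(mask), ncol(mask), nrow(f), ncol(f))
  m <- mask != 0
  if (!any(m))
    btd_stop("btd_error_empty_mask", "mask is empty")
  if (any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) || any(m[, ncol(m)]))
    btd_warn("mask touches the image border; boundary values there are edge-replicated")
  m
}

#' Extract the Dirichlet boundary of a mask
#'
#' The boundary of `M` is the set of pixels outside `M` that are
#' 4-adjacent to at least one pixel of `M`; their intensities, taken from
#' `f`, supply the Dirichlet data `T = f` for the Laplace solve. Where a
#' mask pixel sits on the image border so that a 4-neighbor falls outside
#' the raster, the missing neighbor is synthesized by edge replication of
#' `f` (its value is `f` at the border pixel itself) and reported with
#' `synthetic = TRUE` and its out-of-grid coordinates.
#'
#' @param mask logical matrix, non-empty.
#' @param f radiograph matrix, same shape.
#' @return data frame with columns `row`, `col` (1-based; out-of-grid for
#'   synthetic entries), `value`, `synthetic`.
#' @export
extract_boundary <- function(mask, f) {
  stopifnot(identical(dim(mask), dim(f)))
  if (!any(mask))
    btd_stop("btd_error_empty_mask", "mask is empty")
  h <- nrow(mask); w <- ncol(mask)
  lin <- which(mask)
  r <- ((lin - 1L) %% h) + 1L
  cc <- ((lin - 1L) %/% h) + 1L
  out <- list()
  syn <- list()
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nr <- r + d[1]; nc <- cc + d[2]
    inside <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    qlin <- (nc[inside] - 1L) * h + nr[inside]
    is_bnd <- !mask[qlin]
    out[[length(out) + 1L]] <- qlin[is_bnd]
    if (any(!inside))
      syn[[length(syn) + 1L]] <- data.frame(
        row = nr[!inside], col = nc[!inside],
        value = f[lin[!inside]], synthetic = TRUE)
  }
  blin <- sort(unique(unlist(out)))
  real <- data.frame(
    row = ((blin - 1L) %% h) + 1L,
    col = ((blin - 1L) %/% h) + 1L,
    value = f[blin],
    synthetic = rep(FALSE, length(blin)))
  res <- rbind(real, do.call(rbind, syn))
  rownames(res) <- NULL
  res
}
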