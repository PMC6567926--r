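#' Discrete disk structuring element
#'
#' The disk of radius `r` contains every pixel offset `(dx, dy)` with
#' `dx^2 + dy^2 <= r^2`, as a `(2r+1) x (2r+1)` 0/1 matrix centred on the
#' origin.
#'
#' @param radius Disk radius in pixels (integer >= 1).
#' @return A numeric 0/1 matrix usable as a morphological kernel.
#' @export
disk_kernel <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1 ||
      radius != floor(radius))
    stop("`radius` must be a single integer >= 1", call. = FALSE)
  d <- -radius:radius
  k <- outer(d, d, function(a, b) as.numeric(a^2 + b^2 <= radius^2))
  k
}

#' Black top-hat transform
#'
#' Morphological closing with a disk of the given radius, minus the input:
#' the residue is non-negative and highlights dark features (here gas-filled
#' airspaces, which appear as negative intensity peaks against bright
#' tissue septa) smaller than the structuring element. Pixels where the
#' image is locally flat at that scale give zero.
#'
#' Pixels outside the image border are ignored by the min/max filters
#' (equivalently, padded with -Inf for dilation and +Inf for erosion), so a
#' constant image maps to an all-zero residue.
#'
#' @param slice A numeric matrix (one grayscale slice).
#' @param radius Disk structuring-element radius in pixels.
#' @return A non-negative numeric matrix of the same dimension.
#' @export
black_tophat <- function(slice, radius) {
  if (!is.matrix(slice) || !is.numeric(slice))
    stop("`slice` must be a numeric matrix", call. = FALSE)
  if (2 * radius + 1 > min(dim(slice)))
    stop("structuring element (radius ", radius,
         ") larger than the slice", call. = FALSE)
  k <- disk_kernel(radius)
  # flat grayscale closing is affine-equivariant, so images outside [0, 1]
  # (where the min/max filter backend is not valid) are mapped into [0, 1],
  # closed there, and the residue scaled back
  rng <- range(slice)
  scale <- 1
  x <- slice
  if (rng[1] < 0 || rng[2] > 1) {
    scale <- diff(rng)
    if (scale == 0) return(matrix(0, nrow(slice), ncol(slice)))
    x <- (slice - rng[1]) / scale
  }
  closed <- EBImage::erode(EBImage::dilate(x, k), k)
  res <- (closed - x) * scale
  # guard against floating-point dust from the filter arithmetic
  res[res < 0] <- 0
  res
}

# shift a matrix by (di, dj), filling vacated cells with `fill`
shift_mat <- function(x, di, dj, fill) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(fill, nr, nc)
  ri <- max(1, 1 - di):min(nr, nr - di)
  rj <- max(1, 1 - dj):min(nc, nc - dj)
  out[ri, rj] <- x[ri + di, rj + dj]
  out
}

neighbor_offsets <- function(connectivity) {
  if (connectivity == 8)
    list(di = c(-1, 1, 0, 0, -1, -1, 1, 1), dj = c(0, 0, -1, 1, -1, 1, -1, 1))
  else
    list(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
}

#' Regional minima within a mask
#'
#' A regional minimum is a connected plateau of equal-valued pixels that is
#' strictly darker than every pixel adjacent to the plateau (within the
#' mask; pixels outside the mask are ignored). Each plateau counts as one
#' peak. Used to count one peak per airspace on the grayscale slice.
#'
#' @param x Numeric matrix of intensities.
#' @param mask Logical matrix restricting the search; minima are sought in
#'   and compared against masked-in pixels only.
#' @param connectivity Pixel adjacency, 4 or 8 (default 8).
#' @return A list with `labels` (integer matrix, one positive label per
#'   plateau, 0 elsewhere) and `peaks`, a tibble with one row per plateau:
#'   `peak` (label), `row`, `col` (representative pixel: first plateau pixel
#'   in column-major order) and `value`.
#' @export
regional_minima <- function(x, mask = NULL, connectivity = 8) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(x), ncol(x))
  mask <- mask != 0
  stopifnot(identical(dim(mask), dim(x)))
  if (!connectivity %in% c(4, 8))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  xm <- x
  xm[!mask] <- Inf
  off <- neighbor_offsets(connectivity)
  # a pixel is "low" if no in-mask neighbour is strictly darker; two
  # adjacent low pixels necessarily share the same value, so components of
  # the low set are constant-valued plateau fragments
  has_lower <- matrix(FALSE, nrow(x), ncol(x))
  for (d in seq_along(off$di)) {
    nb <- shift_mat(xm, off$di[d], off$dj[d], Inf)
    has_lower <- has_lower | (nb < xm)
  }
  low <- mask & !has_lower
  lab <- cpp_label_components(low, as.integer(connectivity))
  if (max(lab) > 0L) {
    # a low fragment is a true regional minimum only if the full plateau it
    # belongs to has no darker neighbour; equivalently, no adjacent in-mask
    # pixel carries the same value without itself being low
    eq_nonlow <- matrix(FALSE, nrow(x), ncol(x))
    lowm <- low
    for (d in seq_along(off$di)) {
      nbv <- shift_mat(xm, off$di[d], off$dj[d], Inf)
      nbl <- shift_mat(lowm, off$di[d], off$dj[d], TRUE)
      eq_nonlow <- eq_nonlow | (nbv == xm & !nbl & is.finite(nbv))
    }
    bad <- unique(lab[eq_nonlow & low])
    if (length(bad)) lab[lab %in% bad] <- 0L
    # re-number surviving plateaus consecutively in column-major order
    keep <- sort(unique(lab[lab > 0L]))
    lab[] <- match(lab, keep, nomatch = 0L)
  }
  n <- max(lab)
  if (n == 0L) {
    peaks <- tibble::tibble(peak = integer(), row = integer(),
                            col = integer(), value = numeric())
  } else {
    idx <- which(lab > 0L)
    first <- idx[!duplicated(lab[idx])]
    ord <- order(lab[first])
    first <- first[ord]
    peaks <- tibble::tibble(
      peak = lab[first],
      row = ((first - 1L) %% nrow(x)) + 1L,
      col = ((first - 1L) %/% nrow(x)) + 1L,
      value = x[first])
  }
  list(labels = lab, peaks = peaks)
}

# separable Gaussian smoothing with edge replication; sigma in pixels
smooth_gaussian <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(-r:r)^2 / (2 * sigma^2))
  g <- g / sum(g)
  pad_conv <- function(m) {
    # replicate-pad rows, convolve each column with g
    top <- m[rep(1L, r), , drop = FALSE]
    bot <- m[rep(nrow(m), r), , drop = FALSE]
    mp <- rbind(top, m, bot)
    out <- matrix(0, nrow(m), ncol(m))
    for (k in seq_along(g))
      out <- out + g[k] * mp[k:(k + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(x))))
}
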