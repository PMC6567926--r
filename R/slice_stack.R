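#' Create a slice stack
#'
#' A slice stack is the unit of analysis: an ordered list of 2D grayscale
#' slices (numeric matrices of identical dimension) sharing one isotropic
#' voxel geometry. Forty adjacent slices per acquisition is the conventional
#' protocol depth; any positive number is accepted.
#'
#' @param slices A list of numeric matrices with identical dimensions, or a
#'   single matrix (treated as a one-slice stack).
#' @param voxel_size_um Isotropic voxel side length in micrometres
#'   (default 47.7).
#' @return An object of class `slice_stack`.
#' @export
slice_stack <- function(slices, voxel_size_um = 47.7) {
  if (is.matrix(slices)) slices <- list(slices)
  if (!is.list(slices) || length(slices) == 0L)
    stop("`slices` must be a non-empty list of matrices", call. = FALSE)
  dims <- vapply(slices, dim, integer(2))
  if (!all(dims == dims[, 1]))
    stop("all slices must share the same dimensions", call. = FALSE)
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number", call. = FALSE)
  structure(list(slices = slices, voxel_size_um = voxel_size_um),
            class = "slice_stack")
}

#' @export
length.slice_stack <- function(x) length(x$slices)

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<slice_stack> %d slice(s) of %d x %d px, voxel %.4g um\n",
              length(x$slices), d[1], d[2], x$voxel_size_um))
  invisible(x)
}

n_slices <- function(x) length(x$slices)

slice_dim <- function(x) dim(x$slices[[1]])

#' Read a slice stack from a multi-page TIFF
#'
#' @param path Path to a (multi-page) TIFF file.
#' @param voxel_size_um Voxel side length in micrometres to attach.
#' @return A `slice_stack`.
#' @export
read_stack <- function(path, voxel_size_um = 47.7) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse grayscale-as-RGB
    p
  })
  slice_stack(pages, voxel_size_um = voxel_size_um)
}

#' Write a slice stack to a multi-page TIFF
#'
#' Values are clipped to `[0, 1]` and written as 32-bit samples, one page
#' per slice.
#'
#' @param stack A `slice_stack`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "slice_stack"))
  pages <- lapply(stack$slices, function(s) pmin(pmax(s, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Write a binary mask as a single-page TIFF
#'
#' @param mask A logical (or 0/1) matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  tiff::writeTIFF(m, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a binary mask from a TIFF/PNG-style image file
#'
#' Any strictly positive pixel is foreground.
#'
#' @param path Path to a single-page image file (TIFF).
#' @return A logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0
}
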