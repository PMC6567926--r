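#' Detection parameters
#'
#' Controls the multi-scale top-hat detection chain. The default
#' structuring-element radii span the alveolar scale (about 110 um, i.e.
#' 2.3 px at 47.7 um voxels) up to the alveolar-duct scale (0.5-0.75 mm,
#' about 16 px), so features over the whole expected airspace size range
#' respond to at least one transform.
#'
#' @param se_radii_vox Strictly increasing disk radii (pixels) for the
#'   top-hat sequence.
#' @param binarize_rule `"otsu"` (per-response Otsu threshold, 256 bins
#'   over `[0, max]`) or `"fraction"` (threshold at
#'   `fraction * max(response)`).
#' @param fraction Threshold fraction used by the `"fraction"` rule.
#' @param peak_connectivity Pixel adjacency for peak plateaus and candidate
#'   components, 4 or 8.
#' @param min_area_vox Minimum airspace area in pixels; smaller components
#'   are dropped (default 2, suppressing single-pixel noise).
#' @param smooth_sigma_px Gaussian pre-smoothing (pixels) applied to the
#'   slice before regional-minima counting; suppresses noise-induced
#'   spurious minima on the flat interior of an airspace. 0 disables.
#' @return An object of class `detect_params`.
#' @export
detect_params <- function(se_radii_vox = c(1, 2, 3, 5, 8, 12, 16),
                          binarize_rule = c("otsu", "fraction"),
                          fraction = 0.5,
                          peak_connectivity = 8,
                          min_area_vox = 2,
                          smooth_sigma_px = 1) {
  if (length(se_radii_vox) == 0L || any(se_radii_vox < 1) ||
      any(diff(se_radii_vox) <= 0))
    stop("`se_radii_vox` must be strictly increasing radii >= 1",
         call. = FALSE)
  if (!peak_connectivity %in% c(4, 8))
    stop("`peak_connectivity` must be 4 or 8", call. = FALSE)
  if (min_area_vox < 1) stop("`min_area_vox` must be >= 1", call. = FALSE)
  structure(list(se_radii_vox = as.integer(se_radii_vox),
                 binarize_rule = match.arg(binarize_rule),
                 fraction = fraction,
                 peak_connectivity = as.integer(peak_connectivity),
                 min_area_vox = min_area_vox,
                 smooth_sigma_px = smooth_sigma_px),
            class = "detect_params")
}

#' Binarize a sequence of top-hat responses
#'
#' Each response yields its own binary map: a pixel is foreground iff its
#' response exceeds the threshold. The threshold itself is shared across
#' the sequence and derived from the pixel-wise maximum response over all
#' scales — the top-hat residue of a detected feature equals the feature's
#' depth regardless of the structuring-element size, whereas a
#' small-element response on noisy data may contain no true feature at
#' all, and thresholding it in isolation would split pure noise. Under
#' the Otsu rule the shared threshold is computed on a 256-bin histogram
#' of the maximum response over `[0, max]`, which keeps the binarization
#' invariant to positive affine rescaling of the input image; the
#' fraction rule uses `fraction * max`. An all-zero sequence yields
#' all-false maps.
#'
#' @param tophat_responses List of non-negative numeric matrices, one per
#'   structuring-element radius.
#' @param params A [detect_params()].
#' @return A list of logical matrices.
#' @export
binarize_stack <- function(tophat_responses, params = detect_params()) {
  if (!is.list(tophat_responses) || length(tophat_responses) == 0L)
    stop("`tophat_responses` must be a non-empty list", call. = FALSE)
  M <- tophat_responses[[1]]
  for (r in tophat_responses[-1]) M <- pmax(M, r)
  mx <- max(M)
  if (mx <= 0)
    return(lapply(tophat_responses, function(resp)
      matrix(FALSE, nrow(resp), ncol(resp))))
  thr <- if (params$binarize_rule == "otsu") {
    EBImage::otsu(M, range = c(0, mx), levels = 256L)
  } else {
    params$fraction * mx
  }
  lapply(tophat_responses, function(resp) resp > thr)
}

#' Superimpose binary maps
#'
#' Pixel-wise union (logical OR) of the binary maps derived from the
#' individual top-hat transforms.
#'
#' @param binary_maps Non-empty list of logical matrices of equal
#'   dimension.
#' @return A logical matrix.
#' @export
superimpose <- function(binary_maps) {
  if (!is.list(binary_maps) || length(binary_maps) == 0L)
    stop("`binary_maps` must be a non-empty list", call. = FALSE)
  dims <- vapply(binary_maps, dim, integer(2))
  if (!all(dims == dims[, 1]))
    stop("binary maps must share the same shape", call. = FALSE)
  out <- binary_maps[[1]] != 0
  for (m in binary_maps[-1]) out <- out | (m != 0)
  out
}

#' Count airspaces in one slice
#'
#' Regional minima of the grayscale slice (optionally Gaussian-smoothed)
#' restricted to `gas_candidate & mask & !exclusion` are found; minima on
#' one connected plateau count as one peak. Each candidate connected
#' component receives one label per contained peak — components holding
#' several peaks are split by nearest-peak assignment — and components with
#' no peak or with area below `min_area_vox` are dropped. The count is the
#' number of surviving labels.
#'
#' @param slice Numeric matrix (grayscale slice).
#' @param gas_candidate Logical matrix of candidate gas pixels (the
#'   superimposed top-hat maps).
#' @param mask Logical lung mask (NULL for all-in).
#' @param exclusion Logical exclusion mask (NULL for none).
#' @param params A [detect_params()].
#' @return A list with `labels` (integer matrix) and `airspaces`, a tibble
#'   with one row per airspace: `label`, `area_vox`, `peak_row`,
#'   `peak_col`.
#' @export
count_airspaces <- function(slice, gas_candidate, mask = NULL,
                            exclusion = NULL, params = detect_params()) {
  stopifnot(is.matrix(slice))
  region <- gas_candidate != 0
  stopifnot(identical(dim(region), dim(slice)))
  if (!is.null(mask)) region <- region & (mask != 0)
  if (!is.null(exclusion)) region <- region & !(exclusion != 0)
  empty <- list(labels = matrix(0L, nrow(slice), ncol(slice)),
                airspaces = tibble::tibble(label = integer(),
                                           area_vox = numeric(),
                                           peak_row = integer(),
                                           peak_col = integer()))
  if (!any(region)) return(empty)
  conn <- params$peak_connectivity
  comp <- cpp_label_components(region, conn)
  work <- if (params$smooth_sigma_px > 0)
    smooth_gaussian(slice, params$smooth_sigma_px) else slice
  rm_ <- regional_minima(work, region, connectivity = conn)
  pk <- rm_$peaks
  if (nrow(pk) == 0L) return(empty)
  pk$comp <- comp[cbind(pk$row, pk$col)]
  out <- matrix(0L, nrow(slice), ncol(slice))
  next_label <- 0L
  rows <- integer(0); cols <- integer(0); labs <- integer(0)
  areas <- numeric(0)
  comp_tab <- split(seq_len(nrow(pk)), pk$comp)
  cidx <- which(comp > 0L)
  comp_pix <- split(cidx, comp[cidx])
  for (cid in as.integer(names(comp_tab))) {
    pix <- comp_pix[[as.character(cid)]]
    members <- comp_tab[[as.character(cid)]]
    if (length(members) == 1L) {
      next_label <- next_label + 1L
      out[pix] <- next_label
      labs <- c(labs, next_label)
      rows <- c(rows, pk$row[members]); cols <- c(cols, pk$col[members])
      areas <- c(areas, length(pix))
    } else {
      # split by nearest representative peak; ties go to the
      # earliest peak in scan order
      py <- ((pix - 1L) %% nrow(slice)) + 1L
      px <- ((pix - 1L) %/% nrow(slice)) + 1L
      d2 <- vapply(members, function(m)
        (py - pk$row[m])^2 + (px - pk$col[m])^2, numeric(length(pix)))
      if (length(pix) == 1L) d2 <- matrix(d2, nrow = 1L)
      nearest <- max.col(-d2, ties.method = "first")
      for (j in seq_along(members)) {
        sel <- pix[nearest == j]
        if (length(sel) == 0L) next
        next_label <- next_label + 1L
        out[sel] <- next_label
        labs <- c(labs, next_label)
        rows <- c(rows, pk$row[members[j]])
        cols <- c(cols, pk$col[members[j]])
        areas <- c(areas, length(sel))
      }
    }
  }
  tbl <- tibble::tibble(label = labs, area_vox = areas,
                        peak_row = rows, peak_col = cols)
  # area filter
  small <- tbl$label[tbl$area_vox < params$min_area_vox]
  if (length(small)) {
    out[out %in% small] <- 0L
    tbl <- tbl[!tbl$label %in% small, , drop = FALSE]
    keep <- tbl$label
    out[] <- match(out, keep, nomatch = 0L)
    tbl$label <- seq_len(nrow(tbl))
  }
  list(labels = out, airspaces = tbl)
}

#' Detect airspaces in a slice stack
#'
#' Applies the full per-slice chain — multi-scale black top-hat,
#' independent binarization, superimposition, regional-minima peak
#' counting — and aggregates per-slice counts and surfaces.
#'
#' @param stack A [slice_stack()].
#' @param masks Lung mask: one logical matrix (shared by all slices) or a
#'   list with one per slice. NULL analyses the full frame.
#' @param exclusions Exclusion mask(s), same conventions as `masks`.
#' @param params A [detect_params()].
#' @return An object of class `airspace_map`: a list with `labels` (list
#'   of per-slice label matrices), `airspaces` (tibble: `slice`, `label`,
#'   `area_vox`, `peak_row`, `peak_col`), `per_slice` (tibble: `slice`,
#'   `count`, `surface_vox`) and the parameters used.
#' @export
detect_stack <- function(stack, masks = NULL, exclusions = NULL,
                         params = detect_params()) {
  stopifnot(inherits(stack, "slice_stack"))
  ns <- n_slices(stack)
  as_list_per_slice <- function(x, what) {
    if (is.null(x)) return(vector("list", ns))
    if (is.matrix(x)) return(rep(list(x), ns))
    if (length(x) != ns)
      stop("number of ", what, " (", length(x),
           ") does not match number of slices (", ns, ")", call. = FALSE)
    x
  }
  masks <- as_list_per_slice(masks, "masks")
  exclusions <- as_list_per_slice(exclusions, "exclusion masks")
  labels <- vector("list", ns)
  per_airspace <- vector("list", ns)
  for (s in seq_len(ns)) {
    slice <- stack$slices[[s]]
    th <- lapply(params$se_radii_vox, function(r) black_tophat(slice, r))
    cand <- superimpose(binarize_stack(th, params))
    res <- count_airspaces(slice, cand, masks[[s]], exclusions[[s]],
                           params)
    labels[[s]] <- res$labels
    tb <- res$airspaces
    if (nrow(tb)) tb <- dplyr::mutate(tb, slice = s, .before = 1L)
    else tb$slice <- integer()
    per_airspace[[s]] <- tb
  }
  airspaces <- dplyr::bind_rows(per_airspace)
  per_slice <- tibble::tibble(slice = seq_len(ns)) |>
    dplyr::left_join(
      airspaces |>
        dplyr::group_by(slice = .data$slice) |>
        dplyr::summarise(count = dplyr::n(),
                         surface_vox = sum(.data$area_vox),
                         .groups = "drop"),
      by = "slice") |>
    tidyr::replace_na(list(count = 0L, surface_vox = 0))
  structure(list(labels = labels, airspaces = airspaces,
                 per_slice = per_slice, params = params,
                 voxel_size_um = stack$voxel_size_um),
            class = "airspace_map")
}

#' @export
print.airspace_map <- function(x, ...) {
  cat(sprintf("<airspace_map> %d slice(s), %d airspaces, %s surface px\n",
              length(x$labels), nrow(x$airspaces),
              format(sum(x$airspaces$area_vox))))
  invisible(x)
}
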