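#' Depth from the pleural boundary
#'
#' Computes, for every in-mask pixel, the Euclidean distance in millimetres
#' to the nearest out-of-mask pixel (the pleural surface as seen in 2D).
#' Out-of-mask pixels carry 0.
#'
#' @param mask Logical (or 0/1) matrix: the lung parenchyma mask.
#' @param voxel_size_um Voxel side length in micrometres.
#' @return A numeric matrix of depths in mm.
#' @export
boundary_depth <- function(mask, voxel_size_um = 47.7) {
  m <- mask != 0
  if (!any(m)) stop("empty mask", call. = FALSE)
  d_px <- as.matrix(EBImage::distmap(matrix(as.numeric(m), nrow(m)),
                                     metric = "euclidean"))
  d_px * voxel_size_um / 1000
}

#' Partition a slice into concentric depth ROIs
#'
#' Classifies every pixel into subpleural, mantellar or core by its depth
#' from the pleural surface, with half-open intervals: subpleural is
#' `0 < depth < t1`, mantellar `t1 <= depth < t2`, core `depth >= t2`
#' (defaults 2 and 4 mm). Excluded pixels override all three; pixels with
#' zero depth are background.
#'
#' @param depth Depth map in mm, as returned by [boundary_depth()].
#' @param exclusion Optional logical matrix of pixels to exclude (e.g. the
#'   manually outlined pericardiac region affected by motion artifacts).
#' @param thresholds_mm Two strictly increasing depth cuts in mm.
#' @return An object of class `roi_partition`: an integer label matrix
#'   (0 background, 1 subpleural, 2 mantellar, 3 core, 4 excluded) with the
#'   thresholds stored as attributes.
#' @export
partition_rois <- function(depth, exclusion = NULL,
                           thresholds_mm = c(2, 4)) {
  stopifnot(is.matrix(depth), is.numeric(depth))
  if (length(thresholds_mm) != 2L || diff(thresholds_mm) <= 0 ||
      thresholds_mm[1] <= 0)
    stop("`thresholds_mm` must be two strictly increasing positive cuts",
         call. = FALSE)
  lab <- matrix(ROI_CODE[["background"]], nrow(depth), ncol(depth))
  inmask <- depth > 0
  lab[inmask & depth < thresholds_mm[1]] <- ROI_CODE[["subpleural"]]
  lab[inmask & depth >= thresholds_mm[1] &
        depth < thresholds_mm[2]] <- ROI_CODE[["mantellar"]]
  lab[inmask & depth >= thresholds_mm[2]] <- ROI_CODE[["core"]]
  if (!is.null(exclusion)) {
    stopifnot(identical(dim(exclusion), dim(depth)))
    lab[inmask & (exclusion != 0)] <- ROI_CODE[["excluded"]]
  }
  structure(lab, thresholds_mm = thresholds_mm, class = "roi_partition")
}

#' @export
print.roi_partition <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = ROI_CODE,
                      labels = names(ROI_CODE)))
  cat("<roi_partition>", paste(names(tab), as.integer(tab), sep = "=",
                               collapse = " "), "\n")
  invisible(x)
}

# ROI name at pixel positions (vectors of row/col indices)
roi_at <- function(partition, row, col) {
  codes <- unclass(partition)[cbind(row, col)]
  names(ROI_CODE)[match(codes, ROI_CODE)]
}

#' Per-ROI pixel counts of a partition
#'
#' @param partition A `roi_partition` (or list of them, one per slice).
#' @return A tibble with `roi` and `pixels`, one row per ROI
#'   (subpleural, mantellar, core) plus `ALL` (their union).
#' @export
roi_pixel_counts <- function(partition) {
  parts <- if (inherits(partition, "roi_partition")) list(partition)
           else partition
  counts <- c(subpleural = 0, mantellar = 0, core = 0)
  for (p in parts) {
    v <- unclass(p)
    counts["subpleural"] <- counts["subpleural"] +
      sum(v == ROI_CODE[["subpleural"]])
    counts["mantellar"] <- counts["mantellar"] +
      sum(v == ROI_CODE[["mantellar"]])
    counts["core"] <- counts["core"] + sum(v == ROI_CODE[["core"]])
  }
  tibble::tibble(
    roi = factor(ROI_LEVELS, levels = ROI_LEVELS),
    pixels = c(sum(counts), unname(counts)))
}

#' Assign detected airspaces to ROIs
#'
#' Each airspace is assigned to exactly one ROI: the ROI containing its
#' representative peak pixel. Its full pixel area accrues to that ROI, so
#' per-ROI counts and surfaces sum to the slice totals. Airspaces whose
#' peak falls on an excluded or background pixel are dropped with a
#' message.
#'
#' @param airspaces An `airspace_map` (see [detect_stack()]) or its
#'   `airspaces` tibble.
#' @param partition A `roi_partition`, or a list of them (one per slice).
#' @return The airspace tibble with an added `roi` column (factor
#'   subpleural/mantellar/core), dropped rows removed.
#' @export
assign_airspaces_to_rois <- function(airspaces, partition) {
  tbl <- if (inherits(airspaces, "airspace_map")) airspaces$airspaces
         else airspaces
  parts <- if (inherits(partition, "roi_partition")) list(partition)
           else partition
  if (nrow(tbl) == 0L) {
    tbl$roi <- factor(character(), levels = ROI_LEVELS[-1])
    return(tbl)
  }
  pidx <- if (length(parts) == 1L) rep(1L, nrow(tbl)) else tbl$slice
  if (max(pidx) > length(parts))
    stop("fewer partitions than slices", call. = FALSE)
  roi <- character(nrow(tbl))
  for (k in unique(pidx)) {
    sel <- pidx == k
    roi[sel] <- roi_at(parts[[k]], tbl$peak_row[sel], tbl$peak_col[sel])
  }
  drop <- roi %in% c("excluded", "background")
  if (any(drop))
    message(sum(drop), " airspace(s) with peak on excluded/background ",
            "pixels dropped")
  tbl <- tbl[!drop, , drop = FALSE]
  tbl$roi <- factor(roi[!drop], levels = ROI_LEVELS[-1])
  tbl
}
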