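#' ROI volume in mm^3
#'
#' Per-ROI pixel counts summed over slices times the voxel volume
#' (side^3); at the default 47.7 um side one pixel contributes
#' 1.0853e-4 mm^3. Only the analysed slices enter the volume, not the
#' whole lung.
#'
#' @param partition A `roi_partition` or a list of them (one per slice).
#' @param voxel_size_um Voxel side in micrometres.
#' @param n_slices If `partition` is a single partition shared by all
#'   slices, the number of slices it stands for (default 1).
#' @return A tibble with `roi`, `pixels` and `volume_mm3`.
#' @export
roi_volume <- function(partition, voxel_size_um = 47.7, n_slices = 1L) {
  px <- roi_pixel_counts(partition)
  if (inherits(partition, "roi_partition"))
    px$pixels <- px$pixels * n_slices
  vox_mm3 <- (voxel_size_um / 1000)^3
  px$volume_mm3 <- px$pixels * vox_mm3
  px
}

#' Airspace density (ASden)
#'
#' Number of airspaces per mm^3 of analysed ROI volume.
#'
#' @param total_count Total airspace count in the ROI over all slices.
#' @param roi_volume_mm3 ROI volume in mm^3 (> 0).
#' @return Density in units per mm^3.
#' @export
compute_asden <- function(total_count, roi_volume_mm3) {
  if (any(roi_volume_mm3 <= 0))
    stop("ROI volume must be > 0", call. = FALSE)
  total_count / roi_volume_mm3
}

#' Average airspace surface extension (ASext)
#'
#' The ratio of the sum of airspace-covered surfaces to the sum of
#' airspace counts over all analysed slices — a ratio of sums, not a mean
#' of per-slice ratios. Expressed in voxels of slice area; undefined (NA,
#' with a warning) when no airspaces were counted.
#'
#' @param per_slice A data frame with columns `surface_vox` and `count`
#'   (one row per slice), or a numeric vector of surfaces if `count` is
#'   given separately.
#' @param count Optional numeric vector of per-slice counts.
#' @return Mean surface per airspace, in voxels.
#' @export
compute_asext <- function(per_slice, count = NULL) {
  if (is.data.frame(per_slice)) {
    surface <- per_slice$surface_vox
    count <- per_slice$count
  } else {
    surface <- per_slice
  }
  stopifnot(length(surface) == length(count))
  tc <- sum(count)
  if (tc == 0) {
    warning("ASext undefined: no airspaces counted", call. = FALSE)
    return(NA_real_)
  }
  sum(surface) / tc
}

#' Per-ROI airspace metrics for one acquisition
#'
#' Combines a detection result, a ROI partition and the acquisition's
#' pressure information into the tidy per-ROI metric table: total count,
#' total surface, ROI volume, ASden and ASext, for the three concentric
#' ROIs and for `ALL` (their union).
#'
#' @param detection An `airspace_map` from [detect_stack()].
#' @param partition A `roi_partition` (shared by all slices) or a list,
#'   one per slice.
#' @param pressure_nominal,pressure_measured Nominal and measured PEEP
#'   (cmH2O) of the acquisition.
#' @param animal Optional animal/stack identifier.
#' @return A tibble with one row per ROI: `animal`, `pressure_nominal`,
#'   `pressure_measured`, `roi`, `count`, `surface_vox`, `volume_mm3`,
#'   `asden`, `asext`.
#' @export
roi_metrics <- function(detection, partition, pressure_nominal,
                        pressure_measured = pressure_nominal,
                        animal = NA_character_) {
  stopifnot(inherits(detection, "airspace_map"))
  ns <- length(detection$labels)
  shared <- inherits(partition, "roi_partition")
  vols <- roi_volume(if (shared) partition else partition,
                     voxel_size_um = detection$voxel_size_um,
                     n_slices = if (shared) ns else 1L)
  assigned <- assign_airspaces_to_rois(detection, partition)
  by_roi <- assigned |>
    dplyr::group_by(roi = .data$roi) |>
    dplyr::summarise(count = dplyr::n(),
                     surface_vox = sum(.data$area_vox),
                     .groups = "drop") |>
    tidyr::complete(roi, fill = list(count = 0L, surface_vox = 0))
  all_row <- tibble::tibble(
    roi = factor("ALL", levels = ROI_LEVELS),
    count = sum(by_roi$count),
    surface_vox = sum(by_roi$surface_vox))
  by_roi$roi <- factor(as.character(by_roi$roi), levels = ROI_LEVELS)
  out <- dplyr::bind_rows(all_row, by_roi) |>
    dplyr::left_join(vols[, c("roi", "volume_mm3")], by = "roi")
  out$asden <- ifelse(out$volume_mm3 > 0,
                      out$count / out$volume_mm3, NA_real_)
  out$asext <- ifelse(out$count > 0, out$surface_vox / out$count,
                      NA_real_)
  tibble::tibble(animal = animal,
                 pressure_nominal = pressure_nominal,
                 pressure_measured = pressure_measured,
                 out)
}

#' Convert ASext from voxels to um^2
#'
#' One voxel of slice area is `voxel_size_um^2` square micrometres.
#'
#' @param asext_vox ASext in voxels.
#' @param voxel_size_um Voxel side in micrometres.
#' @return ASext in um^2.
#' @export
asext_um2 <- function(asext_vox, voxel_size_um = 47.7) {
  asext_vox * voxel_size_um^2
}
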