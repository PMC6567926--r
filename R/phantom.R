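#' Phantom specification
#'
#' Describes a synthetic lung-slice phantom: an elliptical parenchyma mask
#' with a circular pericardiac exclusion notch, populated slice by slice
#' with non-overlapping dark (gas) disks separated by bright (tissue)
#' septa. Each airspace carries a critical closing pressure drawn from a
#' Gaussian (optionally uniform) distribution; under `"derecruitment"`
#' deflation an airspace is rendered iff the applied pressure is at or
#' above its closing pressure ("digital" deflation), under `"isotropic"`
#' all airspaces stay open and shrink together ("analog" deflation), and
#' `"mixed"` combines both.
#'
#' Defaults emulate a healthy-lung acquisition: 40 adjacent slices, 47.7 um
#' voxels, airspace radii around 110 um (the alveolar scale), and a closing
#' pressure distribution under which roughly 5% of airspaces close between
#' 12 and 0 cmH2O of end-expiratory pressure.
#'
#' @param image_shape Pixels per slice, `c(rows, cols)`.
#' @param n_slices Number of slices per stack.
#' @param voxel_size_um Isotropic voxel side (um).
#' @param n_airspaces Candidate airspaces per slice.
#' @param radius_mean_um,radius_sd_um,radius_min_um Airspace radius
#'   distribution (Gaussian, truncated below at `radius_min_um`).
#' @param septum_um Minimum tissue wall thickness between airspaces (um).
#' @param closing_mu_cmH2O,closing_sd_cmH2O Critical-closing-pressure
#'   distribution parameters (cmH2O). `closing_mu_cmH2O = -Inf` forces all
#'   airspaces open at any pressure.
#' @param closing_dist `"gaussian"` (default) or `"uniform"` (same mean and
#'   sd, i.e. uniform on `mu +- sqrt(3) * sd`).
#' @param deflation_mode One of `"derecruitment"`, `"isotropic"`, `"mixed"`.
#' @param size_pressure_slope Fractional radius change per cmH2O relative
#'   to `reference_pressure_cmH2O`, used by the isotropic/mixed modes.
#' @param reference_pressure_cmH2O Pressure at which isotropic radii equal
#'   their nominal value.
#' @param gas_intensity,tissue_intensity Gray levels of gas and tissue;
#'   gas must be darker (airspaces are negative intensity peaks).
#' @param noise_sd Additive Gaussian noise scale (gray levels).
#' @param mask_radius_frac Lung ellipse semi-axes as a fraction of the
#'   image half-size.
#' @param notch_radius_frac Pericardiac exclusion disk radius as a fraction
#'   of the lung semi-axis; 0 disables the notch.
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(256L, 256L),
                         n_slices = 40L,
                         voxel_size_um = 47.7,
                         n_airspaces = 400L,
                         radius_mean_um = 110,
                         radius_sd_um = 15,
                         radius_min_um = 80,
                         septum_um = 50,
                         closing_mu_cmH2O = -8,
                         closing_sd_cmH2O = 5,
                         closing_dist = c("gaussian", "uniform"),
                         deflation_mode = c("derecruitment", "isotropic",
                                            "mixed"),
                         size_pressure_slope = 0.01,
                         reference_pressure_cmH2O = 0,
                         gas_intensity = 0.2,
                         tissue_intensity = 0.8,
                         noise_sd = 0.02,
                         mask_radius_frac = 0.9,
                         notch_radius_frac = 0.25,
                         seed = 1L) {
  spec <- list(
    image_shape = as.integer(image_shape),
    n_slices = as.integer(n_slices),
    voxel_size_um = voxel_size_um,
    n_airspaces = as.integer(n_airspaces),
    radius_mean_um = radius_mean_um,
    radius_sd_um = radius_sd_um,
    radius_min_um = radius_min_um,
    septum_um = septum_um,
    closing_mu_cmH2O = closing_mu_cmH2O,
    closing_sd_cmH2O = closing_sd_cmH2O,
    closing_dist = match.arg(closing_dist),
    deflation_mode = match.arg(deflation_mode),
    size_pressure_slope = size_pressure_slope,
    reference_pressure_cmH2O = reference_pressure_cmH2O,
    gas_intensity = gas_intensity,
    tissue_intensity = tissue_intensity,
    noise_sd = noise_sd,
    mask_radius_frac = mask_radius_frac,
    notch_radius_frac = notch_radius_frac,
    seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (length(s$image_shape) != 2L || any(s$image_shape < 16L))
    stop("image_shape must be two integers >= 16", call. = FALSE)
  if (s$n_slices < 1L) stop("n_slices must be >= 1", call. = FALSE)
  if (s$voxel_size_um <= 0) stop("voxel_size_um must be > 0", call. = FALSE)
  if (s$n_airspaces < 0L) stop("n_airspaces must be >= 0", call. = FALSE)
  if (!(s$radius_mean_um > s$septum_um) || !(s$septum_um > 0))
    stop("need radius_mean_um > septum_um > 0", call. = FALSE)
  if (s$radius_min_um <= 0 || s$radius_sd_um < 0)
    stop("radius_min_um must be > 0 and radius_sd_um >= 0", call. = FALSE)
  if (s$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!(s$gas_intensity < s$tissue_intensity))
    stop("gas_intensity must be darker than tissue_intensity",
         call. = FALSE)
  if (s$closing_sd_cmH2O < 0)
    stop("closing_sd_cmH2O must be >= 0", call. = FALSE)
  invisible(s)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %dx%d px, %d slices, %d airspaces/",
                     "slice, mode=%s, seed=%d\n"),
              x$image_shape[1], x$image_shape[2], x$n_slices,
              x$n_airspaces, x$deflation_mode, x$seed))
  invisible(x)
}

# lung parenchyma mask (ellipse) and pericardiac exclusion notch (circle
# centred on the medial mask border), both logical matrices
phantom_masks <- function(spec) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  ry <- spec$mask_radius_frac * (nr - 1) / 2
  rx <- spec$mask_radius_frac * (nc - 1) / 2
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  lung <- ((row - cy) / ry)^2 + ((col - cx) / rx)^2 <= 1
  excl <- matrix(FALSE, nr, nc)
  if (spec$notch_radius_frac > 0) {
    nrad <- spec$notch_radius_frac * min(rx, ry)
    # notch centred on the medial (left) border of the ellipse
    ncy <- cy; ncx <- cx - rx
    excl <- ((row - ncy)^2 + (col - ncx)^2 <= nrad^2) & lung
  }
  list(lung = lung, exclusion = excl)
}

# deterministic seed derivation for per-stage randomness; kept < 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}

# truncated-normal radii (um)
draw_radii <- function(n, spec) {
  r <- rnorm(n, spec$radius_mean_um, spec$radius_sd_um)
  bad <- which(r < spec$radius_min_um)
  tries <- 0L
  while (length(bad) && tries < 100L) {
    r[bad] <- rnorm(length(bad), spec$radius_mean_um, spec$radius_sd_um)
    bad <- which(r < spec$radius_min_um)
    tries <- tries + 1L
  }
  if (length(bad)) r[bad] <- spec$radius_min_um
  r
}

draw_closing <- function(n, spec) {
  if (!is.finite(spec$closing_mu_cmH2O))
    return(rep(spec$closing_mu_cmH2O, n))
  if (spec$closing_dist == "uniform") {
    h <- sqrt(3) * spec$closing_sd_cmH2O
    runif(n, spec$closing_mu_cmH2O - h, spec$closing_mu_cmH2O + h)
  } else {
    rnorm(n, spec$closing_mu_cmH2O, spec$closing_sd_cmH2O)
  }
}

# radius scale factor applied at pressure P for each deflation mode
pressure_radius_scale <- function(spec, pressure) {
  if (spec$deflation_mode == "derecruitment") return(1)
  1 + spec$size_pressure_slope * (pressure - spec$reference_pressure_cmH2O)
}

# dart-throwing placement of one slice's airspace centres; radii in px.
# `place_radius_px` is the per-airspace radius used for the separation rule
# (the largest radius the airspace will ever be rendered at).
place_slice <- function(spec, depth_px, radii_px, place_radius_px) {
  n <- length(radii_px)
  nr <- nrow(depth_px); nc <- ncol(depth_px)
  septum_px <- spec$septum_um / spec$voxel_size_um
  dmax <- 2 * max(place_radius_px, 1) + septum_px
  cell <- dmax
  gr <- ceiling(nr / cell); gc <- ceiling(nc / cell)
  grid <- vector("list", gr * gc)
  ys <- numeric(n); xs <- numeric(n)
  placed <- 0L
  max_tries <- 500L
  for (i in seq_len(n)) {
    ri <- place_radius_px[i]
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      y <- runif(1, 1, nr); x <- runif(1, 1, nc)
      py <- round(y); px <- round(x)
      if (depth_px[py, px] < ri + 1.5) next
      gy <- ceiling(py / cell); gx <- ceiling(px / cell)
      clash <- FALSE
      for (ddy in -1:1) for (ddx in -1:1) {
        gy2 <- gy + ddy; gx2 <- gx + ddx
        if (gy2 < 1 || gy2 > gr || gx2 < 1 || gx2 > gc) next
        for (j in grid[[(gx2 - 1L) * gr + gy2]]) {
          dist2 <- (ys[j] - y)^2 + (xs[j] - x)^2
          need <- place_radius_px[j] + ri + septum_px
          if (dist2 < need^2) { clash <- TRUE; break }
        }
        if (clash) break
      }
      if (!clash) {
        placed <- placed + 1L
        ys[i] <- y; xs[i] <- x
        cellid <- (gx - 1L) * gr + gy
        grid[[cellid]] <- c(grid[[cellid]], i)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf(paste0("could not place %d airspaces with septum %.3g um:",
                          " achievable maximum under this geometry is ",
                          "about %d"),
                   n, spec$septum_um, placed), call. = FALSE)
  }
  list(row = ys, col = xs)
}

# draw the shared airspace population: one set of centres/radii/closing
# pressures per slice, reused across all pressures of a series
phantom_population <- function(spec, max_pressure) {
  set.seed(derive_seed(spec$seed, 1L))
  masks <- phantom_masks(spec)
  region <- masks$lung & !masks$exclusion
  if (!any(region)) stop("empty placement region", call. = FALSE)
  depth_px <- as.matrix(EBImage::distmap(matrix(as.numeric(region),
                                                nrow(region)),
                                         metric = "euclidean"))
  vox <- spec$voxel_size_um
  out <- vector("list", spec$n_slices)
  scale_max <- pressure_radius_scale(spec, max_pressure)
  for (s in seq_len(spec$n_slices)) {
    n <- spec$n_airspaces
    if (n == 0L) {
      out[[s]] <- tibble::tibble(id = integer(), slice = integer(),
                                 row = numeric(), col = numeric(),
                                 radius_um = numeric(),
                                 closing_cmH2O = numeric())
      next
    }
    radius_um <- draw_radii(n, spec)
    closing <- draw_closing(n, spec)
    radii_px <- radius_um / vox
    pos <- place_slice(spec, depth_px, radii_px,
                       radii_px * max(scale_max, 1))
    out[[s]] <- tibble::tibble(
      id = seq_len(n), slice = s, row = pos$row, col = pos$col,
      radius_um = radius_um, closing_cmH2O = closing)
  }
  pop <- dplyr::bind_rows(out)
  if (nrow(pop)) pop$id <- seq_len(nrow(pop))
  list(airspaces = pop, masks = masks)
}

# paint one slice: tissue background, gas disks for open airspaces;
# returns the image and the per-airspace rendered pixel count
render_slice <- function(spec, slice_pop, scale) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  img <- matrix(spec$tissue_intensity, nr, nc)
  areas <- numeric(nrow(slice_pop))
  vox <- spec$voxel_size_um
  for (i in seq_len(nrow(slice_pop))) {
    if (!slice_pop$open[i]) next
    rp <- slice_pop$radius_um[i] * scale / vox
    y <- slice_pop$row[i]; x <- slice_pop$col[i]
    r0 <- max(1L, floor(y - rp)); r1 <- min(nr, ceiling(y + rp))
    c0 <- max(1L, floor(x - rp)); c1 <- min(nc, ceiling(x + rp))
    rows <- r0:r1; cols <- c0:c1
    dd <- outer((rows - y)^2, (cols - x)^2, `+`)
    inside <- dd <= rp^2
    block <- img[rows, cols]
    block[inside] <- spec$gas_intensity
    img[rows, cols] <- block
    areas[i] <- sum(inside)
  }
  list(img = img, areas = areas)
}

#' Generate a phantom pressure series with a shared airspace population
#'
#' One stack per pressure is rendered from a single airspace population
#' (same centres, radii and closing pressures), so the deflation behaviour
#' is a property of the population, not of resampling. In
#' `"derecruitment"` mode airspace i is rendered iff
#' `pressure >= closing_cmH2O[i]`; in `"isotropic"` mode all airspaces are
#' rendered with radii scaled by
#' `1 + size_pressure_slope * (pressure - reference)`; `"mixed"` applies
#' both rules.
#'
#' @param spec A [phantom_spec()].
#' @param pressures Numeric vector of airway pressures (cmH2O), e.g. the
#'   standard deflation protocol `c(12, 9, 6, 3, 0)`.
#' @return A list with one element per pressure, each a list with `stack`
#'   (a [slice_stack()]) and `truth` (a `ground_truth` object).
#' @export
pressure_series <- function(spec, pressures = c(12, 9, 6, 3, 0)) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(pressures) == 0L)
    stop("`pressures` must be non-empty", call. = FALSE)
  if (any(pressures < 0))
    stop("pressures must be >= 0", call. = FALSE)
  pop <- phantom_population(spec, max_pressure = max(pressures))
  partition <- partition_rois(
    boundary_depth(pop$masks$lung, spec$voxel_size_um),
    exclusion = pop$masks$exclusion)
  lapply(seq_along(pressures), function(k) {
    render_phantom_at(spec, pop, partition, pressures[k], k)
  })
}

#' Generate a single phantom stack with ground truth
#'
#' Equivalent to a one-pressure [pressure_series()].
#'
#' @param spec A [phantom_spec()].
#' @param pressure Airway pressure (cmH2O, >= 0).
#' @return A list with `stack` (a [slice_stack()]) and `truth` (a
#'   `ground_truth` object; see Details).
#'
#' @details The `ground_truth` object carries the airspace table (`id`,
#' `slice`, centre `row`/`col`, `radius_um`, `closing_cmH2O`, `open`,
#' rendered `area_vox`, and the concentric `roi` of the centre), the lung
#' and exclusion masks, the applied `pressure`, and a per-slice, per-ROI
#' table of true open counts and true gas-pixel areas.
#' @export
generate_phantom <- function(spec, pressure) {
  stopifnot(inherits(spec, "phantom_spec"), length(pressure) == 1L)
  pressure_series(spec, pressures = pressure)[[1]]
}

render_phantom_at <- function(spec, pop, partition, pressure, k) {
  air <- pop$airspaces
  air$open <- if (spec$deflation_mode == "isotropic") {
    rep(TRUE, nrow(air))
  } else {
    pressure >= air$closing_cmH2O
  }
  scale <- pressure_radius_scale(spec, pressure)
  if (scale <= 0)
    stop("size_pressure_slope drives radii to zero at pressure ",
         pressure, call. = FALSE)
  set.seed(derive_seed(spec$seed, 1000L + k))
  slices <- vector("list", spec$n_slices)
  areas <- numeric(nrow(air))
  for (s in seq_len(spec$n_slices)) {
    sp <- air[air$slice == s, , drop = FALSE]
    rd <- render_slice(spec, sp, scale)
    img <- rd$img
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sd),
                          nrow(img), ncol(img))
    slices[[s]] <- img
    areas[air$slice == s] <- rd$areas
  }
  air$area_vox <- areas
  air$roi <- roi_at(partition, round(air$row), round(air$col))
  per_slice <- air |>
    dplyr::filter(.data$open) |>
    dplyr::group_by(slice = .data$slice, roi = .data$roi) |>
    dplyr::summarise(true_count = dplyr::n(),
                     true_area_vox = sum(.data$area_vox),
                     .groups = "drop")
  truth <- structure(list(
    airspaces = air,
    lung_mask = pop$masks$lung,
    exclusion_mask = pop$masks$exclusion,
    partition = partition,
    per_slice = per_slice,
    pressure = pressure,
    spec = spec), class = "ground_truth")
  list(stack = slice_stack(slices, voxel_size_um = spec$voxel_size_um),
       truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d airspaces (%d open) at %.3g cmH2O\n",
              nrow(x$airspaces), sum(x$airspaces$open), x$pressure))
  invisible(x)
}

#' Write a phantom (stack, masks, ground truth) to a directory
#'
#' Writes the slice stack as a multi-page TIFF, the lung/exclusion masks as
#' single-page TIFFs, the airspace table as CSV and the scalar metadata as
#' JSON.
#'
#' @param phantom A list with `stack` and `truth`, as returned by
#'   [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(phantom$stack, file.path(dir, "stack.tif"))
  write_mask(phantom$truth$lung_mask, file.path(dir, "lung_mask.tif"))
  write_mask(phantom$truth$exclusion_mask,
             file.path(dir, "exclusion_mask.tif"))
  readr::write_csv(phantom$truth$airspaces,
                   file.path(dir, "airspaces.csv"))
  jsonlite::write_json(
    list(pressure = phantom$truth$pressure,
         voxel_size_um = phantom$stack$voxel_size_um,
         n_slices = length(phantom$stack$slices),
         spec = unclass(phantom$truth$spec)),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
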