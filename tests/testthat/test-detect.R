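test_that("black top-hat equals the brute-force min/max oracle exactly", {
  for (img in small_image_fixtures()) {
    for (r in 1:3) {
      expect_equal(black_tophat(img, r), oracle_black_tophat(img, r),
                   tolerance = 0)
    }
  }
})

test_that("black top-hat handles flat images, single dark pixels and bad radii", {
  expect_equal(black_tophat(matrix(2, 10, 10), 3),
               matrix(0, 10, 10))
  # single dark pixel of depth d responds with exactly d at radius 1
  img <- matrix(1, 7, 7); img[4, 4] <- 0.35
  th <- black_tophat(img, 1)
  expect_equal(th[4, 4], 0.65)
  expect_equal(sum(th > 0), 1L)
  expect_error(black_tophat(matrix(0, 5, 5), 3), "larger than the slice")
  expect_true(all(black_tophat(small_image_fixtures()$rand16_1, 2) >= 0))
})

test_that("binarization follows the threshold rules", {
  p_otsu <- detect_params()
  p_frac <- detect_params(binarize_rule = "fraction", fraction = 0.5)
  zero <- matrix(0, 8, 8)
  expect_equal(binarize_stack(list(zero), p_otsu)[[1]],
               matrix(FALSE, 8, 8))
  # bimodal response: Otsu threshold separates the modes
  resp <- matrix(0, 10, 10); resp[3:5, 3:5] <- 8
  bw <- binarize_stack(list(resp), p_otsu)[[1]]
  expect_identical(bw, resp > 4)
  # fixed fraction: threshold at half the max
  resp2 <- matrix(c(0, 4, 6, 10), 2, 2)
  bw2 <- binarize_stack(list(resp2), p_frac)[[1]]
  expect_identical(bw2, resp2 > 5)
  expect_error(binarize_stack(list(), p_otsu), "non-empty")
})

test_that("superimposition is the pixel-wise union", {
  A <- matrix(FALSE, 6, 6); A[2:3, 2:3] <- TRUE
  B <- matrix(FALSE, 6, 6); B[5, 5:6] <- TRUE
  none <- matrix(FALSE, 6, 6)
  expect_identical(superimpose(list(A, none)), A)
  expect_identical(superimpose(list(A, A)), A)
  expect_equal(sum(superimpose(list(A, B))), sum(A) + sum(B))
  expect_error(superimpose(list(A, matrix(FALSE, 3, 3))), "shape")
  expect_error(superimpose(list()), "non-empty")
})

test_that("regional minima merge plateaus and respect the mask", {
  x <- matrix(5, 8, 8)
  x[2:3, 2:3] <- 1      # one 4-pixel plateau
  x[6, 6] <- 2          # one isolated minimum
  rm_ <- regional_minima(x)
  expect_equal(nrow(rm_$peaks), 2L)
  expect_equal(sort(rm_$peaks$value), c(1, 2))
  # plateau fragment with a darker neighbour is not a minimum
  y <- matrix(9, 5, 7)
  y[3, 2:5] <- 4        # plateau ...
  y[3, 6] <- 1          # ... touching a darker pixel
  rm2 <- regional_minima(y)
  expect_equal(rm2$peaks$value, 1)
  # masking restricts both the candidates and the comparison set
  msk <- matrix(TRUE, 5, 7); msk[, 6:7] <- FALSE
  rm3 <- regional_minima(y, msk)
  expect_equal(rm3$peaks$value, 4)
})

test_that("airspace counting finds separated dark disks and their areas", {
  img <- matrix(0.8, 48, 48)
  centers <- list(c(10, 10), c(10, 35), c(35, 22))
  for (cc in centers) {
    d <- outer((1:48 - cc[1])^2, (1:48 - cc[2])^2, `+`)
    img[d <= 9] <- 0.2
  }
  p <- detect_params()
  th <- lapply(p$se_radii_vox[p$se_radii_vox < 24], black_tophat,
               slice = img)
  cand <- superimpose(binarize_stack(th, p))
  res <- count_airspaces(img, cand, params = p)
  expect_equal(nrow(res$airspaces), 3L)
  disk_area <- sum(outer((-4:4)^2, (-4:4)^2, `+`) <= 9)
  expect_true(all(abs(res$airspaces$area_vox - disk_area) <= 2))
  # empty candidate set
  res0 <- count_airspaces(img, matrix(FALSE, 48, 48), params = p)
  expect_equal(nrow(res0$airspaces), 0L)
  expect_true(all(res0$labels == 0L))
  # a constant-depth disk is one plateau, one count
  img1 <- matrix(0.8, 24, 24)
  d <- outer((1:24 - 12)^2, (1:24 - 12)^2, `+`)
  img1[d <= 16] <- 0.2
  p0 <- detect_params(smooth_sigma_px = 0)
  cand1 <- img1 < 0.5
  res1 <- count_airspaces(img1, cand1, params = p0)
  expect_equal(nrow(res1$airspaces), 1L)
})

test_that("candidate components are split one label per contained peak", {
  # dumbbell: two pits joined by a dark bridge, all below threshold
  img <- matrix(0.9, 15, 25)
  img[6:10, 4:20] <- 0.5       # connected dark slab
  img[8, 7] <- 0.1             # pit 1
  img[8, 17] <- 0.15           # pit 2
  p <- detect_params(smooth_sigma_px = 0, min_area_vox = 1)
  res <- count_airspaces(img, img < 0.7, params = p)
  expect_equal(nrow(res$airspaces), 2L)
  # the slab's pixels are partitioned between the two labels
  expect_equal(sum(res$airspaces$area_vox), sum(img < 0.7))
})

test_that("detection on noiseless phantoms recovers ground truth exactly", {
  sp <- tiny_spec(image_shape = c(128L, 128L), n_slices = 3L,
                  n_airspaces = 25L, septum_um = 100,
                  radius_min_um = 96, radius_mean_um = 120,
                  radius_sd_um = 10, closing_mu_cmH2O = -Inf)
  ph <- generate_phantom(sp, 6)
  det <- detect_stack(ph$stack, masks = ph$truth$lung_mask,
                      exclusions = ph$truth$exclusion_mask)
  expect_equal(nrow(det$airspaces), sum(ph$truth$airspaces$open))
  expect_equal(sum(det$airspaces$area_vox),
               sum(ph$truth$airspaces$area_vox[ph$truth$airspaces$open]))
  # per-slice counts agree too
  truth_counts <- ph$truth$per_slice |>
    dplyr::group_by(slice) |>
    dplyr::summarise(n = sum(true_count))
  expect_equal(det$per_slice$count, truth_counts$n)
})

test_that("no detected pixel falls outside mask minus exclusion", {
  sp <- tiny_spec(image_shape = c(128L, 128L), n_airspaces = 30L,
                  n_slices = 1L, noise_sd = 0.04)
  ph <- generate_phantom(sp, 12)
  det <- detect_stack(ph$stack, masks = ph$truth$lung_mask,
                      exclusions = ph$truth$exclusion_mask)
  allowed <- ph$truth$lung_mask & !ph$truth$exclusion_mask
  expect_true(all(allowed[det$labels[[1]] > 0]))
})

test_that("counting is invariant to positive affine intensity changes under Otsu", {
  sp <- tiny_spec(image_shape = c(128L, 128L), n_airspaces = 30L,
                  n_slices = 1L, noise_sd = 0.03, seed = 8L)
  ph <- generate_phantom(sp, 12)
  p <- detect_params()  # otsu default
  d1 <- detect_stack(ph$stack, masks = ph$truth$lung_mask, params = p)
  st2 <- ph$stack
  st2$slices <- lapply(st2$slices, function(s) 3.7 * s + 0.2)
  d2 <- detect_stack(st2, masks = ph$truth$lung_mask, params = p)
  expect_identical(d1$labels, d2$labels)
  expect_equal(d1$airspaces$area_vox, d2$airspaces$area_vox)
})

test_that("an additional well-separated dark disk increases the count by one", {
  img <- matrix(0.8, 90, 90)
  paint <- function(m, cy, cx, r) {
    d <- outer((seq_len(nrow(m)) - cy)^2, (seq_len(ncol(m)) - cx)^2, `+`)
    m[d <= r^2] <- 0.2
    m
  }
  img <- paint(img, 20, 20, 3)
  img <- paint(img, 20, 60, 3)
  p <- detect_params(se_radii_vox = c(1, 2, 3, 5, 8))
  n_before <- nrow(detect_stack(slice_stack(img), params = p)$airspaces)
  img2 <- paint(img, 70, 40, 3)  # >= 2 * max radius away from the others
  n_after <- nrow(detect_stack(slice_stack(img2), params = p)$airspaces)
  expect_equal(n_after, n_before + 1L)
})

test_that("degenerate stacks and mismatched masks are handled", {
  st <- slice_stack(list(matrix(1, 40, 40), matrix(1, 40, 40)))
  det <- detect_stack(st)
  expect_equal(det$per_slice$count, c(0L, 0L))
  expect_error(
    detect_stack(st, masks = list(matrix(TRUE, 40, 40))),
    "does not match")
  expect_error(detect_params(se_radii_vox = c(3, 2)), "increasing")
  expect_error(detect_params(min_area_vox = 0), "min_area_vox")
})
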