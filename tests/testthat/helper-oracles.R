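# Brute-force oracles, written independently of the package internals.
# They define the expected behaviour by direct enumeration on small inputs.

# grayscale erosion/dilation with an arbitrary 0/1 kernel; pixels outside
# the image are ignored (min over the in-image kernel support)
oracle_filter <- function(x, kern, op = min) {
  nr <- nrow(x); nc <- ncol(x)
  kr <- (nrow(kern) - 1L) %/% 2L; kc <- (ncol(kern) - 1L) %/% 2L
  off <- which(kern != 0, arr.ind = TRUE)
  off[, 1] <- off[, 1] - kr - 1L
  off[, 2] <- off[, 2] - kc - 1L
  out <- x
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- i + off[, 1]; jj <- j + off[, 2]
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    out[i, j] <- op(x[cbind(ii[ok], jj[ok])])
  }
  out
}

oracle_black_tophat <- function(x, radius) {
  kern <- disk_kernel(radius)
  closed <- oracle_filter(oracle_filter(x, kern, max), kern, min)
  res <- closed - x
  res[res < 0] <- 0
  res
}

# all-pairs Euclidean distance from each in-mask pixel to the nearest
# out-of-mask pixel, in mm
oracle_depth <- function(mask, voxel_size_um) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j]) {
      out[i, j] <- sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2))
    }
  }
  out * voxel_size_um / 1000
}

# direct-DFT implementation of the single-distance phase filter transfer
# function on one slice (no FFT library; O(N^4) double loop)
oracle_paganin_linear <- function(x, energy_keV, distance_m,
                                  pixel_size_um, delta_beta) {
  n <- nrow(x); m <- ncol(x)
  lambda <- 1.23984198e-9 / energy_keV
  px <- pixel_size_um * 1e-6
  fy <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n] / (n * px)
  fx <- c(0:floor(m / 2), -(ceiling(m / 2) - 1):-1)[1:m] / (m * px)
  H <- 1 / (1 + pi * lambda * distance_m * delta_beta *
              outer(fy^2, fx^2, `+`))
  # forward DFT
  W_n <- exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  W_m <- exp(-2i * pi * outer(0:(m - 1), 0:(m - 1)) / m)
  X <- W_n %*% x %*% W_m
  Y <- X * H
  out <- Conj(W_n) %*% Y %*% Conj(W_m) / (n * m)
  Re(out)
}

# total variation (sum of absolute horizontal + vertical differences)
total_variation <- function(x) {
  sum(abs(diff(x))) + sum(abs(t(diff(t(x)))))
}

rot90 <- function(x) t(x)[ncol(x):1, , drop = FALSE]

# fixture suite of small grayscale images for exact-equivalence checks
small_image_fixtures <- function(seed = 7) {
  set.seed(seed)
  fx <- list(
    constant = matrix(0.5, 9, 9),
    impulse = {m <- matrix(1, 9, 9); m[5, 5] <- 0; m},
    gradient = outer(1:12, 1:10, `+`) / 22,
    checker = outer(1:8, 1:8, function(a, b) (a + b) %% 2),
    two_blobs = {
      m <- matrix(0.9, 16, 16)
      m[3:5, 3:5] <- 0.1; m[10:13, 9:12] <- 0.2; m
    })
  for (k in 1:6)
    fx[[paste0("rand16_", k)]] <- matrix(runif(256), 16, 16)
  for (k in 1:3)
    fx[[paste0("rand32_", k)]] <- matrix(runif(1024), 32, 32)
  fx
}

# fixture suite of small binary masks for depth-map checks
small_mask_fixtures <- function(seed = 11) {
  set.seed(seed)
  fx <- list(
    line = {m <- matrix(0L, 9, 9); m[5, 2:8] <- 1L; m},
    square = {m <- matrix(0L, 12, 12); m[3:10, 3:10] <- 1L; m},
    disk = {
      d <- outer(-8:8, -8:8, function(a, b) a^2 + b^2)
      matrix(as.integer(d <= 49), 17, 17)
    },
    l_shape = {
      m <- matrix(0L, 14, 14)
      m[2:12, 2:5] <- 1L; m[9:12, 2:12] <- 1L; m
    })
  for (k in 1:4) {
    m <- matrix(as.integer(runif(32 * 32) > 0.4), 32, 32)
    if (!any(m == 0L)) m[1, 1] <- 0L
    fx[[paste0("rand_", k)]] <- m
  }
  fx
}

# small phantom spec used across tests; big enough to render a few dozen
# resolvable airspaces in seconds
tiny_spec <- function(...) {
  args <- list(...)
  defaults <- list(image_shape = c(96L, 96L), n_slices = 2L,
                   n_airspaces = 25L, noise_sd = 0, seed = 3L)
  do.call(phantom_spec, utils::modifyList(defaults, args))
}
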