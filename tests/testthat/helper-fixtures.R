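# Seeded fixtures shared by the test files. All randomness is seeded here so
# every test run sees identical inputs.

# Smooth random texture (registrable: broad spatial autocorrelation).
smooth_texture <- function(h, w, seed, sigma = 1.5) {
  set.seed(seed)
  img <- matrix(runif(h * w), h, w)
  k <- caimtools:::gaussian_kernel1d(sigma, 2L * ceiling(3 * sigma) + 1L)
  caimtools:::convolve_separable(img, k)
}

# Brute-force shift search: argmin of ssd_objective over the central crop,
# independent of the FFT implementation. Offset (x, y) in [-ms, ms]^2 maps
# to ssd_objective(template, crop, x - ms, y - ms).
oracle_shift <- function(template, frame, ms) {
  h <- nrow(template); w <- ncol(template)
  crop <- frame[(ms + 1):(h - ms), (ms + 1):(w - ms), drop = FALSE]
  best <- NULL
  for (x in -ms:ms) {
    for (y in -ms:ms) {
      sc <- ssd_objective(template, crop, x - ms, y - ms)
      cand <- list(x = x, y = y, sc = sc)
      if (is.null(best) || sc < best$sc - 1e-15 ||
          (abs(sc - best$sc) <= 1e-15 &&
           (abs(x) + abs(y) < abs(best$x) + abs(best$y) ||
            (abs(x) + abs(y) == abs(best$x) + abs(best$y) &&
             (x < best$x || (x == best$x && y < best$y)))))) {
        best <- cand
      }
    }
  }
  c(best$x, best$y)
}

# Gaussian blob image plus blob centres, for cross-session fixtures.
blob_image <- function(n_blobs, h = 128, w = 128, sigma = 3, seed = 1,
                       margin = 20) {
  set.seed(seed)
  cen <- cbind(runif(n_blobs, margin, h - margin),
               runif(n_blobs, margin, w - margin))
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  img <- matrix(0, h, w)
  for (k in seq_len(n_blobs)) {
    img <- img + exp(-((rows - cen[k, 1])^2 + (cols - cen[k, 2])^2) /
                       (2 * sigma^2))
  }
  list(img = 100 + 100 * img, centres = cen, sigma = sigma)
}

# Label mask of disks at given centres.
disk_mask <- function(centres, h, w, radius) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  lab <- matrix(0L, h, w)
  for (k in seq_len(nrow(centres))) {
    lab[(rows - centres[k, 1])^2 + (cols - centres[k, 2])^2 <= radius^2] <- k
  }
  label_mask(lab, relabel = FALSE)
}

# Build a target session image + mask so that the map target -> reference
# is exactly rigid_matrix(theta, dr, dc) about the image centre.
make_target_session <- function(ref_img, ref_mask, theta_deg, dr, dc) {
  h <- nrow(ref_img); w <- ncol(ref_img)
  centre <- c((h + 1) / 2, (w + 1) / 2)
  M <- caimtools:::rigid_matrix(theta_deg * pi / 180, dr, dc, centre)
  Minv <- caimtools:::invert_transform(M)
  tgt_img <- caimtools:::warp_image(ref_img, Minv, filter = "bilinear",
                                    fill = min(ref_img))
  tgt_mask <- suppressMessages(
    transform_mask(ref_mask, planar_transform(Minv, "affine")))
  list(img = tgt_img, mask = tgt_mask, M = M)
}

# Distance from each ROI centroid of `mask` to its nearest planted centre.
centroid_errors <- function(mask, centres) {
  tb <- roi_table(mask)
  if (nrow(tb) == 0) return(numeric(0))
  vapply(seq_len(nrow(tb)), function(i) {
    min(sqrt((centres[, 1] - tb$row[i])^2 + (centres[, 2] - tb$col[i])^2))
  }, numeric(1))
}

# How many planted centres have an ROI centroid within `tol` px.
recovered_count <- function(mask, centres, tol = 2) {
  tb <- roi_table(mask)
  if (nrow(tb) == 0) return(0L)
  sum(vapply(seq_len(nrow(centres)), function(k) {
    any(sqrt((tb$row - centres[k, 1])^2 + (tb$col - centres[k, 2])^2) <= tol)
  }, logical(1)))
}
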