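# Trial-by-trial identification of active neurons.
#
# Two online algorithms segment one trial's stack into active-neuron ROIs:
#   #1  cumulative dF/F -> Renyi-entropy auto-threshold -> labeling
#   #2  baseline binarization -> exponential run amplification -> labeling

#' Parameters for segmentation algorithm #1
#'
#' @param gaussian_sigma Gaussian sigma (px) used to smooth the binary image
#'   so that neighbouring positive pixels merge.
#' @param area_threshold Minimum ROI area in pixels (default 16).
#' @param intensity_threshold Minimum ROI peak in cumulative-dF/F units
#'   (default 10).
#' @param histogram_bins Histogram bins for the entropy threshold
#'   (default 256).
#' @return A list of class `Alg1Params`.
#' @export
alg1_params <- function(gaussian_sigma = 1, area_threshold = 16,
                        intensity_threshold = 10, histogram_bins = 256L) {
  stopifnot(gaussian_sigma > 0, area_threshold >= 1, histogram_bins >= 2)
  structure(list(gaussian_sigma = gaussian_sigma,
                 area_threshold = area_threshold,
                 intensity_threshold = intensity_threshold,
                 histogram_bins = as.integer(histogram_bins)),
            class = "Alg1Params")
}

#' Parameters for segmentation algorithm #2
#'
#' @param alpha Amplification coefficient, > 1 (default 1.5, which keeps
#'   the geometrically amplified index within a usable dynamic range for
#'   trial-length runs; larger values sharpen run discrimination but let a
#'   long run's smoothed tail exceed `T` far from the cell).
#' @param beta Second amplification coefficient; default `1/alpha`.
#' @param indicator_frames `F`: number of continuous above-threshold frames
#'   considered a valid activity, set from the fluorescent indicator's
#'   dynamics (default 10).
#' @param k Additive offset on the final threshold `T` (default 0).
#' @param smooth_sigma Gaussian sigma for smoothing the sensitivity image
#'   (default 1).
#' @param cell_window Odd kernel size (px) of the cell-sized smoothing
#'   window (default 13).
#' @param threshold_mode `"linear"` gives `T = alpha * F + k` (the default),
#'   `"geometric"` gives `T = alpha^F + k` (matching the geometric growth of
#'   the amplified index).
#' @param baseline_nsd Pixel binarization threshold in baseline SDs
#'   (default 3).
#' @param area_threshold Minimum ROI area in pixels (default 16).
#' @return A list of class `Alg2Params`.
#' @export
alg2_params <- function(alpha = 1.5, beta = 1 / alpha, indicator_frames = 10L,
                        k = 0, smooth_sigma = 1, cell_window = 13L,
                        threshold_mode = c("linear", "geometric"),
                        baseline_nsd = 3, area_threshold = 16) {
  stopifnot(alpha > 1, indicator_frames >= 1, cell_window >= 3,
            cell_window %% 2 == 1)
  structure(list(alpha = alpha, beta = beta,
                 indicator_frames = as.integer(indicator_frames), k = k,
                 smooth_sigma = smooth_sigma,
                 cell_window = as.integer(cell_window),
                 threshold_mode = match.arg(threshold_mode),
                 baseline_nsd = baseline_nsd,
                 area_threshold = area_threshold),
            class = "Alg2Params")
}

# Baseline mean over the trial's baseline frames, per pixel.
baseline_mean <- function(stack, trial) {
  bl <- stack$data[, , trial$baseline_frames, drop = FALSE]
  rowMeans(bl, dims = 2L)
}

#' Per-pixel dF/F of a trial stack
#'
#' For each pixel, subtracts its mean intensity over the baseline frames and
#' divides by it. Pixels whose baseline mean is at or below `eps` (a
#' division-by-zero guard, default 1e-6 of the stack's dynamic range) get a
#' dF/F of 0; their count is reported via `attr(, "n_degenerate")` and a
#' message.
#'
#' @param stack An [image_stack()].
#' @param trial A [trial_structure()].
#' @param eps Baseline-mean floor below which a pixel is treated as
#'   degenerate.
#' @return `H x W x T` array of dF/F values.
#' @export
pixel_dff <- function(stack, trial, eps = NULL) {
  stopifnot(inherits(stack, "ImageStack"), inherits(trial, "TrialStructure"))
  sbar <- baseline_mean(stack, trial)
  if (is.null(eps)) eps <- 1e-6 * max(diff(range(stack$data)), 1)
  bad <- sbar <= eps
  n_bad <- sum(bad)
  if (n_bad > 0) {
    message(sprintf("pixel_dff: %d pixel(s) with near-zero baseline set to 0",
                    n_bad))
  }
  denom <- sbar
  denom[bad] <- 1
  dff <- sweep(sweep(stack$data, c(1, 2), sbar, "-"), c(1, 2), denom, "/")
  if (n_bad > 0) dff[array(bad, dim = dim(dff))] <- 0
  attr(dff, "n_degenerate") <- n_bad
  dff
}

#' Cumulative dF/F image (algorithm #1 score image)
#'
#' Sums each pixel's dF/F over the response frames, floors negative sums at
#' zero, and multiplies by the pixel's temporal standard deviation of dF/F
#' over the response period — a per-pixel scale that boosts transient pixels
#' over flat ones of equal sum.
#'
#' @param dff `H x W x T` dF/F array from [pixel_dff()].
#' @param trial A [trial_structure()]; its `response_frames` must be
#'   nonempty.
#' @return `H x W` cumulative dF/F image.
#' @export
cumulative_dff_image <- function(dff, trial) {
  resp <- trial$response_frames
  stopifnot(length(resp) >= 1)
  s <- dff[, , resp, drop = FALSE]
  v_tilde <- pmax(rowSums(s, dims = 2L), 0)
  mu <- rowMeans(s, dims = 2L)
  sd_t <- sqrt(rowMeans(s^2, dims = 2L) - mu^2)
  sd_t[sd_t < 0] <- 0   # guard tiny negative round-off
  v_tilde * sd_t
}

# Renyi entropy of the foreground/background split at threshold t for the
# probability histogram p; direct formula, used by both the implementation
# and (in loop form) the test oracle.
renyi_criterion <- function(p, t, rho) {
  P1 <- sum(p[seq_len(t)])
  P2 <- 1 - P1
  if (P1 <= 0 || P2 <= 0) return(-Inf)
  b <- p[seq_len(t)] / P1
  f <- p[(t + 1L):length(p)] / P2
  b <- b[b > 0]; f <- f[f > 0]
  if (abs(rho - 1) < 1e-12) {
    -sum(b * log(b)) - sum(f * log(f))
  } else {
    (1 / (1 - rho)) * (log(sum(b^rho)) + log(sum(f^rho)))
  }
}

#' Renyi-entropy automatic threshold
#'
#' Selects a global threshold for a grayscale image by the three-order Renyi
#' entropy procedure: the image is linearly rescaled to `bins` histogram
#' bins, an optimal split is computed for entropy orders 1/2, 1 (Shannon
#' limit) and 2, and the three candidate thresholds are combined with the
#' published order-dependent weighting (closeness window of 5 bins). The
#' returned threshold is mapped back to original intensity units; pixels
#' strictly above it are foreground.
#'
#' @param image Numeric matrix with at least two distinct values.
#' @param bins Number of histogram bins (default 256).
#' @return Scalar threshold in the image's original units, with
#'   `attr(, "bin")` the selected (0-based) bin index.
#' @export
renyi_threshold <- function(image, bins = 256L) {
  rng <- range(image)
  if (diff(rng) == 0) stop("no threshold: image is constant")
  bins <- as.integer(bins)
  scaled <- (image - rng[1L]) / diff(rng)
  idx <- pmin(as.integer(floor(scaled * bins)) + 1L, bins)
  p <- tabulate(idx, nbins = bins) / length(image)
  best_for <- function(rho) {
    crit <- vapply(seq_len(bins - 1L), function(t) renyi_criterion(p, t, rho),
                   numeric(1))
    which.max(crit)
  }
  t_half <- best_for(0.5)
  t_one <- best_for(1)
  t_two <- best_for(2)
  ts <- sort(c(t_half, t_one, t_two))
  t1 <- ts[1L]; t2 <- ts[2L]; t3 <- ts[3L]
  if (abs(t1 - t2) <= 5L) {
    if (abs(t2 - t3) <= 5L) {
      b1 <- 1; b2 <- 2; b3 <- 1
    } else {
      b1 <- 0; b2 <- 1; b3 <- 3
    }
  } else if (abs(t2 - t3) <= 5L) {
    b1 <- 3; b2 <- 1; b3 <- 0
  } else {
    b1 <- 1; b2 <- 2; b3 <- 1
  }
  P <- cumsum(p)
  omega <- P[t3] - P[t1]
  t_opt <- t1 * (P[t1] + 0.25 * omega * b1) + 0.25 * t2 * omega * b2 +
    t3 * ((1 - P[t3]) + 0.25 * omega * b3)
  t_bin <- floor(t_opt)           # 1-based bin index of the cut
  thr <- rng[1L] + (t_bin / bins) * diff(rng)
  attr(thr, "bin") <- t_bin
  thr
}

#' Label candidate ROIs from a binary image
#'
#' Smooths the binary image with a Gaussian (merging neighbouring positive
#' pixels), re-binarizes at 0.5, labels 8-connected components, and drops
#' components smaller than `area_threshold` or whose peak over `score_image`
#' is below `intensity_threshold`. ROIs are ordered by descending peak score,
#' ties by centroid (row, col).
#'
#' @param binary 0/1 matrix of positive pixels.
#' @param score_image Matrix of per-pixel scores used for the intensity
#'   filter and ROI ordering.
#' @param sigma Gaussian sigma (px); `0` skips smoothing.
#' @param area_threshold Minimum component area (px).
#' @param intensity_threshold Minimum peak score; use `-Inf` to disable.
#' @return A [label_mask()] (possibly empty).
#' @export
label_rois <- function(binary, score_image, sigma = 1, area_threshold = 16,
                       intensity_threshold = -Inf) {
  stopifnot(is.matrix(binary), all(binary %in% c(0, 1)))
  if (sigma > 0) {
    size <- 2L * ceiling(3 * sigma) + 1L
    sm <- convolve_separable(binary, gaussian_kernel1d(sigma, size))
    binary <- (sm > 0.5) * 1
  }
  lab <- label_components(binary)
  mask <- label_mask(lab, score_image = score_image, relabel = FALSE)
  keep <- Filter(function(r) {
    r$area >= area_threshold && r$peak >= intensity_threshold
  }, mask$rois)
  if (!length(keep)) {
    return(label_mask(matrix(0L, nrow(binary), ncol(binary)),
                      score_image = score_image))
  }
  o <- order(-vapply(keep, `[[`, numeric(1), "peak"),
             vapply(keep, function(r) r$centroid[["row"]], numeric(1)),
             vapply(keep, function(r) r$centroid[["col"]], numeric(1)))
  out <- matrix(0L, nrow(binary), ncol(binary))
  for (i in seq_along(o)) out[keep[[o[i]]]$pixels] <- i
  label_mask(out, score_image = score_image, relabel = FALSE)
}

#' Segment one trial with algorithm #1 (cumulative dF/F + entropy)
#'
#' Pipeline: per-pixel dF/F, cumulative dF/F image over the response window,
#' Renyi-entropy auto-threshold, Gaussian smoothing and component labeling
#' with area and intensity filters. The cumulative image is the score image
#' for filtering and ordering.
#'
#' @param stack An [image_stack()] holding one trial.
#' @param trial A [trial_structure()].
#' @param params An [alg1_params()].
#' @return A [label_mask()] of active ROIs, ordered by descending peak
#'   cumulative dF/F.
#' @export
segment_trial_alg1 <- function(stack, trial, params = alg1_params()) {
  dff <- pixel_dff(stack, trial)
  v <- cumulative_dff_image(dff, trial)
  thr <- tryCatch(renyi_threshold(v, params$histogram_bins),
                  error = function(e) NULL)
  if (is.null(thr)) {
    return(label_mask(matrix(0L, nrow(v), ncol(v)), score_image = v))
  }
  binary <- (v > thr) * 1
  label_rois(binary, v, sigma = params$gaussian_sigma,
             area_threshold = params$area_threshold,
             intensity_threshold = params$intensity_threshold)
}

#' Binarize a trial stack against its baseline statistics (algorithm #2)
#'
#' Computes each pixel's baseline mean and population SD over the baseline
#' frames and flags frames where the pixel exceeds
#' `mean + baseline_nsd * SD`. Pixels with zero baseline SD fall back to a
#' tiny epsilon threshold above the mean; their count is reported.
#'
#' @param stack An [image_stack()].
#' @param trial A [trial_structure()] with at least 2 baseline frames.
#' @param baseline_nsd Threshold in baseline SDs (default 3).
#' @return `H x W x T` 0/1 array; `attr(, "n_zero_sd")` counts degenerate
#'   pixels.
#' @export
binarize_stack <- function(stack, trial, baseline_nsd = 3) {
  stopifnot(length(trial$baseline_frames) >= 2)
  bl <- stack$data[, , trial$baseline_frames, drop = FALSE]
  sbar <- rowMeans(bl, dims = 2L)
  d <- sqrt(pmax(rowMeans(bl^2, dims = 2L) - sbar^2, 0))
  zero_sd <- d == 0
  n0 <- sum(zero_sd)
  if (n0 > 0) {
    message(sprintf("binarize_stack: %d pixel(s) with zero baseline SD", n0))
    d[zero_sd] <- .Machine$double.eps * pmax(abs(sbar[zero_sd]), 1) /
      baseline_nsd
  }
  thr <- sbar + baseline_nsd * d
  chi <- (stack$data > array(thr, dim = dim(stack$data))) * 1
  attr(chi, "n_zero_sd") <- n0
  chi
}

#' Exponentially amplify runs of consecutive above-threshold frames
#'
#' Applies the per-pixel recurrence `L_t = alpha (L_{t-1} + beta) chi_t`
#' (with `L_1 = chi_1`) along time. Continuous runs grow geometrically —
#' with `beta = 1/alpha`, a run of `n` ones reaches
#' `(alpha^n - 1)/(alpha - 1)` — while isolated noise frames stay at height
#' ~1 and any zero resets the accumulator.
#'
#' @param chi 0/1 array (`H x W x T`, or a vector treated as one pixel's
#'   time series).
#' @param alpha Amplification factor > 1.
#' @param beta Additive constant; default `1/alpha`.
#' @return Array (or vector) of amplified values, same shape as `chi`.
#' @export
amplify_runs <- function(chi, alpha = 2, beta = 1 / alpha) {
  stopifnot(alpha > 1)
  vec <- is.null(dim(chi))
  if (vec) chi <- array(chi, dim = c(1L, 1L, length(chi)))
  nt <- dim(chi)[3L]
  L <- chi
  if (nt >= 2L) {
    for (t in 2:nt) {
      L[, , t] <- alpha * (L[, , t - 1L] + beta) * chi[, , t]
    }
  }
  if (vec) as.vector(L) else L
}

#' Sensitivity index image (algorithm #2)
#'
#' Sums the amplified binary index over time and smooths it with a
#' normalized Gaussian kernel truncated to a cell-sized window, yielding a
#' per-pixel score of how much sustained above-threshold activity the pixel
#' carried.
#'
#' @param L `H x W x T` array from [amplify_runs()].
#' @param smooth_sigma Gaussian sigma (default 1).
#' @param cell_window Odd kernel size in pixels (default 13).
#' @return `H x W` sensitivity image.
#' @export
sensitivity_image <- function(L, smooth_sigma = 1, cell_window = 13L) {
  stopifnot(cell_window >= 3, cell_window %% 2 == 1)
  s <- rowSums(L, dims = 2L)
  convolve_separable(s, gaussian_kernel1d(smooth_sigma, as.integer(cell_window)))
}

#' Segment one trial with algorithm #2 (sensitivity index)
#'
#' Pipeline: binarize against baseline statistics, amplify continuous runs,
#' sum and smooth into a sensitivity image, threshold at
#' `T = alpha * F + k` (or `alpha^F + k` in geometric mode), and label
#' 8-connected components with the area filter. ROIs are ordered by their
#' peak pixel dF/F.
#'
#' @param stack An [image_stack()] holding one trial.
#' @param trial A [trial_structure()].
#' @param params An [alg2_params()].
#' @return A [label_mask()] of active ROIs.
#' @export
segment_trial_alg2 <- function(stack, trial, params = alg2_params()) {
  chi <- binarize_stack(stack, trial, params$baseline_nsd)
  L <- amplify_runs(chi, params$alpha, params$beta)
  S <- sensitivity_image(L, params$smooth_sigma, params$cell_window)
  Tthr <- switch(params$threshold_mode,
                 linear = params$alpha * params$indicator_frames + params$k,
                 geometric = params$alpha^params$indicator_frames + params$k)
  binary <- (S > Tthr) * 1
  dff <- pixel_dff(stack, trial)
  resp <- if (length(trial$response_frames)) trial$response_frames else
    seq_len(trial$n_frames)
  peak_dff <- apply(dff[, , resp, drop = FALSE], c(1, 2), max)
  label_rois(binary, peak_dff, sigma = 0,
             area_threshold = params$area_threshold,
             intensity_threshold = -Inf)
}
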