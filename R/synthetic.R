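#' Simulate heartbeat-like per-frame shifts
#'
#' Generates the per-frame translation ground truth used to corrupt a test
#' movie: a positive half-wave sinusoid (period one heartbeat) plus uniform
#' jitter. In each axis, frame `i` receives
#' `Mx * sin(2 pi rate i / F) + U(-Mr, Mr)` while the sine is nonnegative and
#' pure jitter `U(-Mr, Mr)` while it is negative, rounded to integer pixels.
#'
#' @param n_frames Number of frames.
#' @param fps Acquisition rate `F` (Hz).
#' @param max_shift_x,max_shift_y Sinusoid amplitudes `Mx`, `My` (px).
#' @param jitter Uniform jitter half-width `Mr` (px).
#' @param heartbeat_rate Sinusoid frequency in Hz (default 1: one heartbeat
#'   per second).
#' @param seed Integer RNG seed; identical seeds give identical series.
#' @return A [shift_series()] with `n_frames` rows; every shift is bounded by
#'   `max_shift + jitter` in absolute value.
#' @examples
#' simulate_shifts(8, fps = 4, max_shift_x = 2, jitter = 0, seed = 1)
#' @export
simulate_shifts <- function(n_frames, fps = 15, max_shift_x = 10,
                            max_shift_y = 10, jitter = 3,
                            heartbeat_rate = 1, seed = 1L) {
  stopifnot(n_frames >= 1, max_shift_x >= 0, max_shift_y >= 0, jitter >= 0)
  set.seed(seed)
  i <- seq_len(n_frames)
  s <- sin(2 * pi * heartbeat_rate * i / fps)
  one_axis <- function(mx) {
    base <- ifelse(s < 0, 0, mx * s)
    base + stats::runif(n_frames, -jitter, jitter)
  }
  dx <- one_axis(max_shift_x)
  dy <- one_axis(max_shift_y)
  shift_series(dx = round(dx), dy = round(dy))
}

#' Build a movie of one image under known shifts
#'
#' Compiles a stack whose frame `t` is the base image translated by the
#' ground-truth `(dx, dy)` of frame `t` (edge pixels replicated), emulating a
#' perfectly stable movie corrupted by rigid motion. Registering the result
#' against the base recovers the shift series exactly.
#'
#' @param base `H x W` nonnegative image.
#' @param shifts A [shift_series()].
#' @param fps Frame rate attached to the output stack.
#' @return An [image_stack()] with `attr(, "true_shifts")` set.
#' @export
build_shifted_movie <- function(base, shifts, fps = 15) {
  stopifnot(is.matrix(base))
  if (any(abs(shifts$dx) >= nrow(base)) || any(abs(shifts$dy) >= ncol(base))) {
    stop("shift magnitude reaches image size")
  }
  nt <- nrow(shifts)
  data <- array(0, dim = c(nrow(base), ncol(base), nt))
  for (t in seq_len(nt)) {
    data[, , t] <- translate_int(base, shifts$dx[t], shifts$dy[t],
                                 fill = "replicate")
  }
  stk <- image_stack(data, fps = fps)
  attr(stk, "true_shifts") <- shifts
  stk
}

#' Registration accuracy: per-axis sum of squared shift errors
#'
#' `diff(t, e) = sum_i (t_i - e_i)^2`, computed separately for the row (x)
#' and column (y) axes; 0 means exact recovery.
#'
#' @param truth,estimate Two [shift_series()] of equal length.
#' @param root If `TRUE`, return the root-mean-square error per axis instead
#'   of the raw sum of squares.
#' @return Named numeric vector `c(err_x, err_y)`.
#' @export
registration_error <- function(truth, estimate, root = FALSE) {
  if (nrow(truth) != nrow(estimate)) stop("shift series lengths differ")
  ex <- sum((truth$dx - estimate$dx)^2)
  ey <- sum((truth$dy - estimate$dy)^2)
  if (root) {
    n <- nrow(truth)
    ex <- sqrt(ex / n); ey <- sqrt(ey / n)
  }
  c(err_x = ex, err_y = ey)
}

#' Trial structure of a stimulus-presentation epoch
#'
#' @param n_frames Total frames `N` in the trial.
#' @param baseline_frames Indices (1-based) of the pre-stimulus baseline
#'   period; by default the first `fps` frames (1 s).
#' @param fps Acquisition rate (Hz).
#' @return A list of class `TrialStructure` with `n_frames`,
#'   `baseline_frames`, `response_frames`, `fps`.
#' @export
trial_structure <- function(n_frames, baseline_frames = NULL, fps = 15) {
  n_frames <- as.integer(n_frames)
  stopifnot(n_frames >= 2)
  if (is.null(baseline_frames)) {
    baseline_frames <- seq_len(min(n_frames - 1L, max(1L, round(fps))))
  }
  baseline_frames <- sort(unique(as.integer(baseline_frames)))
  stopifnot(length(baseline_frames) >= 1,
            all(baseline_frames >= 1), all(baseline_frames <= n_frames))
  response <- setdiff(seq_len(n_frames), baseline_frames)
  structure(list(n_frames = n_frames, baseline_frames = baseline_frames,
                 response_frames = response, fps = fps),
            class = "TrialStructure")
}

#' Specification for a planted-cell trial movie
#'
#' Defaults describe one trial of a tone-response imaging experiment at
#' 15 fps: a 1-s baseline followed by a 3-s response window, eight
#' Gaussian-profile cells (sigma 3 px) on a background of 100 intensity
#' units, responsive cells firing a 300% dF/F transient at stimulus onset
#' that decays with a ~1-s time constant, and additive Gaussian read noise.
#'
#' @param height,width Frame size in pixels.
#' @param n_cells Number of planted cells.
#' @param n_responsive Number of cells (the first `n_responsive`) given a
#'   stimulus-locked transient; the rest stay at baseline.
#' @param cell_radius Gaussian sigma of the cell brightness profile (px).
#' @param baseline_level Background intensity level.
#' @param cell_contrast Peak cell brightness as a multiple of
#'   `baseline_level` added on top of it.
#' @param transient_amplitude Peak dF/F of the planted transient.
#' @param transient_onset Frame of transient onset; default the first
#'   response frame.
#' @param decay_tau Exponential decay time constant (frames).
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param min_separation Minimum centre-to-centre cell distance (px);
#'   default `8 * cell_radius`, a sparsely labelled population whose cells
#'   are resolvable by smoothing-based segmentation.
#' @param trial A [trial_structure()].
#' @param seed RNG seed.
#' @return A list of class `CellMovieSpec`.
#' @export
cell_movie_spec <- function(height = 128, width = 128, n_cells = 8,
                            n_responsive = n_cells, cell_radius = 3,
                            baseline_level = 100, cell_contrast = 1,
                            transient_amplitude = 3, transient_onset = NULL,
                            decay_tau = 15, noise_sd = 2,
                            min_separation = 8 * cell_radius,
                            trial = trial_structure(60, fps = 15),
                            seed = 1L) {
  stopifnot(n_cells >= 0, n_responsive >= 0, n_responsive <= n_cells,
            cell_radius > 0, transient_amplitude >= 0, noise_sd >= 0)
  if (is.null(transient_onset)) {
    transient_onset <- if (length(trial$response_frames)) {
      min(trial$response_frames)
    } else {
      trial$n_frames
    }
  }
  structure(list(height = height, width = width, n_cells = n_cells,
                 n_responsive = n_responsive, cell_radius = cell_radius,
                 baseline_level = baseline_level, cell_contrast = cell_contrast,
                 transient_amplitude = transient_amplitude,
                 transient_onset = as.integer(transient_onset),
                 decay_tau = decay_tau, noise_sd = noise_sd,
                 min_separation = min_separation,
                 trial = trial, seed = as.integer(seed)),
            class = "CellMovieSpec")
}

# Rejection-sample cell centres so footprints (2 sigma disks) do not overlap
# and stay separated by at least `min_d` centre-to-centre.
sample_cell_centres <- function(n, h, w, sigma, margin, min_d = 8 * sigma,
                                max_tries = 5000L) {
  centres <- matrix(NA_real_, n, 2L)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place non-overlapping cells; grid too small")
    }
    cand <- c(stats::runif(1, margin, h - margin),
              stats::runif(1, margin, w - margin))
    if (placed == 0L ||
        all(sqrt(rowSums((centres[seq_len(placed), , drop = FALSE] -
                            matrix(cand, placed, 2L, byrow = TRUE))^2)) >= min_d)) {
      placed <- placed + 1L
      centres[placed, ] <- cand
    }
  }
  centres
}

#' Generate a trial movie of planted Gaussian-profile cells
#'
#' Cells are 2-D Gaussian brightness profiles on a constant background.
#' Responsive cells fire a transient at `transient_onset`: an instantaneous
#' rise to `transient_amplitude` (in dF/F units) followed by exponential
#' decay with `decay_tau`. The transient scales every pixel of the cell's
#' ground-truth footprint (the 2-sigma disk) by `1 + a(t)` relative to its
#' own baseline, so the true dF/F trace of each planted ROI is exactly
#' `a(t)`. Gaussian read noise is added last.
#'
#' @param spec A [cell_movie_spec()].
#' @return A list with elements `stack` (the [image_stack()]), `mask` (the
#'   ground-truth [label_mask()]; ROI k is cell k), `traces` (matrix
#'   `n_frames x n_cells` of true dF/F), `centres` (n_cells x 2 matrix of
#'   (row, col)), `responsive` (logical vector), and `spec`.
#' @export
generate_cell_movie <- function(spec = cell_movie_spec()) {
  stopifnot(inherits(spec, "CellMovieSpec"))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  tr <- spec$trial
  nt <- tr$n_frames
  sigma <- spec$cell_radius
  margin <- ceiling(3 * sigma) + 2
  centres <- if (spec$n_cells > 0) {
    sample_cell_centres(spec$n_cells, h, w, sigma, margin,
                        min_d = max(spec$min_separation, 4 * sigma))
  } else {
    matrix(numeric(0), 0L, 2L)
  }
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  baseline_img <- matrix(spec$baseline_level, h, w)
  labels <- matrix(0L, h, w)
  footprints <- vector("list", spec$n_cells)
  for (k in seq_len(spec$n_cells)) {
    d2 <- (rows - centres[k, 1L])^2 + (cols - centres[k, 2L])^2
    prof <- exp(-d2 / (2 * sigma^2))
    baseline_img <- baseline_img +
      spec$cell_contrast * spec$baseline_level * prof
    fp <- d2 <= (2 * sigma)^2
    footprints[[k]] <- fp
    labels[fp] <- k
  }
  responsive <- seq_len(spec$n_cells) <= spec$n_responsive
  # transient dF/F time course, shared by all responsive cells
  a_t <- numeric(nt)
  on <- spec$transient_onset
  if (on <= nt) {
    tt <- on:nt
    a_t[tt] <- spec$transient_amplitude * exp(-(tt - on) / spec$decay_tau)
  }
  data <- array(0, dim = c(h, w, nt))
  for (t in seq_len(nt)) {
    frame <- baseline_img
    if (a_t[t] > 0) {
      for (k in which(responsive)) {
        fp <- footprints[[k]]
        frame[fp] <- baseline_img[fp] * (1 + a_t[t])
      }
    }
    if (spec$noise_sd > 0) {
      frame <- frame + stats::rnorm(h * w, 0, spec$noise_sd)
    }
    data[, , t] <- pmax(frame, 0)
  }
  traces <- matrix(0, nt, spec$n_cells)
  for (k in seq_len(spec$n_cells)) if (responsive[k]) traces[, k] <- a_t
  mask <- label_mask(labels)
  list(stack = image_stack(data, fps = tr$fps), mask = mask,
       traces = traces, centres = centres, responsive = responsive,
       spec = spec)
}
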