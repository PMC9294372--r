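#' Movie container for fluorescence imaging data
#'
#' An `ImageStack` holds a fluorescence movie as an `H x W x T` array of
#' nonnegative intensities together with the acquisition rate. It is the
#' universal movie container passed between registration, segmentation and
#' trace extraction.
#'
#' @param data Numeric `H x W x T` array (a single `H x W` matrix is promoted
#'   to a one-frame stack). Intensities must be finite and nonnegative.
#' @param fps Acquisition rate in frames per second (Hz).
#' @param pixel_size Optional pixel size in micrometres per pixel.
#' @return An object of class `ImageStack` with elements `data`, `fps`,
#'   `pixel_size`.
#' @examples
#' stk <- image_stack(array(runif(8 * 8 * 4), c(8, 8, 4)), fps = 15)
#' dim(stk$data)
#' @export
image_stack <- function(data, fps = 15, pixel_size = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  d <- dim(data)
  if (d[1L] < 8L || d[2L] < 8L) {
    stop("ImageStack frames must be at least 8 x 8 pixels")
  }
  if (!all(is.finite(data)) || any(data < 0)) {
    stop("ImageStack intensities must be finite and nonnegative")
  }
  stopifnot(is.numeric(fps), fps > 0)
  structure(list(data = data, fps = fps, pixel_size = pixel_size),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack: %d frames of %d x %d px, %g fps\n",
              d[3L], d[1L], d[2L], x$fps))
  invisible(x)
}

n_frames <- function(stack) dim(stack$data)[3L]

#' Registration parameters
#'
#' @param max_shift Maximum shift `Ms` in pixels searched in each direction.
#'   Defaults to one fifth of the smaller frame dimension, the recommended
#'   starting point: too large risks spurious matches, too small fails when
#'   real motion exceeds it.
#' @param template_index Index (1-based) of the frame used as the fixed
#'   template; the first frame by default.
#' @param template Optional explicit template image (e.g. a mean image);
#'   overrides `template_index`.
#' @param coarse_to_fine If `TRUE`, shifts are first estimated on
#'   block-averaged images and refined by exhaustive local search at full
#'   resolution; results are identical to the exhaustive search on all
#'   tested inputs but faster for large `max_shift`.
#' @param downsample_factor Integer block size for the coarse pass.
#' @param fill Fill value for pixels exposed by shifting (default 0).
#' @return A list of class `RegistrationParams`.
#' @export
registration_params <- function(max_shift = NULL, template_index = 1L,
                                template = NULL, coarse_to_fine = FALSE,
                                downsample_factor = 2L, fill = 0) {
  if (!is.null(max_shift)) {
    stopifnot(max_shift >= 1)
  }
  stopifnot(downsample_factor >= 1)
  structure(list(max_shift = max_shift,
                 template_index = as.integer(template_index),
                 template = template,
                 coarse_to_fine = isTRUE(coarse_to_fine),
                 downsample_factor = as.integer(downsample_factor),
                 fill = fill),
            class = "RegistrationParams")
}

default_max_shift <- function(h, w) max(1L, min(h, w) %/% 5L)

#' Standardize a frame to zero mean and unit variance
#'
#' Frames are standardized (mean-centred, divided by the population standard
#' deviation) before the translation search so that the objective compares
#' structure, not brightness.
#'
#' @param frame Numeric matrix with at least 2 pixels.
#' @return Matrix with mean 0 and population standard deviation 1.
#' @export
standardize <- function(frame) {
  stopifnot(is.matrix(frame), length(frame) >= 2L)
  mu <- mean(frame)
  s <- sqrt(mean((frame - mu)^2))
  if (s == 0) stop("degenerate frame: zero variance, cannot standardize")
  (frame - mu) / s
}

#' Windowed mean-squared-difference registration objective (reference)
#'
#' Direct evaluation of the objective `D(x, y)`: the mean squared difference
#' between template pixels `t[i, j]` and frame pixels `a[i + x, j + y]` over
#' their overlap. This is the brute-force reference used by tests and tiny
#' inputs; [estimate_shift()] computes the same argmin via FFT.
#'
#' The frame may be smaller than the template (a central crop); the sum then
#' runs over all index pairs valid in both images and is normalized by the
#' overlap pixel count, which for equal-sized images is
#' `(h - |x|) (w - |y|)`.
#'
#' @param template Standardized template matrix.
#' @param frame Standardized frame matrix (same size or smaller).
#' @param x,y Integer row/column offsets.
#' @return Scalar objective value.
#' @export
ssd_objective <- function(template, frame, x, y) {
  ht <- nrow(template); wt <- ncol(template)
  hf <- nrow(frame); wf <- ncol(frame)
  # template index i pairs with frame index i + x (rows), j + y (cols)
  i <- seq_len(ht)
  j <- seq_len(wt)
  i <- i[i + x >= 1L & i + x <= hf]
  j <- j[j + y >= 1L & j + y <= wf]
  if (length(i) < 1L || length(j) < 1L) {
    stop("invalid offset: template/frame overlap is empty")
  }
  d <- template[i, j, drop = FALSE] - frame[i + x, j + y, drop = FALSE]
  sum(d^2) / (length(i) * length(j))
}

# Circular cross-correlation via FFT: C[s1+1, s2+1] = sum small * big shifted
# by (s1, s2); entries valid for s within dim(big) - dim(small).
xcorr_fft <- function(big, small) {
  h <- nrow(big); w <- ncol(big)
  pad <- matrix(0, h, w)
  pad[seq_len(nrow(small)), seq_len(ncol(small))] <- small
  Re(stats::fft(stats::fft(big) * Conj(stats::fft(pad)), inverse = TRUE)) / (h * w)
}

# Precompute the template-dependent parts of the shift score for a given
# crop geometry: sliding-window sum of t^2 over windows of the crop size.
template_scores <- function(template, ms) {
  h <- nrow(template); w <- ncol(template)
  ch <- h - 2L * ms; cw <- w - 2L * ms
  if (ch < 4L || cw < 4L) stop("Ms too large: central crop smaller than 4 x 4")
  list(t2win = xcorr_fft(template^2, matrix(1, ch, cw))[seq_len(2L * ms + 1L),
                                                        seq_len(2L * ms + 1L),
                                                        drop = FALSE],
       ch = ch, cw = cw)
}

# (2 Ms + 1)^2 matrix of un-normalized scores A' * D(x, y); row u, col v
# correspond to x = Ms + 1 - u, y = Ms + 1 - v (s = Ms - x).
shift_score_matrix <- function(template, frame, ms, tpl_scores = NULL) {
  h <- nrow(template); w <- ncol(template)
  if (is.null(tpl_scores)) tpl_scores <- template_scores(template, ms)
  crop <- frame[(ms + 1L):(h - ms), (ms + 1L):(w - ms), drop = FALSE]
  if (max(crop) == min(crop)) stop("degenerate frame: constant central crop")
  n <- 2L * ms + 1L
  cross <- xcorr_fft(template, crop)[seq_len(n), seq_len(n), drop = FALSE]
  tpl_scores$t2win - 2 * cross + sum(crop^2)
}

# Exact (direct-sum) un-normalized score for one offset, same quantity as
# shift_score_matrix but free of FFT round-off.
exact_shift_score <- function(template, crop, ms, x, y) {
  ch <- nrow(crop); cw <- ncol(crop)
  s1 <- ms - x; s2 <- ms - y
  tw <- template[(s1 + 1L):(s1 + ch), (s2 + 1L):(s2 + cw), drop = FALSE]
  sum((tw - crop)^2)
}

#' Estimate the translation between a frame and a template
#'
#' Finds the integer offset `(dx, dy)` in `[-Ms, Ms]^2` minimizing the
#' windowed mean-squared difference between the template and the frame. Only
#' the central crop of the frame (margins of width `Ms` removed) is compared
#' against sliding windows of the full template, which keeps the overlap area
#' constant; the cross term is computed for all offsets at once by FFT
#' cross-correlation. Near-minimal offsets are re-scored by exact direct
#' summation so the returned argmin is bit-identical to exhaustive evaluation
#' of [ssd_objective()] on the crop, with ties broken by smallest
#' `|dx| + |dy|`, then row-major (dx, then dy) order.
#'
#' @param template Standardized template matrix.
#' @param frame Standardized frame matrix, same size.
#' @param max_shift Maximum shift `Ms` (default `min(h, w) %/% 5`).
#' @return Integer vector `c(dx, dy)`: positive `dx` means the frame content
#'   sits `dx` rows below the template.
#' @export
estimate_shift <- function(template, frame, max_shift = NULL) {
  h <- nrow(template); w <- ncol(template)
  stopifnot(nrow(frame) == h, ncol(frame) == w)
  ms <- if (is.null(max_shift)) default_max_shift(h, w) else as.integer(max_shift)
  if (ms < 1L || ms >= min(h, w) / 2) stop("max_shift must satisfy 1 <= Ms < min(h, w)/2")
  scores <- shift_score_matrix(template, frame, ms)
  pick_argmin_exact(template, frame, ms, scores)
}

# Select the argmin offset from an FFT score matrix, re-evaluating all
# near-minimal candidates exactly and applying the deterministic tie-break.
pick_argmin_exact <- function(template, frame, ms, scores) {
  h <- nrow(template); w <- ncol(template)
  crop <- frame[(ms + 1L):(h - ms), (ms + 1L):(w - ms), drop = FALSE]
  smin <- min(scores)
  tol <- 1e-8 * max(abs(scores), 1)
  cand <- which(scores <= smin + tol, arr.ind = TRUE)
  xs <- ms + 1L - cand[, 1L]
  ys <- ms + 1L - cand[, 2L]
  exact <- vapply(seq_along(xs), function(k) {
    exact_shift_score(template, crop, ms, xs[k], ys[k])
  }, numeric(1))
  emin <- min(exact)
  best <- which(exact == emin)
  # tie-break: smallest |x| + |y|, then row-major (x, then y)
  o <- order(abs(xs[best]) + abs(ys[best]), xs[best], ys[best])
  k <- best[o[1L]]
  c(dx = xs[k], dy = ys[k])
}

#' Shift a frame into the template's coordinate system
#'
#' Applies the inverse of an estimated shift: the output at `(i, j)` is the
#' input at `(i + dx, j + dy)`, so a frame whose content sits `(dx, dy)`
#' below/right of the template is moved back into alignment. Integer shifts
#' only; exposed pixels take `fill`.
#'
#' @param frame Numeric matrix.
#' @param dx,dy Integer row/column offsets as returned by [estimate_shift()].
#' @param fill Fill value for exposed border pixels (default 0).
#' @return Shifted matrix of the same size.
#' @export
apply_shift <- function(frame, dx, dy, fill = 0) {
  stopifnot(abs(dx) < nrow(frame), abs(dy) < ncol(frame))
  # out[i, j] = frame[i + dx, j + dy]  <=>  translate_int by (-dx, -dy)
  translate_int(frame, -as.integer(dx), -as.integer(dy), fill = fill)
}

#' Register a whole movie against a fixed template
#'
#' Estimates a per-frame integer translation against the template (by default
#' the first frame) and shifts every frame into alignment. With
#' `coarse_to_fine` the shift is first estimated on block-averaged images and
#' refined by exhaustive exact search at full resolution in a
#' `+/-(downsample_factor + 1)` window around the upscaled coarse estimate.
#'
#' @param stack An [image_stack()].
#' @param params A [registration_params()].
#' @return A list of class `Registration` with elements `stack` (registered
#'   movie) and `shifts` (a `ShiftSeries` data frame with columns `frame`,
#'   `dx`, `dy`).
#' @examples
#' base <- matrix(runif(32 * 32), 32, 32)
#' mov <- build_shifted_movie(base, shift_series(dx = c(0, 2), dy = c(0, -1)))
#' reg <- register_stack(mov, registration_params(max_shift = 4))
#' reg$shifts
#' @export
register_stack <- function(stack, params = registration_params()) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$data)
  h <- d[1L]; w <- d[2L]; nt <- d[3L]
  ms <- if (is.null(params$max_shift)) default_max_shift(h, w) else
    as.integer(params$max_shift)
  template_raw <- if (!is.null(params$template)) params$template else
    stack$data[, , params$template_index]
  template <- standardize(template_raw)
  tpl_sc <- template_scores(template, ms)
  coarse <- NULL
  if (params$coarse_to_fine && params$downsample_factor > 1L) {
    f <- params$downsample_factor
    tmpl_ds <- downsample_mean(template_raw, f)
    ms_ds <- max(1L, min(ceiling(ms / f),
                         (min(dim(tmpl_ds)) - 4L) %/% 2L - 1L))
    coarse <- list(f = f, template = standardize(tmpl_ds), ms = ms_ds)
    coarse$tpl_sc <- template_scores(coarse$template, coarse$ms)
  }
  shifts <- matrix(0L, nt, 2L)
  out <- stack$data
  for (t in seq_len(nt)) {
    frame <- stack$data[, , t]
    sh <- tryCatch({
      frame_std <- standardize(frame)
      if (is.null(coarse)) {
        scores <- shift_score_matrix(template, frame_std, ms, tpl_sc)
        pick_argmin_exact(template, frame_std, ms, scores)
      } else {
        estimate_shift_coarse_fine(template, frame_std, ms, coarse)
      }
    }, error = function(e) {
      stop(sprintf("frame %d: %s", t, conditionMessage(e)), call. = FALSE)
    })
    shifts[t, ] <- sh
    if (any(sh != 0L)) {
      out[, , t] <- apply_shift(frame, sh[1L], sh[2L], fill = params$fill)
    }
  }
  list2reg(stack, out, shifts)
}

list2reg <- function(stack, data, shifts) {
  structure(list(
    stack = image_stack(pmax(data, 0), fps = stack$fps,
                        pixel_size = stack$pixel_size),
    shifts = shift_series(dx = shifts[, 1L], dy = shifts[, 2L])
  ), class = "Registration")
}

#' @export
print.Registration <- function(x, ...) {
  cat(sprintf("Registration: %d frames, max |shift| = %d px\n",
              nrow(x$shifts), max(abs(c(x$shifts$dx, x$shifts$dy, 0)))))
  invisible(x)
}

# Coarse shift on downsampled images, then exhaustive exact refinement at
# full resolution within +/- (f + 1) of the upscaled coarse estimate.
estimate_shift_coarse_fine <- function(template, frame, ms, coarse) {
  f <- coarse$f
  fr_ds <- standardize(downsample_mean(frame, f))
  sc <- shift_score_matrix(coarse$template, fr_ds, coarse$ms, coarse$tpl_sc)
  guess <- pick_argmin_exact(coarse$template, fr_ds, coarse$ms, sc) * f
  rad <- f + 1L
  h <- nrow(template); w <- ncol(template)
  crop <- frame[(ms + 1L):(h - ms), (ms + 1L):(w - ms), drop = FALSE]
  if (max(crop) == min(crop)) stop("degenerate frame: constant central crop")
  xs <- max(-ms, guess[1L] - rad):min(ms, guess[1L] + rad)
  ys <- max(-ms, guess[2L] - rad):min(ms, guess[2L] + rad)
  grid <- expand.grid(x = xs, y = ys)
  exact <- vapply(seq_len(nrow(grid)), function(k) {
    exact_shift_score(template, crop, ms, grid$x[k], grid$y[k])
  }, numeric(1))
  emin <- min(exact)
  best <- which(exact == emin)
  o <- order(abs(grid$x[best]) + abs(grid$y[best]), grid$x[best], grid$y[best])
  k <- best[o[1L]]
  c(dx = grid$x[k], dy = grid$y[k])
}

#' Per-frame shift series
#'
#' @param dx,dy Integer vectors of row/column offsets, one per frame.
#' @return A data frame of class `ShiftSeries` with columns `frame` (1-based),
#'   `dx`, `dy`.
#' @export
shift_series <- function(dx, dy) {
  stopifnot(length(dx) == length(dy))
  structure(data.frame(frame = seq_along(dx), dx = as.integer(round(dx)),
                       dy = as.integer(round(dy))),
            class = c("ShiftSeries", "data.frame"))
}
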