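# Cross-session alignment: rigid/affine registration of time-averaged
# session images, mask warping into the reference frame, and capture-all
# unification of ROIs across sessions.

#' Planar transform (rigid or affine)
#'
#' A 2 x 3 matrix `M` mapping homogeneous target-session coordinates
#' `(row, col, 1)` to reference-session coordinates. The reference frame is
#' the common space: masks from other sessions are warped into it.
#'
#' @param matrix Numeric 2 x 3 matrix.
#' @param kind `"rigid"` or `"affine"`.
#' @return An object of class `PlanarTransform`.
#' @export
planar_transform <- function(matrix, kind = c("affine", "rigid")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(2L, 3L)))
  A <- matrix[, 1:2]
  if (abs(det(A)) < 1e-12) stop("transform linear part is singular")
  if (kind == "rigid" &&
      (max(abs(crossprod(A) - diag(2))) > 1e-6 || det(A) < 0)) {
    stop("rigid transform must have an orthonormal, orientation-preserving linear part")
  }
  structure(list(matrix = matrix, kind = kind), class = "PlanarTransform")
}

#' @export
print.PlanarTransform <- function(x, ...) {
  cat(sprintf("PlanarTransform (%s):\n", x$kind))
  print(round(x$matrix, 4))
  invisible(x)
}

# Rigid transform mapping target -> reference: rotation by theta (radians)
# about the image centre plus translation (dr, dc).
rigid_matrix <- function(theta, dr, dc, centre) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
  t0 <- centre - R %*% centre + c(dr, dc)
  cbind(R, t0)
}

invert_transform <- function(M) {
  A <- M[, 1:2]
  Ainv <- solve(A)
  cbind(Ainv, -Ainv %*% M[, 3L])
}

# Warp `img` (target frame) into the reference frame defined by M
# (target -> reference): output(p) = img(M^{-1} p).
warp_image <- function(img, M, out_dim = dim(img),
                       filter = c("bilinear", "nearest"), fill = 0) {
  filter <- match.arg(filter)
  Minv <- invert_transform(M)
  h <- out_dim[1L]; w <- out_dim[2L]
  rr <- rep(seq_len(h), times = w)
  cc <- rep(seq_len(w), each = h)
  src_r <- Minv[1L, 1L] * rr + Minv[1L, 2L] * cc + Minv[1L, 3L]
  src_c <- Minv[2L, 1L] * rr + Minv[2L, 2L] * cc + Minv[2L, 3L]
  v <- if (filter == "bilinear") {
    bilinear_sample(img, src_r, src_c, fill = fill)
  } else {
    nearest_sample(img, src_r, src_c, fill = fill)
  }
  out <- matrix(v, h, w)
  attr(out, "valid") <- matrix(attr(v, "valid"), h, w)
  out
}

#' Time-averaged image of a movie
#'
#' The pixel-wise mean over frames; used as the anchor image representing a
#' whole imaging session for cross-session alignment.
#'
#' @param stack An [image_stack()].
#' @return `H x W` matrix.
#' @export
time_average <- function(stack) {
  stopifnot(inherits(stack, "ImageStack"))
  rowMeans(stack$data, dims = 2L)
}

# Negative standardized MSE between reference and the warped target over
# valid pixels (higher is better).
similarity_score <- function(ref_std, target, M) {
  wimg <- warp_image(target, M, out_dim = dim(ref_std), filter = "bilinear")
  ok <- attr(wimg, "valid")
  if (sum(ok) < 0.25 * length(ok)) return(-Inf)
  v <- wimg[ok]
  mu <- mean(v); s <- sqrt(mean((v - mu)^2))
  if (s == 0) return(-Inf)
  -mean(((v - mu) / s - ref_std[ok])^2)
}

#' Estimate the transform aligning a target session to a reference
#'
#' Maximizes image similarity (negative mean-squared error after intensity
#' standardization) between the reference image and the warped target over a
#' multi-resolution pyramid (block-mean factors 4, 2, 1). The rigid search
#' initializes rotation on a coarse grid (-6 to 6 degrees, 2-degree steps)
#' with an FFT translation estimate per angle, then refines
#' (theta, dr, dc) by Nelder-Mead at each pyramid level; the affine solution
#' refines all six matrix entries starting from the rigid optimum and never
#' scores worse than it. Deterministic given the inputs.
#'
#' @param reference,target `H x W` images (same shape, non-constant),
#'   typically [time_average()] of each session.
#' @param kind `"affine"` (default) or `"rigid"`.
#' @param max_angle Half-width of the rotation initialization grid (degrees).
#' @return A [planar_transform()] mapping target to reference coordinates,
#'   with attributes `similarity` (final score) and `converged`.
#' @export
estimate_transform <- function(reference, target, kind = c("affine", "rigid"),
                               max_angle = 6) {
  kind <- match.arg(kind)
  stopifnot(all(dim(reference) == dim(target)))
  ref_std <- standardize(reference)
  tgt <- standardize(target)
  centre <- c((nrow(target) + 1) / 2, (ncol(target) + 1) / 2)

  factors <- c(4L, 2L, 1L)
  factors <- factors[min(dim(target)) %/% factors >= 32L]
  if (!length(factors)) factors <- 1L

  pyr_ref <- lapply(factors, function(f) standardize(downsample_mean(reference, f)))
  pyr_tgt <- lapply(factors, function(f) standardize(downsample_mean(target, f)))

  # --- rigid: grid init at coarsest level ---
  f0 <- factors[1L]
  r0 <- pyr_ref[[1L]]; t0 <- pyr_tgt[[1L]]
  c0 <- c((nrow(t0) + 1) / 2, (ncol(t0) + 1) / 2)
  ms0 <- max(2L, min(dim(t0)) %/% 5L)
  best <- NULL
  for (deg in seq(-max_angle, max_angle, by = 2)) {
    th <- deg * pi / 180
    rot <- warp_image(t0, rigid_matrix(th, 0, 0, c0), filter = "bilinear")
    sh <- tryCatch(estimate_shift(r0, standardize(rot), ms0),
                   error = function(e) c(0L, 0L))
    # rot content sits (dx, dy) below reference => map adds -(dx, dy)
    par <- c(th, -sh[1L], -sh[2L])
    sc <- similarity_score(r0, t0, rigid_matrix(par[1L], par[2L], par[3L], c0))
    if (is.null(best) || sc > best$score) best <- list(par = par, score = sc)
  }
  par <- best$par
  converged <- TRUE
  for (li in seq_along(factors)) {
    f <- factors[li]
    rl <- pyr_ref[[li]]; tl <- pyr_tgt[[li]]
    cl <- c((nrow(tl) + 1) / 2, (ncol(tl) + 1) / 2)
    par_l <- c(par[1L], par[2L] * f0 / f, par[3L] * f0 / f)
    opt <- stats::optim(par_l, function(p) {
      -similarity_score(rl, tl, rigid_matrix(p[1L], p[2L], p[3L], cl))
    }, method = "Nelder-Mead",
    control = list(maxit = 300, reltol = 1e-8,
                   parscale = c(0.01, 1, 1)))
    if (opt$convergence != 0) converged <- FALSE
    par <- c(opt$par[1L], opt$par[2L] * f / f0, opt$par[3L] * f / f0)
  }
  rigid_par <- c(par[1L], par[2L] * f0, par[3L] * f0)
  M_rigid <- rigid_matrix(rigid_par[1L], rigid_par[2L], rigid_par[3L], centre)
  rigid_score <- similarity_score(ref_std, tgt, M_rigid)

  if (kind == "rigid") {
    tf <- planar_transform(M_rigid, "rigid")
    attr(tf, "similarity") <- rigid_score
    attr(tf, "converged") <- converged
    return(tf)
  }

  # --- affine refinement from the rigid optimum ---
  M <- M_rigid
  for (li in seq_along(factors)) {
    f <- factors[li]
    rl <- pyr_ref[[li]]; tl <- pyr_tgt[[li]]
    # rescale M to level-l pixel grid: x_l = x / f + (1 - 1/f) * 0.5 approx.
    S <- diag(c(1 / f, 1 / f))
    Ml <- cbind(S %*% M[, 1:2] %*% solve(S), M[, 3L] / f)
    opt <- stats::optim(as.vector(Ml), function(p) {
      -similarity_score(rl, tl, matrix(p, 2L, 3L))
    }, method = "Nelder-Mead",
    control = list(maxit = 500, reltol = 1e-9,
                   parscale = c(0.01, 0.01, 0.01, 0.01, 1, 1)))
    if (opt$convergence != 0) converged <- FALSE
    Ml <- matrix(opt$par, 2L, 3L)
    M <- cbind(Ml[, 1:2], Ml[, 3L] * f)
  }
  affine_score <- similarity_score(ref_std, tgt, M)
  if (affine_score < rigid_score) {
    # refinement may not beat the rigid optimum on degenerate inputs
    M <- M_rigid
    affine_score <- rigid_score
  }
  tf <- planar_transform(M, "affine")
  attr(tf, "similarity") <- affine_score
  attr(tf, "converged") <- converged
  tf
}

#' Warp a label mask into the reference frame
#'
#' Nearest-neighbour warp of the label image (labels are categorical, so no
#' interpolation across labels). ROIs mapped fully outside the output frame
#' are dropped (their ids reported via `attr(, "dropped")` and a message);
#' ROIs crossing the margin are cropped.
#'
#' @param mask A [label_mask()] in target-session coordinates.
#' @param tf A [planar_transform()] mapping target to reference coordinates.
#' @param out_shape `c(H, W)` of the output (default the mask's shape).
#' @return A [label_mask()] in reference coordinates; ROI ids of surviving
#'   ROIs are renumbered consecutively preserving their original order.
#' @export
transform_mask <- function(mask, tf, out_shape = dim(mask$labels)) {
  stopifnot(inherits(mask, "LabelMask"), inherits(tf, "PlanarTransform"))
  lab <- warp_image(mask$labels, tf$matrix, out_dim = out_shape,
                    filter = "nearest", fill = 0)
  lab <- matrix(as.integer(lab), out_shape[1L], out_shape[2L])
  present <- sort(unique(lab[lab > 0L]))
  orig <- vapply(mask$rois, `[[`, integer(1), "id")
  dropped <- setdiff(orig, present)
  if (length(dropped)) {
    message(sprintf("transform_mask: %d ROI(s) fell outside the frame: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  out <- label_mask(lab, relabel = TRUE)
  attr(out, "dropped") <- dropped
  attr(out, "id_map") <- stats::setNames(seq_along(present), present)
  out
}

#' Unify ROI masks across sessions (capture-all)
#'
#' Warps every non-reference session mask into the reference frame using its
#' transform, then merges all masks with [merge_masks()]: every ROI seen in
#' any session is kept, repeated detections are merged with union shapes,
#' and provenance records which (session, ROI) contributed to each unified
#' ROI so traces can later be extracted per session.
#'
#' @param session_masks List of [label_mask()] objects, reference session
#'   first.
#' @param transforms List of [planar_transform()] for sessions 2..n (target
#'   to reference); the reference needs none. `NULL` entries mean identity.
#' @param overlap_fraction Passed to [merge_masks()].
#' @return A `SessionMask` in reference coordinates; provenance `source` is
#'   the session index.
#' @export
unify_sessions <- function(session_masks, transforms = NULL,
                           overlap_fraction = 0.3) {
  n <- length(session_masks)
  stopifnot(n >= 1)
  if (is.null(transforms)) transforms <- vector("list", n - 1L)
  stopifnot(length(transforms) == n - 1L)
  ref_shape <- dim(session_masks[[1L]]$labels)
  warped <- vector("list", n)
  warped[[1L]] <- session_masks[[1L]]
  for (s in seq_len(n - 1L)) {
    tf <- transforms[[s]]
    warped[[s + 1L]] <- if (is.null(tf)) {
      session_masks[[s + 1L]]
    } else {
      transform_mask(session_masks[[s + 1L]], tf, out_shape = ref_shape)
    }
  }
  merge_masks(warped, overlap_fraction = overlap_fraction)
}
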