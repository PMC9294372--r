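# Per-ROI activity extraction: F0 baseline, dF/F traces, active-ROI
# classification and export ordering.

#' Extract per-ROI dF/F traces from a trial
#'
#' For each ROI, `F(t)` is the mean over the ROI's pixels in frame `t`; the
#' baseline `F0` is the mean of `F(t)` over the trial's baseline frames
#' (equivalently the mean of all ROI pixels over the baseline window); the
#' activity trace is `(F(t) - F0) / F0`. ROIs whose `F0` does not exceed
#' `eps` are excluded with a message.
#'
#' @param stack An [image_stack()].
#' @param mask A [label_mask()] on the same grid.
#' @param trial A [trial_structure()].
#' @param eps Positive floor under which an ROI's baseline is considered
#'   degenerate.
#' @return A `TraceSet`: list with `dff` (`T x K` matrix of activity
#'   traces), `f0`, `peak`, `roi_ids`, `centroids` (`K x 2`), `active`
#'   (all `NA` until [classify_active()]), `rank`, `trial`, `excluded`.
#' @export
extract_traces <- function(stack, mask, trial, eps = 1e-9) {
  stopifnot(inherits(stack, "ImageStack"), inherits(mask, "LabelMask"),
            all(dim(stack$data)[1:2] == dim(mask$labels)))
  nt <- n_frames(stack)
  h <- dim(stack$data)[1L]
  K <- length(mask$rois)
  raw <- matrix(NA_real_, nt, K)
  for (k in seq_len(K)) {
    px <- mask$rois[[k]]$pixels
    lin <- px[, 1L] + (px[, 2L] - 1L) * h
    # frame-wise mean over ROI pixels
    raw[, k] <- colMeans(matrix(stack$data[outer(lin, (seq_len(nt) - 1L) * h * ncol(stack$data), "+")],
                                nrow = length(lin)))
  }
  f0 <- colMeans(raw[trial$baseline_frames, , drop = FALSE])
  ok <- f0 > eps
  if (any(!ok)) {
    message(sprintf("extract_traces: excluded %d ROI(s) with degenerate baseline",
                    sum(!ok)))
  }
  dff <- sweep(sweep(raw[, ok, drop = FALSE], 2L, f0[ok], "-"),
               2L, f0[ok], "/")
  ids <- vapply(mask$rois, `[[`, integer(1), "id")[ok]
  cents <- t(vapply(mask$rois[ok], `[[`, numeric(2), "centroid"))
  structure(list(dff = dff, f0 = f0[ok],
                 peak = apply(dff, 2L, max),
                 roi_ids = ids, centroids = cents,
                 active = rep(NA, sum(ok)), rank = rep(NA_integer_, sum(ok)),
                 trial = trial, excluded = which(!ok)),
            class = "TraceSet")
}

#' @export
print.TraceSet <- function(x, ...) {
  cat(sprintf("TraceSet: %d ROI(s) x %d frames; %s active\n",
              ncol(x$dff), nrow(x$dff),
              if (all(is.na(x$active))) "unclassified" else sum(x$active)))
  invisible(x)
}

#' Classify active ROIs by peak activity over baseline variability
#'
#' An ROI is active when its peak dF/F exceeds the mean of its
#' baseline-period dF/F by more than `n_sd` standard deviations of that
#' baseline activity (default 5). Alternative criteria are available: a
#' fixed dF/F floor (`min_peak`) and a minimum ROI size (`min_area`,
#' checked against centroid-bearing records when supplied via `areas`).
#'
#' @param traces A `TraceSet` from [extract_traces()].
#' @param n_sd Number of baseline SDs (default 5; 3 is a common lenient
#'   alternative).
#' @param min_peak Optional fixed dF/F threshold applied in addition.
#' @param areas Optional integer vector of ROI areas (same order as
#'   `traces$roi_ids`) used with `min_area`.
#' @param min_area Optional minimum ROI area.
#' @return The `TraceSet` with `active` and `rank` filled; `rank` orders
#'   active ROIs first, then by descending peak, ties by centroid
#'   (row, col).
#' @export
classify_active <- function(traces, n_sd = 5, min_peak = NULL,
                            areas = NULL, min_area = NULL) {
  stopifnot(inherits(traces, "TraceSet"))
  bl <- traces$trial$baseline_frames
  stopifnot(length(bl) >= 2)
  base <- traces$dff[bl, , drop = FALSE]
  mu <- colMeans(base)
  s <- apply(base, 2L, stats::sd)
  degen <- s == 0
  if (any(degen)) {
    message(sprintf("classify_active: %d ROI(s) with zero baseline SD", sum(degen)))
    s[degen] <- .Machine$double.eps
  }
  active <- traces$peak > mu + n_sd * s
  if (!is.null(min_peak)) active <- active & traces$peak >= min_peak
  if (!is.null(min_area) && !is.null(areas)) active <- active & areas >= min_area
  traces$active <- active
  o <- order(!active, -traces$peak, traces$centroids[, 1L],
             traces$centroids[, 2L])
  traces$rank <- match(seq_along(o), o)
  traces
}

#' Order and export ROI traces
#'
#' Produces export records sorted active-first by descending peak dF/F
#' (ties by centroid), optionally truncated to the top `top_n` ROIs, and
#' writes them to CSV (long format: roi, frame, dff) and a JSON summary
#' (roi, peak, active, rank) when paths are given.
#'
#' @param traces A classified `TraceSet`.
#' @param top_n Keep only the first `top_n` ROIs in rank order (default
#'   all).
#' @param csv,summary_json Optional output paths.
#' @return Invisibly, a list with `summary` (data frame: roi, peak, active,
#'   rank) and `records` (long data frame of traces), both in rank order.
#' @export
sort_export <- function(traces, top_n = NULL, csv = NULL, summary_json = NULL) {
  stopifnot(inherits(traces, "TraceSet"))
  if (all(is.na(traces$active))) traces <- classify_active(traces)
  o <- order(traces$rank)
  if (!is.null(top_n)) o <- utils::head(o, top_n)
  summary <- data.frame(roi = traces$roi_ids[o],
                        peak = traces$peak[o],
                        active = traces$active[o],
                        rank = traces$rank[o])
  records <- do.call(rbind, lapply(o, function(k) {
    data.frame(roi = traces$roi_ids[k],
               frame = seq_len(nrow(traces$dff)),
               dff = traces$dff[, k])
  }))
  if (is.null(records)) {
    records <- data.frame(roi = integer(), frame = integer(), dff = numeric())
  }
  if (!is.null(csv)) utils::write.csv(records, csv, row.names = FALSE)
  if (!is.null(summary_json)) {
    jsonlite::write_json(summary, summary_json, auto_unbox = FALSE,
                         digits = NA)
  }
  invisible(list(summary = summary, records = records))
}
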