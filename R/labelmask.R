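#' Label mask of segmented ROIs
#'
#' A `LabelMask` is an `H x W` integer image (0 = background, `k` = ROI `k`)
#' plus one record per ROI: its pixel set, centroid, area and peak score.
#' Labels are expected to be consecutive from 1; use [label_mask()] to
#' (re)build records from a raw label image.
#'
#' @param labels `H x W` matrix of nonnegative integers.
#' @param score_image Optional `H x W` matrix scored per pixel (e.g. the
#'   cumulative dF/F image); each ROI's `peak` is its maximum over the ROI.
#' @param relabel If `TRUE` (default) labels are renumbered consecutively.
#' @return An object of class `LabelMask`: list with `labels` (integer
#'   matrix) and `rois` (list of records with `id`, `pixels` (n x 2 matrix of
#'   1-based (row, col)), `centroid`, `area`, `peak`).
#' @export
label_mask <- function(labels, score_image = NULL, relabel = TRUE) {
  stopifnot(is.matrix(labels), all(labels >= 0))
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  ids <- sort(unique(labels[labels > 0L]))
  if (relabel && length(ids) > 0L && !identical(ids, seq_along(ids))) {
    remap <- integer(max(ids))
    remap[ids] <- seq_along(ids)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
    ids <- seq_along(ids)
  }
  rois <- lapply(ids, function(k) {
    px <- which(labels == k, arr.ind = TRUE)
    colnames(px) <- c("row", "col")
    peak <- if (is.null(score_image)) NA_real_ else max(score_image[px])
    list(id = k, pixels = px,
         centroid = c(row = mean(px[, 1L]), col = mean(px[, 2L])),
         area = nrow(px), peak = peak)
  })
  structure(list(labels = labels, rois = rois), class = "LabelMask")
}

#' @export
print.LabelMask <- function(x, ...) {
  cat(sprintf("LabelMask: %d ROI(s) on a %d x %d grid\n",
              length(x$rois), nrow(x$labels), ncol(x$labels)))
  if (length(x$rois)) {
    print(utils::head(roi_table(x), 10))
  }
  invisible(x)
}

#' Summarize a mask's ROIs as a data frame
#'
#' @param mask A `LabelMask` or `SessionMask`.
#' @return Data frame with one row per ROI: `id`, `row`, `col` (centroid),
#'   `area`, `peak`.
#' @export
roi_table <- function(mask) {
  if (!length(mask$rois)) {
    return(data.frame(id = integer(), row = numeric(), col = numeric(),
                      area = integer(), peak = numeric()))
  }
  do.call(rbind, lapply(mask$rois, function(r) {
    data.frame(id = r$id, row = r$centroid[["row"]], col = r$centroid[["col"]],
               area = r$area, peak = r$peak)
  }))
}

n_rois <- function(mask) length(mask$rois)

#' Number of ROIs in a mask
#'
#' @param mask A `LabelMask`.
#' @return Integer count.
#' @export
roi_count <- function(mask) length(mask$rois)
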