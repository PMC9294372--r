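# Integration of per-trial (or per-session) label masks into one
# capture-all mask: every ROI seen anywhere is kept; repeated detections of
# the same cell are merged with union shapes.

#' Merge a list of label masks into one session mask
#'
#' ROIs from different masks are considered the same cell when their pixel
#' overlap is at least `overlap_fraction` of the smaller ROI (default 0.3);
#' matches are resolved transitively (union-find), merged shapes are pixel
#' unions, and unmatched ROIs are kept unchanged — no ROI pixel is ever
#' lost. With `mode = "or"` the masks are instead binary-OR'ed and
#' relabelled, the simplest capture-all reading, at the cost of fusing
#' adjacent distinct cells.
#'
#' @param masks List of [label_mask()] objects on the same grid.
#' @param overlap_fraction Minimum overlap as a fraction of the smaller ROI.
#' @param mode `"overlap"` (default) or `"or"`.
#' @return A `SessionMask`: a [label_mask()] whose ROI records also carry
#'   `provenance`, a data frame of (source, roi) contributors. ROIs are
#'   ordered by centroid (row, col).
#' @export
merge_masks <- function(masks, overlap_fraction = 0.3,
                        mode = c("overlap", "or")) {
  mode <- match.arg(mode)
  stopifnot(length(masks) >= 1)
  dims <- lapply(masks, function(m) dim(m$labels))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("incompatible masks: label images differ in shape")
  }
  h <- dims[[1L]][1L]; w <- dims[[1L]][2L]
  if (mode == "or") {
    binary <- Reduce(`|`, lapply(masks, function(m) m$labels > 0L))
    lab <- label_components(binary * 1)
    sm <- label_mask(lab)
    sm <- as_session_mask(sm, provenance_or(sm, masks))
    return(sm)
  }
  # flatten all ROIs with provenance
  entries <- list()
  for (s in seq_along(masks)) {
    for (r in masks[[s]]$rois) {
      entries[[length(entries) + 1L]] <-
        list(source = s, roi = r$id,
             lin = r$pixels[, 1L] + (r$pixels[, 2L] - 1L) * h)
    }
  }
  n <- length(entries)
  if (n == 0L) {
    return(as_session_mask(label_mask(matrix(0L, h, w)), list()))
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  # pixel -> entries incidence for overlap counting
  owner <- vector("list", n)
  for (i in seq_len(n)) owner[[i]] <- entries[[i]]$lin
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (entries[[i]]$source == entries[[j]]$source) next
      ov <- length(intersect(owner[[i]], owner[[j]]))
      if (ov == 0L) next
      smaller <- min(length(owner[[i]]), length(owner[[j]]))
      if (ov >= overlap_fraction * smaller) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)
  # deterministic group order: by (row, col) centroid of the union pixels
  cent <- t(vapply(groups, function(g) {
    lin <- unique(unlist(lapply(g, function(i) entries[[i]]$lin)))
    r <- ((lin - 1L) %% h) + 1L
    c0 <- ((lin - 1L) %/% h) + 1L
    c(mean(r), mean(c0))
  }, numeric(2)))
  o <- order(cent[, 1L], cent[, 2L])
  lab <- matrix(0L, h, w)
  prov <- vector("list", length(groups))
  for (k in seq_along(o)) {
    g <- groups[[o[k]]]
    lin <- unique(unlist(lapply(g, function(i) entries[[i]]$lin)))
    lab[lin] <- k
    prov[[k]] <- data.frame(
      source = vapply(g, function(i) entries[[i]]$source, integer(1)),
      roi = vapply(g, function(i) entries[[i]]$roi, integer(1)))
  }
  as_session_mask(label_mask(lab, relabel = FALSE), prov)
}

as_session_mask <- function(mask, provenance) {
  for (k in seq_along(mask$rois)) {
    mask$rois[[k]]$provenance <-
      if (k <= length(provenance)) provenance[[k]] else
        data.frame(source = integer(), roi = integer())
  }
  class(mask) <- c("SessionMask", "LabelMask")
  mask
}

# provenance for OR mode: contributors are ROIs intersecting each component
provenance_or <- function(sm, masks) {
  h <- nrow(sm$labels)
  lapply(sm$rois, function(r) {
    lin <- r$pixels[, 1L] + (r$pixels[, 2L] - 1L) * h
    out <- NULL
    for (s in seq_along(masks)) {
      hit <- unique(masks[[s]]$labels[lin])
      hit <- hit[hit > 0L]
      if (length(hit)) {
        out <- rbind(out, data.frame(source = s, roi = sort(hit)))
      }
    }
    if (is.null(out)) data.frame(source = integer(), roi = integer()) else out
  })
}

#' @export
print.SessionMask <- function(x, ...) {
  nsrc <- length(unique(unlist(lapply(x$rois, function(r) r$provenance$source))))
  cat(sprintf("SessionMask: %d ROI(s) from %d source mask(s)\n",
              length(x$rois), nsrc))
  invisible(x)
}
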