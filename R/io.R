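# File I/O: multi-page grayscale TIFF movies, label-mask TIFF + JSON
# sidecars, shift CSVs, transform JSONs and YAML run configuration.
#
# Coordinate convention in all JSON/CSV outputs: 0-based [row, col].
# In-memory R objects are 1-based; the conversion lives entirely in this
# file.

#' Read a multi-page grayscale TIFF movie
#'
#' @param path Path to a grayscale multi-page TIFF.
#' @param fps Frame rate to attach (Hz).
#' @param scale Multiplier applied to the normalized \[0, 1\] values
#'   `tiff::readTIFF` returns; the default 65535 restores the 16-bit
#'   intensity range used by [write_stack()].
#' @return An [image_stack()].
#' @export
read_stack <- function(path, fps = 15, scale = 65535) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) != 2L) {
      stop(sprintf("unsupported format: page %d is not single-channel grayscale", i))
    }
  }
  d1 <- dim(pages[[1L]])
  data <- array(0, dim = c(d1, length(pages)))
  for (i in seq_along(pages)) {
    if (!all(dim(pages[[i]]) == d1)) {
      stop(sprintf("truncated or inconsistent TIFF at page %d", i))
    }
    data[, , i] <- pages[[i]] * scale
  }
  image_stack(data, fps = fps)
}

#' Write a movie as a multi-page grayscale TIFF
#'
#' Intensities are stored as `data / scale` in fixed-point TIFF samples; the
#' default 16-bit depth with `scale = 65535` round-trips integer-valued
#' camera intensities exactly through [read_stack()].
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @param scale Full-scale intensity mapped to the TIFF maximum.
#' @param bits Bits per sample (16 or 32).
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path, scale = 65535, bits = 16L) {
  stopifnot(inherits(stack, "ImageStack"))
  mx <- max(stack$data)
  if (mx > scale) {
    stop(sprintf("intensities exceed the TIFF full scale (%g > %g); pass a larger `scale`",
                 mx, scale))
  }
  pages <- lapply(seq_len(n_frames(stack)), function(t) stack$data[, , t] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

roi_to_json <- function(r) {
  out <- list(id = r$id,
              pixels = unname(r$pixels) - 1L,       # 0-based [row, col]
              centroid = unname(r$centroid) - 1,
              area = r$area,
              peak = if (is.na(r$peak)) NULL else r$peak)
  if (!is.null(r$provenance) && nrow(r$provenance) > 0) {
    out$provenance <- r$provenance
  }
  out
}

#' Write a label mask as TIFF plus JSON sidecar
#'
#' The label image goes to a 16-bit TIFF (32-bit float if more than 65535
#' ROIs, with a warning); ROI records (id, pixels, centroid, area, peak,
#' provenance) go to JSON with 0-based [row, col] coordinates.
#'
#' @param mask A [label_mask()] or `SessionMask`.
#' @param tiff_path,json_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, `mask`.
#' @export
write_mask <- function(mask, tiff_path = NULL, json_path = NULL) {
  stopifnot(inherits(mask, "LabelMask"))
  if (!is.null(tiff_path)) {
    mx <- max(mask$labels)
    if (mx > 65535L) {
      warning("more than 65535 labels: writing 32-bit float label TIFF")
      tiff::writeTIFF(mask$labels / (mx + 1), tiff_path, bits.per.sample = 32L)
    } else {
      tiff::writeTIFF(mask$labels / 65535, tiff_path, bits.per.sample = 16L)
    }
  }
  if (!is.null(json_path)) {
    payload <- list(shape = dim(mask$labels),
                    n_rois = length(mask$rois),
                    coordinate_convention = "0-based [row, col]",
                    rois = lapply(mask$rois, roi_to_json))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(mask)
}

#' Read a label mask from its JSON sidecar
#'
#' @param json_path Path written by [write_mask()].
#' @return A [label_mask()] (a `SessionMask` if provenance is present).
#' @export
read_mask <- function(json_path) {
  p <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  h <- p$shape[1L]; w <- p$shape[2L]
  labels <- matrix(0L, h, w)
  rois <- p$rois
  has_prov <- FALSE
  prov <- list()
  if (length(rois)) {
    # simplifyVector gives a data frame of list-columns for uniform records
    for (i in seq_len(p$n_rois)) {
      px <- if (is.data.frame(rois)) rois$pixels[[i]] else rois[[i]]$pixels
      px <- matrix(as.integer(px), ncol = 2L) + 1L
      id <- if (is.data.frame(rois)) rois$id[i] else rois[[i]]$id
      labels[px] <- id
      pv <- if (is.data.frame(rois)) rois$provenance[[i]] else rois[[i]]$provenance
      if (!is.null(pv) && NROW(pv) > 0) {
        has_prov <- TRUE
        prov[[i]] <- as.data.frame(pv)
      } else {
        prov[[i]] <- data.frame(source = integer(), roi = integer())
      }
    }
  }
  mask <- label_mask(labels, relabel = FALSE)
  if (has_prov) mask <- as_session_mask(mask, prov) else mask
}

#' Write / read a shift series as CSV
#'
#' Columns `frame` (0-based), `dx`, `dy`.
#'
#' @param shifts A [shift_series()].
#' @param path CSV path.
#' @return `write_shifts`: invisibly `path`; `read_shifts`: a
#'   [shift_series()].
#' @export
write_shifts <- function(shifts, path) {
  df <- data.frame(frame = shifts$frame - 1L, dx = shifts$dx, dy = shifts$dy)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shifts
#' @export
read_shifts <- function(path) {
  df <- utils::read.csv(path)
  shift_series(dx = df$dx, dy = df$dy)
}

#' Write / read a planar transform as JSON
#'
#' @param tf A [planar_transform()].
#' @param path JSON path.
#' @return `write_transform`: invisibly `path`; `read_transform`: a
#'   [planar_transform()].
#' @export
write_transform <- function(tf, path) {
  jsonlite::write_json(list(kind = tf$kind,
                            matrix = unname(apply(tf$matrix, 1L, c, simplify = FALSE))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- p$matrix
  if (!is.matrix(m)) m <- matrix(unlist(m), 2L, 3L, byrow = TRUE)
  planar_transform(m, kind = p$kind)
}

run_config_keys <- c("input", "output", "fps", "n_frames", "baseline_frames",
                     "algorithm", "max_shift", "template_index",
                     "coarse_to_fine", "downsample_factor", "alg1", "alg2",
                     "overlap_fraction", "merge_mode", "n_sd", "top_n",
                     "transform_override")

#' Read a YAML run configuration
#'
#' Validates that only known keys are present and returns the parsed list.
#'
#' @param path YAML file.
#' @return Named list of class `RunConfig`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(run_config_keys, collapse = ", "))
  }
  structure(cfg, class = "RunConfig")
}

#' Write a run configuration to YAML
#'
#' @param cfg Named list (keys restricted to the documented set).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(cfg, path) {
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
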