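# Internal image-processing primitives shared across modules.

#' @importFrom stats fft optim rnorm runif sd setNames
#' @importFrom utils read.csv write.csv
NULL

# 1-D Gaussian kernel of odd length `size`, normalized to sum 1.
gaussian_kernel1d <- function(sigma, size) {
  stopifnot(size >= 1, size %% 2 == 1)
  if (sigma <= 0) {
    k <- numeric(size)
    k[(size + 1L) / 2L] <- 1
    return(k)
  }
  x <- seq_len(size) - (size + 1L) / 2L
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Pad a matrix by `m` pixels on each side, replicating edge values.
pad_replicate <- function(img, m) {
  if (m == 0L) return(img)
  ri <- c(rep(1L, m), seq_len(nrow(img)), rep(nrow(img), m))
  ci <- c(rep(1L, m), seq_len(ncol(img)), rep(ncol(img), m))
  img[ri, ci, drop = FALSE]
}

# Separable 2-D convolution with a symmetric 1-D kernel, replicate boundary.
# Exact direct summation (no FFT): kernels here are short.
convolve_separable <- function(img, kernel1d, boundary = c("replicate", "zero")) {
  boundary <- match.arg(boundary)
  n <- length(kernel1d)
  m <- (n - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  if (m == 0L) return(img * kernel1d)
  if (boundary == "replicate") {
    p <- pad_replicate(img, m)
  } else {
    p <- matrix(0, h + 2L * m, w + 2L * m)
    p[(m + 1L):(m + h), (m + 1L):(m + w)] <- img
  }
  # rows
  tmp <- matrix(0, h, w + 2L * m)
  for (k in seq_len(n)) {
    tmp <- tmp + kernel1d[k] * p[(k):(k + h - 1L), , drop = FALSE]
  }
  out <- matrix(0, h, w)
  for (k in seq_len(n)) {
    out <- out + kernel1d[k] * tmp[, (k):(k + w - 1L), drop = FALSE]
  }
  out
}

# Label 8-connected components of a logical/0-1 matrix.
# Returns an integer matrix (0 = background, k = component k); components are
# numbered in raster (column-major) order of their first pixel.
label_components <- function(binary) {
  h <- nrow(binary); w <- ncol(binary)
  fg <- which(binary != 0)
  lab <- matrix(0L, h, w)
  if (length(fg) == 0L) return(lab)
  idx <- matrix(0L, h, w)
  idx[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% h) + 1L
  c0 <- ((fg - 1L) %/% h) + 1L
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rn <- r + off[1L]; cn <- c0 + off[2L]
    ok <- rn >= 1L & rn <= h & cn >= 1L & cn <= w
    if (!any(ok)) next
    nb <- idx[cbind(rn[ok], cn[ok])]
    has <- nb > 0L
    if (any(has)) {
      edges <- rbind(edges, cbind(idx[fg[ok]][has], nb[has]))
    }
  }
  if (is.null(edges)) {
    memb <- seq_along(fg)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  }
  # renumber components by first (column-major) pixel occurrence
  first_seen <- !duplicated(memb)
  renum <- integer(max(memb))
  renum[memb[first_seen]] <- seq_len(sum(first_seen))
  lab[fg] <- renum[memb]
  lab
}

# Block-mean downsample by an integer factor (trailing remainder dropped).
downsample_mean <- function(img, factor) {
  factor <- as.integer(factor)
  if (factor <= 1L) return(img)
  h <- (nrow(img) %/% factor) * factor
  w <- (ncol(img) %/% factor) * factor
  x <- img[seq_len(h), seq_len(w), drop = FALSE]
  # average factor x factor blocks
  x <- array(x, dim = c(factor, h %/% factor, w))
  x <- colMeans(x)                       # (h/f) x w
  x <- array(t(x), dim = c(factor, w %/% factor, h %/% factor))
  t(colMeans(x))                         # (h/f) x (w/f)
}

# Sample `img` at fractional (row, col) positions with bilinear interpolation.
# Positions outside the image return `fill`; `valid` marks in-range samples.
bilinear_sample <- function(img, rows, cols, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  ok <- r0 >= 1 & r0 + 1 <= h & c0 >= 1 & c0 + 1 <= w
  # clamp exact bottom/right edge into the last cell
  edge_r <- rows >= 1 & rows <= h & r0 == h
  edge_c <- cols >= 1 & cols <= w & c0 == w
  r0[edge_r] <- h - 1; fr[edge_r] <- 1
  c0[edge_c] <- w - 1; fc[edge_c] <- 1
  ok <- ok | ((r0 >= 1 & r0 + 1 <= h) & (c0 >= 1 & c0 + 1 <= w))
  out <- rep(fill, length(rows))
  if (any(ok)) {
    r0k <- r0[ok]; c0k <- c0[ok]; frk <- fr[ok]; fck <- fc[ok]
    v00 <- img[cbind(r0k, c0k)]
    v10 <- img[cbind(r0k + 1, c0k)]
    v01 <- img[cbind(r0k, c0k + 1)]
    v11 <- img[cbind(r0k + 1, c0k + 1)]
    out[ok] <- v00 * (1 - frk) * (1 - fck) + v10 * frk * (1 - fck) +
      v01 * (1 - frk) * fck + v11 * frk * fck
  }
  attr(out, "valid") <- ok
  out
}

# Nearest-neighbour sampling (for categorical label images).
nearest_sample <- function(img, rows, cols, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  r <- round(rows); c0 <- round(cols)
  ok <- r >= 1 & r <= h & c0 >= 1 & c0 <= w
  out <- rep(fill, length(rows))
  if (any(ok)) out[ok] <- img[cbind(r[ok], c0[ok])]
  attr(out, "valid") <- ok
  out
}

# Translate a matrix by integer (dr, dc): out[i, j] = img[i - dr, j - dc].
# fill = "replicate" pads with edge values, otherwise a constant.
translate_int <- function(img, dr, dc, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  src_r <- seq_len(h) - dr
  src_c <- seq_len(w) - dc
  if (identical(fill, "replicate")) {
    src_r <- pmin(pmax(src_r, 1L), h)
    src_c <- pmin(pmax(src_c, 1L), w)
    return(img[src_r, src_c, drop = FALSE])
  }
  out <- matrix(fill, h, w)
  rok <- src_r >= 1L & src_r <= h
  cok <- src_c >= 1L & src_c <= w
  if (any(rok) && any(cok)) {
    out[rok, cok] <- img[src_r[rok], src_c[cok]]
  }
  out
}
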