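# Primitive image operators composed by the two pipeline stages.
#
# Conventions (shared by all operators and their documentation):
#   * images are numeric matrices in [0,1], masks are logical matrices,
#     indexed [row, col] with origin top-left, 1-based (R convention);
#   * convolution borders use edge-repeating reflection padding;
#   * binary morphology embeds the mask in an infinite background plane
#     (outside the frame = background, for dilation and erosion alike);
#     closing pads the frame by the element radius before dilating so the
#     dilated set never touches the frame edge, then erodes and crops.
#     On this embedding closing is extensive (output contains input) and
#     idempotent.

#' Global mean thresholding
#'
#' Foreground is every pixel whose intensity strictly exceeds the global mean
#' intensity; a constant image therefore yields an all-background mask. With
#' `local = TRUE` the mean is computed per pixel over a square neighborhood
#' instead (adaptive variant).
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param local Use a local (moving-average) mean instead of the global mean.
#' @param window Side of the square neighborhood for the local variant, in
#'   pixels (odd).
#' @return Logical foreground mask of the same shape.
#' @export
mean_threshold <- function(image, local = FALSE, window = 65L) {
  check_grayscale01(image)
  if (!local) {
    return(image > mean(image))
  }
  r <- (as.integer(window) - 1L) %/% 2L
  ones <- matrix(1, nrow(image), ncol(image))
  image > box_sum(image, r) / box_sum(ones, r)
}

#' Sobel gradient magnitude
#'
#' Applies the standard 3x3 Sobel kernels and returns
#' `sqrt(Gx^2 + Gy^2)` per pixel. Borders are padded by edge-repeating
#' reflection.
#'
#' @param image Grayscale matrix, at least 3x3.
#' @return Non-negative matrix of gradient magnitudes with attribute
#'   `kernel_name = "sobel"`.
#' @export
sobel_edges <- function(image) {
  check_grayscale01(image)
  if (nrow(image) < 3L || ncol(image) < 3L) {
    stop("image smaller than the 3x3 Sobel kernel")
  }
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dx (columns)
  gx <- conv3x3(image, kx)
  gy <- conv3x3(image, t(kx))
  out <- sqrt(gx^2 + gy^2)
  attr(out, "kernel_name") <- "sobel"
  out
}

#' Roberts cross gradient magnitude
#'
#' 2x2 diagonal-difference operator; the response of each 2x2 block
#' `[[a, b], [c, d]]` is anchored at its top-left pixel as
#' `sqrt((a - d)^2 + (b - c)^2)`. The last row and column are padded by
#' reflection (edge repetition).
#'
#' @param image Grayscale matrix, at least 2x2.
#' @return Non-negative matrix of gradient magnitudes with attribute
#'   `kernel_name = "roberts"`.
#' @export
roberts_edges <- function(image) {
  check_grayscale01(image)
  h <- nrow(image); w <- ncol(image)
  if (h < 2L || w < 2L) stop("image smaller than the 2x2 Roberts kernel")
  p <- image[c(seq_len(h), h), c(seq_len(w), w)]
  a <- p[seq_len(h), seq_len(w)]
  b <- p[seq_len(h), 1L + seq_len(w)]
  cc <- p[1L + seq_len(h), seq_len(w)]
  d <- p[1L + seq_len(h), 1L + seq_len(w)]
  out <- sqrt((a - d)^2 + (b - cc)^2)
  attr(out, "kernel_name") <- "roberts"
  out
}

#' Sliding-window foreground classification of an edge map
#'
#' Scans square windows across the edge map; a window is foreground when it
#' contains at least `min_edge_count` pixels with magnitude strictly above
#' `edge_threshold`, and every pixel of a foreground window is marked.
#' Overlapping windows combine by logical OR. Window positions start at the
#' top-left corner and advance by `stride`; a final flush window is added on
#' each axis so every pixel is covered.
#'
#' @param edges Non-negative edge-magnitude matrix.
#' @param window Window side, in pixels.
#' @param stride Step between window origins, >= 1.
#' @param edge_threshold Magnitude above which a pixel counts as a hard edge.
#' @param min_edge_count Minimum number of hard-edge pixels for foreground.
#' @return Logical foreground mask.
#' @export
sliding_window_classify <- function(edges, window = 32L, stride = 16L,
                                    edge_threshold = 0.25,
                                    min_edge_count = ceiling(0.02 * window^2)) {
  stopifnot(is.matrix(edges))
  window <- as.integer(window); stride <- as.integer(stride)
  h <- nrow(edges); w <- ncol(edges)
  if (window > h || window > w) stop("window larger than image")
  if (stride < 1L) stop("stride must be >= 1")
  hard <- (edges > edge_threshold) * 1L
  # integral image: S[i+1, j+1] = sum(hard[1:i, 1:j])
  s <- matrix(0, h + 1L, w + 1L)
  s[-1L, -1L] <- apply(apply(hard, 2L, cumsum), 1L, cumsum) |> t()
  rs <- unique(c(seq.int(1L, h - window + 1L, by = stride), h - window + 1L))
  cs <- unique(c(seq.int(1L, w - window + 1L, by = stride), w - window + 1L))
  out <- matrix(FALSE, h, w)
  for (r in rs) {
    r2 <- r + window - 1L
    counts <- s[r2 + 1L, cs + window] - s[r, cs + window] -
      s[r2 + 1L, cs] + s[r, cs]
    for (k in which(counts >= min_edge_count)) {
      cl <- cs[k]
      out[r:r2, cl:(cl + window - 1L)] <- TRUE
    }
  }
  out
}

#' Morphological closing of a binary mask
#'
#' Dilation followed by erosion with a disk (Euclidean, radius `radius`) or
#' square (Chebyshev) structuring element. The mask is treated as a subset of
#' an infinite background plane: closing pads the frame by the element radius
#' before dilating (so the dilated set never touches the frame edge), erodes,
#' and crops back. On this embedding the closing is extensive
#' (`output >= input`) and idempotent.
#'
#' @param mask Logical matrix.
#' @param radius Structuring-element radius in pixels, >= 1.
#' @param shape `"disc"` (offsets with `dy^2 + dx^2 <= radius^2`) or
#'   `"square"` (side `2 * radius + 1`).
#' @return Logical matrix containing `mask`.
#' @export
morphological_close <- function(mask, radius = 3L, shape = c("disc", "square")) {
  shape <- match.arg(shape)
  stopifnot(is.matrix(mask), is.logical(mask))
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1")
  pad <- radius + 1L
  h <- nrow(mask); w <- ncol(mask)
  big <- matrix(FALSE, h + 2L * pad, w + 2L * pad)
  big[pad + seq_len(h), pad + seq_len(w)] <- mask
  out <- binary_erode(binary_dilate(big, radius, shape), radius, shape)
  out[pad + seq_len(h), pad + seq_len(w)]
}

#' @rdname morphological_close
#' @export
binary_dilate <- function(mask, radius = 3L, shape = c("disc", "square")) {
  shape <- match.arg(shape)
  if (!any(mask) || all(mask)) return(mask)
  if (shape == "disc") {
    d <- as.matrix(EBImage::distmap(matrix(as.numeric(!mask), nrow(mask))))
    mask | (d <= radius)
  } else {
    shift_or(mask, radius)
  }
}

#' @rdname morphological_close
#' @export
binary_erode <- function(mask, radius = 3L, shape = c("disc", "square")) {
  shape <- match.arg(shape)
  if (!any(mask)) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  # embed in a background ring so frame-adjacent pixels see plane background
  pad <- if (shape == "disc") 1L else radius
  big <- matrix(FALSE, h + 2L * pad, w + 2L * pad)
  big[pad + seq_len(h), pad + seq_len(w)] <- mask
  er <- if (shape == "disc") {
    d <- as.matrix(EBImage::distmap(matrix(as.numeric(big), nrow(big))))
    big & (d > radius)
  } else {
    !shift_or(!big, radius)
  }
  er[pad + seq_len(h), pad + seq_len(w)]
}

# separable square dilation by OR of shifted copies (outside = FALSE)
shift_or <- function(mask, r) {
  h <- nrow(mask); w <- ncol(mask)
  acc <- mask
  for (k in seq_len(r)) {
    acc[seq_len(h - k), ] <- acc[seq_len(h - k), ] | mask[k + seq_len(h - k), ]
    acc[k + seq_len(h - k), ] <- acc[k + seq_len(h - k), ] | mask[seq_len(h - k), ]
  }
  out <- acc
  for (k in seq_len(r)) {
    out[, seq_len(w - k)] <- out[, seq_len(w - k)] | acc[, k + seq_len(w - k)]
    out[, k + seq_len(w - k)] <- out[, k + seq_len(w - k)] | acc[, seq_len(w - k)]
  }
  out
}

# 3x3 correlation with edge-repeating reflection padding
conv3x3 <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  p <- m[c(1L, seq_len(h), h), c(1L, seq_len(w), w)]
  out <- matrix(0, h, w)
  for (i in 1:3) {
    for (j in 1:3) {
      if (k[i, j] != 0) {
        out <- out + k[i, j] * p[(i - 1L) + seq_len(h), (j - 1L) + seq_len(w)]
      }
    }
  }
  out
}

# sum over the (2r+1)^2 window centred on each pixel, truncated at borders
box_sum <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  s <- matrix(0, h + 1L, w + 1L)
  s[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  r1 <- pmax(seq_len(h) - r, 1L); r2 <- pmin(seq_len(h) + r, h)
  c1 <- pmax(seq_len(w) - r, 1L); c2 <- pmin(seq_len(w) + r, w)
  s[r2 + 1L, c2 + 1L, drop = FALSE] - s[r1, c2 + 1L, drop = FALSE] -
    s[r2 + 1L, c1, drop = FALSE] + s[r1, c1, drop = FALSE]
}

# connected-component labelling with 8-connectivity: EBImage::bwlabel is
# 4-connected, so labels touching diagonally are merged via a label graph
label8 <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask))))
  n <- max(lab)
  if (n <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1L, -1L]   # \ diagonal
  a2 <- lab[-h, -1L]; b2 <- lab[-1L, -w]   # / diagonal
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  edges <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  edges <- unique(edges)
  if (nrow(edges) == 0L) return(lab)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  map <- igraph::components(g)$membership
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  out
}

largest_component <- function(mask) {
  lab <- label8(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

remove_small_components <- function(mask, min_px) {
  if (!any(mask)) return(mask)
  lab <- label8(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask))
}

# Otsu threshold of a numeric vector (maximises between-class variance over a
# fixed-bin histogram); returns a cut value on the data scale
otsu_threshold <- function(v, nbins = 256L) {
  v <- v[is.finite(v)]
  lo <- min(v); hi <- max(v)
  if (hi - lo < .Machine$double.eps) return(hi)
  br <- seq(lo, hi, length.out = nbins + 1L)
  counts <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  p <- counts / sum(counts)
  mids <- (br[-1L] + br[-(nbins + 1L)]) / 2
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu <- mu1[nbins]
  sb <- (mu * w1 - mu1)^2 / (w1 * (1 - w1))
  sb[!is.finite(sb)] <- 0
  br[which.max(sb) + 1L]
}
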